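## helper: a minimal single-environment trial data.frame
make_plain_trial <- function(y, entries, env = "E1", block = "B1",
                             anth = NULL) {
  n <- length(entries)
  if (is.null(anth)) anth <- rep(100, n)
  TrialTable(data.frame(env = env, block = block, entry_id = entries,
                        is_check = FALSE, check_id = NA_character_,
                        days_to_anthesis = anth, y = y),
             traitNames = "y")
}

test_that("saturated case: one block, no checks, no covariate gives raw values", {
  y <- c(3.2, -1.1, 0.7, 5.0)
  tr <- make_plain_trial(y, paste0("G", 1:4))
  b <- fitBluesSingleEnv(tr, "E1", "y")
  expect_equal(unname(b[paste0("G", 1:4)]), y, tolerance = 1e-9)
})

test_that("BLUEs are invariant to adding a constant to the covariate", {
  d <- as.data.frame(fix_sim$trial)
  b1 <- fitBluesSingleEnv(fix_sim$trial, "E1", "P")
  d$days_to_anthesis <- d$days_to_anthesis + 365
  b2 <- fitBluesSingleEnv(TrialTable(d, traitNames(fix_sim$trial)), "E1", "P")
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("BLUEs are invariant to relabeling blocks", {
  d <- as.data.frame(fix_sim$trial)
  b1 <- fitBluesSingleEnv(fix_sim$trial, "E1", "P")
  d$block <- paste0("Z_", d$block)
  b2 <- fitBluesSingleEnv(TrialTable(d, traitNames(fix_sim$trial)), "E1", "P")
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("single-env BLUEs recover simulated genotype effects at high h2", {
  pars <- simParams("T1", h2 = 0.8, envSd = 1, blockSd = 0.5,
                    covariateSlope = 0.05)
  ds <- designSpec(nLines = 100, nChecks = 3, nBlocksPerEnv = 4,
                   environments = "E1")
  mk <- simulateMarkers(103, 200, seed = 61)
  sim <- simulateTrial(mk, ds, pars, seed = 62)
  b <- fitBluesSingleEnv(sim$trial, "E1", "T1")
  bv <- sim$truth@breedingValues[names(b), "T1"]
  expect_gt(cor(b, bv), 0.85)
})

test_that("combined BLUEs equal the mean of per-env BLUEs when G x E is zero", {
  pars <- simParams("T1", h2 = 0.7, gxeVar = 0, envSd = 1, blockSd = 0.3)
  ds <- designSpec(nLines = 60, nChecks = 3, nBlocksPerEnv = 2,
                   environments = c("E1", "E2"))
  mk <- simulateMarkers(63, 150, seed = 71)
  sim <- simulateTrial(mk, ds, pars, seed = 72)
  comb <- fitBluesCombined(sim$trial, "T1")
  per <- (fitBluesSingleEnv(sim$trial, "E1", "T1")[names(comb)] +
          fitBluesSingleEnv(sim$trial, "E2", "T1")[names(comb)]) / 2
  expect_equal(length(comb), 60)
  ## equal up to a common constant (each model's intercept differs)
  centred <- (comb - mean(comb)) - (per - mean(per))
  expect_lt(sd(centred), 0.1 * sd(comb))
  expect_gt(cor(comb, per), 0.98)
})

test_that("combined BLUEs track true breeding values at high h2", {
  pars <- simParams("T1", h2 = 0.8, gxeVar = 0.2, envSd = 1, blockSd = 0.5,
                    covariateSlope = 0.03)
  ds <- designSpec(nLines = 236, nChecks = 3, nBlocksPerEnv = 6,
                   environments = c("E1", "E2", "E3"))
  mk <- simulateMarkers(239, 300, seed = 81)
  sim <- simulateTrial(mk, ds, pars, seed = 82)
  b <- fitBluesCombined(sim$trial, "T1")
  expect_equal(length(b), 236)
  bv <- sim$truth@breedingValues[names(b), "T1"]
  ## the attainable ceiling is sqrt(H2) = 0.894 at H2 = 0.8
  expect_gt(cor(b, bv), 0.85)
})

test_that("computeBlues assembles all traits with one row per test entry", {
  blues <- computeBlues(fix_sim$trial, dataset = "E1")
  expect_s4_class(blues, "BlueTable")
  expect_equal(dim(as.matrix(blues)), c(40, 3))
  expect_equal(traitNames(blues), c("P", "S1", "S2"))
  expect_false(any(grepl("CHK", lineIds(blues))))
})

test_that("ANOVA mean squares match a textbook two-way oracle on balanced data", {
  ## 2 genotypes x 2 environments x 3 replicates, no blocks, no checks
  set.seed(10)
  g <- rep(c(0, 1), each = 6)
  e <- rep(rep(c(0, 2), each = 3), 2)
  y <- 5 + g + e + rnorm(12, sd = 0.5)
  d <- data.frame(env = rep(rep(c("E1", "E2"), each = 3), 2),
                  block = "B1",
                  entry_id = rep(c("G1", "G2"), each = 6),
                  is_check = FALSE, check_id = NA_character_,
                  days_to_anthesis = 100, y = y)
  a <- anovaMeanSquares(TrialTable(d, "y"), "y")
  ## hand-computed sums of squares
  ybar <- mean(y)
  ss_g <- 6 * sum((tapply(y, d$entry_id, mean) - ybar)^2)
  ss_e <- 6 * sum((tapply(y, d$env, mean) - ybar)^2)
  cell <- tapply(y, interaction(d$entry_id, d$env), mean)
  ss_cells <- 3 * sum((cell - ybar)^2)
  ss_ge <- ss_cells - ss_g - ss_e
  expect_equal(a$mean_sq[a$term == "Genotype (G)"], ss_g / 1, tolerance = 1e-8)
  expect_equal(a$mean_sq[a$term == "Environment (E)"], ss_e / 1, tolerance = 1e-8)
  expect_equal(a$mean_sq[a$term == "Interaction (G x E)"], ss_ge / 1,
               tolerance = 1e-8)
  expect_equal(a$df, c(1, 1, 1, 8))
})

test_that("large environment effects dominate the residual mean square", {
  pars <- simParams("T1", h2 = 0.5, gxeVar = 0.1, envSd = 10, blockSd = 0.2)
  ds <- designSpec(nLines = 50, nChecks = 3, nBlocksPerEnv = 3,
                   environments = c("E1", "E2", "E3"))
  mk <- simulateMarkers(53, 100, seed = 91)
  sim <- simulateTrial(mk, ds, pars, seed = 92)
  a <- anovaMeanSquares(sim$trial, "T1")
  expect_gt(a$mean_sq[a$term == "Environment (E)"],
            20 * a$mean_sq[a$term == "Residual"])
  expect_error(anovaMeanSquares(make_plain_trial(rnorm(4), paste0("G", 1:4)), "y"),
               "environments")
})

test_that("genotype and interaction tests hold their size under the null", {
  ## zero genotypic and interaction variance: rejection rate at 5% must stay
  ## inside the binomial envelope over 200 simulated trials
  set.seed(123)
  n_gen <- 8; n_env <- 2; n_blk <- 3
  pg <- pge <- numeric(200)
  for (r in 1:200) {
    d <- expand.grid(entry_id = paste0("G", 1:n_gen),
                     env = paste0("E", 1:n_env), block = paste0("B", 1:n_blk))
    d$is_check <- FALSE; d$check_id <- NA_character_
    d$days_to_anthesis <- 100
    env_eff <- rnorm(n_env, sd = 1)[as.integer(factor(d$env))]
    d$y <- 3 + env_eff + rnorm(nrow(d))
    a <- anovaMeanSquares(TrialTable(d, "y"), "y")
    pg[r] <- a$p[a$term == "Genotype (G)"]
    pge[r] <- a$p[a$term == "Interaction (G x E)"]
  }
  ## 200 trials at alpha = .05: 95% binomial interval is roughly [0.02, 0.09]
  expect_gt(mean(pg < 0.05), 0.01); expect_lt(mean(pg < 0.05), 0.10)
  expect_gt(mean(pge < 0.05), 0.01); expect_lt(mean(pge < 0.05), 0.10)
})

test_that("broad-sense heritability evaluates its closed form exactly", {
  expect_equal(broadSenseHeritability(VarianceComponents(1, 0, 0, nEnv = 3)), 1)
  expect_equal(broadSenseHeritability(VarianceComponents(1, 1, 1, nEnv = 2)), 0.5)
  expect_error(broadSenseHeritability(VarianceComponents(0, 0, 0, nEnv = 2)),
               "undefined")
  expect_error(VarianceComponents(-1, 0, 1, nEnv = 2), "non-negative")
})

test_that("H2 is monotone in its components", {
  h2 <- function(g, ge, e, n) broadSenseHeritability(
    VarianceComponents(g, ge, e, nEnv = n))
  expect_gt(h2(2, 1, 1, 3), h2(1, 1, 1, 3))   # increasing in sigma2G
  expect_gt(h2(1, 1, 1, 4), h2(1, 1, 1, 3))   # increasing in n
  expect_lt(h2(1, 2, 1, 3), h2(1, 1, 1, 3))   # decreasing in sigma2GxE
  expect_lt(h2(1, 1, 2, 3), h2(1, 1, 1, 3))   # decreasing in sigma2e
})

test_that("variance components recover a true H2 of 0.4 across replicates", {
  pars <- simParams("T1", h2 = 0.4, gxeVar = 0.4, envSd = 1, blockSd = 0.4)
  ds <- designSpec(nLines = 100, nChecks = 3, nBlocksPerEnv = 3,
                   environments = c("E1", "E2", "E3"))
  ests <- vapply(1:10, function(r) {
    mk <- simulateMarkers(103, 150, seed = 100 + r)
    sim <- simulateTrial(mk, ds, pars, seed = 200 + r)
    broadSenseHeritability(estimateVarianceComponents(sim$trial, "T1"))
  }, numeric(1))
  expect_gt(mean(ests), 0.3)
  expect_lt(mean(ests), 0.5)
})

test_that("trait correlations: identity, sign flip, constant columns", {
  blues <- computeBlues(fix_sim$trial, dataset = "E1")
  ct <- traitCorrelations(blues)
  expect_equal(diag(ct$r), c(P = 1, S1 = 1, S2 = 1))
  expect_equal(ct$r, t(ct$r))
  v <- as.matrix(blues)
  v[, "S1"] <- -v[, "S1"]
  ct2 <- traitCorrelations(BlueTable(v, "E1"))
  expect_equal(ct2$r["P", "S1"], -ct$r["P", "S1"], tolerance = 1e-12)
  v[, "S2"] <- 1  # constant column: undefined correlations reported missing
  ct3 <- traitCorrelations(BlueTable(v, "E1"))
  expect_true(is.na(ct3$r["P", "S2"]))
})
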