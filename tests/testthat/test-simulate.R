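test_that("simulated markers use the -1/0/+1 coding with the requested shape", {
  m <- simulateMarkers(236, 1000, mafRange = c(0.05, 0.5), missingRate = 0,
                       seed = 1)
  codes <- as.matrix(m)
  expect_equal(dim(codes), c(236, 1000))
  expect_true(all(codes %in% c(-1, 0, 1)))
  expect_false(anyNA(codes))
  expect_equal(length(unique(lineIds(m))), 236)
})

test_that("missingness lands at the requested rate (binomial oracle)", {
  m <- simulateMarkers(236, 1000, missingRate = 0.1, seed = 1)
  frac <- mean(is.na(as.matrix(m)))
  ## binomial count: sd of the observed fraction is ~0.0006 at 236,000 cells,
  ## so +/-0.02 is a generous envelope around 0.1
  expect_lt(abs(frac - 0.1), 0.02)
})

test_that("marker simulation is reproducible and validates its parameters", {
  a <- simulateMarkers(20, 50, seed = 9)
  b <- simulateMarkers(20, 50, seed = 9)
  expect_identical(as.matrix(a), as.matrix(b))
  expect_error(simulateMarkers(20, 50, mafRange = c(0.2, 0.6)), "mafRange")
  expect_error(simulateMarkers(20, 50, mafRange = c(0.4, 0.2)), "mafRange")
  expect_error(simulateMarkers(20, 50, missingRate = 1), "missingRate")
  expect_error(simulateMarkers(1, 50), "nLines")
})

test_that("allele frequencies follow the requested MAF interval", {
  m <- simulateMarkers(500, 300, mafRange = c(0.3, 0.4), seed = 3)
  ## minor allele count per marker = #(-1)*2 + #(0); frequency in [0.3, 0.4]
  codes <- as.matrix(m)
  maf <- colMeans(1 - codes) / 2
  expect_gt(min(maf), 0.2)   # sampling noise around the drawn frequency
  expect_lt(max(maf), 0.5)
  expect_gt(mean(maf), 0.3)
  expect_lt(mean(maf), 0.4)
})

test_that("the simulated trial is a valid augmented design", {
  d <- as.data.frame(fix_sim$trial)
  ## each (env, block) holds every check exactly once
  for (env in unique(d$env)) for (blk in unique(d$block)) {
    here <- d[d$env == env & d$block == blk, ]
    expect_equal(sort(here$check_id[here$is_check]),
                 sort(unique(d$check_id[d$is_check])))
    expect_equal(anyDuplicated(here$entry_id[!here$is_check]), 0L)
  }
  ## every test entry appears exactly once per environment (r = 1)
  tab <- table(d$entry_id[!d$is_check], d$env[!d$is_check])
  expect_true(all(tab == 1))
})

test_that("trial simulation is bit-reproducible under a seed", {
  again <- simulateTrial(fix_trial_markers, fix_design, fix_params, seed = 11)
  expect_identical(as.data.frame(again$trial), as.data.frame(fix_sim$trial))
  expect_identical(again$truth@breedingValues, fix_sim$truth@breedingValues)
  other <- simulateTrial(fix_trial_markers, fix_design, fix_params, seed = 12)
  expect_false(identical(as.data.frame(other$trial), as.data.frame(fix_sim$trial)))
})

test_that("stored heritabilities are recomputable from the stored components", {
  tr <- fix_sim$truth
  h2 <- diag(tr@geneticCovariance) /
    (diag(tr@geneticCovariance) + tr@gxeVariances / tr@nEnv +
       tr@residualVariances / (tr@nEnv * tr@nRep))
  expect_equal(unname(h2), unname(tr@heritabilities), tolerance = 1e-10)
  expect_equal(unname(tr@heritabilities), fix_params$h2, tolerance = 1e-10)
})

test_that("independent traits with no GxE show near-zero cross-trait correlation", {
  pars <- simParams(c("A", "B"), h2 = c(0.5, 0.5), geneticCor = diag(2),
                    gxeVar = c(0, 0), envSd = c(1, 1), blockSd = 0.3)
  ds <- designSpec(nLines = 200, nChecks = 3, nBlocksPerEnv = 4,
                   environments = "E1")
  mk <- simulateMarkers(203, 300, seed = 31)
  sim <- simulateTrial(mk, ds, pars, seed = 32)
  d <- as.data.frame(sim$trial)
  d <- d[!d$is_check, ]
  r <- cor(d$A, d$B)
  expect_lt(abs(r), 3 / sqrt(nrow(d)))  # within MC error of zero
})

test_that("realized heritability matches the target (single env, r = 1)", {
  pars <- simParams("T1", h2 = 0.5, envSd = 1, blockSd = 0)
  ds <- designSpec(nLines = 236, nChecks = 3, nBlocksPerEnv = 1,
                   environments = "E1")
  mk <- simulateMarkers(239, 500, seed = 41)
  sim <- simulateTrial(mk, ds, pars, seed = 42)
  d <- as.data.frame(sim$trial); d <- d[!d$is_check, ]
  bv <- sim$truth@breedingValues[d$entry_id, "T1"]
  h2_real <- var(bv) / var(d$T1)
  expect_gt(h2_real, 0.4)
  expect_lt(h2_real, 0.6)
})

test_that("a requested genetic correlation shows up in breeding values and phenotypes", {
  pars <- simParams(c("P", "S"), h2 = c(0.5, 0.5),
                    geneticCor = matrix(c(1, .6, .6, 1), 2),
                    envSd = c(1, 1), blockSd = 0.3)
  ds <- designSpec(nLines = 236, nChecks = 3, nBlocksPerEnv = 4,
                   environments = "E1")
  mk <- simulateMarkers(239, 400, seed = 51)
  sim <- simulateTrial(mk, ds, pars, seed = 52)
  bv <- sim$truth@breedingValues
  ct <- cor.test(bv[, "P"], bv[, "S"])
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  expect_lt(abs(ct$estimate - 0.6), 0.15)
  d <- as.data.frame(sim$trial); d <- d[!d$is_check, ]
  expect_gt(cor(d$P, d$S), 0)  # attenuated but positive at the plot level
})

test_that("invalid simulation parameters are rejected", {
  bad_cor <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3, 3)  # not PSD
  expect_error(simParams(c("A", "B", "C"), h2 = rep(.5, 3), geneticCor = bad_cor),
               "positive semi-definite")
  expect_error(simParams("A", h2 = 1.2), "h2")
  ## gxe too large for the requested h2 given one environment
  expect_error(
    simulateTrial(fix_trial_markers,
                  designSpec(nLines = 40, nChecks = 3, nBlocksPerEnv = 2,
                             environments = "E1"),
                  simParams("P", h2 = 0.9, gxeVar = 2), seed = 1),
    "unreachable")
  expect_error(simulateTrial(fix_markers, fix_design, fix_params, seed = 1),
               "rows")
})

test_that("the study-patterned defaults are internally consistent", {
  p <- defaultSimParams()
  expect_equal(p$traits, c("HI", "GY", "GN", "SPI", "FE", "NDVI", "CT"))
  expect_equal(p$h2[p$traits == "NDVI"], 0.64)
  ev <- eigen(p$geneticCor, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  ## NDVI correlates positively, CT negatively, with the yield traits
  expect_gt(p$geneticCor["GY", "NDVI"], 0)
  expect_lt(p$geneticCor["GY", "CT"], 0)
})
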