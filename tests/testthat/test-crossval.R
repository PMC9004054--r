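test_that("split sizes follow the 70/30 floor rule", {
  sp <- makeSplits(sprintf("G%03d", 1:236), trainFraction = 0.7, nReps = 25,
                   seed = 3)
  expect_length(sp, 25)
  expect_true(all(vapply(sp, function(s) length(s$trainIds), 1L) == 165))
  expect_true(all(vapply(sp, function(s) length(s$testIds), 1L) == 71))
  sp10 <- makeSplits(sprintf("G%02d", 1:10), nReps = 3, seed = 1)
  expect_equal(length(sp10[[1]]$trainIds), 7)
  expect_equal(length(sp10[[1]]$testIds), 3)
})

test_that("each split is a clean partition, reproducible under the seed", {
  ids <- sprintf("G%03d", 1:50)
  a <- makeSplits(ids, nReps = 10, seed = 42)
  b <- makeSplits(ids, nReps = 10, seed = 42)
  expect_identical(a, b)
  for (s in a) {
    expect_length(intersect(s$trainIds, s$testIds), 0)
    expect_setequal(c(s$trainIds, s$testIds), ids)
  }
  expect_error(makeSplits(ids, trainFraction = 1.2), "trainFraction")
  expect_error(makeSplits(ids[1:5]), "at least 10")
})

test_that("pairwise train-set overlap matches the hypergeometric expectation", {
  ids <- sprintf("G%03d", 1:236)
  sp <- makeSplits(ids, nReps = 100, seed = 7)
  ## independent 165-of-236 draws: E[overlap] = 165^2 / 236 = 115.4
  ov <- vapply(seq_len(99), function(i)
    length(intersect(sp[[i]]$trainIds, sp[[i + 1]]$trainIds)), 1L)
  expect_lt(abs(mean(ov) - 165^2 / 236), 5)
})

test_that("percent increase reproduces the published arithmetic", {
  mk_res <- function(scheme, meanr) new("CvResult", scheme = scheme,
    trait = "GY", datasetLabel = "C18", perRepR = meanr, meanR = meanr,
    seR = 0.01, nValidReps = 1, predictions = list())
  ## published pairs: 0.21 -> 0.50 prints as 138.1; 0.13 -> 0.31 as 138.5
  expect_equal(round(percentIncrease(mk_res("ST-CV1", 0.21), mk_res("MT-CV2", 0.50)), 1),
               138.1)
  expect_equal(round(percentIncrease(mk_res("ST-CV1", 0.13), mk_res("MT-CV2", 0.31)), 1),
               138.5)
  expect_equal(percentIncrease(mk_res("ST-CV1", 0.20), mk_res("MT-CV2", 0.20)), 0)
  expect_warning(p <- percentIncrease(mk_res("ST-CV1", -0.1), mk_res("MT-CV2", 0.3)),
                 "not positive")
  expect_true(is.na(p))
  bad <- mk_res("MT-CV2", 0.3); bad@trait <- "HI"
  expect_error(percentIncrease(mk_res("ST-CV1", 0.2), bad), "different")
})

test_that("mask specifications enforce scheme requirements", {
  expect_s4_class(maskSpec("ST-CV1", "P"), "MaskSpec")
  expect_error(maskSpec("MT-CV2", "P"), "secondary")
  expect_error(maskSpec("MT-CV1", "P", "P"), "primary")
  expect_error(maskSpec("CV9", "P", "S"), "scheme")
})

## small CV setup shared by the scheme tests: correlated secondary helps
cv_blues <- local({
  km <- as.matrix(fix_K)
  e <- eigen(km, symmetric = TRUE)
  set.seed(61)
  G <- (e$vectors %*% (sqrt(pmax(e$values, 0)) * matrix(rnorm(60 * 2), 60, 2))) %*%
    chol(matrix(c(1, .7, .7, 1), 2))
  Y <- G + cbind(rnorm(60, sd = 1), rnorm(60, sd = 0.5))
  dimnames(Y) <- list(rownames(km), c("P", "S"))
  BlueTable(Y, "sim")
})
cv_splits <- makeSplits(lineIds(cv_blues), nReps = 3, seed = 71)
cv_cfg <- gibbsConfig(burnIn = 200, nIter = 1200, seed = 81)

test_that("all three schemes run and aggregate valid replicates", {
  for (sch in c("ST-CV1", "MT-CV1", "MT-CV2")) {
    res <- runScheme(cv_blues, fix_K, maskSpec(sch, "P", "S"), cv_splits, cv_cfg)
    expect_s4_class(res, "CvResult")
    expect_equal(res@nValidReps, 3)
    expect_length(res@perRepR, 3)
    expect_true(all(abs(res@perRepR) <= 1))
    expect_equal(res@meanR, mean(res@perRepR))
  }
})

test_that("identical seeds give identical CV results", {
  r1 <- runScheme(cv_blues, fix_K, maskSpec("MT-CV2", "P", "S"), cv_splits, cv_cfg)
  r2 <- runScheme(cv_blues, fix_K, maskSpec("MT-CV2", "P", "S"), cv_splits, cv_cfg)
  expect_identical(r1@perRepR, r2@perRepR)
})

test_that("held-out primary phenotypes are provably unused in fitting", {
  ## corrupt the test lines' primary values; every scheme's predictions must
  ## be bit-identical because masking removes those cells before fitting
  for (sch in c("ST-CV1", "MT-CV1", "MT-CV2")) {
    base <- runScheme(cv_blues, fix_K, maskSpec(sch, "P", "S"), cv_splits,
                      cv_cfg, keepPredictions = TRUE)
    for (i in seq_along(cv_splits)) {
      s <- cv_splits[[i]]
      v <- as.matrix(cv_blues)
      v[s$testIds, "P"] <- 999          # corrupt this replicate's held-out cells
      if (sch == "MT-CV1") v[s$testIds, "S"] <- -999
      corrupted <- runScheme(BlueTable(v, "sim"), fix_K, maskSpec(sch, "P", "S"),
                             list(s), cv_cfg, keepPredictions = TRUE)
      expect_identical(base@predictions[[i]], corrupted@predictions[[i]])
    }
  }
})

test_that("replicates with undefined correlation are excluded, not zero-filled", {
  v <- as.matrix(cv_blues)
  v[, "P"] <- 7  # constant observations: correlation undefined in every rep
  suppressMessages({
    res <- runScheme(BlueTable(v, "sim"), fix_K, maskSpec("ST-CV1", "P"),
                     cv_splits, cv_cfg)
  })
  expect_equal(res@nValidReps, 0)
  expect_true(all(is.na(res@perRepR)))
})

test_that("a single secondary trait is a valid multi-trait configuration", {
  res_one <- runScheme(cv_blues, fix_K, maskSpec("MT-CV2", "P", "S"),
                       cv_splits, cv_cfg)
  expect_equal(res_one@nValidReps, 3)
})

test_that("missing trait columns are reported by name", {
  expect_error(runScheme(cv_blues, fix_K, maskSpec("MT-CV2", "P", "NDVI"),
                         cv_splits, cv_cfg), "NDVI")
})
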