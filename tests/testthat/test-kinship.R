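test_that("mean imputation fills with the observed marker mean and nothing else", {
  ## columns: m1 = (-1, 0, 1); m2 = (NA, 0, NA); m3 = (1, 0, NA)
  m <- matrix(c(-1, 0, 1,
                NA, 0, NA,
                 1, 0, NA), nrow = 3, byrow = FALSE,
              dimnames = list(paste0("L", 1:3), paste0("m", 1:3)))
  out <- as.matrix(imputeMissing(MarkerMatrix(m)))
  expect_equal(out["L1", "m2"], 0)          # mean of the single observed 0
  expect_equal(out["L3", "m3"], 0.5)        # mean of (1, 0)
  obs <- !is.na(m)
  expect_identical(out[obs], m[obs])        # observed cells untouched
})

test_that("a column (-1, missing, +1) imputes to (-1, 0, +1)", {
  m <- matrix(c(-1, NA, 1), 3, 1, dimnames = list(paste0("L", 1:3), "m1"))
  out <- as.matrix(imputeMissing(MarkerMatrix(m)))
  expect_equal(drop(out), c(L1 = -1, L2 = 0, L3 = 1))
})

test_that("a complete matrix is returned unchanged, bit-identical", {
  expect_identical(imputeMissing(fix_markers), fix_markers)
})

test_that("an all-missing marker raises an error naming it", {
  m <- matrix(c(-1, 1, NA, NA), 2, 2,
              dimnames = list(c("L1", "L2"), c("ok", "bad")))
  expect_error(imputeMissing(MarkerMatrix(m)), "bad")
})

test_that("knn imputation matches a brute-force nearest-neighbour oracle", {
  set.seed(77)
  m <- matrix(sample(c(-1, 0, 1), 10 * 20, replace = TRUE), 10, 20,
              dimnames = list(sprintf("L%02d", 1:10), sprintf("m%02d", 1:20)))
  m[1, 3] <- NA; m[4, 7] <- NA; m[9, 20] <- NA
  out <- as.matrix(imputeMissing(MarkerMatrix(m), method = "knn", k = 3))
  ## brute-force oracle: rank lines by RMS distance over shared markers
  for (cell in list(c(1, 3), c(4, 7), c(9, 20))) {
    i <- cell[1]; jm <- cell[2]
    d <- sapply(1:10, function(j) {
      if (j == i) return(Inf)
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      sqrt(mean((m[i, ok] - m[j, ok])^2))
    })
    nb <- order(d)[1:3]
    expected <- round(mean(m[nb, jm], na.rm = TRUE))
    expect_equal(out[i, jm], expected)
    expect_true(out[i, jm] %in% c(-1, 0, 1))
  }
})

test_that("K matches a brute-force per-entry sum on a 5 x 8 hand example", {
  set.seed(5)
  m <- matrix(sample(c(-1, 0, 1), 40, replace = TRUE), 5, 8,
              dimnames = list(paste0("L", 1:5), paste0("m", 1:8)))
  K <- as.matrix(additiveRelationship(MarkerMatrix(m)))
  ## oracle: direct summation, entry by entry
  f <- (colMeans(m) + 1) / 2
  keep <- f > 0 & f < 1
  cc <- sum(2 * f[keep] * (1 - f[keep]))
  expected <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    s <- 0
    for (k in which(keep)) {
      s <- s + (m[i, k] - mean(m[, k])) * (m[j, k] - mean(m[, k]))
    }
    expected[i, j] <- s / cc
  }
  expect_lt(max(abs(K - expected)), 1e-6)
})

test_that("two identical lines have K[1,2] = K[1,1]", {
  m <- as.matrix(simulateMarkers(6, 100, seed = 13))
  m[2, ] <- m[1, ]
  K <- as.matrix(additiveRelationship(MarkerMatrix(m)))
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-10)
})

test_that("the mean diagonal of K is near 1 under HWE (Monte-Carlo oracle)", {
  K <- as.matrix(additiveRelationship(simulateMarkers(200, 2000, seed = 17)))
  expect_gt(mean(diag(K)), 0.9)
  expect_lt(mean(diag(K)), 1.3)
})

test_that("K is invariant to marker order and to duplicating every column", {
  m <- as.matrix(fix_markers)
  K1 <- as.matrix(additiveRelationship(MarkerMatrix(m)))
  perm <- sample(ncol(m))
  K2 <- as.matrix(additiveRelationship(MarkerMatrix(m[, perm])))
  expect_equal(K1, K2, tolerance = 1e-12)
  dbl <- cbind(m, m)
  colnames(dbl) <- sprintf("M%05d", seq_len(ncol(dbl)))
  K3 <- as.matrix(additiveRelationship(MarkerMatrix(dbl)))
  expect_equal(K1, K3, tolerance = 1e-12)
})

test_that("K is PSD (stabilized if needed) and degenerate inputs error", {
  ev <- eigen(as.matrix(fix_K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  mono <- matrix(1, 4, 3, dimnames = list(paste0("L", 1:4), paste0("m", 1:3)))
  expect_error(additiveRelationship(MarkerMatrix(mono)), "degenerate")
  expect_error(additiveRelationship(simulateMarkers(5, 10, missingRate = 0.3,
                                                    seed = 1)),
               "missing")
})

test_that("minimum-MAF filtering drops rare markers from K's scale", {
  m <- as.matrix(simulateMarkers(50, 200, mafRange = c(0.02, 0.5), seed = 23))
  K_all <- additiveRelationship(MarkerMatrix(m))
  K_maf <- additiveRelationship(MarkerMatrix(m), minMaf = 0.2)
  expect_false(identical(as.matrix(K_all), as.matrix(K_maf)))
  ## oracle: manual filter then plain computation
  f <- (colMeans(m) + 1) / 2
  keep <- pmin(f, 1 - f) >= 0.2 & f > 0 & f < 1
  K_manual <- additiveRelationship(MarkerMatrix(m[, keep]))
  expect_equal(as.matrix(K_maf), as.matrix(K_manual), tolerance = 1e-12)
})

test_that("subsetKinship reorders and errors on unknown lines", {
  ids <- rev(lineIds(fix_K))[1:5]
  Ks <- subsetKinship(fix_K, ids)
  expect_equal(lineIds(Ks), ids)
  expect_equal(as.matrix(Ks), as.matrix(fix_K)[ids, ids])
  expect_error(subsetKinship(fix_K, "nope"), "unknown")
})
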