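## Shared fixtures, built once per test run. Sizes are kept small; anything
## that needs the study scale builds its own data locally.

## small marker panel + kinship reused by the sampler tests
fix_markers <- simulateMarkers(60, 400, seed = 421)
fix_K <- additiveRelationship(fix_markers)

## a tiny augmented 2-environment trial with 3 traits and known truth
fix_design <- designSpec(nLines = 40, nChecks = 3, nBlocksPerEnv = 2,
                         environments = c("E1", "E2"))
fix_params <- simParams(c("P", "S1", "S2"), h2 = c(0.4, 0.6, 0.6),
                        geneticCor = matrix(c(1, .5, .3,
                                              .5, 1, .2,
                                              .3, .2, 1), 3, 3),
                        gxeVar = c(0.2, 0.1, 0.1),
                        envSd = rep(1, 3), blockSd = 0.5,
                        covariateSlope = c(0.05, 0.02, 0))
fix_trial_markers <- simulateMarkers(43, 200, seed = 7)
fix_sim <- simulateTrial(fix_trial_markers, fix_design, fix_params, seed = 11)

## simulate a phenotype vector with known variance components on a kinship
sim_y_on_K <- function(K, s2g, s2e, mu = 0, seed = 1) {
  km <- as.matrix(K)
  e <- eigen(km, symmetric = TRUE)
  local_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); force(code)
  }
  local_seed(seed, {
    g <- e$vectors %*% (sqrt(pmax(e$values, 0) * s2g) * rnorm(nrow(km)))
    y <- mu + g + rnorm(nrow(km), sd = sqrt(s2e))
    list(y = setNames(drop(y), rownames(km)), g = drop(g))
  })
}
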