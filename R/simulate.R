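## Synthetic marker panels and augmented multi-environment trials with known
## ground truth. The generator follows an additive infinitesimal model: MVN
## breeding values on the realized genomic relationship matrix, independent
## per-(genotype, env, trait) G x E draws, and a genotype-level anthesis-date
## covariate with an additive effect on every trait.

#' DesignSpec: layout of an augmented multi-environment trial
#'
#' @slot nLines number of unreplicated test entries.
#' @slot nChecks number of repeated check varieties per block (default 3).
#' @slot nBlocksPerEnv blocks within each environment.
#' @slot environments environment labels.
#' @slot trainFraction default training proportion for cross-validation.
#' @slot nRep replications of each test entry per environment (1 = augmented).
#' @export
setClass("DesignSpec",
  representation(nLines = "numeric", nChecks = "numeric",
                 nBlocksPerEnv = "numeric", environments = "character",
                 trainFraction = "numeric", nRep = "numeric")
)

setValidity("DesignSpec", function(object) {
  if (object@nLines < 2) return("need at least 2 test entries")
  if (object@nChecks < 0) return("nChecks cannot be negative")
  if (object@nBlocksPerEnv < 1) return("need at least one block per environment")
  if (length(object@environments) < 1) return("need at least one environment")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must lie in (0, 1)")
  if (object@nRep < 1) return("nRep must be >= 1")
  TRUE
})

#' Construct a DesignSpec
#'
#' Defaults mirror the study layout: 236 test entries, 3 repeated checks per
#' block, three environments, 70% training fraction, one replication per
#' environment (augmented design).
#'
#' @param nLines,nChecks,nBlocksPerEnv,environments,trainFraction,nRep see
#'   \code{\linkS4class{DesignSpec}}.
#' @return a \code{DesignSpec}.
#' @export
designSpec <- function(nLines = 236, nChecks = 3, nBlocksPerEnv = 6,
                       environments = c("Q17", "Q18", "C18"),
                       trainFraction = 0.7, nRep = 1) {
  new("DesignSpec", nLines = nLines, nChecks = nChecks,
      nBlocksPerEnv = nBlocksPerEnv, environments = as.character(environments),
      trainFraction = trainFraction, nRep = nRep)
}

## run code under a seed without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a biallelic SNP marker panel
#'
#' Per-marker minor allele frequencies are drawn uniformly from
#' \code{mafRange}; genotypes are sampled under Hardy-Weinberg equilibrium and
#' coded -1 (homozygous minor), 0 (heterozygous), +1 (homozygous major).
#' Missing calls are dropped independently at rate \code{missingRate}.
#'
#' @param nLines number of lines (rows); >= 2.
#' @param nMarkers number of SNPs (columns); >= 1.
#' @param mafRange length-2 interval inside (0, 0.5] for the minor allele
#'   frequency.
#' @param missingRate per-cell missing probability in [0, 1).
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @param lineIds optional row names (defaults to L001, L002, ...).
#' @return a \code{\linkS4class{MarkerMatrix}}.
#' @examples
#' m <- simulateMarkers(20, 50, seed = 1)
#' table(as.matrix(m))
#' @export
simulateMarkers <- function(nLines, nMarkers, mafRange = c(0.05, 0.5),
                            missingRate = 0, seed = 1, lineIds = NULL) {
  if (nLines < 2) stop("nLines must be >= 2")
  if (nMarkers < 1) stop("nMarkers must be >= 1")
  if (length(mafRange) != 2 || mafRange[1] > mafRange[2] ||
      mafRange[1] <= 0 || mafRange[2] > 0.5)
    stop("mafRange must be an interval inside (0, 0.5]")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  if (is.null(lineIds)) lineIds <- sprintf("L%03d", seq_len(nLines))

  codes <- local_seed(seed, {
    maf <- runif(nMarkers, mafRange[1], mafRange[2])
    ## minor-allele count per line per marker under HWE
    cnt <- matrix(rbinom(nLines * nMarkers, 2, rep(maf, each = nLines)),
                  nrow = nLines)
    m <- 1 - cnt  # 0 copies -> +1 (major hom), 1 -> 0 (het), 2 -> -1 (minor hom)
    if (missingRate > 0)
      m[matrix(runif(nLines * nMarkers) < missingRate, nrow = nLines)] <- NA
    m
  })
  dimnames(codes) <- list(lineIds, sprintf("M%05d", seq_len(nMarkers)))
  MarkerMatrix(codes)
}

#' Simulation parameters for \code{simulateTrial}
#'
#' Per-trait genetic variances default to 1 (traits are simulated on a
#' standardized scale); residual variances are derived from the target
#' heritabilities by inverting
#' \eqn{H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{G\times E}/n + \sigma^2_e/(nr))},
#' so the requested \code{h2} is exactly the broad-sense heritability implied
#' by the generated components for the design at hand.
#'
#' @param traits character vector of trait names.
#' @param h2 per-trait target broad-sense heritability in (0, 1].
#' @param geneticCor t x t genetic correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite).
#' @param geneticVar per-trait genetic variance (default 1).
#' @param gxeVar per-trait genotype-by-environment variance.
#' @param envSd per-trait SD of environment main effects.
#' @param blockSd SD of block effects within environment.
#' @param mu per-trait overall mean.
#' @param covariateSlope per-trait phenotype change per day of anthesis date.
#' @param anthesisMean,anthesisSd distribution of genotype-level days to
#'   anthesis.
#' @return a validated parameter list for \code{\link{simulateTrial}}.
#' @export
simParams <- function(traits, h2,
                      geneticCor = diag(length(traits)),
                      geneticVar = rep(1, length(traits)),
                      gxeVar = rep(0, length(traits)),
                      envSd = rep(2, length(traits)),
                      blockSd = 0.5,
                      mu = rep(0, length(traits)),
                      covariateSlope = rep(0, length(traits)),
                      anthesisMean = 105, anthesisSd = 5) {
  t <- length(traits)
  stopifnot(length(h2) == t, length(geneticVar) == t, length(gxeVar) == t,
            length(envSd) == t, length(mu) == t, length(covariateSlope) == t)
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must lie in (0, 1]")
  if (any(geneticVar <= 0) || any(gxeVar < 0)) stop("invalid variance parameters")
  geneticCor <- as.matrix(geneticCor)
  if (nrow(geneticCor) != t || max(abs(geneticCor - t(geneticCor))) > 1e-8 ||
      max(abs(diag(geneticCor) - 1)) > 1e-8)
    stop("geneticCor must be a symmetric correlation matrix for the traits")
  if (min(eigen(geneticCor, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("geneticCor must be positive semi-definite")
  list(traits = traits, h2 = h2, geneticCor = geneticCor,
       geneticVar = geneticVar, gxeVar = gxeVar, envSd = envSd,
       blockSd = blockSd, mu = mu, covariateSlope = covariateSlope,
       anthesisMean = anthesisMean, anthesisSd = anthesisSd)
}

#' Study-patterned default simulation parameters
#'
#' Seven traits named as in the wheat panel (five primary: HI, GY, GN, SPI,
#' FE; two secondary physiological: NDVI, CT) with the panel's reported
#' broad-sense heritabilities, a genetic correlation matrix patterned on the
#' observed combined-dataset trait correlations (projected to the nearest
#' positive-definite matrix), small G x E for the physiological traits and
#' substantial G x E for the primary traits, and large environment main
#' effects. Traits are on a standardized scale (unit genetic variance).
#'
#' @param nEnv number of environments the residual variances are calibrated
#'   for (defaults to 3).
#' @param nRep replications per environment (1 = augmented).
#' @return a parameter list as from \code{\link{simParams}}.
#' @export
defaultSimParams <- function(nEnv = 3, nRep = 1) {
  traits <- c("HI", "GY", "GN", "SPI", "FE", "NDVI", "CT")
  h2 <- c(0.38, 0.34, 0.28, 0.26, 0.25, 0.64, 0.37)
  ## combined-panel trait correlation pattern (signs and magnitudes as observed:
  ## positive among yield-related traits and with NDVI, negative for CT)
  r <- matrix(c(
     1.00, 0.59, 0.42, 0.29, 0.35, 0.41, -0.11,
     0.59, 1.00, 0.82, 0.25, 0.32, 0.36, -0.24,
     0.42, 0.82, 1.00, 0.23, 0.47, 0.20, -0.31,
     0.29, 0.25, 0.23, 1.00,-0.32, 0.13, -0.07,
     0.35, 0.32, 0.47,-0.32, 1.00, 0.12, -0.08,
     0.41, 0.36, 0.20, 0.13, 0.12, 1.00,  0.09,
    -0.11,-0.24,-0.31,-0.07,-0.08, 0.09,  1.00), 7, 7,
    dimnames = list(traits, traits))
  ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8) {
    r <- as.matrix(Matrix::nearPD(r, corr = TRUE)$mat)
    dimnames(r) <- list(traits, traits)
  }
  gxe <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.1, 0.1)
  simParams(traits = traits, h2 = h2, geneticCor = r, gxeVar = gxe,
            covariateSlope = rep(0.02, 7))
}

## residual variance that makes the requested h2 exact for (n, r)
.residual_from_h2 <- function(s2g, h2, gxe, n, r) {
  s2e <- n * r * s2g * (1 / h2 - 1) - r * gxe
  if (any(s2e < -1e-12))
    stop("requested h2 unreachable: G x E variance alone exceeds the implied ",
         "non-genetic variance; lower gxeVar or h2")
  pmax(s2e, 0)
}

#' Simulate an augmented multi-environment trial with known ground truth
#'
#' Breeding values for all lines (test entries and checks) are drawn from
#' \eqn{MVN(0, \Sigma \otimes K)} where K is the additive relationship matrix
#' realized from \code{markers}. Each plot value is
#' overall mean + environment effect + block effect + breeding value +
#' G x E draw + covariate slope x (days to anthesis - mean) + residual.
#' Residual variances are calibrated so the requested heritabilities are exact
#' for the design (see \code{\link{simParams}}).
#'
#' @param markers a \code{MarkerMatrix} whose rows are the
#'   \code{design@nLines} test entries followed by \code{design@nChecks}
#'   checks.
#' @param design a \code{\link{designSpec}}.
#' @param params a list from \code{\link{simParams}}.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with elements \code{trial} (a
#'   \code{\linkS4class{TrialTable}}) and \code{truth} (a
#'   \code{\linkS4class{SimTruth}}).
#' @examples
#' mk <- simulateMarkers(23, 200, seed = 3)
#' ds <- designSpec(nLines = 20, nBlocksPerEnv = 2, environments = c("E1", "E2"))
#' sim <- simulateTrial(mk, ds, simParams(c("A", "B"), h2 = c(0.4, 0.6),
#'                                        geneticCor = matrix(c(1, .5, .5, 1), 2)),
#'                      seed = 9)
#' sim$truth
#' @export
simulateTrial <- function(markers, design, params, seed = 1) {
  stopifnot(is(markers, "MarkerMatrix"), is(design, "DesignSpec"))
  nL <- design@nLines; nC <- design@nChecks
  if (nrow(as.matrix(markers)) != nL + nC)
    stop("markers must have design@nLines + design@nChecks rows (entries then checks)")
  tn <- params$traits; t <- length(tn)
  nEnv <- length(design@environments); r <- design@nRep

  sdv <- sqrt(params$geneticVar)
  Sigma <- params$geneticCor * (sdv %o% sdv)
  dimnames(Sigma) <- list(tn, tn)
  s2e <- .residual_from_h2(params$geneticVar, params$h2, params$gxeVar, nEnv, r)
  h2 <- .h2_from_components(params$geneticVar, params$gxeVar, s2e, nEnv, r)

  ids <- lineIds(markers)
  entry_ids <- ids[seq_len(nL)]
  check_ids <- if (nC > 0) ids[nL + seq_len(nC)] else character()

  K <- additiveRelationship(imputeMissing(markers))
  ek <- eigen(as.matrix(K), symmetric = TRUE)
  Lk <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)), nrow(as.matrix(K)))
  Ls <- chol(Sigma + diag(1e-10, t))

  out <- local_seed(seed, {
    n_all <- nL + nC
    BV <- Lk %*% matrix(rnorm(n_all * t), n_all, t) %*% Ls
    dimnames(BV) <- list(ids, tn)
    envEff <- matrix(rnorm(nEnv * t, sd = rep(params$envSd, each = nEnv)),
                     nEnv, t, dimnames = list(design@environments, tn))
    anth <- setNames(rnorm(n_all, params$anthesisMean, params$anthesisSd), ids)

    blocks <- sprintf("B%02d", seq_len(design@nBlocksPerEnv))
    rows <- list(); k <- 0L
    for (m in seq_len(nEnv)) {
      env <- design@environments[m]
      blkEff <- matrix(rnorm(length(blocks) * t, sd = params$blockSd),
                       length(blocks), t, dimnames = list(blocks, tn))
      ## independent G x E draw per genotype in this environment
      gxe <- matrix(rnorm(n_all * t, sd = rep(sqrt(params$gxeVar), each = n_all)),
                    n_all, t, dimnames = list(ids, tn))
      place <- function(id, blk, is_chk, chk) {
        k <<- k + 1L
        y <- params$mu + envEff[m, ] + blkEff[blk, ] + BV[id, ] + gxe[id, ] +
          params$covariateSlope * (anth[id] - params$anthesisMean) +
          rnorm(t, sd = sqrt(s2e))
        rows[[k]] <<- data.frame(env = env, block = blk, entry_id = id,
                                 is_check = is_chk,
                                 check_id = if (is_chk) chk else NA_character_,
                                 days_to_anthesis = unname(anth[id]),
                                 as.list(setNames(y, tn)))
      }
      for (rep_i in seq_len(r)) {
        perm <- sample(entry_ids)
        blk_of <- rep(blocks, length.out = nL)
        for (i in seq_len(nL)) place(perm[i], blk_of[i], FALSE, NA)
      }
      for (b in blocks) for (cid in check_ids) place(cid, b, TRUE, cid)
    }
    list(records = do.call(rbind, rows), BV = BV, envEff = envEff, anth = anth)
  })

  trial <- TrialTable(out$records, traitNames = tn)
  truth <- new("SimTruth",
               geneticCovariance = Sigma, residualVariances = s2e,
               gxeVariances = params$gxeVar, envEffects = out$envEff,
               breedingValues = out$BV, heritabilities = h2,
               covariateSlope = params$covariateSlope,
               anthesisDates = out$anth,
               nEnv = nEnv, nRep = r, seed = as.numeric(seed))
  list(trial = trial, truth = truth)
}
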