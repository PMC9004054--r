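#' @include AllGenerics.R
#' @import methods
#' @importFrom stats var cor sd rnorm rbinom runif rchisq anova aov lm
#'   as.formula coef cor.test pf predict quantile setNames complete.cases
#' @importFrom utils read.csv write.csv head
#' @useDynLib MultiTraitGP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## MarkerMatrix
## ---------------------------------------------------------------------------

#' MarkerMatrix: coded SNP genotypes for a line panel
#'
#' Lines x markers matrix of additively coded biallelic SNPs: -1 homozygous
#' minor, 0 heterozygous, +1 homozygous major; \code{NA} marks missing calls.
#' After mean imputation cells may hold fractional values in [-1, 1].
#'
#' @slot codes numeric matrix, lines x markers, dimnames = (line ids, marker
#'   ids); values in [-1, 1] or \code{NA}.
#' @slot imputed logical; \code{TRUE} once missing cells have been filled.
#' @export
setClass("MarkerMatrix",
  representation(codes = "matrix", imputed = "logical"),
  prototype(imputed = FALSE)
)

setValidity("MarkerMatrix", function(object) {
  m <- object@codes
  if (!is.numeric(m)) return("codes must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("codes must carry line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(m))) return("line ids must be unique")
  if (anyDuplicated(colnames(m))) return("marker ids must be unique")
  v <- m[!is.na(m)]
  if (length(v) && (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9))
    return("non-missing codes must lie in [-1, 1]")
  if (!object@imputed) {
    vr <- v[abs(v - round(v)) > 1e-9]
    if (length(vr)) return("raw (non-imputed) codes must be in {-1, 0, +1}")
  }
  TRUE
})

#' Construct a MarkerMatrix
#'
#' @param codes numeric matrix with line ids as rownames and marker ids as
#'   colnames; entries in \{-1, 0, +1\} or \code{NA}.
#' @param imputed logical, whether fractional imputed values are permitted.
#' @return a \code{MarkerMatrix}.
#' @examples
#' m <- matrix(c(-1, 0, 1, 1, 0, -1), nrow = 2,
#'             dimnames = list(c("L1", "L2"), c("m1", "m2", "m3")))
#' MarkerMatrix(m)
#' @export
MarkerMatrix <- function(codes, imputed = FALSE) {
  storage.mode(codes) <- "double"
  new("MarkerMatrix", codes = codes, imputed = imputed)
}

#' @describeIn MarkerMatrix the underlying codes matrix.
#' @param x a \code{MarkerMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "MarkerMatrix", function(x, ...) x@codes)

#' @rdname lineIds
#' @export
setMethod("lineIds", "MarkerMatrix", function(x) rownames(x@codes))

#' @rdname markerIds
#' @export
setMethod("markerIds", "MarkerMatrix", function(x) colnames(x@codes))

setMethod("show", "MarkerMatrix", function(object) {
  m <- object@codes
  nmis <- sum(is.na(m))
  cat(sprintf("MarkerMatrix: %d lines x %d markers (%s; %.2f%% missing)\n",
              nrow(m), ncol(m),
              if (object@imputed) "imputed" else "raw codes -1/0/+1",
              100 * nmis / length(m)))
})

## ---------------------------------------------------------------------------
## KinshipMatrix
## ---------------------------------------------------------------------------

#' KinshipMatrix: additive genomic relationship matrix
#'
#' Symmetric VanRaden-type relationship matrix K among lines, positive
#' semi-definite after stabilization.
#'
#' @slot values symmetric numeric matrix with line ids as dimnames.
#' @slot stabilized logical; \code{TRUE} if a ridge was added to reach PSD.
#' @slot epsilon the ridge added to the diagonal (0 when not stabilized).
#' @export
setClass("KinshipMatrix",
  representation(values = "matrix", stabilized = "logical", epsilon = "numeric"),
  prototype(stabilized = FALSE, epsilon = 0)
)

setValidity("KinshipMatrix", function(object) {
  k <- object@values
  if (!is.numeric(k) || nrow(k) != ncol(k)) return("values must be a square numeric matrix")
  if (is.null(rownames(k)) || !identical(rownames(k), colnames(k)))
    return("row and column line ids must be present and identical")
  if (anyDuplicated(rownames(k))) return("line ids must be unique")
  if (max(abs(k - t(k))) > 1e-6 * max(1, max(abs(k))))
    return("K must be symmetric to numerical tolerance")
  ev <- min(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) return(sprintf("K must be PSD (min eigenvalue %.3g); stabilize first", ev))
  TRUE
})

#' Construct a KinshipMatrix
#'
#' @param values symmetric numeric matrix with line ids as dimnames.
#' @param stabilized,epsilon stabilization metadata (see
#'   \code{\link{additiveRelationship}}).
#' @return a \code{KinshipMatrix}.
#' @export
KinshipMatrix <- function(values, stabilized = FALSE, epsilon = 0) {
  values <- (values + t(values)) / 2
  new("KinshipMatrix", values = values, stabilized = stabilized, epsilon = epsilon)
}

#' @describeIn KinshipMatrix the relationship matrix itself.
#' @param x a \code{KinshipMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "KinshipMatrix", function(x, ...) x@values)

#' @rdname lineIds
#' @export
setMethod("lineIds", "KinshipMatrix", function(x) rownames(x@values))

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d lines, mean diagonal %.3f%s\n",
              nrow(object@values), mean(diag(object@values)),
              if (object@stabilized)
                sprintf(" (stabilized, epsilon = %.3g)", object@epsilon) else ""))
})

## ---------------------------------------------------------------------------
## TrialTable
## ---------------------------------------------------------------------------

#' TrialTable: plot-level records of an augmented multi-environment trial
#'
#' Long-format phenotype records: one row per plot, with environment, block,
#' entry identity, check status, the days-to-anthesis covariate and one column
#' per trait. Checks are replicated in every block; test entries are
#' unreplicated (augmented design).
#'
#' @slot records data.frame with columns \code{env}, \code{block},
#'   \code{entry_id}, \code{is_check}, \code{check_id},
#'   \code{days_to_anthesis}, then trait columns.
#' @slot traitNames character, the trait column names.
#' @export
setClass("TrialTable",
  representation(records = "data.frame", traitNames = "character")
)

setValidity("TrialTable", function(object) {
  d <- object@records
  need <- c("env", "block", "entry_id", "is_check", "check_id", "days_to_anthesis")
  miss <- setdiff(need, names(d))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!all(object@traitNames %in% names(d)))
    return("traitNames must all be columns of records")
  if (!is.logical(d$is_check)) return("is_check must be logical")
  bad <- xor(d$is_check, !is.na(d$check_id))
  if (any(bad)) return("is_check must hold exactly when check_id is present")
  ## every (env, block) must contain every check id
  chk <- unique(d$check_id[d$is_check])
  if (length(chk)) {
    tab <- table(d$env[d$is_check], d$block[d$is_check])
    eb <- unique(d[, c("env", "block")])
    for (i in seq_len(nrow(eb))) {
      here <- d$is_check & d$env == eb$env[i] & d$block == eb$block[i]
      if (!all(chk %in% d$check_id[here]))
        return(sprintf("block %s in env %s lacks some checks", eb$block[i], eb$env[i]))
    }
  }
  TRUE
})

#' Construct a TrialTable
#'
#' @param records data.frame in the schema documented for
#'   \code{\linkS4class{TrialTable}}.
#' @param traitNames character vector naming the trait columns; defaults to all
#'   columns after the design columns.
#' @return a \code{TrialTable}.
#' @export
TrialTable <- function(records, traitNames = NULL) {
  design_cols <- c("env", "block", "entry_id", "is_check", "check_id", "days_to_anthesis")
  if (is.null(traitNames)) traitNames <- setdiff(names(records), design_cols)
  records$env <- as.character(records$env)
  records$block <- as.character(records$block)
  records$entry_id <- as.character(records$entry_id)
  records$check_id <- as.character(records$check_id)
  new("TrialTable", records = records, traitNames = traitNames)
}

#' @rdname traitNames
#' @export
setMethod("traitNames", "TrialTable", function(x) x@traitNames)

#' @describeIn TrialTable the plot-level records.
#' @param x a \code{TrialTable}.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "TrialTable", function(x, ...) x@records)

setMethod("show", "TrialTable", function(object) {
  d <- object@records
  cat(sprintf("TrialTable: %d plots, %d environments, %d genotypes (%d checks), traits: %s\n",
              nrow(d), length(unique(d$env)),
              length(unique(d$entry_id[!d$is_check])),
              length(unique(d$check_id[d$is_check])),
              paste(object@traitNames, collapse = ", ")))
})

## ---------------------------------------------------------------------------
## BlueTable
## ---------------------------------------------------------------------------

#' BlueTable: genotype x trait adjusted means for one dataset
#'
#' Best linear unbiased estimates (fixed-genotype adjusted means) for the
#' non-check genotypes, for a single environment or the combined analysis.
#'
#' @slot datasetLabel e.g. an environment label or \code{"combined"}.
#' @slot values numeric matrix, genotypes x traits; \code{NA} allowed.
#' @export
setClass("BlueTable",
  representation(datasetLabel = "character", values = "matrix")
)

setValidity("BlueTable", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("values must have unique genotype rownames")
  if (is.null(colnames(v))) return("values must have trait colnames")
  TRUE
})

#' Construct a BlueTable
#'
#' @param values numeric matrix, genotype rows x trait columns.
#' @param datasetLabel label of the dataset (environment or "combined").
#' @return a \code{BlueTable}.
#' @export
BlueTable <- function(values, datasetLabel = "combined") {
  new("BlueTable", datasetLabel = datasetLabel, values = values)
}

#' @describeIn BlueTable the adjusted-mean matrix.
#' @param x a \code{BlueTable}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "BlueTable", function(x, ...) x@values)

#' @rdname lineIds
#' @export
setMethod("lineIds", "BlueTable", function(x) rownames(x@values))

#' @rdname traitNames
#' @export
setMethod("traitNames", "BlueTable", function(x) colnames(x@values))

setMethod("show", "BlueTable", function(object) {
  cat(sprintf("BlueTable '%s': %d genotypes x %d traits\n",
              object@datasetLabel, nrow(object@values), ncol(object@values)))
})

## ---------------------------------------------------------------------------
## VarianceComponents
## ---------------------------------------------------------------------------

#' VarianceComponents: single-trait variance decomposition
#'
#' Genotypic, genotype-by-environment and residual variances together with the
#' number of environments (n) and replications per environment (r), as used by
#' the broad-sense heritability formula
#' \eqn{H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{G\times E}/n + \sigma^2_e/(nr))}.
#'
#' @slot sigma2G genotypic variance (trait units squared).
#' @slot sigma2GxE genotype-by-environment variance.
#' @slot sigma2E residual variance.
#' @slot nEnv number of environments.
#' @slot nRep replications per environment (1 for an augmented design).
#' @export
setClass("VarianceComponents",
  representation(sigma2G = "numeric", sigma2GxE = "numeric", sigma2E = "numeric",
                 nEnv = "numeric", nRep = "numeric")
)

setValidity("VarianceComponents", function(object) {
  if (any(c(object@sigma2G, object@sigma2GxE, object@sigma2E) < 0))
    return("variance components must be non-negative")
  if (object@nEnv < 1 || object@nRep < 1) return("nEnv and nRep must be >= 1")
  TRUE
})

#' Construct a VarianceComponents object
#'
#' @param sigma2G,sigma2GxE,sigma2E non-negative variances.
#' @param nEnv,nRep environment and replication counts.
#' @return a \code{VarianceComponents}.
#' @export
VarianceComponents <- function(sigma2G, sigma2GxE, sigma2E, nEnv, nRep = 1) {
  new("VarianceComponents", sigma2G = sigma2G, sigma2GxE = sigma2GxE,
      sigma2E = sigma2E, nEnv = nEnv, nRep = nRep)
}

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents: sigma2G=%.4g, sigma2GxE=%.4g, sigma2e=%.4g (n=%g, r=%g)\n",
              object@sigma2G, object@sigma2GxE, object@sigma2E, object@nEnv, object@nRep))
})

## ---------------------------------------------------------------------------
## SimTruth
## ---------------------------------------------------------------------------

#' SimTruth: ground truth behind a simulated trial
#'
#' Every latent component drawn by \code{\link{simulateTrial}}: the genetic
#' covariance between traits, residual and genotype-by-environment variances,
#' environment effects, true breeding values, the anthesis-date covariate and
#' its per-trait slope, and the heritabilities implied by the components.
#'
#' @slot geneticCovariance t x t genetic covariance (\eqn{\Sigma}) used to draw
#'   breeding values.
#' @slot residualVariances,gxeVariances per-trait variances.
#' @slot envEffects environments x traits matrix of environment main effects.
#' @slot breedingValues lines x traits matrix of true genetic values.
#' @slot heritabilities per-trait broad-sense heritability implied by the
#'   components (recomputable via \code{\link{broadSenseHeritability}}).
#' @slot covariateSlope per-trait effect of one day of anthesis date.
#' @slot anthesisDates genotype-level simulated days to anthesis.
#' @slot nEnv,nRep design counts entering the heritability formula.
#' @slot seed integer seed that produced the draw.
#' @export
setClass("SimTruth",
  representation(geneticCovariance = "matrix", residualVariances = "numeric",
                 gxeVariances = "numeric", envEffects = "matrix",
                 breedingValues = "matrix", heritabilities = "numeric",
                 covariateSlope = "numeric", anthesisDates = "numeric",
                 nEnv = "numeric", nRep = "numeric", seed = "numeric")
)

setValidity("SimTruth", function(object) {
  S <- object@geneticCovariance
  if (max(abs(S - t(S))) > 1e-8) return("geneticCovariance must be symmetric")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    return("geneticCovariance must be positive semi-definite")
  if (any(object@heritabilities < 0 | object@heritabilities > 1))
    return("heritabilities must lie in [0, 1]")
  h2 <- .h2_from_components(diag(S), object@gxeVariances, object@residualVariances,
                            object@nEnv, object@nRep)
  if (max(abs(h2 - object@heritabilities)) > 1e-6)
    return("heritabilities are not consistent with the stored variance components")
  TRUE
})

#' @rdname traitNames
#' @export
setMethod("traitNames", "SimTruth", function(x) colnames(x@breedingValues))

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d lines x %d traits, %d envs; h2 = %s (seed %d)\n",
              nrow(object@breedingValues), ncol(object@breedingValues),
              object@nEnv,
              paste(sprintf("%.2f", object@heritabilities), collapse = ", "),
              as.integer(object@seed)))
})

## broad-sense heritability from raw components (shared by class validity and
## the exported operation)
.h2_from_components <- function(s2g, s2gxe, s2e, n, r) {
  s2g / (s2g + s2gxe / n + s2e / (n * r))
}

## ---------------------------------------------------------------------------
## GibbsConfig
## ---------------------------------------------------------------------------

#' GibbsConfig: sampler settings for the Bayesian genomic prediction models
#'
#' Defaults follow the study protocol: 2000 burn-in iterations out of 12,000
#' total, no thinning. Priors are weakly informative: scaled-inverse-chi-square
#' with \code{priorDfVariance} degrees of freedom for the scalar variances
#' (scale set so the prior mode is half the observed trait variance), and an
#' inverse-Wishart for the genetic covariance whose degrees of freedom default
#' to t + 3 (\code{priorDfWishart = NA} means "resolve to t + 3 at fit time").
#'
#' @slot burnIn discarded initial iterations.
#' @slot nIter total Gibbs iterations.
#' @slot thin keep every \code{thin}-th post-burn-in draw.
#' @slot seed integer RNG seed for the chain.
#' @slot priorDfVariance df of the scaled-inverse-chi-square variance priors.
#' @slot priorDfWishart df of the inverse-Wishart prior on \eqn{\Sigma}
#'   (\code{NA} = number of traits + 3).
#' @export
setClass("GibbsConfig",
  representation(burnIn = "numeric", nIter = "numeric", thin = "numeric",
                 seed = "numeric", priorDfVariance = "numeric",
                 priorDfWishart = "numeric")
)

setValidity("GibbsConfig", function(object) {
  if (object@burnIn < 0 || object@nIter <= 0 || object@thin < 1)
    return("all iteration counts must be positive")
  if (object@burnIn >= object@nIter) return("burnIn must be smaller than nIter")
  if (object@priorDfVariance <= 0) return("priorDfVariance must be positive")
  TRUE
})

#' Construct a GibbsConfig
#'
#' @param burnIn,nIter,thin,seed,priorDfVariance,priorDfWishart see
#'   \code{\linkS4class{GibbsConfig}}.
#' @return a \code{GibbsConfig}.
#' @examples
#' gibbsConfig()                      # study defaults: 2000 / 12000
#' gibbsConfig(burnIn = 500, nIter = 3000, seed = 7)
#' @export
gibbsConfig <- function(burnIn = 2000, nIter = 12000, thin = 1, seed = 1,
                        priorDfVariance = 5, priorDfWishart = NA_real_) {
  new("GibbsConfig", burnIn = burnIn, nIter = nIter, thin = thin, seed = seed,
      priorDfVariance = priorDfVariance, priorDfWishart = priorDfWishart)
}

setMethod("show", "GibbsConfig", function(object) {
  cat(sprintf("GibbsConfig: %g iterations (%g burn-in, thin %g), seed %g\n",
              object@nIter, object@burnIn, object@thin, object@seed))
})

## ---------------------------------------------------------------------------
## PosteriorSummary
## ---------------------------------------------------------------------------

#' PosteriorSummary: output of the Gibbs samplers
#'
#' Posterior means of the model unknowns, predictions for missing phenotype
#' cells (via data augmentation), and retained variance-component chains for
#' diagnostics.
#'
#' @slot model "ST" or "MT".
#' @slot muHat per-trait intercept posterior means.
#' @slot gebvValues lines x traits posterior-mean genetic values.
#' @slot yPred lines x traits posterior-mean predictions for cells that were
#'   missing in the input (\code{NA} where the cell was observed).
#' @slot observed logical lines x traits mask of observed input cells.
#' @slot sigma2G,sigma2E per-trait posterior-mean variances (ST; for MT these
#'   are the diagonals of \code{SigmaHat} and \code{RHat}).
#' @slot SigmaHat,RHat posterior-mean genetic covariance and (diagonal)
#'   residual covariance between traits (MT).
#' @slot chains list of retained sample matrices (variance components; and the
#'   genetic-value chain when requested).
#' @export
setClass("PosteriorSummary",
  representation(model = "character", muHat = "numeric", gebvValues = "matrix",
                 yPred = "matrix", observed = "matrix",
                 sigma2G = "numeric", sigma2E = "numeric",
                 SigmaHat = "matrix", RHat = "matrix", chains = "list")
)

setValidity("PosteriorSummary", function(object) {
  if (!object@model %in% c("ST", "MT")) return("model must be 'ST' or 'MT'")
  S <- object@SigmaHat
  if (length(S)) {
    if (max(abs(S - t(S))) > 1e-8) return("SigmaHat must be symmetric")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      return("SigmaHat must be positive semi-definite")
  }
  R <- object@RHat
  if (length(R)) {
    if (any(R[row(R) != col(R)] != 0)) return("RHat must be diagonal")
    if (any(diag(R) <= 0)) return("RHat diagonal must be positive")
  }
  TRUE
})

#' @rdname gebv
#' @export
setMethod("gebv", "PosteriorSummary", function(x) x@gebvValues)

#' @rdname sigmaHat
#' @export
setMethod("sigmaHat", "PosteriorSummary", function(x) x@SigmaHat)

#' @rdname residualMatrix
#' @export
setMethod("residualMatrix", "PosteriorSummary", function(x) x@RHat)

#' @rdname lineIds
#' @export
setMethod("lineIds", "PosteriorSummary", function(x) rownames(x@gebvValues))

#' @rdname traitNames
#' @export
setMethod("traitNames", "PosteriorSummary", function(x) colnames(x@gebvValues))

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary (%s): %d lines x %d trait(s)\n",
              object@model, nrow(object@gebvValues), ncol(object@gebvValues)))
  if (object@model == "ST") {
    cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g\n",
                object@sigma2G[1], object@sigma2E[1]))
  } else {
    cat("  Sigma_hat diagonal:", sprintf("%.4g", diag(object@SigmaHat)), "\n")
  }
})

## ---------------------------------------------------------------------------
## MaskSpec and CvResult
## ---------------------------------------------------------------------------

#' MaskSpec: which cross-validation scheme to run, and on which traits
#'
#' \describe{
#'   \item{ST-CV1}{single-trait model; test lines have no phenotypes.}
#'   \item{MT-CV1}{multi-trait model; ALL traits masked for test lines.}
#'   \item{MT-CV2}{multi-trait model; only the primary trait masked for test
#'     lines, secondary traits observed everywhere.}
#' }
#'
#' @slot scheme one of "ST-CV1", "MT-CV1", "MT-CV2".
#' @slot primaryTrait name of the trait being predicted.
#' @slot secondaryTraits names of correlated helper traits (MT schemes).
#' @export
setClass("MaskSpec",
  representation(scheme = "character", primaryTrait = "character",
                 secondaryTraits = "character")
)

setValidity("MaskSpec", function(object) {
  if (!object@scheme %in% c("ST-CV1", "MT-CV1", "MT-CV2"))
    return("scheme must be ST-CV1, MT-CV1 or MT-CV2")
  if (length(object@primaryTrait) != 1) return("exactly one primary trait")
  if (object@scheme != "ST-CV1" && length(object@secondaryTraits) < 1)
    return("MT schemes require at least one secondary trait")
  if (object@primaryTrait %in% object@secondaryTraits)
    return("primary trait cannot also be secondary")
  TRUE
})

#' Construct a MaskSpec
#'
#' @param scheme "ST-CV1", "MT-CV1" or "MT-CV2".
#' @param primaryTrait trait to predict.
#' @param secondaryTraits helper traits (ignored for ST-CV1).
#' @return a \code{MaskSpec}.
#' @export
maskSpec <- function(scheme, primaryTrait, secondaryTraits = character()) {
  if (scheme == "ST-CV1") secondaryTraits <- character()
  new("MaskSpec", scheme = scheme, primaryTrait = primaryTrait,
      secondaryTraits = secondaryTraits)
}

#' CvResult: predictive ability of one scheme on one trait and dataset
#'
#' @slot scheme,trait,datasetLabel identification of the run.
#' @slot perRepR Pearson correlation (observed vs predicted, test lines) per
#'   replicate; \code{NA} for invalid replicates.
#' @slot meanR,seR mean and standard error over valid replicates.
#' @slot nValidReps number of replicates entering the mean.
#' @slot predictions per-replicate named prediction vectors (kept only when
#'   requested; used by the masking audit).
#' @export
setClass("CvResult",
  representation(scheme = "character", trait = "character",
                 datasetLabel = "character", perRepR = "numeric",
                 meanR = "numeric", seR = "numeric", nValidReps = "numeric",
                 predictions = "list")
)

setValidity("CvResult", function(object) {
  if (length(object@meanR) == 1 && is.finite(object@meanR) && abs(object@meanR) > 1)
    return("|meanR| cannot exceed 1")
  TRUE
})

#' @rdname meanPredictiveAbility
#' @export
setMethod("meanPredictiveAbility", "CvResult", function(x) x@meanR)

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult %s / %s (%s): mean r = %.3f (SE %.3f, %d valid reps)\n",
              object@scheme, object@trait, object@datasetLabel,
              object@meanR, object@seR, object@nValidReps))
})
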