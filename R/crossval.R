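## Monte-Carlo cross-validation: ST-CV1, MT-CV1 and MT-CV2. Splits are shared
## across schemes for paired comparisons; per-replicate sampler seeds are
## derived deterministically from (config seed, replicate index).

#' Random training/testing partitions of a genotype panel
#'
#' Each replicate is an independent uniform random partition with
#' \code{floor(trainFraction * n)} training genotypes (70% of 236 gives
#' 165 training / 71 testing). Reproducible under \code{seed}.
#'
#' @param ids genotype identifiers (>= 10).
#' @param trainFraction training proportion in (0, 1); default 0.7.
#' @param nReps number of replicates; default 100.
#' @param seed integer seed.
#' @return list of splits, each a list with \code{repIndex}, \code{trainIds},
#'   \code{testIds}.
#' @examples
#' sp <- makeSplits(sprintf("L%03d", 1:236), seed = 1)
#' lengths(sp[[1]][c("trainIds", "testIds")])  # 165 and 71
#' @export
makeSplits <- function(ids, trainFraction = 0.7, nReps = 100, seed = 1) {
  n <- length(ids)
  if (n < 10) stop("need at least 10 genotypes")
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  n_train <- floor(trainFraction * n)
  local_seed(seed, {
    lapply(seq_len(nReps), function(r) {
      tr <- sort(sample(ids, n_train))
      list(repIndex = r, trainIds = tr, testIds = sort(setdiff(ids, tr)))
    })
  })
}

## deterministic per-replicate chain seed below 2^31
.rep_seed <- function(seed, rep_index) {
  as.integer((as.numeric(seed) * 1009 + rep_index * 7919) %% 2147483647)
}

#' Run one cross-validation scheme
#'
#' Per replicate the held-out test genotypes are masked according to the
#' scheme (see \code{\link{maskSpec}}): ST-CV1 fits the single-trait model on
#' the training lines' primary phenotypes; MT-CV1 masks all traits of the
#' test lines; MT-CV2 masks only the primary trait, leaving secondary traits
#' observed for every line. Predictive ability is the Pearson correlation
#' between the held-out observed primary BLUEs and the model predictions on
#' the test lines, aggregated over replicates. Replicates with undefined
#' correlation (zero variance, or fewer than 3 test observations) are flagged
#' invalid and excluded.
#'
#' @param blues a \code{BlueTable} holding the primary (and, for MT schemes,
#'   secondary) traits.
#' @param kinship a \code{KinshipMatrix} covering the panel.
#' @param mask a \code{\link{maskSpec}}.
#' @param splits from \code{\link{makeSplits}}; share the same splits across
#'   schemes for paired comparisons.
#' @param config a \code{\link{gibbsConfig}}; each replicate runs its own
#'   chain with a seed derived from \code{config@seed} and the replicate
#'   index.
#' @param keepPredictions retain per-replicate prediction vectors (used by
#'   masking audits).
#' @return a \code{\linkS4class{CvResult}}.
#' @export
runScheme <- function(blues, kinship, mask, splits, config = gibbsConfig(),
                      keepPredictions = FALSE) {
  stopifnot(is(blues, "BlueTable"), is(mask, "MaskSpec"))
  v <- as.matrix(blues)
  need <- c(mask@primaryTrait, mask@secondaryTraits)
  miss <- setdiff(need, colnames(v))
  if (length(miss)) stop("trait(s) absent from blues: ", paste(miss, collapse = ", "))

  per_rep <- rep(NA_real_, length(splits))
  preds_kept <- if (keepPredictions) vector("list", length(splits)) else list()
  for (s in splits) {
    test <- s$testIds
    cfg <- gibbsConfig(burnIn = config@burnIn, nIter = config@nIter,
                       thin = config@thin, seed = .rep_seed(config@seed, s$repIndex),
                       priorDfVariance = config@priorDfVariance,
                       priorDfWishart = config@priorDfWishart)
    if (mask@scheme == "ST-CV1") {
      y <- v[, mask@primaryTrait]
      y[test] <- NA
      fit <- fitSingleTrait(y, kinship, cfg, trait = mask@primaryTrait)
    } else {
      Y <- v[, need, drop = FALSE]
      if (mask@scheme == "MT-CV1") Y[test, ] <- NA
      else Y[test, mask@primaryTrait] <- NA
      fit <- fitMultiTrait(Y, kinship, cfg, keepSigmaChain = FALSE)
    }
    pred <- predict(fit, ids = test, trait = mask@primaryTrait)
    if (keepPredictions) preds_kept[[s$repIndex]] <- pred
    obs <- v[test, mask@primaryTrait]
    ok <- !is.na(obs)
    if (sum(ok) < 3 || sd(obs[ok]) == 0 || sd(pred[ok]) == 0) {
      message(sprintf("runScheme %s rep %d: undefined correlation, replicate excluded",
                      mask@scheme, s$repIndex))
      next
    }
    per_rep[s$repIndex] <- cor(obs[ok], pred[ok])
  }

  valid <- per_rep[!is.na(per_rep)]
  new("CvResult", scheme = mask@scheme, trait = mask@primaryTrait,
      datasetLabel = blues@datasetLabel, perRepR = per_rep,
      meanR = mean(valid),
      seR = if (length(valid) > 1) sd(valid) / sqrt(length(valid)) else NA_real_,
      nValidReps = length(valid), predictions = preds_kept)
}

#' Percent increase in predictive ability between two schemes
#'
#' \code{100 * (mt - st) / st} on the mean predictive abilities, as used to
#' compare MT-CV2 against the single-trait baseline.
#'
#' @param st,mt \code{CvResult}s for the same trait and dataset.
#' @return percentage; \code{NA} with a warning when the baseline mean is
#'   not positive.
#' @examples
#' \dontrun{percentIncrease(st_result, mt_result)}
#' @export
percentIncrease <- function(st, mt) {
  stopifnot(is(st, "CvResult"), is(mt, "CvResult"))
  if (st@trait != mt@trait || st@datasetLabel != mt@datasetLabel)
    stop("results compare different traits or datasets")
  if (!is.finite(st@meanR) || st@meanR <= 0) {
    warning("baseline mean predictive ability is not positive; percent increase undefined")
    return(NA_real_)
  }
  100 * (mt@meanR - st@meanR) / st@meanR
}
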