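## Phenotype adjustment for augmented multi-environment trials.
##
## Model terms follow the augmented-design convention: Gen carries the test
## entries (checks collapsed into one level), Check carries the check
## identities (entries collapsed), and IDCheck separates checks as a group
## from entries. Genotype, check, IDCheck, environment and the anthesis-date
## covariate are fixed; blocks and all x-environment interactions are random.
## Fitting is REML via lme4 (falling back to lm when no random term remains).

.CHECK_LEVEL <- "_CHECK_"
.ENTRY_LEVEL <- "_ENTRY_"

## add the model factors to a records data.frame
.prep_factors <- function(d, trait) {
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  entries <- sort(unique(d$entry_id[!d$is_check]))
  checks <- sort(unique(d$check_id[d$is_check]))
  d$genF <- factor(ifelse(d$is_check, .CHECK_LEVEL, d$entry_id),
                   levels = c(entries, if (length(checks)) .CHECK_LEVEL))
  d$checkF <- factor(ifelse(d$is_check, d$check_id, .ENTRY_LEVEL),
                     levels = c(.ENTRY_LEVEL, checks))
  d$idcheckF <- factor(ifelse(d$is_check, "check", "entry"),
                       levels = c("entry", if (length(checks)) "check"))
  d$envF <- factor(d$env)
  d$blockF <- factor(d$block)
  d$cov_c <- d$days_to_anthesis - mean(d$days_to_anthesis)
  attr(d, "entries") <- entries
  d
}

.lmer_ctrl <- function() {
  lme4::lmerControl(check.rankX = "silent.drop.cols",
                    check.conv.singular = "ignore",
                    calc.derivs = FALSE)
}

## error if a *test-entry* genotype column was dropped for rank deficiency
## (structural aliasing among IDCheck/Check/Gen check levels is expected)
.check_gen_aliasing <- function(fit, entries) {
  dropped <- character()
  if (inherits(fit, "merMod")) {
    dropped <- attr(lme4::getME(fit, "X"), "col.dropped")
    dropped <- if (is.null(dropped)) character() else names(dropped)
  } else {
    cf <- coef(fit)
    dropped <- names(cf)[is.na(cf)]
  }
  bad <- intersect(dropped, paste0("genF", entries))
  if (length(bad))
    stop("rank-deficient design; aliased genotype terms: ",
         paste(sub("^genF", "", bad), collapse = ", "))
  invisible(NULL)
}

.fixed_prediction <- function(fit, newdata) {
  if (inherits(fit, "merMod")) {
    predict(fit, newdata = newdata, re.form = NA)
  } else {
    suppressWarnings(predict(fit, newdata = newdata))
  }
}

#' Per-environment BLUEs for one trait
#'
#' Fits \code{trait ~ IDCheck + Gen + Check + covariate + (1 | block)} within
#' one environment (dropping degenerate terms: single block, no checks, or a
#' constant covariate) and returns the adjusted genotype mean, i.e. the
#' fixed-effect prediction for each test entry at the covariate mean,
#' averaging block effects out. Adding a constant to the covariate leaves the
#' result unchanged (it is centered internally).
#'
#' @param trial a \code{TrialTable}.
#' @param env environment label present in the trial.
#' @param trait trait column name.
#' @param covariate logical; adjust for days to anthesis (default TRUE).
#' @return named numeric vector of BLUEs, one per test entry present in the
#'   environment.
#' @export
fitBluesSingleEnv <- function(trial, env, trait, covariate = TRUE) {
  stopifnot(is(trial, "TrialTable"))
  d <- as.data.frame(trial)
  if (!env %in% d$env) stop("environment not present: ", env)
  if (!trait %in% traitNames(trial)) stop("unknown trait: ", trait)
  d <- .prep_factors(d[d$env == env, , drop = FALSE], trait)
  entries <- attr(d, "entries")
  if (!length(entries)) stop("no test entries with data in ", env)

  fixed <- c("genF",
             if (nlevels(d$idcheckF) > 1) "idcheckF",
             if (nlevels(d$checkF) > 1) "checkF",
             if (covariate && sd(d$cov_c) > 0) "cov_c")
  has_block <- nlevels(droplevels(d$blockF)) > 1
  if (has_block) {
    f <- as.formula(paste(trait, "~", paste(fixed, collapse = " + "), "+ (1 | blockF)"))
    fit <- suppressMessages(lme4::lmer(f, data = d, control = .lmer_ctrl()))
  } else {
    f <- as.formula(paste(trait, "~", paste(fixed, collapse = " + ")))
    fit <- lm(f, data = d)
  }
  .check_gen_aliasing(fit, entries)

  nd <- data.frame(genF = factor(entries, levels = levels(d$genF)),
                   idcheckF = factor("entry", levels = levels(d$idcheckF)),
                   checkF = factor(.ENTRY_LEVEL, levels = levels(d$checkF)),
                   cov_c = 0)
  setNames(.fixed_prediction(fit, nd), entries)
}

#' Combined-across-environments BLUEs for one trait
#'
#' Fits the across-environment model with genotype, check, IDCheck,
#' environment and covariate fixed and all-by-environment interactions plus
#' blocks-within-environment random:
#' \code{trait ~ IDCheck + Gen + Check + Env + covariate + (1 | Gen:Env) +
#' (1 | Check:Env) + (1 | IDCheck:Env) + (1 | Env:Block)}.
#' Returns the fixed-effect genotype prediction at the covariate mean,
#' averaged over environments.
#'
#' @inheritParams fitBluesSingleEnv
#' @return named numeric vector of BLUEs, one per test entry.
#' @export
fitBluesCombined <- function(trial, trait, covariate = TRUE) {
  stopifnot(is(trial, "TrialTable"))
  d <- as.data.frame(trial)
  if (length(unique(d$env)) < 2) stop("combined analysis needs >= 2 environments")
  if (!trait %in% traitNames(trial)) stop("unknown trait: ", trait)
  d <- .prep_factors(d, trait)
  entries <- attr(d, "entries")

  fixed <- c("genF",
             if (nlevels(d$idcheckF) > 1) "idcheckF",
             if (nlevels(d$checkF) > 1) "checkF",
             "envF",
             if (covariate && sd(d$cov_c) > 0) "cov_c")
  rand <- c("(1 | genF:envF)",
            if (nlevels(d$checkF) > 1) "(1 | checkF:envF)",
            if (nlevels(d$idcheckF) > 1) "(1 | idcheckF:envF)",
            if (any(tapply(d$blockF, d$envF, function(b) length(unique(b))) > 1))
              "(1 | envF:blockF)")
  f <- as.formula(paste(trait, "~", paste(c(fixed, rand), collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(f, data = d, control = .lmer_ctrl()))
  .check_gen_aliasing(fit, entries)

  envs <- levels(d$envF)
  per_env <- vapply(envs, function(e) {
    nd <- data.frame(genF = factor(entries, levels = levels(d$genF)),
                     idcheckF = factor("entry", levels = levels(d$idcheckF)),
                     checkF = factor(.ENTRY_LEVEL, levels = levels(d$checkF)),
                     envF = factor(e, levels = envs),
                     cov_c = 0)
    .fixed_prediction(fit, nd)
  }, numeric(length(entries)))
  setNames(rowMeans(per_env), entries)
}

#' BLUEs for all traits of a dataset
#'
#' Convenience wrapper calling \code{\link{fitBluesSingleEnv}} (for an
#' environment label) or \code{\link{fitBluesCombined}} (for
#' \code{"combined"}) on every trait, assembling a \code{BlueTable} whose rows
#' are the union of test entries (cells missing where a genotype was absent).
#'
#' @param trial a \code{TrialTable}.
#' @param dataset an environment label or \code{"combined"}.
#' @param covariate adjust for days to anthesis (default TRUE).
#' @return a \code{\linkS4class{BlueTable}}.
#' @export
computeBlues <- function(trial, dataset = "combined", covariate = TRUE) {
  d <- as.data.frame(trial)
  entries <- sort(unique(d$entry_id[!d$is_check]))
  tn <- traitNames(trial)
  v <- matrix(NA_real_, length(entries), length(tn),
              dimnames = list(entries, tn))
  for (tr in tn) {
    b <- if (identical(dataset, "combined")) fitBluesCombined(trial, tr, covariate)
         else fitBluesSingleEnv(trial, dataset, tr, covariate)
    v[names(b), tr] <- b
  }
  BlueTable(v, datasetLabel = dataset)
}

#' Combined ANOVA mean squares for genotype, environment and interaction
#'
#' Sequential (type-I) ANOVA of the combined fixed model
#' \code{trait ~ Env + Env:Block + Genotype + Genotype:Env}, where genotype
#' levels include the check varieties (whose replication across blocks
#' supplies the residual degrees of freedom in an augmented design). F tests
#' are against the residual mean square.
#'
#' @param trial a \code{TrialTable} spanning >= 2 environments.
#' @param trait trait column name.
#' @return data.frame with rows Genotype (G), Environment (E),
#'   Interaction (G x E) and Residual; columns \code{df}, \code{mean_sq},
#'   \code{F}, \code{p}.
#' @export
anovaMeanSquares <- function(trial, trait) {
  stopifnot(is(trial, "TrialTable"))
  d <- as.data.frame(trial)
  if (length(unique(d$env)) < 2)
    stop("interaction undefined: need >= 2 environments")
  if (!trait %in% traitNames(trial)) stop("unknown trait: ", trait)
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  d$entryF <- factor(ifelse(d$is_check, d$check_id, d$entry_id))
  d$envF <- factor(d$env)
  d$blockF <- factor(d$block)
  multi_block <- any(tapply(d$blockF, d$envF, function(b) length(unique(b))) > 1)
  terms <- c("envF", if (multi_block) "envF:blockF", "entryF", "envF:entryF")
  f <- as.formula(paste(trait, "~", paste(terms, collapse = " + ")))
  a <- anova(lm(f, data = d))
  pick <- function(nm) {
    i <- match(nm, rownames(a))
    c(df = a$Df[i], mean_sq = a$`Mean Sq`[i], F = a$`F value`[i], p = a$`Pr(>F)`[i])
  }
  out <- rbind(`Genotype (G)` = pick("entryF"),
               `Environment (E)` = pick("envF"),
               `Interaction (G x E)` = pick("envF:entryF"),
               Residual = pick("Residuals"))
  data.frame(term = rownames(out), out, row.names = NULL, check.names = FALSE)
}

#' Estimate variance components for broad-sense heritability
#'
#' All-random REML fit (lme4):
#' \code{trait ~ covariate + (1 | Genotype) + (1 | Env) + (1 | Genotype:Env) +
#' (1 | Env:Block)}, genotype levels including checks. Components are
#' non-negative by construction of REML on the variance scale.
#'
#' @param trial a \code{TrialTable}.
#' @param trait trait column name.
#' @param covariate adjust for days to anthesis (default TRUE).
#' @return a \code{\linkS4class{VarianceComponents}} with \code{nEnv} the
#'   number of environments and \code{nRep} the median replication of test
#'   entries within an environment.
#' @export
estimateVarianceComponents <- function(trial, trait, covariate = TRUE) {
  stopifnot(is(trial, "TrialTable"))
  d <- as.data.frame(trial)
  if (!trait %in% traitNames(trial)) stop("unknown trait: ", trait)
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  d$entryF <- factor(ifelse(d$is_check, d$check_id, d$entry_id))
  d$envF <- factor(d$env)
  d$blockF <- factor(d$block)
  d$cov_c <- d$days_to_anthesis - mean(d$days_to_anthesis)
  n_env <- nlevels(d$envF)
  multi_block <- any(tapply(d$blockF, d$envF, function(b) length(unique(b))) > 1)

  fixed <- if (covariate && sd(d$cov_c) > 0) "cov_c" else "1"
  rand <- c("(1 | entryF)",
            if (n_env > 1) c("(1 | envF)", "(1 | entryF:envF)"),
            if (multi_block) "(1 | envF:blockF)")
  f <- as.formula(paste(trait, "~", fixed, "+", paste(rand, collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(f, data = d, control = .lmer_ctrl()))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  reps <- table(d$entry_id[!d$is_check], d$env[!d$is_check])
  n_rep <- max(1, stats::median(reps[reps > 0]))
  VarianceComponents(sigma2G = comp("entryF"),
                     sigma2GxE = comp("entryF:envF"),
                     sigma2E = comp("Residual"),
                     nEnv = n_env, nRep = n_rep)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{G\times E}/n +
#'   \sigma^2_e/(nr)}}
#' with n the number of environments and r the replications per environment
#' (r = 1 for an augmented design).
#'
#' @param vc a \code{\linkS4class{VarianceComponents}}.
#' @return heritability in [0, 1].
#' @examples
#' broadSenseHeritability(VarianceComponents(1, 1, 1, nEnv = 2, nRep = 1)) # 0.5
#' @export
broadSenseHeritability <- function(vc) {
  stopifnot(is(vc, "VarianceComponents"))
  if (vc@sigma2G + vc@sigma2GxE + vc@sigma2E <= 0)
    stop("all variance components are zero: heritability undefined")
  .h2_from_components(vc@sigma2G, vc@sigma2GxE, vc@sigma2E, vc@nEnv, vc@nRep)
}

#' Pairwise Pearson correlations between traits at the BLUE level
#'
#' Pairwise-complete Pearson correlation with two-sided p-values
#' (\code{cor.test}); pairs with a constant column or fewer than 3 complete
#' genotype rows are reported as \code{NA}.
#'
#' @param blues a \code{BlueTable}.
#' @return list with matrices \code{r}, \code{p} and \code{n} (complete
#'   pairs).
#' @export
traitCorrelations <- function(blues) {
  stopifnot(is(blues, "BlueTable"))
  v <- as.matrix(blues)
  t <- ncol(v); tn <- colnames(v)
  r <- p <- n <- matrix(NA_real_, t, t, dimnames = list(tn, tn))
  diag(r) <- 1; diag(p) <- 0
  diag(n) <- colSums(!is.na(v))
  for (i in seq_len(t)) for (j in seq_len(t)) {
    if (j >= i) next
    ok <- complete.cases(v[, c(i, j)])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3 || sd(v[ok, i]) == 0 || sd(v[ok, j]) == 0) next
    ct <- cor.test(v[ok, i], v[ok, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = n)
}
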