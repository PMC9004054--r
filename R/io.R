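## Plain-text readers and writers for the package's data objects.
## Marker CSV dialect: rows = line ids (first column), columns = marker ids,
## cells in {-1, 0, 1} or empty for missing. VCF is read through vcfR; the
## writer emits a minimal uncompressed VCFv4.2 with synthetic REF/ALT bases
## where REF is the major and ALT the minor allele, so GT fields are
## consistent with the -1/0/+1 coding.

#' Write / read a MarkerMatrix as CSV
#'
#' @param markers a \code{MarkerMatrix}.
#' @param file path to a CSV file.
#' @return \code{readMarkerCSV} returns a \code{MarkerMatrix};
#'   \code{writeMarkerCSV} returns \code{file} invisibly.
#' @export
writeMarkerCSV <- function(markers, file) {
  stopifnot(is(markers, "MarkerMatrix"))
  m <- as.matrix(markers)
  df <- data.frame(line_id = rownames(m), m, check.names = FALSE)
  write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' @rdname writeMarkerCSV
#' @export
readMarkerCSV <- function(file) {
  df <- read.csv(file, check.names = FALSE, na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  imputed <- any(abs(m - round(m)) > 1e-9, na.rm = TRUE)
  MarkerMatrix(m, imputed = imputed)
}

#' Write a MarkerMatrix as a minimal VCF
#'
#' Diploid GT fields consistent with the additive coding: +1 (homozygous
#' major) becomes \code{0/0}, 0 becomes \code{0/1}, -1 (homozygous minor)
#' becomes \code{1/1}, missing becomes \code{./.}. REF/ALT bases are
#' synthetic (A/G); markers are placed at consecutive 1-based positions on a
#' single chromosome. Only integer-coded (non-imputed) matrices can be
#' written.
#'
#' @param markers a \code{MarkerMatrix} with codes in \{-1, 0, +1\}/NA.
#' @param file output path (uncompressed \code{.vcf}).
#' @return \code{file}, invisibly.
#' @export
writeMarkerVCF <- function(markers, file) {
  stopifnot(is(markers, "MarkerMatrix"))
  m <- as.matrix(markers)
  if (any(abs(m - round(m)) > 1e-9, na.rm = TRUE))
    stop("only raw {-1, 0, +1} codes can be written as VCF")
  gt_of <- c("1/1", "0/1", "0/0")  # codes -1, 0, +1
  lines <- c("##fileformat=VCFv4.2",
             "##source=MultiTraitGP",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(m)), collapse = "\t"))
  body <- vapply(seq_len(ncol(m)), function(j) {
    gt <- ifelse(is.na(m[, j]), "./.", gt_of[m[, j] + 2])
    paste(c("1", j, colnames(m)[j], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), file)
  invisible(file)
}

#' Read coded markers from a VCF
#'
#' GT fields are converted to ALT-allele dosages 0/1/2 and then to the
#' additive \{-1, 0, +1\} coding oriented by the minor allele: the
#' homozygous-minor genotype is coded -1 (minor allele determined from the
#' observed allele frequency at each site, ties resolved to ALT).
#'
#' @param file path to a VCF (plain or bgzipped; anything vcfR reads).
#' @return a \code{\linkS4class{MarkerMatrix}}.
#' @export
readMarkerVCF <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ## ALT dosage from diploid GT, tolerant of / or | separators
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean %in% c("0/0")] <- 0
  dose[clean %in% c("0/1", "1/0")] <- 1
  dose[clean %in% c("1/1")] <- 2
  ## orient by minor allele per site (ties: ALT is minor)
  altf <- rowMeans(dose, na.rm = TRUE) / 2
  codes <- dose
  alt_minor <- altf <= 0.5
  codes[alt_minor, ] <- 1 - dose[alt_minor, , drop = FALSE]
  codes[!alt_minor, ] <- dose[!alt_minor, , drop = FALSE] - 1
  codes <- t(codes)  # lines x markers
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("M%05d", seq_len(ncol(codes)))
  MarkerMatrix(codes)
}

#' Write / read a KinshipMatrix as CSV
#'
#' Line ids are written as both header and first column.
#'
#' @param kinship a \code{KinshipMatrix}.
#' @param file path to a CSV file.
#' @return \code{readKinshipCSV} returns a \code{KinshipMatrix}.
#' @export
writeKinshipCSV <- function(kinship, file) {
  stopifnot(is(kinship, "KinshipMatrix"))
  k <- as.matrix(kinship)
  df <- data.frame(line_id = rownames(k), k, check.names = FALSE)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeKinshipCSV
#' @export
readKinshipCSV <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  k <- as.matrix(df[, -1, drop = FALSE])
  rownames(k) <- df[[1]]
  KinshipMatrix(k)
}

#' Write / read a TrialTable as long-format CSV
#'
#' Columns: env, block, entry_id, is_check, check_id (empty for test
#' entries), days_to_anthesis, then one column per trait.
#'
#' @param trial a \code{TrialTable}.
#' @param file path to a CSV file.
#' @param traitNames trait columns (for \code{readTrialCSV}; default = all
#'   columns after the design columns).
#' @return \code{readTrialCSV} returns a \code{TrialTable}.
#' @export
writeTrialCSV <- function(trial, file) {
  stopifnot(is(trial, "TrialTable"))
  write.csv(as.data.frame(trial), file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' @rdname writeTrialCSV
#' @export
readTrialCSV <- function(file, traitNames = NULL) {
  df <- read.csv(file, check.names = FALSE, na.strings = "")
  df$is_check <- as.logical(df$is_check)
  TrialTable(df, traitNames = traitNames)
}

#' Write / read a BlueTable as CSV
#'
#' @param blues a \code{BlueTable}.
#' @param file path to a CSV file; conventionally carries the dataset label,
#'   e.g. \code{blues_combined.csv}.
#' @param datasetLabel label to attach on reading.
#' @return \code{readBlueCSV} returns a \code{BlueTable}.
#' @export
writeBlueCSV <- function(blues, file) {
  stopifnot(is(blues, "BlueTable"))
  v <- as.matrix(blues)
  df <- data.frame(genotype = rownames(v), v, check.names = FALSE)
  write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' @rdname writeBlueCSV
#' @export
readBlueCSV <- function(file, datasetLabel = "combined") {
  df <- read.csv(file, check.names = FALSE, na.strings = "")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  BlueTable(v, datasetLabel = datasetLabel)
}

.matrix_to_list <- function(m) {
  list(rows = rownames(m), cols = colnames(m), data = as.numeric(m))
}
.list_to_matrix <- function(l) {
  matrix(l$data, nrow = length(l$rows),
         dimnames = list(l$rows, l$cols))
}

#' Serialize / restore a SimTruth as a YAML sidecar
#'
#' @param truth a \code{SimTruth}.
#' @param file path to a YAML file.
#' @return \code{readSimTruth} returns a \code{SimTruth}.
#' @export
writeSimTruth <- function(truth, file) {
  stopifnot(is(truth, "SimTruth"))
  obj <- list(
    genetic_covariance = .matrix_to_list(truth@geneticCovariance),
    residual_variances = as.numeric(truth@residualVariances),
    gxe_variances = as.numeric(truth@gxeVariances),
    env_effects = .matrix_to_list(truth@envEffects),
    breeding_values = .matrix_to_list(truth@breedingValues),
    heritabilities = as.numeric(truth@heritabilities),
    covariate_slope = as.numeric(truth@covariateSlope),
    anthesis_dates = list(ids = names(truth@anthesisDates),
                          values = as.numeric(truth@anthesisDates)),
    n_env = truth@nEnv, n_rep = truth@nRep, seed = truth@seed)
  yaml::write_yaml(obj, file, precision = 17)
  invisible(file)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(file) {
  l <- yaml::read_yaml(file)
  new("SimTruth",
      geneticCovariance = .list_to_matrix(l$genetic_covariance),
      residualVariances = as.numeric(l$residual_variances),
      gxeVariances = as.numeric(l$gxe_variances),
      envEffects = .list_to_matrix(l$env_effects),
      breedingValues = .list_to_matrix(l$breeding_values),
      heritabilities = as.numeric(l$heritabilities),
      covariateSlope = as.numeric(l$covariate_slope),
      anthesisDates = setNames(as.numeric(l$anthesis_dates$values),
                               l$anthesis_dates$ids),
      nEnv = l$n_env, nRep = l$n_rep, seed = l$seed)
}
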