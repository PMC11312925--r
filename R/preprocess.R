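#' @title Glycopeptide abundance preprocessing
#' @description Raw glycopeptide intensities are carried as a numeric matrix
#'   (individuals in rows, glycoform names in columns) with a `stage`
#'   attribute tracking the preprocessing state: `"raw"`, `"relative"`,
#'   `"outlier-filtered"` or `"quantile-normalized"`. Missing measurements
#'   are `NA`. The pipeline order is fixed: peptide-wise total-area
#'   normalisation, then 4-SD outlier masking, then rank-based
#'   inverse-normal (quantile) normalisation.
#' @name preprocess
NULL

abundance_stage <- function(x) {
  s <- attr(x, "stage")
  if (is.null(s)) "raw" else s
}

`abundance_stage<-` <- function(x, value) {
  attr(x, "stage") <- value
  x
}

#' Peptide-wise total-area normalisation
#'
#' Converts raw glycopeptide intensities to relative abundances by dividing
#' each intensity by the intensity sum of all glycopeptide species sharing
#' the same tryptic peptide, per individual. Peptide groups whose intensities
#' are all zero (or all missing) for an individual become missing for that
#' individual rather than 0/0.
#'
#' @param raw numeric matrix, individuals x glycoforms, intensities >= 0;
#'   column names must be parseable glycoform names unless `peptides` is
#'   supplied.
#' @param peptides optional character vector assigning each column to a
#'   peptide group; derived from the column names by default.
#' @return matrix of relative abundances with stage `"relative"`; within each
#'   individual the non-missing abundances of each peptide sum to 1.
#' @export
total_area_normalize <- function(raw, peptides = NULL) {
  stopifnot(is.matrix(raw), is.numeric(raw))
  if (any(raw < 0, na.rm = TRUE)) stop("negative intensity", call. = FALSE)
  if (is.null(peptides)) peptides <- parse_glycoform_name(colnames(raw))$peptide
  stopifnot(length(peptides) == ncol(raw))
  rel <- raw
  for (pep in unique(peptides)) {
    idx <- which(peptides == pep)
    block <- raw[, idx, drop = FALSE]
    tot <- rowSums(block, na.rm = TRUE)
    all_na <- rowSums(!is.na(block)) == 0L
    tot[tot == 0 | all_na] <- NA_real_
    rel[, idx] <- block / tot
  }
  abundance_stage(rel) <- "relative"
  rel
}

#' Mask outliers beyond k standard deviations from the mean
#'
#' Single-pass rule: the mean and SD are computed once from all non-missing
#' values, and entries strictly more than `k` SDs away from the mean are
#' masked. A value lying exactly at `mean + k * SD` is retained, and a
#' constant vector (SD = 0) masks nothing.
#'
#' @param values numeric vector (at least 2 non-missing values).
#' @param k SD multiplier; default 4.
#' @return logical vector: `TRUE` where the entry is retained, `NA` stays `NA`.
#' @export
remove_outliers <- function(values, k = 4) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  keep <- rep(NA, length(values))
  keep[ok] <- abs(values[ok] - m) <= k * s
  keep
}

#' Apply the outlier mask column-wise to an abundance table
#'
#' Convenience wrapper: masks (sets to `NA`) entries of each column that
#' [remove_outliers()] flags, and advances the stage tag.
#'
#' @param x abundance matrix at stage `"relative"` (or a derived-trait table).
#' @param k SD multiplier; default 4.
#' @return matrix with outliers set to `NA`, stage `"outlier-filtered"`.
#' @export
mask_outliers <- function(x, k = 4) {
  stopifnot(is.matrix(x))
  for (j in seq_len(ncol(x))) {
    if (sum(!is.na(x[, j])) < 2L) next
    keep <- remove_outliers(x[, j], k = k)
    x[which(!keep), j] <- NA_real_
  }
  abundance_stage(x) <- "outlier-filtered"
  x
}

#' Rank-based inverse-normal (quantile) normalisation
#'
#' Maps values to standard-normal quantiles by rank: a value of rank `r`
#' among `n` non-missing values (ties receive the average rank) is mapped to
#' `qnorm(r / (n + 1))`. The transform is monotone and missing entries stay
#' missing. The `offset` argument selects the rank offset: `"r/(n+1)"`
#' (default) or Blom's `(r - 3/8)/(n + 1/4)`; the two differ negligibly.
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @param offset rank-to-probability rule.
#' @return numeric vector of normal scores.
#' @export
quantile_normalize <- function(values, offset = c("r/(n+1)", "blom")) {
  offset <- match.arg(offset)
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  r <- rank(values[ok], ties.method = "average")
  n <- sum(ok)
  p <- if (offset == "blom") (r - 3 / 8) / (n + 1 / 4) else r / (n + 1)
  out <- values
  out[ok] <- stats::qnorm(p)
  out
}

#' Full preprocessing pipeline for a raw intensity table
#'
#' Runs, in fixed order: peptide-wise total-area normalisation, 4-SD outlier
#' masking per glycopeptide, and quantile normalisation per glycopeptide.
#' The intermediate relative-abundance table (after outlier masking) is what
#' conversion-rate ratios consume; the quantile-normalised table is what the
#' association and twin models consume.
#'
#' @param raw numeric matrix of raw intensities (individuals x glycoforms).
#' @param k outlier SD multiplier (default 4).
#' @param offset rank offset rule passed to [quantile_normalize()].
#' @return list with elements `relative` (stage `"outlier-filtered"`,
#'   untransformed relative abundances with outliers masked) and `normalized`
#'   (stage `"quantile-normalized"`), plus `log`, a character vector of the
#'   steps applied.
#' @export
preprocess_abundances <- function(raw, k = 4, offset = "r/(n+1)") {
  rel <- total_area_normalize(raw)
  rel <- mask_outliers(rel, k = k)
  qn <- rel
  for (j in seq_len(ncol(qn))) qn[, j] <- quantile_normalize(qn[, j], offset = offset)
  abundance_stage(qn) <- "quantile-normalized"
  list(
    relative = rel,
    normalized = qn,
    log = c("total_area_normalize", sprintf("mask_outliers(k=%g)", k),
            sprintf("quantile_normalize(offset=%s)", offset))
  )
}
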