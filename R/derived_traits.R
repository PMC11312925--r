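#' Derived glycosylation trait definitions
#'
#' A derived trait summarises structurally related glycoforms expressed on a
#' single tryptic peptide into one number per individual, computed from
#' relative abundances as
#' `sum(weight * abundance over numerator) / sum(weight * abundance over denominator)`,
#' with denominator `"1"` meaning a plain weighted sum. Typical families are
#' fraction sialylated, average sialic acids per glycoform, galactosylation,
#' fucosylation and bisection of a peptide's glycoform panel.
#'
#' @param name trait identifier.
#' @param peptide peptide code all referenced glycoforms must share.
#' @param numerator named numeric vector: `c(glycoform = weight, ...)`.
#' @param denominator named numeric vector like `numerator`, or the string
#'   `"1"` for a weighted sum.
#' @return an object of class `derived_trait_definition`.
#' @examples
#' derived_trait_definition("TPL_nS", "TPL",
#'   numerator = c(TPL_H5N5F1S1 = 1, TPL_H5N5F1S2 = 2),
#'   denominator = c(TPL_H5N5F1S0 = 1, TPL_H5N5F1S1 = 1, TPL_H5N5F1S2 = 1))
#' @export
derived_trait_definition <- function(name, peptide, numerator, denominator = "1") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(peptide), length(peptide) == 1L, nzchar(peptide))
  check_side <- function(side, what) {
    if (identical(side, "1")) return(invisible())
    if (!is.numeric(side) || is.null(names(side)) || any(!nzchar(names(side))))
      stop(what, " must be a named numeric vector or \"1\"", call. = FALSE)
    if (any(!is.finite(side))) stop(what, " weights must be finite", call. = FALSE)
    peps <- parse_glycoform_name(names(side))$peptide
    if (any(peps != peptide))
      stop(what, " references glycoforms off peptide ", peptide, call. = FALSE)
  }
  check_side(numerator, "numerator")
  check_side(denominator, "denominator")
  structure(list(name = name, peptide = peptide,
                 numerator = numerator, denominator = denominator),
            class = "derived_trait_definition")
}

#' @export
print.derived_trait_definition <- function(x, ...) {
  side <- function(s) {
    if (identical(s, "1")) return("1")
    paste(sprintf("%g*%s", unname(s), names(s)), collapse = " + ")
  }
  cat(x$name, " [", x$peptide, "]: (", side(x$numerator), ") / (",
      side(x$denominator), ")\n", sep = "")
  invisible(x)
}

#' Read derived-trait definitions from a YAML config
#'
#' The config is a YAML list; each entry has fields `name`, `peptide`,
#' `numerator` (mapping glycoform -> weight) and `denominator` (mapping, or
#' the string `"1"`).
#'
#' @param path YAML file path.
#' @return list of [derived_trait_definition()] objects.
#' @export
read_trait_definitions <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(d) {
    num <- unlist(d$numerator)
    den <- if (identical(d$denominator, "1")) "1" else unlist(d$denominator)
    derived_trait_definition(d$name, d$peptide, num, den)
  })
}

#' Standard derived-trait families for a glycoform panel
#'
#' Builds, for each peptide in `compositions`, illustrative definitions of
#' the glycosylation-feature families: average sialic acids per glycoform
#' (`<pep>_nS`), fraction sialylated (`<pep>_Sfrac`), average hexoses
#' (galactosylation proxy, `<pep>_nG`), fraction fucosylated (`<pep>_Ffrac`)
#' and fraction bisected (`<pep>_bis`, glycoforms with N >= `bisect_n`).
#' Definitions whose numerator would be empty (feature absent from the
#' panel) are dropped.
#'
#' @param compositions a `glycoform_composition` data frame
#'   ([parse_glycoform_name()]).
#' @param bisect_n N-acetylhexosamine count from which a glycoform counts as
#'   bisected; default 5.
#' @return list of [derived_trait_definition()] objects.
#' @export
standard_trait_definitions <- function(compositions, bisect_n = 5L) {
  defs <- list()
  for (pep in unique(compositions$peptide)) {
    cc <- compositions[compositions$peptide == pep, , drop = FALSE]
    all1 <- stats::setNames(rep(1, nrow(cc)), cc$name)
    add <- function(nm, num) {
      if (length(num) == 0L || all(num == 0)) return(invisible())
      defs[[length(defs) + 1L]] <<-
        derived_trait_definition(nm, pep, num, all1)
    }
    add(paste0(pep, "_nS"), stats::setNames(as.numeric(cc$S), cc$name))
    add(paste0(pep, "_Sfrac"),
        stats::setNames(rep(1, sum(cc$S >= 1L)), cc$name[cc$S >= 1L]))
    add(paste0(pep, "_nG"), stats::setNames(as.numeric(cc$H), cc$name))
    add(paste0(pep, "_Ffrac"),
        stats::setNames(rep(1, sum(cc$F >= 1L)), cc$name[cc$F >= 1L]))
    add(paste0(pep, "_bis"),
        stats::setNames(rep(1, sum(cc$N >= bisect_n)), cc$name[cc$N >= bisect_n]))
  }
  defs
}

#' Compute derived traits from relative abundances
#'
#' Evaluates each definition per individual on a relative-abundance table.
#' Missing abundances propagate to the trait; zero denominators yield
#' missing values (counted in the `"zero_denominator"` attribute) rather
#' than errors, since compositional zeros are expected at small n.
#'
#' @param relative abundance matrix at stage `"relative"` or
#'   `"outlier-filtered"` (untransformed relative abundances).
#' @param defs list of [derived_trait_definition()] objects.
#' @return numeric matrix, individuals x traits, with a `zero_denominator`
#'   attribute giving the per-trait count of zero-denominator individuals.
#' @export
compute_derived_traits <- function(relative, defs) {
  stopifnot(is.matrix(relative))
  if (inherits(defs, "derived_trait_definition")) defs <- list(defs)
  out <- matrix(NA_real_, nrow(relative), length(defs),
                dimnames = list(rownames(relative),
                                vapply(defs, `[[`, "", "name")))
  zden <- integer(length(defs))
  side_value <- function(side) {
    if (identical(side, "1")) return(rep(1, nrow(relative)))
    miss <- setdiff(names(side), colnames(relative))
    if (length(miss))
      stop("unknown glycoform(s) in definition: ",
           paste(miss, collapse = ", "), call. = FALSE)
    as.numeric(relative[, names(side), drop = FALSE] %*% unname(side))
  }
  for (k in seq_along(defs)) {
    num <- side_value(defs[[k]]$numerator)
    den <- side_value(defs[[k]]$denominator)
    zero <- !is.na(den) & den == 0
    zden[k] <- sum(zero)
    den[zero] <- NA_real_
    out[, k] <- num / den
  }
  attr(out, "zero_denominator") <- stats::setNames(zden, colnames(out))
  out
}
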