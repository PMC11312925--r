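#' Parse glycoform names into peptide and monosaccharide counts
#'
#' Glycopeptide species are named `<PEPTIDE>_H<h>N<n>F<f>S<s>`, where the
#' peptide code is the letter code of the tryptic peptide (e.g. `HYT`, `LSL`,
#' `TPL`, `SES`, `ENI`, `LAGC`, `LAGY`, or an IgG peptide code) and the four
#' integers count hexoses (H), N-acetylhexosamines (N), fucoses (F) and
#' sialic acids (S) of the glycan composition. The composition is the
#' coordinate system for derived traits and for enzymatic reaction chains.
#'
#' @param name character vector of glycoform names, e.g. `"TPL_H5N5F1S2"`.
#' @return A data frame of class `glycoform_composition` with columns
#'   `name`, `peptide`, `H`, `N`, `F`, `S`, one row per input name.
#' @examples
#' parse_glycoform_name("TPL_H5N5F1S2")
#' parse_glycoform_name(c("HYT_H3N5F0S0", "LAGC_H5N4F0S1"))
#' @export
parse_glycoform_name <- function(name) {
  stopifnot(is.character(name), length(name) >= 1L)
  rx <- "^([A-Za-z]+)_H([0-9]+)N([0-9]+)F([0-9]+)S([0-9]+)$"
  bad <- !grepl(rx, name)
  if (any(bad)) {
    stop("malformed glycoform name(s): ",
         paste(utils::head(name[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    name    = name,
    peptide = sub(rx, "\\1", name),
    H       = as.integer(sub(rx, "\\2", name)),
    N       = as.integer(sub(rx, "\\3", name)),
    F       = as.integer(sub(rx, "\\4", name)),
    S       = as.integer(sub(rx, "\\5", name)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("glycoform_composition", "data.frame")
  out
}

#' Format glycoform compositions back into names
#'
#' Inverse of [parse_glycoform_name()]: `format_glycoform(parse_glycoform_name(x))`
#' returns `x`.
#'
#' @param x a `glycoform_composition` data frame (or any data frame with
#'   columns `peptide`, `H`, `N`, `F`, `S`).
#' @return character vector of names.
#' @export
format_glycoform <- function(x) {
  stopifnot(all(c("peptide", "H", "N", "F", "S") %in% names(x)))
  sprintf("%s_H%dN%dF%dS%d", x$peptide, x$H, x$N, x$F, x$S)
}

#' @export
print.glycoform_composition <- function(x, ...) {
  cat("Glycoform compositions (", nrow(x), " species, ",
      length(unique(x$peptide)), " peptide(s))\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
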