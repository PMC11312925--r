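#' Enumerate substrate/product reaction pairs in composition space
#'
#' A glycosyltransferase reaction adds exactly one residue: sialylation
#' S+1, galactosylation H+1, N-acetylgalactosaminylation N+1, fucosylation
#' F+1. This enumerates all pairs of same-peptide glycoforms differing by
#' exactly +1 in the reaction's residue and by 0 elsewhere; the per-pair
#' product/substrate abundance ratio is the descriptive proxy for the
#' reaction's conversion rate.
#'
#' @param compositions a `glycoform_composition` data frame (duplicates
#'   removed) or character vector of glycoform names.
#' @param type reaction type: `"sialylation"`, `"galactosylation"`,
#'   `"galnac"` (N-acetylgalactosaminylation) or `"fucosylation"`.
#' @return data frame with columns `substrate`, `product`, `peptide`,
#'   `type`, sorted by peptide then substrate composition.
#' @examples
#' identify_reaction_pairs(c("TPL_H5N5F1S0", "TPL_H5N5F1S1", "TPL_H5N5F1S2"),
#'                         "sialylation")
#' @export
identify_reaction_pairs <- function(compositions,
                                    type = c("sialylation", "galactosylation",
                                             "galnac", "fucosylation")) {
  type <- match.arg(type)
  if (is.character(compositions)) compositions <- parse_glycoform_name(compositions)
  cc <- unique(as.data.frame(compositions))
  residue <- switch(type, sialylation = "S", galactosylation = "H",
                    galnac = "N", fucosylation = "F")
  others <- setdiff(c("H", "N", "F", "S"), residue)
  key <- function(d) do.call(paste, c(d[c("peptide", others)], sep = "_"))
  cc$.key <- key(cc)
  rows <- list()
  for (k in unique(cc$.key)) {
    grp <- cc[cc$.key == k, , drop = FALSE]
    grp <- grp[order(grp[[residue]]), , drop = FALSE]
    cnt <- grp[[residue]]
    for (i in seq_len(nrow(grp))) {
      j <- match(cnt[i] + 1L, cnt)
      if (!is.na(j)) {
        rows[[length(rows) + 1L]] <- data.frame(
          substrate = grp$name[i], product = grp$name[j],
          peptide = grp$peptide[i], type = type, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(substrate = character(), product = character(),
                      peptide = character(), type = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$peptide, out$substrate), , drop = FALSE]
}

#' Per-individual conversion-rate ratio of a reaction pair
#'
#' Ratio of product to substrate relative abundance, computed on
#' untransformed relative frequencies (after outlier masking, never on
#' quantile-normalised values). Individuals with a zero or missing
#' substrate, or a missing product, get a missing ratio. The summary
#' reports the median and interquartile range of the ratios.
#'
#' @param substrate,product numeric vectors of relative abundances (same
#'   individuals).
#' @return list: `ratio` (numeric vector), `n` (non-missing ratios),
#'   `median`, `iqr` (length-2, 25th and 75th percentiles).
#' @export
conversion_ratio <- function(substrate, product) {
  stopifnot(length(substrate) == length(product))
  ratio <- ifelse(is.na(substrate) | is.na(product) | substrate == 0,
                  NA_real_, product / substrate)
  if (all(is.na(ratio))) stop("all ratios missing", call. = FALSE)
  qq <- stats::quantile(ratio, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  list(ratio = ratio, n = sum(!is.na(ratio)),
       median = stats::median(ratio, na.rm = TRUE), iqr = qq)
}

#' Assemble multi-step conversion chains from reaction pairs
#'
#' Builds maximal directed paths in the substrate -> product graph of one
#' reaction type: chains of at least two consecutive enzymatic
#' transformations of the same underlying glycan structure (e.g.
#' `TPL_H5N5F1S0 -> TPL_H5N5F1S1 -> TPL_H5N5F1S2` for sequential
#' sialylation). Isolated single pairs do not form chains.
#'
#' @param pairs data frame from [identify_reaction_pairs()].
#' @return list of chains; each chain is a character vector of glycoform
#'   names along the path (length >= 3, i.e. >= 2 steps).
#' @export
build_conversion_chains <- function(pairs) {
  if (!nrow(pairs)) return(list())
  succ <- stats::setNames(pairs$product, pairs$substrate)
  starts <- setdiff(pairs$substrate, pairs$product)
  chains <- list()
  for (s in starts) {
    path <- s
    while (!is.na(succ[utils::tail(path, 1L)])) {
      path <- c(path, unname(succ[utils::tail(path, 1L)]))
      if (length(path) > length(succ) + 1L) break  # cycle guard
    }
    if (length(path) >= 3L) chains[[length(chains) + 1L]] <- path
  }
  chains
}

#' Compare conversion rates of consecutive reaction steps
#'
#' Along a conversion chain, tests whether the ratio distribution of each
#' step differs from the next one: paired Wilcoxon signed-rank test on the
#' per-individual ratios of the two steps (the same individuals contribute
#' both ratios; the unpaired rank-sum variant is available via
#' `paired = FALSE`). The direction compares step medians; the Bonferroni
#' bound divides `alpha` by the number of junctions actually tested.
#'
#' @param relative relative-abundance matrix (stage `"relative"` or
#'   `"outlier-filtered"`) with the chain's glycoforms as columns.
#' @param chain character vector of glycoform names along the chain
#'   (from [build_conversion_chains()]).
#' @param paired use the signed-rank (paired) Wilcoxon test; default `TRUE`.
#' @param alpha family-wise error rate for the Bonferroni bound; default 0.05.
#' @param min_pairs minimum paired non-missing ratios per junction; default 10.
#' @return data frame: one row per junction with `step1`, `step2` (labels
#'   `substrate->product`), `n`, `median1`, `median2`, `p`, `direction`
#'   (`"decrease"`, `"increase"` or `"equal"`), `threshold`, `significant`.
#' @export
compare_consecutive_steps <- function(relative, chain, paired = TRUE,
                                      alpha = 0.05, min_pairs = 10L) {
  stopifnot(is.matrix(relative), length(chain) >= 3L,
            all(chain %in% colnames(relative)))
  n_steps <- length(chain) - 1L
  ratios <- lapply(seq_len(n_steps), function(i) {
    conversion_ratio(relative[, chain[i]], relative[, chain[i + 1L]])$ratio
  })
  n_junctions <- n_steps - 1L
  thr <- bonferroni_threshold(alpha, n_junctions)
  rows <- vector("list", n_junctions)
  for (j in seq_len(n_junctions)) {
    r1 <- ratios[[j]]; r2 <- ratios[[j + 1L]]
    ok <- !is.na(r1) & !is.na(r2)
    if (sum(ok) < min_pairs)
      stop("insufficient pairs at junction ", j, " (", sum(ok), " < ",
           min_pairs, ")", call. = FALSE)
    m1 <- stats::median(r1[ok]); m2 <- stats::median(r2[ok])
    if (isTRUE(all.equal(r1[ok], r2[ok]))) {
      p <- 1
      dir <- "equal"
    } else {
      wt <- if (paired) {
        suppressWarnings(stats::wilcox.test(r1[ok], r2[ok], paired = TRUE))
      } else {
        suppressWarnings(stats::wilcox.test(r1[ok], r2[ok]))
      }
      p <- wt$p.value
      dir <- if (m2 < m1) "decrease" else if (m2 > m1) "increase" else "equal"
    }
    rows[[j]] <- data.frame(
      step1 = paste0(chain[j], "->", chain[j + 1L]),
      step2 = paste0(chain[j + 1L], "->", chain[j + 2L]),
      n = sum(ok), median1 = m1, median2 = m2, p = p, direction = dir,
      threshold = thr, significant = p < thr, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Full ratio pipeline for one reaction type
#'
#' Enumerates reaction pairs on the panel's glycoforms, assembles
#' multi-step chains, and tests all consecutive-step junctions, using the
#' total number of junctions across chains as the Bonferroni denominator.
#'
#' @param relative relative-abundance matrix with glycoform column names.
#' @inheritParams identify_reaction_pairs
#' @inheritParams compare_consecutive_steps
#' @return list: `pairs`, `chains`, `junctions` (combined junction table
#'   across chains with a chain id column, Bonferroni over all junctions),
#'   `n_junctions`.
#' @export
conversion_chain_analysis <- function(relative, type = "sialylation",
                                      paired = TRUE, alpha = 0.05,
                                      min_pairs = 10L) {
  pairs <- identify_reaction_pairs(colnames(relative), type)
  chains <- build_conversion_chains(pairs)
  n_junctions <- sum(vapply(chains, length, 0L) - 2L)
  rows <- list()
  for (ci in seq_along(chains)) {
    tab <- compare_consecutive_steps(relative, chains[[ci]], paired = paired,
                                     alpha = alpha, min_pairs = min_pairs)
    tab$threshold <- bonferroni_threshold(alpha, n_junctions)
    tab$significant <- tab$p < tab$threshold
    tab <- cbind(chain = ci, tab)
    rows[[ci]] <- tab
  }
  list(pairs = pairs, chains = chains,
       junctions = if (length(rows)) do.call(rbind, rows) else NULL,
       n_junctions = n_junctions)
}
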