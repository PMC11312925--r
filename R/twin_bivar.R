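#' @title Bivariate twin variance decomposition
#' @description Internal machinery: each twin pair contributes a 4-variate
#'   normal observation (x1, y1, x2, y2). The within-individual covariance
#'   is G + E and the cross-twin block is r * G with r = 1 (MZ) or 1/2
#'   (DZ), where G and E are Cholesky-parameterised 2x2 genetic and
#'   environmental covariance matrices (bivariate AE model; a shared-C
#'   extension is not fitted because the shared-heritability arithmetic
#'   uses only h2 and 1 - h2).
#' @name twin_bivar_internal
NULL

# Sufficient statistics of a 4-variate group: n, column sums, scatter.
quad_suffstats <- function(Z) {
  list(n = nrow(Z), s = colSums(Z), S = crossprod(Z))
}

# Build the 4x4 pair covariance from Cholesky factors (la, le are length-3
# lower-triangular entries: l11, l21, l22).
biv_cov <- function(la, le, r) {
  La <- matrix(c(la[1], la[2], 0, la[3]), 2, 2)
  Le <- matrix(c(le[1], le[2], 0, le[3]), 2, 2)
  G <- La %*% t(La); E <- Le %*% t(Le)
  W <- G + E
  rbind(cbind(W, r * G), cbind(r * G, W))
}

biv_negloglik <- function(theta, st_mz, st_dz, constraint = NULL) {
  if (!is.null(constraint)) theta <- constraint(theta)
  mu <- rep(theta[1:2], 2L)
  la <- theta[3:5]; le <- theta[6:8]
  total <- 0
  for (g in list(list(st = st_mz, r = 1), list(st = st_dz, r = 0.5))) {
    Om <- biv_cov(la, le, g$r)
    ch <- tryCatch(chol(Om), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- 2 * sum(log(diag(ch)))
    Oi <- chol2inv(ch)
    st <- g$st
    quad <- sum(Oi * st$S) - 2 * sum(mu * (Oi %*% st$s)) +
      st$n * sum(mu * (Oi %*% mu))
    total <- total + st$n / 2 * (4 * log(2 * pi) + ldet) + quad / 2
  }
  total
}

fit_biv_once <- function(st_mz, st_dz, theta0, constraint = NULL, free = NULL) {
  if (is.null(free)) free <- seq_along(theta0)
  nll <- function(th_free) {
    th <- theta0
    th[free] <- th_free
    biv_negloglik(th, st_mz, st_dz, constraint = constraint)
  }
  opt <- stats::optim(theta0[free], nll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-12))
  opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-12))
  th <- theta0
  th[free] <- opt$par
  if (!is.null(constraint)) th <- constraint(th)
  list(theta = th, logLik = -opt$value, converged = opt$convergence == 0L)
}

#' Bivariate twin model: heritabilities and genetic/environmental correlations
#'
#' Maximum-likelihood bivariate AE variance decomposition on twin pairs:
#' returns the heritability of each trait, the genetic (`rho_g`),
#' environmental (`rho_e`) and phenotypic (`rho_p`) cross-trait
#' correlations, and likelihood-ratio test p-values for each correlation
#' being zero (the null model refits with the corresponding covariance
#' constrained to 0; the chi-square(1) reference is the standard choice and
#' is only asymptotic for correlations near the +-1 boundary).
#'
#' @param pairs a `twin_pairs` data frame with columns `zygosity`, `x1`,
#'   `y1`, `x2`, `y2` ([make_twin_pairs()] with a two-column trait), both
#'   traits standardised; at least 20 MZ and 20 DZ pairs.
#' @param lrt which likelihood-ratio tests to compute: `TRUE` (all of
#'   `rho_g`, `rho_e`, `rho_p`), `FALSE` (none), or a character subset;
#'   each test requires a constrained refit.
#' @return object of class `twin_bivar` with elements `h2_x`, `h2_y`,
#'   `rho_g`, `rho_e`, `rho_p`, `p_rho_g`, `p_rho_e`, `p_rho_p`, `G`, `E`
#'   (2x2 covariance matrices), `logLik`, `df`, `AIC`, `converged`.
#' @examples
#' samples <- simulate_samples(cohort_design(250, 250, 0), seed = 3)
#' bm <- bivariate_trait_model(trait_model(0.5, 0, 0.5),
#'                             trait_model(0.5, 0, 0.5), rho_g = 0.6, rho_e = 0.2)
#' tr <- simulate_bivariate_traits(samples, bm, seed = 3)
#' fit <- twin_bivar(make_twin_pairs(samples, tr[, c("x", "y")]))
#' fit$rho_g
#' @export
twin_bivar <- function(pairs, lrt = TRUE) {
  stopifnot(inherits(pairs, "twin_pairs"),
            all(c("x1", "y1", "x2", "y2") %in% names(pairs)))
  mz <- as.matrix(pairs[pairs$zygosity == "MZ", c("x1", "y1", "x2", "y2")])
  dz <- as.matrix(pairs[pairs$zygosity == "DZ", c("x1", "y1", "x2", "y2")])
  if (nrow(mz) < 20L || nrow(dz) < 20L)
    stop("need at least 20 MZ and 20 DZ pairs", call. = FALSE)
  st_mz <- quad_suffstats(mz)
  st_dz <- quad_suffstats(dz)

  # Moment-based start: MZ cross-twin block estimates G, within-person
  # covariance estimates G + E.
  cmz <- stats::cov(mz); cdz <- stats::cov(dz)
  W0 <- (cmz[1:2, 1:2] + cmz[3:4, 3:4] + cdz[1:2, 1:2] + cdz[3:4, 3:4]) / 4
  B0 <- (cmz[1:2, 3:4] + t(cmz[1:2, 3:4])) / 2
  G0 <- B0; E0 <- W0 - G0
  psd <- function(M, floor = 0.05) {
    ei <- eigen((M + t(M)) / 2, symmetric = TRUE)
    ei$vectors %*% diag(pmax(ei$values, floor)) %*% t(ei$vectors)
  }
  ch <- function(M) { L <- t(chol(psd(M))); c(L[1, 1], L[2, 1], L[2, 2]) }
  theta0 <- c(mean(c(mz[, c(1, 3)], dz[, c(1, 3)])),
              mean(c(mz[, c(2, 4)], dz[, c(2, 4)])),
              ch(G0), ch(E0))

  full <- fit_biv_once(st_mz, st_dz, theta0)
  th <- full$theta
  La <- matrix(c(th[3], th[4], 0, th[5]), 2, 2)
  Le <- matrix(c(th[6], th[7], 0, th[8]), 2, 2)
  G <- La %*% t(La); E <- Le %*% t(Le)
  P <- G + E
  rho_g <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
  rho_e <- E[1, 2] / sqrt(E[1, 1] * E[2, 2])
  rho_p <- P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  h2_x <- G[1, 1] / P[1, 1]
  h2_y <- G[2, 2] / P[2, 2]

  which_lrt <- if (isTRUE(lrt)) c("rho_g", "rho_e", "rho_p")
  else if (isFALSE(lrt)) character() else match.arg(lrt, c("rho_g", "rho_e", "rho_p"),
                                                    several.ok = TRUE)
  p_g <- p_e <- p_p <- NA_real_
  conv <- full$converged
  lr_p <- function(fit0) {
    stat <- max(0, 2 * (full$logLik - fit0$logLik))
    stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  }
  if ("rho_g" %in% which_lrt) {
    # rho_g = 0 <=> La[2,1] = 0
    th_g0 <- th; th_g0[4] <- 0
    fit_g0 <- fit_biv_once(st_mz, st_dz, th_g0, free = c(1:3, 5:8))
    p_g <- lr_p(fit_g0); conv <- conv && fit_g0$converged
  }
  if ("rho_e" %in% which_lrt) {
    # rho_e = 0 <=> Le[2,1] = 0
    th_e0 <- th; th_e0[7] <- 0
    fit_e0 <- fit_biv_once(st_mz, st_dz, th_e0, free = c(1:3, 5:6, 8))
    p_e <- lr_p(fit_e0); conv <- conv && fit_e0$converged
  }
  if ("rho_p" %in% which_lrt) {
    # rho_p = 0 <=> G12 + E12 = 0: substitute le21 = -la21*la11/le11
    con_p <- function(t) { t[7] <- -t[4] * t[3] / t[6]; t }
    fit_p0 <- fit_biv_once(st_mz, st_dz, th, constraint = con_p,
                           free = c(1:6, 8))
    p_p <- lr_p(fit_p0); conv <- conv && fit_p0$converged
  }

  out <- list(h2_x = h2_x, h2_y = h2_y, rho_g = rho_g, rho_e = rho_e,
              rho_p = rho_p, p_rho_g = p_g, p_rho_e = p_e, p_rho_p = p_p,
              G = G, E = E, mu = th[1:2], logLik = full$logLik, df = 8L,
              AIC = 2 * 8L - 2 * full$logLik, converged = conv,
              n_mz = nrow(mz), n_dz = nrow(dz))
  class(out) <- "twin_bivar"
  out
}

#' @export
print.twin_bivar <- function(x, digits = 3, ...) {
  cat("Bivariate twin model (AE), ", x$n_mz, " MZ + ", x$n_dz, " DZ pairs\n",
      sep = "")
  cat(sprintf("  h2_x = %.*f  h2_y = %.*f\n", digits, x$h2_x, digits, x$h2_y))
  cat(sprintf("  rho_g = %.*f (p = %.2g)  rho_e = %.*f (p = %.2g)  rho_p = %.*f (p = %.2g)\n",
              digits, x$rho_g, x$p_rho_g, digits, x$rho_e, x$p_rho_e,
              digits, x$rho_p, x$p_rho_p))
  cat("  logLik = ", round(x$logLik, 2), "  AIC = ", round(x$AIC, 2),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' @export
coef.twin_bivar <- function(object, ...) {
  c(h2_x = object$h2_x, h2_y = object$h2_y, rho_g = object$rho_g,
    rho_e = object$rho_e, rho_p = object$rho_p)
}

#' @export
logLik.twin_bivar <- function(object, ...) {
  structure(object$logLik, df = object$df,
            nobs = 2L * (object$n_mz + object$n_dz), class = "logLik")
}

#' Shared heritability of a trait pair
#'
#' From a bivariate twin fit (or raw numbers), computes the genetic and
#' environmental covariances
#' `COV_G = rho_g * sqrt(h2_x) * sqrt(h2_y)` and
#' `COV_E = rho_e * sqrt(1 - h2_x) * sqrt(1 - h2_y)`, and the shared
#' heritability `h2_xy = COV_G / (COV_G + COV_E)` -- the proportion of the
#' phenotypic covariance of the two traits attributable to genetics. A
#' correlation whose test p-value exceeds `alpha` is constrained to zero
#' before the covariances are formed, so its covariance contribution
#' vanishes.
#'
#' @param object a `twin_bivar` fit, or `NULL` when raw numbers are given.
#' @param rho_g,rho_e genetic and environmental correlations in [-1, 1].
#' @param h2_x,h2_y heritabilities in [0, 1].
#' @param p_rho_g,p_rho_e p-values for the correlations (default 0, i.e.
#'   both retained).
#' @param alpha zeroing threshold for the correlations; default 0.05.
#' @return list of class `shared_heritability`: `cov_g`, `cov_e`, `h2_xy`,
#'   `constrained` (logical vector: which correlations were zeroed),
#'   `defined` (`FALSE` when `cov_g + cov_e == 0`, in which case `h2_xy` is
#'   `NA`), `out_of_range` (`TRUE` when `cov_g` and `cov_e` have opposite
#'   signs so `h2_xy` falls outside [0, 1]).
#' @examples
#' shared_heritability(rho_g = 0.8, rho_e = 0.2, h2_x = 0.5, h2_y = 0.5)
#' @export
shared_heritability <- function(object = NULL, rho_g, rho_e, h2_x, h2_y,
                                p_rho_g = 0, p_rho_e = 0, alpha = 0.05) {
  if (!is.null(object)) {
    stopifnot(inherits(object, "twin_bivar"))
    rho_g <- object$rho_g; rho_e <- object$rho_e
    h2_x <- object$h2_x; h2_y <- object$h2_y
    p_rho_g <- object$p_rho_g; p_rho_e <- object$p_rho_e
  }
  stopifnot(h2_x >= 0, h2_x <= 1, h2_y >= 0, h2_y <= 1,
            abs(rho_g) <= 1, abs(rho_e) <= 1)
  zero_g <- is.na(p_rho_g) || p_rho_g > alpha
  zero_e <- is.na(p_rho_e) || p_rho_e > alpha
  if (zero_g) rho_g <- 0
  if (zero_e) rho_e <- 0
  cov_g <- rho_g * sqrt(h2_x) * sqrt(h2_y)
  cov_e <- rho_e * sqrt(1 - h2_x) * sqrt(1 - h2_y)
  tot <- cov_g + cov_e
  defined <- tot != 0
  h2_xy <- if (defined) cov_g / tot else NA_real_
  out <- list(cov_g = cov_g, cov_e = cov_e, h2_xy = h2_xy,
              constrained = c(rho_g = zero_g, rho_e = zero_e),
              defined = defined,
              out_of_range = defined && (cov_g * cov_e < 0))
  class(out) <- "shared_heritability"
  out
}

#' @export
print.shared_heritability <- function(x, ...) {
  cat(sprintf("COV_G = %.4f  COV_E = %.4f  h2_xy = %s\n",
              x$cov_g, x$cov_e,
              if (x$defined) sprintf("%.4f", x$h2_xy) else "undefined"))
  if (any(x$constrained))
    cat("  constrained to zero:",
        paste(names(x$constrained)[x$constrained], collapse = ", "), "\n")
  if (x$out_of_range)
    cat("  note: COV_G and COV_E have opposite signs; h2_xy outside [0, 1]\n")
  invisible(x)
}

#' Genetic covariance of a trait pair conditional on lead SNPs
#'
#' Residualises two traits on fixed covariates, random groupings and the
#' dosages of specified lead SNPs, refits the bivariate twin model on the
#' standardised residuals, and returns the conditional genetic covariance
#' `A_x * A_y * rho_g` (with `A = sqrt(h2)`). Comparing against an
#' unconditional fit quantifies how much of the shared genetic covariance
#' the conditioning SNPs account for.
#'
#' @param samples sample sheet.
#' @param x,y numeric trait vectors aligned with `samples`.
#' @param covariates optional data frame of fixed covariates (age, sex, ...).
#' @param groups optional named list of random grouping factors (plate, ...).
#' @param snp_dosages optional numeric matrix of lead-SNP dosages
#'   (individuals x SNPs, rows aligned with `samples`).
#' @param unconditional optional `twin_bivar` fit (or a number: the
#'   unconditional `cov_g`) for the proportion-removed summary.
#' @return list of class `conditional_cov_g`: `cov_g`, `fit` (the
#'   conditional `twin_bivar`), and when an unconditional reference is
#'   given, `cov_g_unconditional` and `proportion_removed`.
#' @export
conditional_genetic_covariance <- function(samples, x, y, covariates = NULL,
                                           groups = list(), snp_dosages = NULL,
                                           unconditional = NULL) {
  adjust <- function(v) {
    X <- covariates
    if (!is.null(snp_dosages)) {
      sd_df <- as.data.frame(snp_dosages)
      names(sd_df) <- paste0("snp_", seq_len(ncol(sd_df)))
      X <- if (is.null(X)) sd_df else cbind(as.data.frame(X), sd_df)
    }
    residualize(v, X = X, groups = groups, standardize = TRUE)
  }
  rx <- adjust(x); ry <- adjust(y)
  pairs <- make_twin_pairs(samples, cbind(rx, ry), standardize = TRUE)
  fit <- twin_bivar(pairs, lrt = FALSE)
  cov_g <- sqrt(fit$h2_x) * sqrt(fit$h2_y) * fit$rho_g
  out <- list(cov_g = cov_g, fit = fit)
  if (!is.null(unconditional)) {
    cg0 <- if (inherits(unconditional, "twin_bivar")) {
      sqrt(unconditional$h2_x) * sqrt(unconditional$h2_y) * unconditional$rho_g
    } else as.numeric(unconditional)
    out$cov_g_unconditional <- cg0
    out$proportion_removed <- 1 - cov_g / cg0
  }
  class(out) <- "conditional_cov_g"
  out
}

#' @export
print.conditional_cov_g <- function(x, ...) {
  cat(sprintf("Conditional genetic covariance: %.4f\n", x$cov_g))
  if (!is.null(x$cov_g_unconditional))
    cat(sprintf("  unconditional: %.4f  proportion removed: %.1f%%\n",
                x$cov_g_unconditional, 100 * x$proportion_removed))
  invisible(x)
}
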