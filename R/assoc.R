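#' Linear mixed model with random intercepts for plate and family
#'
#' Fits `y ~ fixed covariates + (1 | G1) + ... + (1 | Gk)` by REML through
#' \pkg{lme4}, the standard model for testing glycan traits against age and
#' sex while absorbing plate batch effects and family structure as random
#' intercepts. Fixed-effect p-values are Wald tests on the normal
#' approximation (single-coefficient hypotheses).
#'
#' @param y numeric response.
#' @param X data frame (or numeric matrix) of fixed covariates, no intercept
#'   column (one is added); may be `NULL` for an intercept-only model.
#' @param groups named list (or data frame) of grouping factors, e.g.
#'   `list(plate = ..., family = ...)`; may be empty, in which case the fit
#'   reduces to ordinary least squares.
#' @return object of class `glyco_lmm`: list with `fixef` (data frame:
#'   estimate, se, z, p per coefficient), `varcomp` (named vector of
#'   variance components, one per grouping plus `residual`), `logLik`, `n`,
#'   `converged`, and `fit` (the underlying lmer/lm fit).
#' @export
fit_lmm <- function(y, X = NULL, groups = list()) {
  dat <- data.frame(.y = y)
  fixed_terms <- "1"
  if (!is.null(X)) {
    X <- as.data.frame(X)
    stopifnot(nrow(X) == length(y))
    dat <- cbind(dat, X)
    fixed_terms <- c(fixed_terms, colnames(X))
  }
  groups <- as.list(groups)
  if (length(groups)) {
    stopifnot(!is.null(names(groups)), all(nzchar(names(groups))))
    for (g in names(groups)) {
      fg <- factor(groups[[g]])
      if (nlevels(fg) < 2L)
        stop("grouping '", g, "' has a single level", call. = FALSE)
      dat[[g]] <- fg
    }
  }
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]

  if (length(groups) == 0L) {
    fml <- stats::reformulate(fixed_terms, response = ".y")
    fit <- stats::lm(fml, data = dat)
    cf <- summary(fit)$coefficients
    fixef <- data.frame(estimate = cf[, 1], se = cf[, 2],
                        z = cf[, 3], p = 2 * stats::pnorm(-abs(cf[, 3])))
    vc <- c(residual = summary(fit)$sigma^2)
    out <- list(fixef = fixef, varcomp = vc,
                logLik = as.numeric(stats::logLik(fit)),
                n = nrow(dat), converged = TRUE, fit = fit)
  } else {
    rand <- sprintf("(1 | %s)", names(groups))
    fml <- stats::as.formula(paste(".y ~", paste(c(fixed_terms, rand), collapse = " + ")))
    fit <- lme4::lmer(fml, data = dat, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
    cf <- stats::coef(summary(fit))
    fixef <- data.frame(estimate = cf[, 1], se = cf[, 2],
                        z = cf[, 3], p = 2 * stats::pnorm(-abs(cf[, 3])))
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    vc <- stats::setNames(vcdf$vcov, ifelse(vcdf$grp == "Residual", "residual", vcdf$grp))
    conv <- length(fit@optinfo$conv$lme4) == 0L ||
      is.null(fit@optinfo$conv$lme4$code) || fit@optinfo$conv$lme4$code == 0L
    out <- list(fixef = fixef, varcomp = vc,
                logLik = as.numeric(stats::logLik(fit)),
                n = nrow(dat), converged = conv, fit = fit)
  }
  out$kept <- keep
  class(out) <- "glyco_lmm"
  out
}

#' @export
print.glyco_lmm <- function(x, ...) {
  cat("Linear mixed model (n = ", x$n, ")\nFixed effects:\n", sep = "")
  print(round(x$fixef, 4))
  cat("Variance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' Mixed-model residuals for downstream correlation and twin analysis
#'
#' Adjusts a (quantile-normalised) trait for fixed covariates and random
#' grouping factors and returns the standardised conditional residuals
#' (BLUPs subtracted), the preprocessing step behind trait-trait
#' correlation networks and conditional twin model fits. With no grouping
#' factors (or zero random-effect variance) this reduces to standardised
#' ordinary least-squares residuals.
#'
#' @inheritParams fit_lmm
#' @param standardize divide residuals by their SD (default `TRUE`).
#' @return numeric vector of residuals, `NA` where the model frame was
#'   incomplete.
#' @export
residualize <- function(y, X = NULL, groups = list(), standardize = TRUE) {
  fit <- fit_lmm(y, X = X, groups = groups)
  r <- stats::residuals(fit$fit)
  if (standardize) r <- r / stats::sd(r)
  out <- rep(NA_real_, length(y))
  out[fit$kept] <- r
  out
}

#' Effective number of independent tests (Li & Ji)
#'
#' Given the correlation matrix of a trait panel, each eigenvalue
#' contributes `I(|lambda| >= 1) + (|lambda| - floor(|lambda|))` and the
#' effective number of tests is the sum of the contributions. A perfectly
#' correlated panel collapses to 1 effective test; an identity correlation
#' matrix gives back the panel dimension. Bonferroni corrections then
#' divide alpha by the (rounded) effective number instead of the raw trait
#' count.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param integer_rule how to discretise for Bonferroni: `"round"`
#'   (default) or `"floor"`.
#' @return list with `m_eff` (raw real value) and `m_eff_int` (integer used
#'   for Bonferroni).
#' @export
effective_tests_li_ji <- function(corr, integer_rule = c("round", "floor")) {
  integer_rule <- match.arg(integer_rule)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix not symmetric", call. = FALSE)
  lam <- abs(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  # snap numerically-integer eigenvalues so floor() is stable
  snap <- abs(lam - round(lam)) < 1e-8
  lam[snap] <- round(lam[snap])
  m_eff <- sum((lam >= 1) + (lam - floor(lam)))
  m_int <- if (integer_rule == "floor") floor(m_eff) else round(m_eff)
  list(m_eff = m_eff, m_eff_int = as.integer(max(1L, m_int)))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of (effective) tests, >= 1.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 37)   # 1.35e-3
#' bonferroni_threshold(0.05, 24)   # 2.08e-3
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Trait-trait correlation network on mixed-model residuals
#'
#' Computes Pearson correlations (pairwise-complete observations, p-values
#' from the t approximation) between residualised traits, and keeps edges
#' passing both an absolute-correlation floor and the applicable Bonferroni
#' bound: intra-class pairs are tested at `alpha / (N (N - 1) / 2)` with `N`
#' the class' effective number of tests; inter-class pairs at
#' `alpha / (N_A * N_B)`.
#'
#' @param traits numeric matrix of residualised traits (individuals x traits).
#' @param classes character vector of class labels (e.g. `"IgA"`/`"IgG"`),
#'   one per trait.
#' @param m_eff named numeric vector giving the effective number of tests
#'   per class (defaults to the raw trait counts per class).
#' @param rho_min absolute-correlation floor; default 0.25.
#' @param alpha family-wise error rate; default 0.05.
#' @return data frame of class `correlation_network`: one row per tested
#'   pair with columns `trait1`, `trait2`, `class1`, `class2`, `type`
#'   (intra/inter), `rho`, `n`, `p`, `threshold`, `edge` (logical).
#' @export
pairwise_correlations <- function(traits, classes, m_eff = NULL,
                                  rho_min = 0.25, alpha = 0.05) {
  stopifnot(is.matrix(traits), ncol(traits) >= 2L,
            length(classes) == ncol(traits))
  cls <- unique(classes)
  if (is.null(m_eff)) m_eff <- stats::setNames(as.numeric(table(classes)[cls]), cls)
  stopifnot(all(cls %in% names(m_eff)))
  nm <- colnames(traits)
  if (is.null(nm)) nm <- paste0("trait", seq_len(ncol(traits)))
  pairs <- utils::combn(ncol(traits), 2L)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    ok <- stats::complete.cases(traits[, c(i, j)])
    n <- sum(ok)
    if (n < 3L) stop("fewer than 3 complete observations for pair ",
                     nm[i], " / ", nm[j], call. = FALSE)
    rho <- stats::cor(traits[ok, i], traits[ok, j])
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    intra <- classes[i] == classes[j]
    thr <- if (intra) {
      N <- m_eff[[classes[i]]]
      bonferroni_threshold(alpha, N * (N - 1) / 2)
    } else {
      bonferroni_threshold(alpha, m_eff[[classes[i]]] * m_eff[[classes[j]]])
    }
    rows[[k]] <- data.frame(
      trait1 = nm[i], trait2 = nm[j],
      class1 = classes[i], class2 = classes[j],
      type = if (intra) "intra" else "inter",
      rho = rho, n = n, p = p, threshold = thr,
      edge = abs(rho) > rho_min & p < thr,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_network", "data.frame")
  out
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Correlation network: ", nrow(x), " tested pairs, ",
      sum(x$edge), " edges (",
      sum(x$edge & x$type == "intra"), " intra-class, ",
      sum(x$edge & x$type == "inter"), " inter-class)\n", sep = "")
  invisible(x)
}
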