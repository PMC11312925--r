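#' Assemble complete twin pairs from a sample sheet
#'
#' Pairs co-twins by family, optionally pre-adjusting the trait for fixed
#' covariates (ordinary least squares) and standardising the result, the
#' two-stage adjustment used before variance-component estimation. Pairs
#' with unknown zygosity or a missing co-twin value are dropped, as are
#' singletons (they contribute only to the covariate adjustment).
#'
#' @param samples sample sheet (`id`, `family_id`, `zygosity`, ...).
#' @param value numeric trait vector aligned with `samples` rows (for one
#'   trait), or a two-column matrix / data frame for a trait pair.
#' @param covariates optional data frame of fixed covariates to residualise
#'   on before pairing.
#' @param standardize scale the (adjusted) trait(s) to unit variance
#'   (default `TRUE`).
#' @return data frame of class `twin_pairs`: `zygosity`, `t1`, `t2` for one
#'   trait, or `zygosity`, `x1`, `y1`, `x2`, `y2` for a pair of traits.
#' @export
make_twin_pairs <- function(samples, value, covariates = NULL, standardize = TRUE) {
  v <- if (is.data.frame(value)) as.matrix(value) else value
  if (is.matrix(v)) stopifnot(ncol(v) == 2L, nrow(v) == nrow(samples))
  else { stopifnot(length(v) == nrow(samples)); v <- matrix(v, ncol = 1L) }
  for (j in seq_len(ncol(v))) {
    if (!is.null(covariates)) {
      fit <- stats::lm(v[, j] ~ ., data = as.data.frame(covariates),
                       na.action = stats::na.exclude)
      v[, j] <- stats::residuals(fit)
    }
    if (standardize) v[, j] <- as.numeric(scale(v[, j]))
  }
  birth <- stats::ave(seq_len(nrow(samples)), samples$family_id, FUN = seq_along)
  fam <- samples$family_id
  first <- which(birth == 1L)
  # index of the co-twin for each first-born, NA for singletons
  idx2 <- vapply(first, function(i) {
    j <- which(fam == fam[i] & seq_along(fam) != i)
    if (length(j)) j[1L] else NA_integer_
  }, integer(1L))
  keep <- !is.na(idx2) & !is.na(samples$zygosity[first])
  i1 <- first[keep]; i2 <- idx2[keep]
  if (ncol(v) == 1L) {
    out <- data.frame(zygosity = samples$zygosity[i1],
                      t1 = v[i1, 1L], t2 = v[i2, 1L], stringsAsFactors = FALSE)
    out <- out[stats::complete.cases(out), , drop = FALSE]
  } else {
    out <- data.frame(zygosity = samples$zygosity[i1],
                      x1 = v[i1, 1L], y1 = v[i1, 2L],
                      x2 = v[i2, 1L], y2 = v[i2, 2L], stringsAsFactors = FALSE)
    out <- out[stats::complete.cases(out), , drop = FALSE]
  }
  class(out) <- c("twin_pairs", "data.frame")
  out
}

# Sufficient statistics of a bivariate-normal twin group: n, sum of all
# values, sum of squares, sum of within-pair cross-products.
pair_suffstats <- function(t1, t2) {
  list(n = length(t1), s1 = sum(t1) + sum(t2),
       s2 = sum(t1^2) + sum(t2^2), s12 = sum(t1 * t2))
}

# Negative log-likelihood of MZ+DZ pair data under common mean mu, common
# variance v, and zygosity-specific within-pair covariance (cmz, cdz).
pair_negloglik <- function(mu, v, cmz, cdz, stats_mz, stats_dz) {
  one_group <- function(st, cc) {
    det2 <- v^2 - cc^2
    if (det2 <= 0 || v <= 0) return(Inf)
    qsum <- v * (st$s2 - 2 * mu * st$s1 + 2 * st$n * mu^2) -
      2 * cc * (st$s12 - mu * st$s1 + st$n * mu^2)
    st$n * log(2 * pi) + st$n / 2 * log(det2) + qsum / (2 * det2)
  }
  one_group(stats_mz, cmz) + one_group(stats_dz, cdz)
}

#' Univariate twin variance decomposition (ACE / AE / CE / E)
#'
#' Maximum-likelihood fit of the classical twin model: each twin pair is
#' bivariate normal with common mean and variance; the expected within-pair
#' covariance is `a2 + c2` for MZ pairs and `a2/2 + c2` for DZ pairs, where
#' `a2`, `c2` and `e2` are the additive-genetic, shared-environment and
#' unique-environment variance proportions. Components are parameterised as
#' squared path coefficients, so estimates are bounded to `[0, 1]` and sum
#' to 1 on the standardised trait. Standard errors come from the observed
#' information at the optimum via the delta method.
#'
#' @param pairs a `twin_pairs` data frame ([make_twin_pairs()]) with at
#'   least 20 MZ and 20 DZ pairs.
#' @param model which sub-model to fit: `"ACE"`, `"AE"`, `"CE"` or `"E"`.
#' @return object of class `twin_ace`: variance proportions (`a2`, `c2`,
#'   `e2`), their SEs, `mu`, `total_var`, `logLik`, `df` (free parameters),
#'   `AIC`, `converged`, `n_mz`, `n_dz`.
#' @examples
#' samples <- simulate_samples(cohort_design(200, 200, 0), seed = 7)
#' tr <- simulate_twin_traits(samples, trait_model(0.5, 0.2, 0.3), seed = 7)
#' fit <- twin_ace(make_twin_pairs(samples, tr$value))
#' coef(fit)
#' @export
twin_ace <- function(pairs, model = c("ACE", "AE", "CE", "E")) {
  model <- match.arg(model)
  stopifnot(inherits(pairs, "twin_pairs"), all(c("t1", "t2") %in% names(pairs)))
  mz <- pairs[pairs$zygosity == "MZ", ]
  dz <- pairs[pairs$zygosity == "DZ", ]
  if (nrow(mz) < 20L || nrow(dz) < 20L)
    stop("need at least 20 MZ and 20 DZ pairs", call. = FALSE)
  smz <- pair_suffstats(mz$t1, mz$t2)
  sdz <- pair_suffstats(dz$t1, dz$t2)

  free <- switch(model,
                 ACE = c("pa", "pc", "pe"), AE = c("pa", "pe"),
                 CE = c("pc", "pe"), E = "pe")
  # method-of-moments starting values
  rmz <- suppressWarnings(stats::cor(mz$t1, mz$t2))
  rdz <- suppressWarnings(stats::cor(dz$t1, dz$t2))
  vv <- (smz$s2 + sdz$s2) / (2 * (smz$n + sdz$n))
  a0 <- min(max(2 * (rmz - rdz), 0.01), 0.95)
  c0 <- min(max(2 * rdz - rmz, 0.01), 0.95)
  e0 <- max(1 - a0 - c0, 0.05)
  start_full <- c(pa = sqrt(a0 * vv), pc = sqrt(c0 * vv), pe = sqrt(e0 * vv))
  theta0 <- c(mu = mean(c(mz$t1, mz$t2, dz$t1, dz$t2)), start_full[free])

  nll <- function(theta) {
    mu <- theta[1L]
    p <- stats::setNames(numeric(3L), c("pa", "pc", "pe"))
    p[free] <- theta[-1L]
    v <- sum(p^2)
    pair_negloglik(mu, v, p["pa"]^2 + p["pc"]^2, p["pa"]^2 / 2 + p["pc"]^2,
                   smz, sdz)
  }
  opt <- stats::optim(theta0, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12),
                      hessian = TRUE)
  p <- stats::setNames(numeric(3L), c("pa", "pc", "pe"))
  p[free] <- opt$par[-1L]
  v <- sum(p^2)
  comp <- c(a2 = unname(p["pa"]^2 / v), c2 = unname(p["pc"]^2 / v),
            e2 = unname(p["pe"]^2 / v))

  vcv_comp <- matrix(NA_real_, 3L, 3L, dimnames = list(names(comp), names(comp)))
  se <- stats::setNames(rep(NA_real_, 3L), names(comp))
  ih <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (!is.null(ih)) {
    to_comp <- function(theta) {
      pp <- stats::setNames(numeric(3L), c("pa", "pc", "pe"))
      pp[free] <- theta[-1L]
      pp^2 / sum(pp^2)
    }
    J <- num_jacobian(to_comp, opt$par)
    vcv_comp <- J %*% ih %*% t(J)
    dimnames(vcv_comp) <- list(names(comp), names(comp))
    se <- stats::setNames(sqrt(pmax(diag(vcv_comp), 0)), names(comp))
  }

  out <- list(model = model, a2 = comp[["a2"]], c2 = comp[["c2"]],
              e2 = comp[["e2"]], se = se, vcov = vcv_comp,
              mu = unname(opt$par[1L]), total_var = v,
              logLik = -opt$value, df = length(theta0),
              AIC = 2 * length(theta0) + 2 * opt$value,
              converged = opt$convergence == 0L,
              n_mz = nrow(mz), n_dz = nrow(dz))
  class(out) <- "twin_ace"
  out
}

# Central finite-difference Jacobian of f at x.
num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Fit all four twin sub-models and select by AIC
#'
#' Fits ACE, AE, CE and E on the same pairs and returns the fit with the
#' smallest AIC; exact ties go to the model with fewer parameters.
#' Non-convergent fits are excluded from the selection with a warning.
#'
#' @inheritParams twin_ace
#' @return the selected `twin_ace` fit, with the full list of fits in
#'   `$fits` and the selection order in `$ranking`.
#' @export
twin_ace_select <- function(pairs) {
  labels <- c("ACE", "AE", "CE", "E")
  fits <- lapply(labels, function(m) twin_ace(pairs, model = m))
  names(fits) <- labels
  ok <- vapply(fits, `[[`, TRUE, "converged")
  if (!all(ok)) {
    warning("non-convergent fit(s) excluded from selection: ",
            paste(labels[!ok], collapse = ", "))
  }
  cand <- fits[ok]
  aic <- vapply(cand, `[[`, 0, "AIC")
  dfp <- vapply(cand, `[[`, 0, "df")
  ord <- order(aic, dfp)
  best <- cand[[ord[1L]]]
  best$fits <- fits
  best$ranking <- names(cand)[ord]
  best$selected <- TRUE
  best
}

#' @export
print.twin_ace <- function(x, digits = 3, ...) {
  cat("Twin variance decomposition (", x$model, " model), ",
      x$n_mz, " MZ + ", x$n_dz, " DZ pairs\n", sep = "")
  est <- round(c(a2 = x$a2, c2 = x$c2, e2 = x$e2), digits)
  cat("  a2 = ", est[1], "  c2 = ", est[2], "  e2 = ", est[3], "\n", sep = "")
  cat("  logLik = ", round(x$logLik, 2), "  AIC = ", round(x$AIC, 2),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  if (!is.null(x$ranking))
    cat("  AIC selection order: ", paste(x$ranking, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.twin_ace <- function(object, ...) {
  tab <- data.frame(estimate = c(object$a2, object$c2, object$e2),
                    se = object$se,
                    row.names = c("a2", "c2", "e2"))
  structure(list(model = object$model, table = tab, logLik = object$logLik,
                 AIC = object$AIC, n_mz = object$n_mz, n_dz = object$n_dz,
                 converged = object$converged),
            class = "summary.twin_ace")
}

#' @export
print.summary.twin_ace <- function(x, ...) {
  cat("Twin model:", x$model, "\n")
  print(round(x$table, 4))
  cat("logLik:", round(x$logLik, 2), " AIC:", round(x$AIC, 2),
      " pairs:", x$n_mz, "MZ /", x$n_dz, "DZ\n")
  invisible(x)
}

#' @export
coef.twin_ace <- function(object, ...) {
  c(a2 = object$a2, c2 = object$c2, e2 = object$e2)
}

#' @export
vcov.twin_ace <- function(object, ...) object$vcov

#' @export
logLik.twin_ace <- function(object, ...) {
  structure(object$logLik, df = object$df,
            nobs = 2L * (object$n_mz + object$n_dz), class = "logLik")
}

#' @export
simulate.twin_ace <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  one <- function() {
    draw <- function(n, r) {
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      sdv <- sqrt(object$total_var)
      cbind(object$mu + sdv * z1,
            object$mu + sdv * (r * z1 + sqrt(1 - r^2) * z2))
    }
    rmz <- object$a2 + object$c2
    rdz <- object$a2 / 2 + object$c2
    mzd <- draw(object$n_mz, rmz)
    dzd <- draw(object$n_dz, rdz)
    out <- data.frame(zygosity = rep(c("MZ", "DZ"), c(object$n_mz, object$n_dz)),
                      t1 = c(mzd[, 1], dzd[, 1]), t2 = c(mzd[, 2], dzd[, 2]),
                      stringsAsFactors = FALSE)
    class(out) <- c("twin_pairs", "data.frame")
    out
  }
  if (nsim == 1L) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @export
plot.twin_ace <- function(x, ...) {
  graphics::barplot(matrix(c(x$a2, x$c2, x$e2), ncol = 1),
                    names.arg = x$model, horiz = FALSE,
                    col = c("orange", "darkgreen", "white"),
                    ylab = "variance proportion",
                    legend.text = c("A (additive genetic)",
                                    "C (shared environment)",
                                    "E (unique environment)"), ...)
  invisible(x)
}
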