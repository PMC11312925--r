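#' Kinship model for mixed-model association
#'
#' Builds the expected-relatedness covariance of the cohort, either from
#' the pedigree (block-diagonal: MZ co-twins 1, DZ co-twins 1/2, unrelated
#' individuals 0) or as the empirical genetic relationship matrix (GRM)
#' `X Xt / m` on standardised dosages.
#'
#' @param samples sample sheet (needed in pedigree mode; `zygosity` must be
#'   known for every twin).
#' @param genotypes a `genotype_matrix` or dosage matrix (needed in grm
#'   mode, >= 100 SNPs).
#' @param mode `"pedigree"` or `"grm"`.
#' @return object of class `kinship_model`: `K` (n x n symmetric PSD
#'   matrix with sample ids as dimnames), `mode`.
#' @export
build_kinship <- function(samples = NULL, genotypes = NULL,
                          mode = c("pedigree", "grm")) {
  mode <- match.arg(mode)
  if (mode == "pedigree") {
    stopifnot(is.data.frame(samples))
    n <- nrow(samples)
    K <- diag(n)
    dimnames(K) <- list(samples$id, samples$id)
    for (fam in unique(samples$family_id)) {
      idx <- which(samples$family_id == fam)
      if (length(idx) < 2L) next
      zyg <- samples$zygosity[idx[1L]]
      if (is.na(zyg)) stop("unknown zygosity for family ", fam, call. = FALSE)
      r <- if (zyg == "MZ") 1 else 0.5
      K[idx[1L], idx[2L]] <- K[idx[2L], idx[1L]] <- r
    }
  } else {
    dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else genotypes
    stopifnot(is.matrix(dos), ncol(dos) >= 100L)
    keep <- apply(dos, 2L, stats::sd) > 0
    Z <- scale(dos[, keep, drop = FALSE])
    K <- tcrossprod(Z) / ncol(Z)
    dimnames(K) <- list(rownames(dos), rownames(dos))
  }
  structure(list(K = K, mode = mode), class = "kinship_model")
}

#' @export
print.kinship_model <- function(x, ...) {
  cat("Kinship model (", x$mode, "): ", nrow(x$K), " individuals\n", sep = "")
  invisible(x)
}

# REML fit of y = X b + g + e with cov(g) = vg * K, cov(e) = ve * I,
# profiled over delta = ve / vg on the eigenbasis of K (EMMA-style).
# Returns the rotation and the null variance components, which the
# association scan then holds fixed across SNPs.
kinship_null_model <- function(y, X, K = NULL) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(K)) {
    # identity kinship: the rotation is a no-op (vg and ve are then not
    # separately identifiable, but their sum -- all that the GLS needs -- is)
    U <- NULL
    lam <- rep(1, n)
    yt <- y
    Xt <- X
  } else {
    stopifnot(nrow(K) == n)
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    U <- eg$vectors
    lam <- pmax(eg$values, 0)
    yt <- crossprod(U, y)
    Xt <- crossprod(U, X)
  }
  p <- ncol(X)
  reml <- function(logdelta) {
    d <- exp(logdelta)
    w <- lam + d
    sw <- 1 / sqrt(w)
    Xw <- Xt * sw
    yw <- yt * sw
    XtX <- crossprod(Xw)
    b <- tryCatch(solve(XtX, crossprod(Xw, yw)), error = function(e) NULL)
    if (is.null(b)) return(-1e10)
    r <- yw - Xw %*% b
    rss <- sum(r^2)
    vg <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * vg) + 1) + sum(log(w)) +
              determinant(XtX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(reml, c(-30, 15), maximum = TRUE, tol = 1e-6)
  d <- exp(opt$maximum)
  w <- lam + d
  sw <- 1 / sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  b <- solve(crossprod(Xw), crossprod(Xw, yw))
  vg <- sum((yw - Xw %*% b)^2) / (n - p)
  list(U = U, lambda = lam, delta = d, vg = vg, ve = vg * d,
       w = w, yt = as.numeric(yt), Xt = Xt, reml = opt$objective)
}

# Normalise genotype input to a dosage matrix + allele frequency vector.
as_dosage <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix")) {
    list(dosage = genotypes$dosage, af = genotypes$allele_freq)
  } else {
    stopifnot(is.matrix(genotypes))
    list(dosage = genotypes, af = colMeans(genotypes, na.rm = TRUE) / 2)
  }
}

#' Kinship-aware single-SNP association scan
#'
#' Linear mixed-model GWAS in two steps: the polygenic and residual
#' variance components are estimated once by REML under the null
#' (covariates-only) model on the eigenbasis of the kinship matrix, then
#' each SNP is tested by generalised least squares with those components
#' held fixed (the P3D approximation). Effect alleles are oriented to the
#' minor allele, SNPs below the MAF floor are excluded, and p-values are
#' Wald t-tests.
#'
#' @param y quantile-normalised trait vector.
#' @param genotypes a `genotype_matrix` or dosage matrix (rows aligned
#'   with `y`).
#' @param covariates optional data frame / matrix of fixed covariates.
#' @param kinship a `kinship_model`, or `NULL` for independent observations.
#' @param maf_min minor-allele-frequency floor; default 0.05.
#' @return data frame of class `gwas_result`: `snp`, `eaf` (minor/effect
#'   allele frequency), `beta`, `se`, `p`, `n`, with attributes
#'   `varcomp` (null variance components) and `n_excluded_maf`.
#' @export
run_gwas <- function(y, genotypes, covariates = NULL, kinship = NULL,
                     maf_min = 0.05) {
  gd <- as_dosage(genotypes)
  n <- length(y)
  stopifnot(nrow(gd$dosage) == n)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    X <- cbind(X, cv)
  }
  maf <- pmin(gd$af, 1 - gd$af)
  keep <- which(maf > maf_min & maf > 0)
  n_excl <- ncol(gd$dosage) - length(keep)
  null <- kinship_null_model(y, X, if (is.null(kinship)) NULL else kinship$K)
  # coordinates with numerically zero variance weight (degenerate kinship
  # eigenvalues, e.g. exact duplicates) carry no information: drop them so
  # residual degrees of freedom are counted on the informative subspace
  active <- null$w > max(null$w) * 1e-10
  n_act <- sum(active)
  sw <- 1 / sqrt(null$w[active])
  Xw <- null$Xt[active, , drop = FALSE] * sw
  yw <- null$yt[active] * sw
  G_rot <- if (is.null(null$U)) gd$dosage[, keep, drop = FALSE]
  else crossprod(null$U, gd$dosage[, keep, drop = FALSE])
  Gw <- G_rot[active, , drop = FALSE] * sw
  p_cov <- ncol(Xw)
  res <- matrix(NA_real_, length(keep), 3L,
                dimnames = list(NULL, c("beta", "se", "p")))
  for (j in seq_along(keep)) {
    g <- Gw[, j]
    if (stats::sd(gd$dosage[, keep[j]]) == 0)
      stop("zero-variance SNP: ", colnames(gd$dosage)[keep[j]], call. = FALSE)
    fit <- stats::lm.fit(cbind(Xw, g), yw)
    if (fit$rank < p_cov + 1L) next  # collinear with covariates (e.g. a lead): NA
    dfres <- n_act - p_cov - 1L
    sigma2 <- sum(fit$residuals^2) / dfres
    XtXi <- chol2inv(chol(crossprod(cbind(Xw, g))))
    beta <- fit$coefficients[p_cov + 1L]
    se <- sqrt(sigma2 * XtXi[p_cov + 1L, p_cov + 1L])
    res[j, ] <- c(beta, se, 2 * stats::pt(-abs(beta / se), dfres))
  }
  # orient to the minor allele: flip effect where the counted allele is major
  flip <- gd$af[keep] > 0.5
  res[flip, "beta"] <- -res[flip, "beta"]
  out <- data.frame(snp = colnames(gd$dosage)[keep],
                    eaf = maf[keep], beta = res[, "beta"], se = res[, "se"],
                    p = res[, "p"], n = n, stringsAsFactors = FALSE)
  attr(out, "varcomp") <- c(vg = null$vg, ve = null$ve, delta = null$delta)
  attr(out, "n_excluded_maf") <- n_excl
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' @export
print.gwas_result <- function(x, ...) {
  cat("GWAS scan: ", nrow(x), " SNPs, n = ", x$n[1L],
      "; min p = ", format(min(x$p), digits = 3),
      "; lambda = ", round(genomic_inflation(x$p), 3), "\n", sep = "")
  invisible(x)
}

#' Genomic inflation factor
#'
#' `lambda = median(chi-square statistics) / 0.4549...`, the ratio of the
#' observed median association statistic to the median of the chi-square
#' distribution with 1 degree of freedom; `lambda` near 1 indicates
#' calibrated tests with no residual stratification or relatedness.
#'
#' @param p vector of p-values (converted through the inverse chi-square),
#'   or `NULL` when `chisq` is given.
#' @param chisq optional vector of 1-df chi-square statistics.
#' @return the inflation factor lambda.
#' @export
genomic_inflation <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    stopifnot(!is.null(p), length(p) >= 100L)
    chisq <- stats::qchisq(p, df = 1L, lower.tail = FALSE)
  } else stopifnot(length(chisq) >= 100L)
  stats::median(chisq) / stats::qchisq(0.5, df = 1L)
}

#' Stepwise conditional scan for independent signals at a locus
#'
#' Iteratively conditions on lead SNPs: while any SNP in the window passes
#' the genome-wide threshold, the top SNP's dosage is added to the
#' covariates and the window is rescanned. Returns the ordered list of
#' lead SNPs; rerunning with all leads as covariates finds nothing
#' (idempotence).
#'
#' @param y trait vector.
#' @param genotypes `genotype_matrix` or dosage matrix restricted to the
#'   locus window (>= 1 SNP).
#' @param covariates optional fixed covariates.
#' @param kinship optional `kinship_model`.
#' @param gw_threshold genome-wide significance threshold, e.g. `5e-8`.
#' @param maf_min MAF floor passed to [run_gwas()].
#' @param max_steps safety cap on conditioning rounds; default 10.
#' @return list: `leads` (character vector of lead SNP ids, possibly
#'   empty), `final_min_p` (minimum p after conditioning on all leads),
#'   `scans` (list of per-round `gwas_result`s).
#' @export
conditional_scan <- function(y, genotypes, covariates = NULL, kinship = NULL,
                             gw_threshold = 5e-8, maf_min = 0.05,
                             max_steps = 10L) {
  gd <- as_dosage(genotypes)
  if (ncol(gd$dosage) == 0L) stop("window contains no SNPs", call. = FALSE)
  leads <- character()
  scans <- list()
  covs <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  repeat {
    scan <- run_gwas(y, genotypes, covariates = covs, kinship = kinship,
                     maf_min = maf_min)
    scan <- scan[!scan$snp %in% leads & !is.na(scan$p), , drop = FALSE]
    scans[[length(scans) + 1L]] <- scan
    top <- which.min(scan$p)
    if (!length(top) || scan$p[top] >= gw_threshold || length(leads) >= max_steps)
      break
    lead <- scan$snp[top]
    leads <- c(leads, lead)
    lead_dos <- data.frame(gd$dosage[, lead, drop = FALSE])
    names(lead_dos) <- paste0("lead_", gsub("[^A-Za-z0-9]", "_", lead))
    covs <- if (is.null(covs)) lead_dos else cbind(covs, lead_dos)
  }
  final <- scans[[length(scans)]]
  list(leads = leads,
       final_min_p = if (nrow(final)) min(final$p) else NA_real_,
       scans = scans)
}

#' Phenotypic variance explained by a SNP
#'
#' `sigma = 2 p q beta^2` for an additively acting biallelic SNP with
#' minor/major allele frequencies `p`, `q = 1 - p` and per-allele effect
#' `beta` on a unit-variance trait. Totals over the independent lead SNPs
#' of a trait give its SNP-based variance explained; dividing by the twin
#' heritability gives the share of genetic variance explained.
#'
#' @param beta per-allele effect size(s).
#' @param freq effect (minor) allele frequency(ies) in (0, 1).
#' @param h2 optional trait heritability; when given, the genetic-variance
#'   share `sum(sigma) / h2` is returned as attribute `"genetic_share"`.
#' @return vector of per-SNP variance fractions `sigma`.
#' @examples
#' snp_variance_explained(1, 0.5)                # 0.5
#' snp_variance_explained(-0.489, 0.284)         # 0.0972...
#' @export
snp_variance_explained <- function(beta, freq, h2 = NULL) {
  stopifnot(length(beta) == length(freq), all(freq > 0), all(freq < 1))
  sigma <- 2 * freq * (1 - freq) * beta^2
  if (!is.null(h2)) attr(sigma, "genetic_share") <- sum(sigma) / h2
  sigma
}

#' Discovery-to-replication verdict
#'
#' A discovery signal is replicated when the replication effect has the
#' same sign as the discovery effect (after orienting both to the
#' discovery effect allele) and its p-value is strictly below
#' `alpha / m_pairs`, the Bonferroni bound over the trait-locus pairs
#' taken forward.
#'
#' @param discovery,replication data frames with columns `snp`, `beta`,
#'   `p` (a `gwas_result` works); `trait` optional, matched when present
#'   in both.
#' @param m_pairs number of trait-locus pairs tested for replication.
#' @param alpha family-wise error rate; default 0.05.
#' @return data frame of class `replication_verdict`: per matched signal,
#'   `snp`, `beta_disc`, `beta_repl`, `p_repl`, `concordant`, `threshold`,
#'   `replicated`.
#' @export
check_replication <- function(discovery, replication, m_pairs, alpha = 0.05) {
  stopifnot(all(c("snp", "beta", "p") %in% names(discovery)),
            all(c("snp", "beta", "p") %in% names(replication)),
            m_pairs >= 1)
  key <- function(d) {
    if ("trait" %in% names(d)) paste(d$trait, d$snp, sep = "|") else d$snp
  }
  kd <- key(discovery); kr <- key(replication)
  m <- match(kd, kr)
  if (anyNA(m)) stop("unmatched SNP/trait in replication: ",
                     paste(kd[is.na(m)], collapse = ", "), call. = FALSE)
  thr <- bonferroni_threshold(alpha, m_pairs)
  conc <- sign(discovery$beta) == sign(replication$beta[m])
  out <- data.frame(snp = discovery$snp,
                    beta_disc = discovery$beta,
                    beta_repl = replication$beta[m],
                    p_repl = replication$p[m],
                    concordant = conc,
                    threshold = thr,
                    replicated = conc & replication$p[m] < thr,
                    stringsAsFactors = FALSE)
  if ("trait" %in% names(discovery)) out <- cbind(trait = discovery$trait, out)
  class(out) <- c("replication_verdict", "data.frame")
  out
}

#' @export
print.replication_verdict <- function(x, ...) {
  cat("Replication: ", sum(x$replicated), "/", nrow(x),
      " signals replicated (threshold ", format(x$threshold[1L], digits = 3),
      ")\n", sep = "")
  invisible(x)
}
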