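test_that("pedigree kinship encodes expected relatedness blocks", {
  s <- quick_cohort(2, 2, 1, seed = 61)
  kin <- build_kinship(s, mode = "pedigree")
  K <- kin$K
  mz <- which(s$zygosity == "MZ")
  expect_equal(K[s$id[mz[1]], s$id[mz[2]]], 1)
  dz <- which(s$zygosity == "DZ")
  expect_equal(K[s$id[dz[1]], s$id[dz[2]]], 0.5)
  expect_equal(unname(diag(K)), rep(1, nrow(s)))
  # unknown zygosity in a pair is an error
  s_bad <- s
  s_bad$zygosity[mz[1]] <- NA
  s_bad$zygosity[mz[2]] <- NA
  expect_error(build_kinship(s_bad, mode = "pedigree"), "zygosity")
})

test_that("GRM concentrates around pedigree relatedness", {
  s <- quick_cohort(30, 30, 40, seed = 62)
  g <- simulate_genotypes(s, 5000, c(0.1, 0.5), seed = 62)
  kin <- build_kinship(genotypes = g, mode = "grm")
  K <- kin$K
  mz1 <- which(s$zygosity == "MZ")[1]
  co <- match(paste0(s$family_id[mz1], "_2"), s$id)
  expect_lt(abs(K[mz1, co] - 1), 0.08)
  # unrelated individuals: off-diagonals near zero
  singles <- which(is.na(s$zygosity))
  off <- K[singles[1], singles[2:10]]
  expect_lt(max(abs(off)), 0.08)
})

test_that("identity kinship and no covariates reduce to per-SNP OLS", {
  set.seed(63)
  n <- 300
  dos <- matrix(rbinom(n * 20, 2, 0.3), n,
                dimnames = list(NULL, paste0("s", 1:20)))
  y <- rnorm(n)
  res <- run_gwas(y, dos, kinship = NULL, maf_min = 0.01)
  for (j in c(1, 7, 20)) {
    ols <- summary(lm(y ~ dos[, j]))$coefficients
    af <- mean(dos[, j]) / 2
    flip <- if (af > 0.5) -1 else 1
    row <- res[res$snp == paste0("s", j), ]
    expect_equal(row$beta, flip * ols[2, 1], tolerance = 1e-8)
    expect_equal(row$se, ols[2, 2], tolerance = 1e-8)
    expect_equal(row$p, ols[2, 4], tolerance = 1e-8)
  }
})

test_that("MAF filtering and allele orientation are applied", {
  set.seed(64)
  n <- 500
  dos <- cbind(rare = rbinom(n, 2, 0.01), common = rbinom(n, 2, 0.4),
               flipme = rbinom(n, 2, 0.8))
  y <- 0.3 * scale(dos[, "flipme"]) + rnorm(n)
  res <- run_gwas(as.numeric(y), dos, maf_min = 0.05)
  expect_false("rare" %in% res$snp)
  expect_equal(attr(res, "n_excluded_maf"), 1L)
  row <- res[res$snp == "flipme", ]
  expect_lte(row$eaf, 0.5)
  expect_lt(row$beta, 0)  # counted allele flipped to the minor allele
})

test_that("genomic inflation follows the chi-square median", {
  expect_equal(genomic_inflation(chisq = rep(qchisq(0.5, 1), 200)), 1)
  set.seed(65)
  x <- 1.2 * rchisq(10000, 1)
  expect_lt(abs(genomic_inflation(chisq = x) - 1.2), 0.03)
  p <- pchisq(x, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p), genomic_inflation(chisq = x),
               tolerance = 1e-10)
})

test_that("sigma = 2pq beta^2 evaluates exactly and totals recover truth", {
  expect_equal(snp_variance_explained(1, 0.5), 0.5)
  expect_equal(snp_variance_explained(0, 0.3), 0)
  # printed worked example: EAF 0.284, beta -0.489
  expect_equal(snp_variance_explained(-0.489, 0.284),
               2 * 0.284 * 0.716 * 0.489^2)
  expect_equal(round(snp_variance_explained(-0.489, 0.284), 4), 0.0972)
  expect_error(snp_variance_explained(1, 0))
  # genetic share attribute
  sg <- snp_variance_explained(c(0.2, 0.1), c(0.3, 0.4), h2 = 0.5)
  expect_equal(attr(sg, "genetic_share"), sum(sg) / 0.5)
})

test_that("causal SNP variance totals match the configured share", {
  s <- quick_cohort(1000, 1000, 0, seed = 66)
  g <- simulate_genotypes(s, 50, c(0.1, 0.5), seed = 66)
  eff <- data.frame(snp = 1:5, beta = sqrt(rep(0.02, 5)))
  tr <- simulate_twin_traits(s, trait_model(0.5, 0, 0.5, snp_effects = eff),
                             genotypes = g, seed = 66)
  kin <- build_kinship(s, mode = "pedigree")
  res <- run_gwas(tr$value, g, kinship = kin, maf_min = 0.01)
  leads <- res[res$snp %in% g$snp_ids[1:5], ]
  sig_total <- sum(snp_variance_explained(leads$beta, leads$eaf))
  expect_lt(abs(sig_total - 0.10), 0.02)
})

test_that("kinship restores calibration on duplicated individuals", {
  set.seed(67)
  n <- 250
  dos0 <- matrix(rbinom(n * 800, 2, 0.3), n)
  y0 <- rnorm(n)
  # duplicate everyone (fake MZ pairs): ignoring kinship inflates lambda
  dos <- rbind(dos0, dos0)
  rownames(dos) <- paste0("i", seq_len(2 * n))
  colnames(dos) <- paste0("s", seq_len(800))
  y <- c(y0, y0)
  lam_naive <- genomic_inflation(run_gwas(y, dos, kinship = NULL)$p)
  fake_sheet <- data.frame(id = rownames(dos),
                           family_id = rep(paste0("f", 1:n), 2),
                           zygosity = "MZ")
  fake_sheet <- fake_sheet[order(fake_sheet$family_id), ]
  dos_ord <- dos[fake_sheet$id, ]
  y_ord <- y[match(fake_sheet$id, rownames(dos))]
  kin <- build_kinship(fake_sheet, mode = "pedigree")
  lam_kin <- genomic_inflation(run_gwas(y_ord, dos_ord, kinship = kin)$p)
  expect_gt(lam_naive, 1.3)
  expect_lt(abs(lam_kin - 1), 0.12)
})

test_that("conditional scans find the independent signals and stop", {
  # one causal SNP with LD proxies: exactly one lead, then nothing
  dos <- simulate_ld_block(1500, 8, maf = 0.3, flip_prob = 0.03, seed = 68)
  set.seed(68)
  y <- as.numeric(scale(dos[, 1]) * sqrt(0.06) + rnorm(1500, 0, sqrt(0.94)))
  cs <- conditional_scan(y, dos, gw_threshold = 5e-8)
  expect_length(cs$leads, 1L)
  expect_gte(cs$final_min_p, 5e-8)

  # no signal below threshold: empty lead list
  set.seed(69)
  y_null <- rnorm(1500)
  cs0 <- conditional_scan(y_null, dos, gw_threshold = 5e-8)
  expect_length(cs0$leads, 0L)

  # idempotence: conditioning on the found lead finds nothing more
  lead_dos <- dos[, cs$leads, drop = FALSE]
  cs_again <- conditional_scan(y, dos, covariates = data.frame(lead = lead_dos),
                               gw_threshold = 5e-8)
  expect_length(cs_again$leads, 0L)

  expect_error(conditional_scan(y, dos[, 0, drop = FALSE]), "no SNPs")
})

test_that("replication verdicts combine direction and threshold", {
  disc <- data.frame(snp = "rs1", beta = -0.489, p = 2.9e-49)
  repl <- data.frame(snp = "rs1", beta = -0.459, p = 8.8e-10)
  v <- check_replication(disc, repl, m_pairs = 72)
  expect_true(v$replicated)
  expect_true(v$concordant)
  expect_equal(v$threshold, 0.05 / 72)

  # opposite sign: never replicated
  repl_flip <- transform(repl, beta = 0.459)
  expect_false(check_replication(disc, repl_flip, 72)$replicated)

  # boundary: p exactly at alpha/m is NOT replicated (strict <)
  repl_edge <- transform(repl, p = 0.05 / 72)
  expect_false(check_replication(disc, repl_edge, 72)$replicated)
  repl_under <- transform(repl, p = 0.05 / 72 - 1e-12)
  expect_true(check_replication(disc, repl_under, 72)$replicated)

  # unmatched SNPs are an error
  expect_error(check_replication(disc, transform(repl, snp = "rs2"), 72),
               "unmatched")
})
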