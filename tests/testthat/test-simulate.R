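test_that("cohort design validates its invariants", {
  d <- cohort_design(10, 20, 5)
  expect_equal(2 * (10 + 20) + 5, nrow(simulate_samples(d, seed = 1)))
  expect_error(cohort_design(0, 0, 0))
  expect_error(cohort_design(10, 10, 0, age_range = c(88, 19)))
})

test_that("sample sheets are deterministic under a fixed seed", {
  d <- cohort_design(30, 30, 10)
  expect_identical(simulate_samples(d, seed = 42), simulate_samples(d, seed = 42))
  g1 <- simulate_genotypes(simulate_samples(d, seed = 1), 50, seed = 9)
  g2 <- simulate_genotypes(simulate_samples(d, seed = 1), 50, seed = 9)
  expect_identical(g1$dosage, g2$dosage)
  s <- simulate_samples(d, seed = 1)
  t1 <- simulate_twin_traits(s, trait_model(0.5, 0.2, 0.3), seed = 3)
  t2 <- simulate_twin_traits(s, trait_model(0.5, 0.2, 0.3), seed = 3)
  expect_identical(t1, t2)
})

test_that("MZ co-twins carry identical genotypes; DZ share half", {
  s <- quick_cohort(80, 500, 20, seed = 2)
  g <- simulate_genotypes(s, 400, c(0.25, 0.35), seed = 2)
  birth <- ave(seq_len(nrow(s)), s$family_id, FUN = seq_along)
  for (z in c("MZ", "DZ")) {
    idx <- which(s$zygosity == z & birth == 1L)
    co <- match(paste0(s$family_id[idx], "_2"), s$id)
    if (z == "MZ") {
      expect_true(all(g$dosage[idx, ] == g$dosage[co, ]))
    } else {
      wc <- vapply(seq_along(idx), function(i)
        cor(g$dosage[idx[i], ], g$dosage[co[i], ]), 0)
      expect_lt(abs(mean(wc) - 0.5), 0.05)
    }
  }
})

test_that("MAF bounds are validated and realised MAFs recomputed", {
  s <- quick_cohort(20, 20, 0, seed = 3)
  expect_error(simulate_genotypes(s, 10, c(0.6, 0.7)), "MAF")
  expect_error(simulate_genotypes(s, 10, c(0, 0.5)), "MAF")
  g <- simulate_genotypes(s, 200, c(0.2, 0.3), seed = 3)
  expect_true(all(g$maf <= 0.5))
  expect_equal(unname(g$allele_freq), unname(colMeans(g$dosage) / 2))
})

test_that("simulated traits realise the configured twin correlations", {
  # no familial component: r_MZ ~ r_DZ ~ 0
  s0 <- quick_cohort(1000, 1000, 0, seed = 4)
  t0 <- simulate_twin_traits(s0, trait_model(0, 0, 1), seed = 4)
  p0 <- make_twin_pairs(s0, t0$value)
  expect_lt(abs(cor(p0$t1[p0$zygosity == "MZ"], p0$t2[p0$zygosity == "MZ"])), 0.05)
  expect_lt(abs(cor(p0$t1[p0$zygosity == "DZ"], p0$t2[p0$zygosity == "DZ"])), 0.05)

  # oracle: expected correlations a2 + c2 (MZ) and a2/2 + c2 (DZ)
  s1 <- quick_cohort(2000, 2000, 0, seed = 5)
  t1 <- simulate_twin_traits(s1, trait_model(0.6, 0.2, 0.2), seed = 5)
  p1 <- make_twin_pairs(s1, t1$value)
  rmz <- cor(p1$t1[p1$zygosity == "MZ"], p1$t2[p1$zygosity == "MZ"])
  rdz <- cor(p1$t1[p1$zygosity == "DZ"], p1$t2[p1$zygosity == "DZ"])
  expect_lt(abs(rmz - 0.8), 0.03)
  expect_lt(abs(rdz - 0.5), 0.03)
})

test_that("explicit SNP effects are counted inside the additive variance", {
  s <- quick_cohort(1000, 1000, 0, seed = 6)
  g <- simulate_genotypes(s, 20, c(0.2, 0.4), seed = 6)
  eff <- data.frame(snp = 1:4, beta = sqrt(c(0.05, 0.05, 0.05, 0.05)))
  tr <- simulate_twin_traits(s, trait_model(0.5, 0, 0.5, snp_effects = eff),
                             genotypes = g, seed = 6)
  # total variance still ~ 1 and MZ correlation still ~ a2
  expect_lt(abs(var(tr$value) - 1), 0.1)
  p <- make_twin_pairs(s, tr$value)
  rmz <- cor(p$t1[p$zygosity == "MZ"], p$t2[p$zygosity == "MZ"])
  expect_lt(abs(rmz - 0.5), 0.05)
  # sum of per-SNP 2pq beta^2 on the standardised scale recovers the
  # configured SNP share of a2
  expect_error(simulate_twin_traits(
    s, trait_model(0.5, 0, 0.5,
                   snp_effects = data.frame(snp = 999, beta = 0.1)), g),
    "outside")
})

test_that("glycoform panel allocation saturates, stays positive, recovers truth", {
  lay <- list(TPL = c("TPL_H5N5F1S0", "TPL_H5N5F1S1"))
  # saturation: huge latent pushes all mass to the S-carrying form
  pan_hi <- simulate_glycoform_panel(list(TPL = rep(50, 5)), lay,
                                     noise_sd = 0, seed = 1)
  rel_hi <- total_area_normalize(pan_hi$raw)
  expect_true(all(rel_hi[, "TPL_H5N5F1S1"] > 0.999))

  expect_error(simulate_glycoform_panel(list(P = rep(0, 3)),
                                        list(P = "P_H1N1F0S0"), seed = 1),
               "fewer than 2")

  # positivity and ground-truth recovery at the configured 0.3 sialylation
  set.seed(2)
  lay3 <- toy_layout()
  lat <- lapply(lay3, function(...) rnorm(2000, 0, 0.5))
  pan <- simulate_glycoform_panel(lat, lay3,
                                  target_fraction = c(TPL = 0.3), seed = 2)
  expect_true(all(pan$raw > 0))
  rel <- total_area_normalize(pan$raw)
  sfrac <- compute_derived_traits(
    rel, derived_trait_definition(
      "TPL_Sfrac", "TPL",
      c(TPL_H5N5F1S1 = 1, TPL_H5N5F1S2 = 1),
      c(TPL_H5N5F1S0 = 1, TPL_H5N5F1S1 = 1, TPL_H5N5F1S2 = 1)))
  expect_equal(unname(sfrac[, 1]), pan$truth$TPL_Sfrac, tolerance = 1e-12)
  expect_lt(abs(mean(sfrac) - 0.3), 0.02)
})

test_that("bivariate generator realises the configured cross-trait structure", {
  s <- quick_cohort(1500, 1500, 0, seed = 7)
  # null cross-correlations
  bm0 <- bivariate_trait_model(trait_model(0.5, 0, 0.5),
                               trait_model(0.5, 0, 0.5), rho_g = 0, rho_e = 0)
  tr0 <- simulate_bivariate_traits(s, bm0, seed = 7)
  expect_lt(abs(cor(tr0$x, tr0$y)), 0.05)

  # oracle: phenotypic correlation = rho_g sqrt(h2x h2y) + rho_e sqrt(e2x e2y)
  bm <- bivariate_trait_model(trait_model(0.5, 0, 0.5),
                              trait_model(0.5, 0, 0.5), rho_g = 0.8, rho_e = 0.2)
  tr <- simulate_bivariate_traits(s, bm, seed = 8)
  expect_lt(abs(cor(tr$x, tr$y) - 0.5), 0.05)

  # MZ cross-twin cross-trait covariance ~ 2x the DZ value when c2 = 0
  pp <- make_twin_pairs(s, tr[, c("x", "y")], standardize = FALSE)
  xym <- with(pp[pp$zygosity == "MZ", ], cov(x1, y2) / 2 + cov(x2, y1) / 2)
  xyd <- with(pp[pp$zygosity == "DZ", ], cov(x1, y2) / 2 + cov(x2, y1) / 2)
  expect_lt(abs(xym - 2 * xyd), 0.06)
  expect_lt(abs(xym - 0.8 * 0.5), 0.05)  # rho_g * sqrt(a2x a2y)
})

test_that("realised variance decomposition matches the configured components", {
  s <- quick_cohort(1000, 1000, 0, seed = 9)
  tr <- simulate_twin_traits(s, trait_model(0.3, 0.4, 0.3), seed = 9)
  p <- make_twin_pairs(s, tr$value)
  rmz <- cor(p$t1[p$zygosity == "MZ"], p$t2[p$zygosity == "MZ"])
  rdz <- cor(p$t1[p$zygosity == "DZ"], p$t2[p$zygosity == "DZ"])
  a2_hat <- 2 * (rmz - rdz); c2_hat <- 2 * rdz - rmz
  se3 <- 3 / sqrt(1000)
  expect_lt(abs(a2_hat - 0.3), 3 * se3)   # Falconer moments within MC noise
  expect_lt(abs(c2_hat - 0.4), 3 * se3)
})

test_that("cohort files round-trip through disk", {
  s <- quick_cohort(5, 5, 2, seed = 10)
  g <- simulate_genotypes(s, 12, c(0.2, 0.4), seed = 10)
  tr <- simulate_twin_traits(s, trait_model(0.5, 0.2, 0.3), seed = 10)
  dir <- tempfile()
  files <- write_cohort(dir, s, data.frame(id = tr$id, trait = tr$value),
                        genotypes = g, truth = attr(tr, "truth"))
  expect_true(all(file.exists(file.path(dir, c("samples.tsv", "phenotypes.tsv",
                                               "dosages.tsv", "genotypes.vcf",
                                               "truth.json")))))
  g2 <- read_dosage_tsv(file.path(dir, "dosages.tsv"))
  expect_equal(unname(g2$dosage), unname(g$dosage))
  g3 <- read_vcf_dosage(file.path(dir, "genotypes.vcf"))
  expect_equal(unname(g3$dosage[s$id, ]), unname(g$dosage))
})
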