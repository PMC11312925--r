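test_that("total-area normalisation closes each peptide to 1", {
  raw <- matrix(c(2, 3, 5, 1, 1, 3), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"),
                                c("TPL_H5N5F1S0", "TPL_H5N5F1S1", "TPL_H5N5F1S2")))
  rel <- total_area_normalize(raw)
  expect_equal(unname(rel["a", ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(rowSums(rel)), c(1, 1), tolerance = 1e-9)
  expect_identical(attr(rel, "stage"), "relative")
})

test_that("peptides are normalised independently", {
  raw <- matrix(c(1, 1, 3, 1), nrow = 1,
                dimnames = list("a", c("TPL_H5N5F1S0", "TPL_H5N5F1S1",
                                       "HYT_H3N5F0S0", "HYT_H3N5F0S1")))
  rel <- total_area_normalize(raw)
  expect_equal(unname(rel[1, ]), c(0.5, 0.5, 0.75, 0.25))
})

test_that("all-zero peptide groups become missing, not 0/0", {
  raw <- matrix(c(0, 0, 2, 2), nrow = 1,
                dimnames = list("a", c("TPL_H5N5F1S0", "TPL_H5N5F1S1",
                                       "HYT_H3N5F0S0", "HYT_H3N5F0S1")))
  rel <- total_area_normalize(raw)
  expect_true(all(is.na(rel[1, 1:2])))
  expect_equal(unname(rel[1, 3:4]), c(0.5, 0.5))
})

test_that("negative intensities are rejected", {
  raw <- matrix(c(-1, 2), nrow = 1,
                dimnames = list("a", c("TPL_H5N5F1S0", "TPL_H5N5F1S1")))
  expect_error(total_area_normalize(raw), "negative")
})

test_that("4-SD outlier rule is single-pass with a strict boundary", {
  set.seed(42)
  v <- c(rnorm(1000), 10)
  keep <- remove_outliers(v)
  expect_false(keep[1001])            # the planted outlier is masked
  # brute-force oracle: same mask from direct mean/SD arithmetic
  m <- mean(v); s <- sd(v)
  expect_identical(unname(keep), abs(v - m) <= 4 * s)

  # constant vector: SD 0, nothing masked
  expect_true(all(remove_outliers(rep(2, 10))))

  # the fence at mean + 4 SD is strict: a value a hair inside is retained,
  # a hair outside is masked. The mean/SD include the fence value itself,
  # so solve a = mean(c(base, a)) + 4 * sd(c(base, a)) for the fence.
  base <- rep(c(-1, 1), 30)
  f <- function(a) {
    v <- c(base, a)
    a - (mean(v) + 4 * sd(v))
  }
  a_star <- uniroot(f, c(0.1, 100), tol = 1e-12)$root
  keep_in <- remove_outliers(c(base, a_star - 1e-6))
  expect_true(keep_in[length(keep_in)])
  keep_out <- remove_outliers(c(base, a_star + 1e-3))
  expect_false(keep_out[length(keep_out)])
})

test_that("quantile normalisation maps ranks to normal quantiles", {
  expect_equal(quantile_normalize(c(3, 1, 2)),
               qnorm(c(0.75, 0.25, 0.5)), tolerance = 1e-12)
  expect_equal(round(quantile_normalize(c(3, 1, 2)), 4),
               c(0.6745, -0.6745, 0))

  # monotone on strictly increasing input
  x <- sort(runif(50))
  expect_true(all(diff(quantile_normalize(x)) > 0))

  # ties get the average rank, hence identical output
  y <- quantile_normalize(c(5, 2, 2, 9))
  expect_equal(y[2], y[3])

  # missing entries stay missing; mean ~ 0, SD ~ 1 at n >= 100
  set.seed(1)
  z <- c(rexp(200), NA)
  qz <- quantile_normalize(z)
  expect_true(is.na(qz[201]))
  expect_lt(abs(mean(qz, na.rm = TRUE)), 0.05)
  expect_lt(abs(sd(qz, na.rm = TRUE) - 1), 0.05)
})

test_that("derived traits evaluate weighted-sum ratios per individual", {
  rel <- matrix(c(0.5, 0.5, 0, 0, 0, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"),
                                c("TPL_H5N5F1S0", "TPL_H5N5F1S1", "TPL_H5N5F1S2")))
  all3 <- c(TPL_H5N5F1S0 = 1, TPL_H5N5F1S1 = 1, TPL_H5N5F1S2 = 1)
  sfrac <- derived_trait_definition("TPL_Sfrac", "TPL",
                                    c(TPL_H5N5F1S1 = 1, TPL_H5N5F1S2 = 1), all3)
  ns <- derived_trait_definition("TPL_nS", "TPL",
                                 c(TPL_H5N5F1S0 = 0, TPL_H5N5F1S1 = 1,
                                   TPL_H5N5F1S2 = 2), all3)
  out <- compute_derived_traits(rel, list(sfrac, ns))
  expect_equal(unname(out["a", "TPL_Sfrac"]), 0.5)
  expect_equal(unname(out["b", "TPL_nS"]), 2)

  # three-form toy panel against direct spreadsheet-style arithmetic
  ab <- c(0.2, 0.3, 0.5)
  rel2 <- matrix(ab, nrow = 1,
                 dimnames = list("x", names(all3)))
  out2 <- compute_derived_traits(rel2, list(sfrac, ns))
  expect_equal(unname(out2[1, "TPL_Sfrac"]), (0.3 + 0.5) / 1)
  expect_equal(unname(out2[1, "TPL_nS"]), (0.3 * 1 + 0.5 * 2) / 1)
})

test_that("derived traits reject unknown glycoforms and flag zero denominators", {
  rel <- matrix(c(0.5, 0.5), nrow = 1,
                dimnames = list("a", c("TPL_H5N5F1S0", "TPL_H5N5F1S1")))
  bad <- derived_trait_definition("t", "TPL", c(TPL_H5N5F1S9 = 1))
  expect_error(compute_derived_traits(rel, list(bad)), "unknown glycoform")

  rel0 <- matrix(c(1, 0), nrow = 1,
                 dimnames = list("a", c("TPL_H5N5F1S0", "TPL_H5N5F1S1")))
  ratio <- derived_trait_definition("r", "TPL", c(TPL_H5N5F1S0 = 1),
                                    c(TPL_H5N5F1S1 = 1))
  out <- compute_derived_traits(rel0, list(ratio))
  expect_true(is.na(out[1, 1]))
  expect_equal(unname(attr(out, "zero_denominator")["r"]), 1L)
})

test_that("trait definitions are config-round-trippable through YAML", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(
    "- name: TPL_Sfrac\n  peptide: TPL\n  numerator:\n    TPL_H5N5F1S1: 1\n  denominator:\n    TPL_H5N5F1S0: 1\n    TPL_H5N5F1S1: 1\n- name: TPL_sum\n  peptide: TPL\n  numerator:\n    TPL_H5N5F1S1: 2\n  denominator: '1'",
    cfg)
  defs <- read_trait_definitions(cfg)
  expect_length(defs, 2L)
  expect_s3_class(defs[[1]], "derived_trait_definition")
  expect_identical(defs[[2]]$denominator, "1")
  rel <- matrix(c(0.25, 0.75), nrow = 1,
                dimnames = list("a", c("TPL_H5N5F1S0", "TPL_H5N5F1S1")))
  out <- compute_derived_traits(rel, defs)
  expect_equal(unname(out[1, ]), c(0.75, 1.5))
})

test_that("pipeline runs in fixed order and logs it", {
  set.seed(3)
  lay <- toy_layout()
  lat <- lapply(lay, function(...) rnorm(300, 0, 0.5))
  pan <- simulate_glycoform_panel(lat, lay, seed = 3)
  out <- preprocess_abundances(pan$raw)
  expect_identical(attr(out$relative, "stage"), "outlier-filtered")
  expect_identical(attr(out$normalized, "stage"), "quantile-normalized")
  expect_match(out$log[1], "total_area")
  expect_match(out$log[3], "quantile")
  # closure holds on the un-masked entries of each peptide
  tpl <- out$relative[, lay$TPL]
  full_rows <- complete.cases(tpl)
  expect_true(all(abs(rowSums(tpl[full_rows, ]) - 1) < 1e-9))
})

test_that("residualisation strips covariate and plate structure", {
  set.seed(11)
  s <- quick_cohort(150, 150, 50, seed = 11)
  tr <- simulate_twin_traits(
    s, trait_model(0.4, 0.1, 0.5, beta_age = 0.02, plate_sd = 0.5), seed = 11)
  X <- data.frame(age = s$age, sex = as.numeric(s$sex == "F"))
  r <- residualize(tr$value, X, groups = list(plate = s$plate,
                                              family = s$family_id))
  expect_lt(abs(cor(r, s$age)), 0.05)
  # between-plate variance of residuals ~ 0
  plate_means <- tapply(r, s$plate, mean)
  expect_lt(var(plate_means), 0.02)

  # with zero random-effect variance the result equals OLS residuals
  set.seed(12)
  y <- rnorm(200)
  X2 <- data.frame(a = rnorm(200))
  g <- rep(1:10, each = 20)
  r_lmm <- residualize(y, X2, groups = list(g = g), standardize = FALSE)
  r_ols <- residuals(lm(y ~ a, data = cbind(data.frame(y = y), X2)))
  expect_equal(unname(r_lmm), unname(r_ols), tolerance = 1e-6)
})

test_that("the shipped example trait-definition config loads and evaluates", {
  path <- system.file("extdata", "derived_traits_example.yaml",
                      package = "glycotwin")
  defs <- read_trait_definitions(path)
  expect_length(defs, 4L)
  expect_setequal(vapply(defs, `[[`, "", "peptide"), c("TPL", "TPL", "HYT", "LSL"))
  rel <- matrix(c(0.2, 0.3, 0.5), nrow = 1,
                dimnames = list("a", c("TPL_H5N5F1S0", "TPL_H5N5F1S1",
                                       "TPL_H5N5F1S2")))
  out <- compute_derived_traits(rel, defs[1:2])
  expect_equal(unname(out[1, "TPL_Sfrac"]), 0.8)
  expect_equal(unname(out[1, "TPL_nS"]), 1.3)
})
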