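#' Twin cohort design
#'
#' Describes the shape of a simulated twin cohort: numbers of monozygotic
#' (MZ) and dizygotic (DZ) twin pairs and of singletons, the female
#' fraction, the age range (years, uniform) and the number of LC-MS plates.
#' Defaults mirror a large adult volunteer twin registry: 513 MZ and 615 DZ
#' pairs plus 167 singletons, 78% female, ages 19-88.
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons cohort composition (counts >= 0).
#' @param sex_fraction_female proportion of females in [0, 1].
#' @param age_range numeric length-2, min and max age in years.
#' @param n_plates number of measurement plates (>= 1).
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_mz_pairs = 513, n_dz_pairs = 615, n_singletons = 167,
                          sex_fraction_female = 0.78, age_range = c(19, 88),
                          n_plates = 20) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0, n_singletons >= 0,
            n_mz_pairs + n_dz_pairs + n_singletons > 0,
            sex_fraction_female >= 0, sex_fraction_female <= 1,
            length(age_range) == 2L, age_range[1] <= age_range[2],
            n_plates >= 1)
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_singletons = as.integer(n_singletons),
                 sex_fraction_female = sex_fraction_female,
                 age_range = age_range, n_plates = as.integer(n_plates)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Twin cohort design: ", x$n_mz_pairs, " MZ pairs, ", x$n_dz_pairs,
      " DZ pairs, ", x$n_singletons, " singletons (",
      2L * (x$n_mz_pairs + x$n_dz_pairs) + x$n_singletons, " individuals); ",
      round(100 * x$sex_fraction_female), "% female, ages ",
      x$age_range[1], "-", x$age_range[2], ", ", x$n_plates, " plates\n",
      sep = "")
  invisible(x)
}

#' Simulate the sample sheet of a twin cohort
#'
#' Draws individual-level metadata for a [cohort_design()]: family IDs,
#' zygosity (`MZ`/`DZ`, `NA` for singletons), sex (co-twins share sex; MZ
#' by definition, DZ here for simplicity of the sex model), age (uniform on
#' the design range, shared within pair) and plate. Plates are assigned
#' round-robin by family so that zygosity is not confounded with plate.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return data frame (the sample sheet): `id`, `family_id`, `zygosity`,
#'   `sex` (`"F"`/`"M"`), `age`, `plate`.
#' @export
simulate_samples <- function(design, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  n_fam <- design$n_mz_pairs + design$n_dz_pairs + design$n_singletons
  fam_zyg <- rep(c("MZ", "DZ", NA_character_),
                 c(design$n_mz_pairs, design$n_dz_pairs, design$n_singletons))
  fam_size <- ifelse(is.na(fam_zyg), 1L, 2L)
  fam_sex <- ifelse(stats::runif(n_fam) < design$sex_fraction_female, "F", "M")
  fam_age <- stats::runif(n_fam, design$age_range[1], design$age_range[2])
  fam_plate <- ((seq_len(n_fam) - 1L) %% design$n_plates) + 1L
  fam_id <- sprintf("FAM%04d", seq_len(n_fam))
  idx <- rep(seq_len(n_fam), fam_size)
  birth <- unlist(lapply(fam_size, seq_len))
  data.frame(
    id = sprintf("%s_%d", fam_id[idx], birth),
    family_id = fam_id[idx],
    zygosity = fam_zyg[idx],
    sex = fam_sex[idx],
    age = round(fam_age[idx], 1),
    plate = fam_plate[idx],
    stringsAsFactors = FALSE
  )
}

#' Simulate genotypes under a parental-gamete model
#'
#' Each family receives two simulated parents whose four haplotypes carry
#' independent alleles at frequency drawn uniformly from `maf_range` per
#' SNP. Children inherit one gamete from each parent (independent
#' assortment across SNPs): MZ co-twins share one genome, DZ co-twins draw
#' independent gametes (expected dosage correlation 1/2), singletons draw
#' one genome. Minor allele frequencies are recomputed from the realised
#' dosages.
#'
#' @param samples sample sheet from [simulate_samples()].
#' @param n_snp number of SNPs (>= 1).
#' @param maf_range length-2 numeric, 0 < low <= high <= 0.5.
#' @param seed integer seed.
#' @return list of class `genotype_matrix`: `dosage` (individuals x SNPs
#'   integer matrix in 0/1/2, rownames = sample ids), `snp_ids`, `maf`
#'   (realised minor allele frequency per SNP), `allele_freq` (realised
#'   frequency of the counted allele).
#' @export
simulate_genotypes <- function(samples, n_snp, maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L, n_snp >= 1L,
            length(maf_range) == 2L)
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] && maf_range[2] <= 0.5))
    stop("invalid MAF bounds: need 0 < low <= high <= 0.5", call. = FALSE)
  set.seed(seed + 1L)
  fams <- unique(samples$family_id)
  nf <- length(fams)
  p <- stats::runif(n_snp, maf_range[1], maf_range[2])
  hap <- function() matrix(stats::rbinom(nf * n_snp, 1L, rep(p, each = nf)), nf, n_snp)
  pat1 <- hap(); pat2 <- hap(); mat1 <- hap(); mat2 <- hap()
  gamete_pair <- function() {
    # one child genome: one gamete from each parent, free recombination
    sp <- matrix(stats::runif(nf * n_snp) < 0.5, nf, n_snp)
    sm <- matrix(stats::runif(nf * n_snp) < 0.5, nf, n_snp)
    ifelse(sp, pat1, pat2) + ifelse(sm, mat1, mat2)
  }
  child1 <- gamete_pair()
  child2 <- gamete_pair()   # used only by DZ second twins
  fam_row <- match(samples$family_id, fams)
  birth <- stats::ave(seq_len(nrow(samples)), samples$family_id, FUN = seq_along)
  dos <- matrix(0L, nrow(samples), n_snp,
                dimnames = list(samples$id, sprintf("snp%05d", seq_len(n_snp))))
  for (i in seq_len(nrow(samples))) {
    use2 <- birth[i] == 2L && identical(samples$zygosity[i], "DZ")
    dos[i, ] <- if (use2) child2[fam_row[i], ] else child1[fam_row[i], ]
  }
  af <- colMeans(dos) / 2
  structure(list(dosage = dos, snp_ids = colnames(dos),
                 maf = pmin(af, 1 - af), allele_freq = af),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " SNPs; realised MAF ",
      sprintf("%.3f-%.3f", min(x$maf), max(x$maf)), "\n", sep = "")
  invisible(x)
}

#' Generative trait model for a twin cohort
#'
#' Specifies the latent variance decomposition of a simulated trait:
#' additive genetic (`a2`), shared-environment (`c2`) and unique-environment
#' (`e2`) proportions summing to 1 (the variance of the latent trait before
#' covariate effects), plus optional explicit SNP effects (drawn from
#' designated causal SNPs; `beta` is per standardised allele, so each SNP
#' contributes `beta^2` of latent variance, counted inside `a2`), and age,
#' sex and plate covariate effects.
#'
#' @param a2,c2,e2 variance proportions, each >= 0, summing to 1.
#' @param snp_effects `NULL`, or a data frame with columns `snp` (index or
#'   id) and `beta` (effect per standardised allele).
#' @param beta_age fixed effect per year of age.
#' @param beta_sex fixed effect of female sex.
#' @param plate_sd SD of the Gaussian plate random effect.
#' @return object of class `trait_model`.
#' @export
trait_model <- function(a2, c2, e2, snp_effects = NULL,
                        beta_age = 0, beta_sex = 0, plate_sd = 0) {
  stopifnot(a2 >= 0, c2 >= 0, e2 >= 0, abs(a2 + c2 + e2 - 1) < 1e-8,
            plate_sd >= 0)
  if (!is.null(snp_effects))
    stopifnot(is.data.frame(snp_effects), all(c("snp", "beta") %in% names(snp_effects)))
  structure(list(a2 = a2, c2 = c2, e2 = e2, snp_effects = snp_effects,
                 beta_age = beta_age, beta_sex = beta_sex, plate_sd = plate_sd),
            class = "trait_model")
}

# Draw the familial components (A, C, E) for all individuals of a sample
# sheet. A is a pair component with cross-twin correlation 1 (MZ) / r_dz
# (DZ); C is identical within pair; E independent. Returns an n x 3 matrix.
draw_ace_components <- function(samples, va, vc, ve, r_dz = 0.5) {
  n <- nrow(samples)
  fams <- unique(samples$family_id)
  fam_row <- match(samples$family_id, fams)
  birth <- stats::ave(seq_len(n), samples$family_id, FUN = seq_along)
  fam_zyg <- samples$zygosity[match(fams, samples$family_id)]
  nf <- length(fams)
  # A: draw (A1, A2) per family with corr 1 (MZ) or r_dz (DZ)
  z1 <- stats::rnorm(nf); z2 <- stats::rnorm(nf)
  r <- ifelse(is.na(fam_zyg), 0, ifelse(fam_zyg == "MZ", 1, r_dz))
  a1 <- sqrt(va) * z1
  a2v <- sqrt(va) * (r * z1 + sqrt(pmax(1 - r^2, 0)) * z2)
  cfam <- sqrt(vc) * stats::rnorm(nf)
  A <- ifelse(birth == 1L, a1[fam_row], a2v[fam_row])
  C <- cfam[fam_row]
  E <- sqrt(ve) * stats::rnorm(n)
  cbind(A = A, C = C, E = E)
}

# Standardize dosage columns by their realised allele frequency: (d - 2p)/sqrt(2pq).
standardize_dosage <- function(genotypes, cols) {
  d <- genotypes$dosage[, cols, drop = FALSE]
  p <- genotypes$allele_freq[cols]
  sweep(sweep(d, 2L, 2 * p), 2L, sqrt(2 * p * (1 - p)), "/")
}

#' Simulate a twin-cohort quantitative trait with known variance components
#'
#' Generates a latent trait as the sum of explicit SNP effects (on
#' standardised dosages), a residual polygenic pair component with cross-twin
#' correlation 1 (MZ) / 0.5 (DZ), a shared-environment pair component, a
#' unique-environment component, and age/sex/plate covariate effects. The
#' residual polygenic variance is `a2` minus the explicit SNP variance
#' `sum(beta^2)`, so the total additive-genetic variance equals `a2`.
#'
#' @param samples sample sheet from [simulate_samples()].
#' @param model a [trait_model()].
#' @param genotypes a `genotype_matrix` (required when `model$snp_effects`
#'   is non-`NULL`).
#' @param seed integer seed.
#' @return data frame `id`, `value`, with a `"truth"` attribute recording
#'   the generative parameters (including the realised SNP variance).
#' @export
simulate_twin_traits <- function(samples, model, genotypes = NULL, seed = 1L) {
  stopifnot(inherits(model, "trait_model"))
  set.seed(seed + 2L)
  n <- nrow(samples)
  g <- numeric(n)
  var_snp <- 0
  if (!is.null(model$snp_effects)) {
    stopifnot(inherits(genotypes, "genotype_matrix"))
    idx <- model$snp_effects$snp
    if (is.numeric(idx) && any(idx < 1 | idx > ncol(genotypes$dosage)))
      stop("SNP effect indexed outside the genotype matrix", call. = FALSE)
    if (is.character(idx) && any(!idx %in% genotypes$snp_ids))
      stop("SNP effect indexed outside the genotype matrix", call. = FALSE)
    if (!all(samples$id %in% rownames(genotypes$dosage)))
      stop("genotypes do not cover all individuals", call. = FALSE)
    Z <- standardize_dosage(genotypes, idx)[samples$id, , drop = FALSE]
    g <- as.numeric(Z %*% model$snp_effects$beta)
    var_snp <- sum(model$snp_effects$beta^2)
    if (var_snp > model$a2 + 1e-8)
      stop("explicit SNP variance exceeds a2", call. = FALSE)
  }
  va_resid <- max(model$a2 - var_snp, 0)
  comp <- draw_ace_components(samples, va_resid, model$c2, model$e2)
  plate_u <- model$plate_sd * stats::rnorm(max(samples$plate))
  value <- g + comp[, "A"] + comp[, "C"] + comp[, "E"] +
    model$beta_age * samples$age +
    model$beta_sex * as.numeric(samples$sex == "F") +
    plate_u[samples$plate]
  out <- data.frame(id = samples$id, value = value, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(a2 = model$a2, c2 = model$c2, e2 = model$e2,
                             var_snp = var_snp, beta_age = model$beta_age,
                             beta_sex = model$beta_sex, plate_sd = model$plate_sd)
  out
}

#' Bivariate generative trait model
#'
#' Two [trait_model()]s coupled through a genetic correlation `rho_g`
#' (between the residual polygenic components) and a unique-environment
#' correlation `rho_e`; `rho_c` optionally correlates the shared-environment
#' components. The implied 2x2 correlation matrices must be positive
#' semi-definite (automatic for single correlations in [-1, 1]).
#'
#' @param model_x,model_y [trait_model()]s for the two traits.
#' @param rho_g,rho_e,rho_c cross-trait correlations in [-1, 1].
#' @return object of class `bivariate_trait_model`.
#' @export
bivariate_trait_model <- function(model_x, model_y, rho_g, rho_e, rho_c = 0) {
  stopifnot(inherits(model_x, "trait_model"), inherits(model_y, "trait_model"),
            abs(rho_g) <= 1, abs(rho_e) <= 1, abs(rho_c) <= 1)
  structure(list(model_x = model_x, model_y = model_y,
                 rho_g = rho_g, rho_e = rho_e, rho_c = rho_c),
            class = "bivariate_trait_model")
}

#' Simulate a correlated trait pair on a twin cohort
#'
#' Generates two traits whose residual polygenic, shared-environment and
#' unique-environment components are cross-correlated (`rho_g`, `rho_c`,
#' `rho_e`). Shared explicit SNP effects (the same SNP appearing in both
#' trait models) additionally contribute `beta_x * beta_y` of genetic
#' covariance. Cross-twin cross-trait genetic covariance is
#' `rho_g * sqrt(va_x * va_y)` for MZ pairs and half that for DZ pairs.
#'
#' @param samples sample sheet from [simulate_samples()].
#' @param model a [bivariate_trait_model()].
#' @param genotypes optional `genotype_matrix` for explicit SNP effects.
#' @param seed integer seed.
#' @return data frame `id`, `x`, `y` with a `"truth"` attribute.
#' @export
simulate_bivariate_traits <- function(samples, model, genotypes = NULL, seed = 1L) {
  stopifnot(inherits(model, "bivariate_trait_model"))
  set.seed(seed + 3L)
  mx <- model$model_x; my <- model$model_y
  n <- nrow(samples)
  gx <- gy <- numeric(n)
  var_snp_x <- var_snp_y <- 0
  for (side in c("x", "y")) {
    m <- if (side == "x") mx else my
    if (is.null(m$snp_effects)) next
    stopifnot(inherits(genotypes, "genotype_matrix"))
    Z <- standardize_dosage(genotypes, m$snp_effects$snp)[samples$id, , drop = FALSE]
    gv <- as.numeric(Z %*% m$snp_effects$beta)
    if (side == "x") { gx <- gv; var_snp_x <- sum(m$snp_effects$beta^2) }
    else { gy <- gv; var_snp_y <- sum(m$snp_effects$beta^2) }
  }
  vax <- max(mx$a2 - var_snp_x, 0); vay <- max(my$a2 - var_snp_y, 0)
  # Draw a correlated pair of standard components per channel, then scale:
  # the y-channel reuses the x-channel standard draws with weight rho.
  draw2 <- function(vx, vy, rho) {
    sx <- draw_ace_components(samples, 1, 0, 0)[, "A"]
    s2 <- draw_ace_components(samples, 1, 0, 0)[, "A"]
    list(x = sqrt(vx) * sx, y = sqrt(vy) * (rho * sx + sqrt(1 - rho^2) * s2))
  }
  A <- draw2(vax, vay, model$rho_g)
  # C: shared within family, cross-trait corr rho_c
  fams <- unique(samples$family_id)
  fam_row <- match(samples$family_id, fams)
  z1 <- stats::rnorm(length(fams)); z2 <- stats::rnorm(length(fams))
  Cx <- sqrt(mx$c2) * z1[fam_row]
  Cy <- sqrt(my$c2) * (model$rho_c * z1 + sqrt(1 - model$rho_c^2) * z2)[fam_row]
  e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
  Ex <- sqrt(mx$e2) * e1
  Ey <- sqrt(my$e2) * (model$rho_e * e1 + sqrt(1 - model$rho_e^2) * e2)
  cov_fix <- function(m) {
    m$beta_age * samples$age + m$beta_sex * as.numeric(samples$sex == "F")
  }
  out <- data.frame(id = samples$id,
                    x = gx + A$x + Cx + Ex + cov_fix(mx),
                    y = gy + A$y + Cy + Ey + cov_fix(my),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(a2_x = mx$a2, a2_y = my$a2, c2_x = mx$c2,
                             c2_y = my$c2, e2_x = mx$e2, e2_y = my$e2,
                             rho_g = model$rho_g, rho_e = model$rho_e,
                             rho_c = model$rho_c,
                             var_snp_x = var_snp_x, var_snp_y = var_snp_y)
  out
}

#' Logistic-normal allocation of glycoform proportions
#'
#' Row-wise softmax: maps unconstrained scores to strictly positive
#' proportions summing to 1, monotone in each score. This is the
#' compositional link of the glycoform panel generator.
#'
#' @param scores numeric matrix (individuals x glycoforms) of latent scores.
#' @return matrix of proportions, rows summing to 1.
#' @export
logistic_normal_allocation <- function(scores) {
  stopifnot(is.matrix(scores))
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Simulate a compositional glycoform panel from latent traits
#'
#' For each peptide, per-individual glycoform proportions are a
#' logistic-normal allocation: `softmax(baseline + loading * latent + noise)`,
#' where the loading is the glycoform's count of the chosen feature residue
#' (default sialic acids, so a higher latent shifts mass toward more
#' sialylated forms). Proportions are scaled to arbitrary intensity units
#' by a per-individual log-normal total, giving strictly positive raw
#' abundances. When `target_fraction` is supplied the baseline is
#' calibrated (at latent 0, ignoring noise) so the expected fraction of
#' feature-carrying forms matches it. Ground-truth derived traits computed
#' from the allocation itself are recorded for recovery testing.
#'
#' @param latent named list: peptide -> numeric vector of per-individual
#'   latent trait values (use 0s for a static panel).
#' @param layout named list: peptide -> character vector of glycoform names
#'   (>= 2 per peptide, all on that peptide).
#' @param feature residue whose count loads on the latent: `"S"`, `"H"`,
#'   `"N"` or `"F"`.
#' @param target_fraction optional named numeric: peptide -> desired mean
#'   fraction of feature-carrying glycoforms.
#' @param noise_sd SD of the per-entry Gaussian score noise (within-peptide
#'   biological variability not driven by the latent).
#' @param intensity_meanlog,intensity_sdlog log-normal parameters of the
#'   per-individual total intensity.
#' @param seed integer seed.
#' @return list: `raw` (individuals x glycoforms intensity matrix, stage
#'   `"raw"`), `truth` (data frame of per-individual ground-truth derived
#'   traits `<pep>_Sfrac`-style fractions and `<pep>_nS`-style counts for
#'   the chosen feature).
#' @export
simulate_glycoform_panel <- function(latent, layout, feature = "S",
                                     target_fraction = NULL, noise_sd = 0.3,
                                     intensity_meanlog = 10, intensity_sdlog = 0.4,
                                     seed = 1L) {
  stopifnot(is.list(latent), is.list(layout),
            all(names(latent) %in% names(layout)),
            feature %in% c("H", "N", "F", "S"))
  set.seed(seed + 4L)
  n <- length(latent[[1L]])
  cols <- unlist(layout, use.names = FALSE)
  raw <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  truth <- list()
  total <- stats::rlnorm(n, intensity_meanlog, intensity_sdlog)
  for (pep in names(layout)) {
    forms <- layout[[pep]]
    if (length(forms) < 2L)
      stop("peptide ", pep, " has fewer than 2 glycoforms", call. = FALSE)
    comp <- parse_glycoform_name(forms)
    stopifnot(all(comp$peptide == pep))
    load <- comp[[feature]]
    lat <- latent[[pep]]
    if (is.null(lat)) lat <- numeric(n)
    stopifnot(length(lat) == n)
    scores <- outer(lat, load) +
      matrix(stats::rnorm(n * length(forms), sd = noise_sd), n, length(forms))
    if (!is.null(target_fraction) && pep %in% names(target_fraction)) {
      # calibrate a common shift of the feature-carrying forms so the mean
      # realised carrier fraction matches the target (solved on the actual
      # scores, so the nonlinearity of the softmax is accounted for)
      tgt <- target_fraction[[pep]]
      carrier <- load >= 1
      stopifnot(any(carrier), !all(carrier), tgt > 0, tgt < 1)
      f <- function(t) {
        a <- logistic_normal_allocation(scores +
                                          matrix(t * carrier, n, length(forms),
                                                 byrow = TRUE))
        mean(rowSums(a[, carrier, drop = FALSE])) - tgt
      }
      shift <- stats::uniroot(f, c(-50, 50))$root
      scores <- scores + matrix(shift * carrier, n, length(forms), byrow = TRUE)
    }
    alloc <- logistic_normal_allocation(scores)
    raw[, forms] <- alloc * total
    truth[[paste0(pep, "_", feature, "frac")]] <-
      rowSums(alloc[, load >= 1, drop = FALSE])
    truth[[paste0(pep, "_n", feature)]] <- as.numeric(alloc %*% load)
  }
  abundance_stage(raw) <- "raw"
  list(raw = raw, truth = as.data.frame(truth, check.names = FALSE))
}

#' Simulate an LD block of unrelated individuals
#'
#' Generates haplotype-level genotypes for unrelated individuals where every
#' SNP is a noisy copy of a shared base haplotype pair: each haplotype
#' allele is flipped independently with probability `flip_prob`, so all
#' columns are mutually in linkage disequilibrium (high r^2 for small
#' `flip_prob`). Used to exercise conditional scans on a locus with one
#' causal SNP and LD proxies.
#'
#' @param n number of individuals.
#' @param n_snp number of SNPs in the block.
#' @param maf allele frequency of the base haplotype.
#' @param flip_prob per-allele flip probability for proxy SNPs (column 1 is
#'   the unflipped base SNP).
#' @param seed integer seed.
#' @return integer dosage matrix n x n_snp.
#' @export
simulate_ld_block <- function(n, n_snp, maf = 0.3, flip_prob = 0.02, seed = 1L) {
  stopifnot(n >= 1, n_snp >= 1, maf > 0, maf < 1, flip_prob >= 0, flip_prob < 0.5)
  set.seed(seed + 5L)
  h1 <- stats::rbinom(n, 1L, maf)
  h2 <- stats::rbinom(n, 1L, maf)
  dos <- matrix(0L, n, n_snp, dimnames = list(NULL, sprintf("ld%03d", seq_len(n_snp))))
  dos[, 1L] <- h1 + h2
  if (n_snp > 1L) for (j in 2:n_snp) {
    f1 <- stats::rbinom(n, 1L, flip_prob)
    f2 <- stats::rbinom(n, 1L, flip_prob)
    dos[, j] <- abs(h1 - f1) + abs(h2 - f2)
  }
  dos
}
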