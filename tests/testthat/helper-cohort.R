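# Shared fixture builders: small cohorts assembled in code at test time.

quick_cohort <- function(n_mz = 100, n_dz = 100, n_singletons = 0, seed = 1) {
  simulate_samples(cohort_design(n_mz, n_dz, n_singletons), seed = seed)
}

# A toy three-peptide glycoform panel layout used across preprocessing and
# ratio tests.
toy_layout <- function() {
  list(
    TPL = c("TPL_H5N5F1S0", "TPL_H5N5F1S1", "TPL_H5N5F1S2"),
    HYT = c("HYT_H3N5F0S0", "HYT_H3N5F0S1", "HYT_H4N5F0S1"),
    LSL = c("LSL_H5N4F0S0", "LSL_H5N4F0S1")
  )
}

# Brute-force enumeration of +1-residue reaction pairs, the independent
# oracle for identify_reaction_pairs on small sets.
brute_force_pairs <- function(names, residue) {
  cc <- parse_glycoform_name(unique(names))
  out <- list()
  for (i in seq_len(nrow(cc))) for (j in seq_len(nrow(cc))) {
    if (i == j || cc$peptide[i] != cc$peptide[j]) next
    d <- c(cc$H[j] - cc$H[i], cc$N[j] - cc$N[i],
           cc$F[j] - cc$F[i], cc$S[j] - cc$S[i])
    names(d) <- c("H", "N", "F", "S")
    if (d[[residue]] == 1L && all(d[setdiff(names(d), residue)] == 0L))
      out[[length(out) + 1L]] <- c(cc$name[i], cc$name[j])
  }
  out
}
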