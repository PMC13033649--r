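# Shared fixture builders: everything is generated in code at test time.

make_cohort <- function(n, seed = 1) {
  generate_cohort(sim_config(n_patients = n, seed = seed))
}

empty_mask <- function(n) {
  matrix(FALSE, n, length(site_features()),
         dimnames = list(NULL, site_features()))
}

# Mask specific (row, feature) cells of a cohort; returns masked + mask.
mask_cells <- function(cohort, cells) {
  mask <- empty_mask(nrow(cohort))
  masked <- cohort
  for (cell in cells) {
    mask[cell$row, cell$feature] <- TRUE
    masked[[cell$feature]][cell$row] <- NA_real_
  }
  list(masked = masked, mask = mask)
}

# A standard small masked fixture for imputer tests.
make_masked_fixture <- function(n = 60, rate = 0.15, seed = 7) {
  cohort <- make_cohort(n, seed = seed)
  mc <- apply_mcar(cohort, rate = rate, seed = seed + 1)
  list(cohort = cohort, masked = mc$masked, mask = mc$mask)
}

expect_observed_preserved <- function(imputed, masked, mask) {
  for (f in colnames(mask)) {
    expect_identical(imputed[[f]][!mask[, f]], masked[[f]][!mask[, f]])
  }
}
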