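# Shared fixtures, memoised so expensive cohorts build once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Tiny handcrafted dataset: 5 genes x 8 cells, 2 patients x 2 cell types.
toy_sc <- function(scale = "counts") {
  m <- matrix(c(
    10, 0, 8, 1, 12, 2, 9, 0,
    0, 5, 1, 6, 1, 7, 0, 5,
    2, 2, 2, 2, 2, 2, 2, 2,
    1, 0, 0, 0, 0, 0, 0, 1,
    5, 5, 6, 4, 5, 6, 4, 5), nrow = 5, byrow = TRUE,
    dimnames = list(paste0("g", 1:5), paste0("c", 1:8)))
  sc <- single_cell_dataset(
    m, cell_type = rep(c("A", "B"), 4),
    sample_id = rep(c("p1", "p2"), each = 4), scale = "counts")
  if (scale == "cpm") cpm_normalize(sc) else sc
}

# The standard synthetic cohort (stated defaults, seed 3), CPM-normalized.
default_cohort <- function() cached_fixture("default_cohort", {
  co <- generate_cohort(synth_config(), seed = 3)
  list(sc = cpm_normalize(co$sc), truth = co$truth, config = co$config)
})

# Low-patient-effect cohort used to isolate planted marker structure.
mild_cohort <- function() cached_fixture("mild_cohort", {
  co <- generate_cohort(synth_config(patient_effect_sd = 0.2), seed = 5)
  list(sc = cpm_normalize(co$sc), truth = co$truth)
})

# 100-sample simulations at the canonical seed, shared by ordering and
# deconvolution tests (and matching the acceptance-scale setup).
acceptance_sim <- function() cached_fixture("acceptance_sim", {
  co <- generate_cohort(synth_config(), seed = 1)
  sc <- cpm_normalize(co$sc)
  spec <- profile_spec(malignant_label = co$truth$malignant_label)
  fr <- simulate_fractions_beta(fit_beta(observed_patient_fractions(sc)),
                                100, seed = 1001)
  homo <- simulate_bulk_homogeneous(sc, fr, spec, seed = 1002)
  list(sc = sc, truth = co$truth, spec = spec, fractions = fr,
       homo = homo$bulk, homo_truth = homo$fractions,
       semi = simulate_bulk_semiheterogeneous(sc, fr, spec, seed = 1003),
       heter = simulate_bulk_heterogeneous(sc, fr, spec, seed = 1004))
})

expect_colsums_cpm <- function(bulk, tol = 1e-6) {
  cs <- colSums(bulk$expression)
  expect_true(all(abs(cs - 1e6) <= tol * 1e6),
              label = sprintf("columns of %s sum to 1e6", bulk$provenance))
}
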