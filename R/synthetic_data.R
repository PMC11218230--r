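# Synthetic multi-patient tumor scRNA-seq cohorts with controllable
# intra-cell-type heterogeneity. The generator is first-class, seeded code:
# its truth tables (planted markers, patient effects, subtype labels) are the
# oracles for the rest of the test suite.

#' Configuration of the synthetic cohort generator
#'
#' Defaults describe a desk-scale tumor cohort: 4 cell types (the first,
#' `Malignant`, carries the optional subtype structure), 8 patients, 20–60
#' cells per (patient, type), 40 planted marker genes per type elevated by
#' log2FC 3, and per-patient per-gene log-normal expression shifts within
#' each cell type (`patient_effect_sd`, natural-log scale) — the dial that
#' creates the patient heterogeneity the simulation strategies do or do not
#' preserve. Counts are negative binomial so gene-level overdispersion exists
#' even with the patient dial at zero.
#'
#' @param n_genes total genes.
#' @param n_cell_types number of cell types (named `Malignant`, `CT2`, ...).
#' @param n_patients number of patients.
#' @param cells_per_patient_per_type integer range, cells drawn uniformly.
#' @param n_marker_genes_per_type planted markers per type (disjoint blocks).
#' @param marker_log2fc planted marker elevation (log2 scale).
#' @param patient_effect_sd sd of the per-patient, per-gene, per-type
#'   log-normal multiplicative effect (0 switches patient structure off).
#' @param n_subtypes malignant subtypes (1 = no subtype structure).
#' @param subtype_log2fc elevation of each subtype's gene block.
#' @param n_subtype_genes genes per subtype block.
#' @param nb_size negative binomial size (inverse dispersion); variance is
#'   mu + mu^2 / size.
#' @param library_size_range UMI-per-cell range (uniform).
#' @return object of class `SynthConfig`.
#' @export
synth_config <- function(n_genes = 1000, n_cell_types = 4, n_patients = 8,
                         cells_per_patient_per_type = c(20, 60),
                         n_marker_genes_per_type = 40, marker_log2fc = 3,
                         patient_effect_sd = 0.8,
                         n_subtypes = 1, subtype_log2fc = 1, n_subtype_genes = 30,
                         nb_size = 10, library_size_range = c(2000, 6000)) {
  cfg <- structure(as.list(environment()), class = "SynthConfig")
  with(cfg, {
    if (!.is_count(n_genes) || !.is_count(n_cell_types) || !.is_count(n_patients) ||
        !.is_count(n_subtypes))
      .stopf("sizes must be positive integers")
    if (length(cells_per_patient_per_type) != 2L ||
        cells_per_patient_per_type[1] < 1 ||
        cells_per_patient_per_type[1] > cells_per_patient_per_type[2])
      .stopf("cells_per_patient_per_type must be an increasing range >= 1")
    if (patient_effect_sd < 0) .stopf("patient_effect_sd must be >= 0")
    if (marker_log2fc <= 0 || subtype_log2fc <= 0) .stopf("fold changes must be > 0")
    if (n_marker_genes_per_type * n_cell_types +
        (n_subtypes > 1) * n_subtypes * n_subtype_genes > n_genes)
      .stopf("not enough genes for the planted marker/subtype blocks")
    if (nb_size <= 0) .stopf("nb_size must be > 0")
  })
  cfg
}

#' Generate a synthetic multi-patient cohort
#'
#' Counts are NegBin(mean = L_c * p_c, size = nb_size) where the cell's gene
#' probabilities p_c renormalize base_g * type_effect * patient_effect *
#' subtype_effect: a log-normal base profile, planted 2^logFC marker blocks
#' per type, per-(gene, patient, type) log-normal shifts, and (optionally)
#' subtype blocks within the malignant type. Deterministic under `seed`.
#'
#' @param config a `SynthConfig`.
#' @param seed RNG seed.
#' @return list: `sc` (a counts-scale `SingleCellDataset`; malignant subtype
#'   in its `subcluster` slot when `n_subtypes > 1`), `truth` with
#'   `markers` (list per type), `patient_effects` (gene x patient x type
#'   array), `subtype` (per-cell label or NULL), `cell_types`,
#'   `malignant_label`.
#' @export
generate_cohort <- function(config = synth_config(), seed = NULL) {
  stopifnot(is(config, "SynthConfig"))
  .with_seed(seed, {
    G <- config$n_genes; K <- config$n_cell_types; P <- config$n_patients
    cts <- c("Malignant", if (K > 1) paste0("CT", 2:K))
    patients <- sprintf("patient%02d", seq_len(P))
    genes <- sprintf("G%04d", seq_len(G))

    base <- stats::rlnorm(G, meanlog = 1, sdlog = 1)
    # disjoint planted marker blocks, then subtype blocks
    markers <- list()
    type_mult <- matrix(1, G, K, dimnames = list(genes, cts))
    for (k in seq_len(K)) {
      block <- ((k - 1) * config$n_marker_genes_per_type + 1):
        (k * config$n_marker_genes_per_type)
      markers[[cts[k]]] <- genes[block]
      type_mult[block, k] <- 2^config$marker_log2fc
    }
    sub_mult <- NULL
    if (config$n_subtypes > 1) {
      offset <- K * config$n_marker_genes_per_type
      sub_mult <- matrix(1, G, config$n_subtypes)
      for (s in seq_len(config$n_subtypes)) {
        block <- offset + ((s - 1) * config$n_subtype_genes + 1):
          (s * config$n_subtype_genes)
        sub_mult[block, s] <- 2^config$subtype_log2fc
      }
    }
    patient_eff <- array(
      exp(rnorm(G * P * K, 0, config$patient_effect_sd)),
      dim = c(G, P, K), dimnames = list(genes, patients, cts))

    n_cells_tab <- matrix(
      sample(seq(config$cells_per_patient_per_type[1],
                 config$cells_per_patient_per_type[2]),
             P * K, replace = TRUE),
      P, K, dimnames = list(patients, cts))
    total <- sum(n_cells_tab)
    expr <- matrix(0L, G, total, dimnames = list(genes, NULL))
    cell_type <- character(total); sample_id <- character(total)
    subtype <- if (config$n_subtypes > 1) character(total) else NULL
    cell_ids <- character(total)
    col <- 0L
    for (p in seq_len(P)) for (k in seq_len(K)) {
      n_c <- n_cells_tab[p, k]
      mu_base <- base * type_mult[, k] * patient_eff[, p, k]
      for (i in seq_len(n_c)) {
        col <- col + 1L
        st <- if (!is.null(sub_mult) && k == 1L)
          sample.int(config$n_subtypes, 1) else NA_integer_
        mu <- mu_base
        if (!is.na(st)) mu <- mu * sub_mult[, st]
        L <- runif(1, config$library_size_range[1], config$library_size_range[2])
        expr[, col] <- rnbinom(G, size = config$nb_size, mu = L * mu / sum(mu))
        cell_type[col] <- cts[k]; sample_id[col] <- patients[p]
        cell_ids[col] <- sprintf("%s_%s_c%03d", patients[p], cts[k], i)
        if (!is.null(subtype))
          subtype[col] <- if (is.na(st)) "" else paste0("subtype", st)
      }
    }
    colnames(expr) <- cell_ids
    # a fully zero cell would break CPM normalization; resample its library
    zero <- which(colSums(expr) == 0)
    for (z in zero)
      expr[, z] <- rnbinom(G, size = config$nb_size,
                           mu = config$library_size_range[2] * base / sum(base))
    sc <- single_cell_dataset(expr * 1.0, cell_type, sample_id, scale = "counts")
    list(sc = sc,
         truth = list(markers = markers, patient_effects = patient_eff,
                      subtype = subtype, cell_types = cts,
                      malignant_label = "Malignant"),
         config = config)
  })
}

#' Bundled end-to-end benchmark fixture
#'
#' One seeded call producing everything the downstream stages consume: a
#' CPM-normalized cohort, beta-simulated fractions, and bulk datasets from
#' all four strategies — small enough to run in well under two minutes.
#'
#' @param n_samples simulated bulk samples per strategy.
#' @param config a `SynthConfig`.
#' @param seed RNG seed (child seeds are derived per stage).
#' @return list: `sc_cpm`, `truth`, `beta_params`, `fractions`,
#'   `realized_fractions` (homogeneous ground truth), `bulk` (named list of
#'   the four `BulkDataset`s), `baseline`.
#' @export
generate_benchmark_fixture <- function(n_samples = 20, config = synth_config(),
                                       seed = 1) {
  cohort <- generate_cohort(config, seed = seed)
  sc <- cpm_normalize(cohort$sc)
  spec <- profile_spec(malignant_label = cohort$truth$malignant_label)
  params <- fit_beta(observed_patient_fractions(sc))
  fr <- simulate_fractions_beta(params, n_samples, seed = seed + 1)
  homo <- simulate_bulk_homogeneous(sc, fr, spec, seed = seed + 2)
  semi <- simulate_bulk_semiheterogeneous(sc, fr, spec, seed = seed + 3)
  heter <- simulate_bulk_heterogeneous(sc, fr, spec, seed = seed + 4)
  free <- simulate_bulk_heterogeneous_sampleIDfree(sc, fr, spec, seed = seed + 5)
  list(sc_cpm = sc, truth = cohort$truth, beta_params = params, fractions = fr,
       realized_fractions = homo$fractions,
       bulk = list(homogeneous = homo$bulk, semi_heterogeneous = semi,
                   heterogeneous = heter, heterogeneous_sampleIDfree = free),
       baseline = baseline_pseudobulk(sc))
}
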