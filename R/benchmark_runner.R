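# Orchestrates the benchmark grid: strategies x references x methods x
# repeats, collecting per-cell-type evaluation records with full provenance.

BENCH_STRATEGIES <- c("homogeneous", "semi_heterogeneous", "heterogeneous",
                      "heterogeneous_sampleIDfree")

#' @noRd
.child_seed <- function(master, repeat_idx) {
  # documented scheme: child = master * 1000 + repeat index (stays < 2^31
  # for any sane master seed), so single repeats reproduce in isolation
  as.integer(master * 1000 + repeat_idx)
}

#' @noRd
.build_reference <- function(sc, reference, logfc_threshold) {
  switch(reference,
    all_genes = celltype_mean_profile(sc),
    de_markers = signature_from_markers(
      sc, de_markers(sc, mode = "onevsrest", logfc_threshold = logfc_threshold)),
    hv_genes = {
      sig <- celltype_mean_profile(sc)
      genes <- select_hv_genes(max_specificity_scores(sig), threshold = 0.3)
      signature_matrix(sig$values[genes, , drop = FALSE])
    },
    .stopf("unknown reference: %s", reference))
}

#' Run the benchmark grid
#'
#' For each repeat: simulate fractions from the cohort's fitted beta laws,
#' simulate bulk under every requested strategy, build each reference from
#' the same single cells, run each registered method, and score it. Failed
#' external methods are recorded (`pearson_r = NA`) and the run continues.
#' The master seed spawns per-repeat child seeds (`master * 1000 + repeat`),
#' so any single repeat can be reproduced in isolation.
#'
#' @param sc_cpm CPM-scale `SingleCellDataset`.
#' @param strategies subset of
#'   `homogeneous, semi_heterogeneous, heterogeneous, heterogeneous_sampleIDfree`.
#' @param methods method names known to [get_deconvolution_method()].
#' @param references subset of `all_genes`, `de_markers`, `hv_genes`.
#' @param n_repeats repeats of the whole pipeline (default 10).
#' @param n_samples simulated samples per bulk dataset (default 100).
#' @param spec a `ProfileSpec`; its `malignant_label` is required when
#'   `semi_heterogeneous` is requested.
#' @param seed master seed.
#' @param dataset_label provenance label stored in the records.
#' @param logfc_threshold passed to the DE reference builder.
#' @return list: `records` (one row per strategy x method x reference x
#'   repeat x cell type), `summary` (mean/min/max of per-repeat mean r and
#'   mean RMSE per grid cell), `ranks` (dense rank by mean r within
#'   strategy).
#' @export
run_benchmark <- function(sc_cpm, strategies = BENCH_STRATEGIES,
                          methods = "nnls", references = "all_genes",
                          n_repeats = 10, n_samples = 100,
                          spec = profile_spec(), seed = 1,
                          dataset_label = "dataset1", logfc_threshold = 2) {
  sc <- .require_cpm(sc_cpm)
  strategies <- match.arg(strategies, BENCH_STRATEGIES, several.ok = TRUE)
  for (m in methods) get_deconvolution_method(m)  # fail fast on unknown names
  refs <- lapply(setNames(references, references), .build_reference,
                 sc = sc, logfc_threshold = logfc_threshold)
  params <- fit_beta(observed_patient_fractions(sc))
  records <- list()
  for (r in seq_len(n_repeats)) {
    cs <- .child_seed(seed, r)
    fr <- simulate_fractions_beta(params, n_samples, seed = cs)
    for (strat in strategies) {
      sim <- switch(strat,
        homogeneous = simulate_bulk_homogeneous(sc, fr, spec, seed = cs + 1L),
        semi_heterogeneous = list(
          bulk = simulate_bulk_semiheterogeneous(sc, fr, spec, seed = cs + 2L),
          fractions = fr),
        heterogeneous = list(
          bulk = simulate_bulk_heterogeneous(sc, fr, spec, seed = cs + 3L),
          fractions = fr),
        heterogeneous_sampleIDfree = list(
          bulk = simulate_bulk_heterogeneous_sampleIDfree(sc, fr, spec, seed = cs + 4L),
          fractions = fr))
      for (ref_name in references) for (m in methods) {
        est <- tryCatch(get_deconvolution_method(m)(sim$bulk, refs[[ref_name]]),
                        error = function(e) structure(
                          list(reason = conditionMessage(e)), class = "deconv_failure"))
        if (is(est, "deconv_failure")) {
          records[[length(records) + 1L]] <- data.frame(
            dataset = dataset_label, repeat_idx = r, strategy = strat,
            regression_choice = m, reference_choice = ref_name,
            cell_type = NA_character_, pearson_r = NA_real_, rmse = NA_real_,
            seed = cs, failed = TRUE)
          next
        }
        ev <- evaluate_deconvolution(est, sim$fractions)
        records[[length(records) + 1L]] <- data.frame(
          dataset = dataset_label, repeat_idx = r, strategy = strat,
          regression_choice = m, reference_choice = ref_name,
          cell_type = ev$per_type$cell_type, pearson_r = ev$per_type$pearson_r,
          rmse = ev$rmse, seed = cs, failed = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  summary <- summarize_benchmark(records)
  list(records = records, summary = summary, ranks = .rank_table(summary))
}

#' Summarize benchmark records
#'
#' Per (strategy, method, reference): the mean over repeats of the
#' per-repeat mean cell-type Pearson r (undefined correlations excluded),
#' its min/max across repeats, and the mean RMSE.
#'
#' @param records record data.frame from [run_benchmark()].
#' @return summary data.frame.
#' @export
summarize_benchmark <- function(records) {
  ok <- records[!records$failed & !is.na(records$pearson_r), , drop = FALSE]
  key <- interaction(ok$strategy, ok$regression_choice, ok$reference_choice,
                     ok$repeat_idx, drop = TRUE)
  per_rep <- do.call(rbind, lapply(split(ok, key), function(d) data.frame(
    strategy = d$strategy[1], regression_choice = d$regression_choice[1],
    reference_choice = d$reference_choice[1], repeat_idx = d$repeat_idx[1],
    mean_r = mean(d$pearson_r), rmse = d$rmse[1])))
  key2 <- interaction(per_rep$strategy, per_rep$regression_choice,
                      per_rep$reference_choice, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_rep, key2), function(d) data.frame(
    strategy = d$strategy[1], regression_choice = d$regression_choice[1],
    reference_choice = d$reference_choice[1],
    mean_r = mean(d$mean_r), min_r = min(d$mean_r), max_r = max(d$mean_r),
    mean_rmse = mean(d$rmse), n_repeats = nrow(d))))
  rownames(out) <- NULL
  out
}

#' @noRd
.rank_table <- function(summary) {
  do.call(rbind, lapply(split(summary, summary$strategy), function(d) {
    d$rank <- match(-d$mean_r, sort(unique(-d$mean_r)))  # dense rank, ties share
    d[order(d$rank), c("strategy", "regression_choice", "reference_choice",
                       "mean_r", "rank")]
  }))
}

#' Rank shift between two simulation strategies
#'
#' Dense ranks of each (method, reference) pair by mean r within each of two
#' strategies, reported side by side — the movement off the diagonal is how
#' much a method's apparent standing depends on the simulation regime.
#' Pairs missing in either strategy are excluded with a warning.
#'
#' @param summary summary data.frame from [run_benchmark()].
#' @param strategy_a,strategy_b two strategy names present in the summary.
#' @return data.frame `method`, `reference`, `rank_a`, `rank_b`.
#' @export
rank_shift_table <- function(summary, strategy_a, strategy_b) {
  pick <- function(s) summary[summary$strategy == s, , drop = FALSE]
  a <- pick(strategy_a); b <- pick(strategy_b)
  if (!nrow(a) || !nrow(b)) .stopf("strategy missing from summary")
  key <- function(d) paste(d$regression_choice, d$reference_choice)
  common <- intersect(key(a), key(b))
  lost <- setdiff(union(key(a), key(b)), common)
  if (length(lost))
    .warnf("method(s) missing in one strategy excluded: %s",
           paste(lost, collapse = "; "))
  a <- a[key(a) %in% common, ]; b <- b[key(b) %in% common, ]
  dense <- function(x) match(-x, sort(unique(-x)))
  a$rank <- dense(a$mean_r); b$rank <- dense(b$mean_r)
  m <- match(key(a), key(b))
  data.frame(method = a$regression_choice, reference = a$reference_choice,
             rank_a = a$rank, rank_b = b$rank[m])
}
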