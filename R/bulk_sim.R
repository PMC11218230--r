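# Bulk mixture simulation under four heterogeneity regimes.
#
# All strategies operate on CPM-scale single cells and conserve the CPM
# library size: every simulated column sums to 1e6 because each component
# profile sums to 1e6 and the mixing weights sum to 1.

#' Simulation parameters shared by the bulk strategies
#'
#' @param subsample_low,subsample_high when building a patient (or
#'   sub-cluster) profile, the fraction of pooled cells used is drawn
#'   uniformly from this range; defaults 0.5–1.0 so no profile reuses the
#'   exact same cells across simulated samples.
#' @param threshold minimum cells per (patient, cell type) before pooling
#'   across additional patients kicks in.
#' @param n_cells cells aggregated per homogeneous sample; `NULL` means the
#'   per-patient median cell count of the input dataset.
#' @param malignant_label the cell type treated as malignant by the
#'   semi-heterogeneous strategy.
#' @return object of class `ProfileSpec`.
#' @export
profile_spec <- function(subsample_low = 0.5, subsample_high = 1.0,
                         threshold = 10, n_cells = NULL,
                         malignant_label = NULL) {
  if (!(subsample_low > 0 && subsample_low <= subsample_high && subsample_high <= 1))
    .stopf("need 0 < subsample_low <= subsample_high <= 1")
  if (!.is_count(threshold)) .stopf("threshold must be a positive integer")
  if (!is.null(n_cells) && !.is_count(n_cells)) .stopf("n_cells must be a positive integer")
  structure(list(subsample_low = subsample_low, subsample_high = subsample_high,
                 threshold = as.integer(threshold),
                 n_cells = if (is.null(n_cells)) NULL else as.integer(n_cells),
                 malignant_label = malignant_label),
            class = "ProfileSpec")
}

#' @noRd
.default_n_cells <- function(sc, spec) {
  if (!is.null(spec$n_cells)) return(spec$n_cells)
  max(1L, as.integer(round(median(table(sc$sample_id)))))
}

#' @noRd
.require_cpm <- function(sc) {
  validate_single_cell_dataset(sc)
  if (!identical(sc$scale, "cpm")) .stopf("CPM-scale input required (run cpm_normalize)")
  sc
}

#' Largest-remainder apportionment of n items over target fractions
#'
#' Integer allocation proportional to `fractions` (which need not sum to 1;
#' they are normalized). Floors are assigned first; remaining items go to the
#' largest fractional remainders, ties broken by cell-type name order.
#'
#' @param n total items to allocate.
#' @param fractions named non-negative weights.
#' @return named integer vector summing to `n`.
#' @export
largest_remainder <- function(n, fractions) {
  if (is.null(names(fractions))) names(fractions) <- paste0("CT", seq_along(fractions))
  f <- fractions / sum(fractions)
  raw <- n * f
  base <- floor(raw)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    ord <- order(-(raw - base), names(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Baseline pseudobulk: one sample per patient
#'
#' The realism yardstick for variance comparison — each patient's column is
#' the arithmetic mean of that patient's CPM cell profiles, so library sizes
#' stay at 1e6.
#'
#' @param sc_cpm CPM-scale `SingleCellDataset`.
#' @return a `BulkDataset` with provenance `baseline`.
#' @export
baseline_pseudobulk <- function(sc_cpm) {
  sc <- .require_cpm(sc_cpm)
  patients <- sort(unique(sc$sample_id))
  m <- vapply(patients, function(p)
    rowMeans(sc$expression[, sc$sample_id == p, drop = FALSE]),
    numeric(nrow(sc$expression)))
  bulk_dataset(m, provenance = "baseline")
}

#' Build a patient-specific cell-type profile C_k
#'
#' If the patient has at least `spec$threshold` cells of the type, a random
#' 50–100% subset (u ~ Uniform(subsample_low, subsample_high), at least one
#' cell, without replacement) is averaged. Below the threshold, cells of the
#' same type from additional randomly chosen patients are pooled until the
#' threshold is reached, then subsampled the same way — this prevents both
#' cell reuse across simulated samples and sparsity in small patients.
#' Uses the current RNG stream (seed at the strategy level).
#'
#' @param sc_cpm CPM-scale `SingleCellDataset`.
#' @param cell_type the cell type of the profile.
#' @param patient the patient (sample_id) anchoring the profile.
#' @param spec a `ProfileSpec`.
#' @return named list: `profile` (sums to 1e6), `n_pool`, `n_selected`.
#' @export
build_patient_profile <- function(sc_cpm, cell_type, patient, spec = profile_spec()) {
  sc <- .require_cpm(sc_cpm)
  is_type <- sc$cell_type == cell_type
  if (!any(is_type)) .stopf("cell type %s has no cells", cell_type)
  pool <- which(is_type & sc$sample_id == patient)
  if (length(pool) < spec$threshold) {
    others <- setdiff(unique(sc$sample_id[is_type]), patient)
    for (p in sample(others)) {
      if (length(pool) >= spec$threshold) break
      pool <- c(pool, which(is_type & sc$sample_id == p))
    }
  }
  u <- runif(1, spec$subsample_low, spec$subsample_high)
  n_sel <- max(1L, as.integer(round(u * length(pool))))
  sel <- if (n_sel >= length(pool)) pool else sample(pool, n_sel)
  list(profile = rowMeans(sc$expression[, sel, drop = FALSE]),
       n_pool = length(pool), n_selected = length(sel))
}

#' @noRd
.profile_from_indices <- function(sc, idx_pool, spec) {
  u <- runif(1, spec$subsample_low, spec$subsample_high)
  n_sel <- max(1L, as.integer(round(u * length(idx_pool))))
  sel <- if (n_sel >= length(idx_pool)) idx_pool else sample(idx_pool, n_sel)
  rowMeans(sc$expression[, sel, drop = FALSE])
}

#' Homogeneous bulk simulation
#'
#' The conventional pseudobulk construction: per sample, `n_cells` cells are
#' allocated over cell types by largest-remainder apportionment of the target
#' fractions, drawn uniformly from ALL patients (without replacement unless a
#' type's request exceeds availability), and averaged. The returned ground
#' truth is the realized count fraction n_k/n, which removes rounding bias
#' from evaluation.
#'
#' @param sc_cpm CPM-scale `SingleCellDataset`.
#' @param fractions target `FractionMatrix` (samples x cell types).
#' @param spec a `ProfileSpec`.
#' @param seed RNG seed.
#' @return list: `bulk` (a `BulkDataset`, provenance `homogeneous`),
#'   `fractions` (realized `FractionMatrix`).
#' @export
simulate_bulk_homogeneous <- function(sc_cpm, fractions, spec = profile_spec(),
                                      seed = NULL) {
  sc <- .require_cpm(sc_cpm)
  validate_fraction_matrix(fractions)
  cts <- colnames(fractions$values)
  missing_ct <- setdiff(cts[colSums(fractions$values) > 0], unique(sc$cell_type))
  if (length(missing_ct))
    .stopf("cell type(s) absent from dataset: %s", paste(missing_ct, collapse = ", "))
  n <- .default_n_cells(sc, spec)
  .with_seed(seed, {
    type_idx <- lapply(cts, function(ct) which(sc$cell_type == ct))
    names(type_idx) <- cts
    G <- nrow(sc$expression)
    Y <- matrix(0, G, nrow(fractions$values),
                dimnames = list(rownames(sc$expression), rownames(fractions$values)))
    realized <- matrix(0, nrow(fractions$values), length(cts),
                       dimnames = dimnames(fractions$values))
    for (s in seq_len(nrow(fractions$values))) {
      f <- setNames(fractions$values[s, ], colnames(fractions$values))
      if (n < sum(f > 0))
        .stopf("n_cells=%d cannot represent %d cell types with positive fractions",
               n, sum(f > 0))
      counts <- largest_remainder(n, f)
      acc <- numeric(G)
      for (ct in cts) {
        nk <- counts[[ct]]
        if (nk == 0L) next
        idx <- type_idx[[ct]]
        sel <- sample(idx, nk, replace = nk > length(idx))
        acc <- acc + rowSums(sc$expression[, sel, drop = FALSE])
      }
      Y[, s] <- acc / n
      realized[s, ] <- counts / n
    }
    list(bulk = bulk_dataset(Y, provenance = "homogeneous", seed = seed),
         fractions = fraction_matrix(realized))
  })
}

#' Heterogeneous bulk simulation
#'
#' Per sample, the expression of each cell type k with positive fraction
#' comes exclusively from one randomly chosen patient's k profile C_k
#' (see [build_patient_profile()]); the column is the fraction-weighted sum
#' of the per-type profiles. This preserves patient-level coherence of each
#' component and hence sample-level biological variance.
#'
#' @inheritParams simulate_bulk_homogeneous
#' @return a `BulkDataset` with provenance `heterogeneous`; the input
#'   fractions are the exact ground truth.
#' @export
simulate_bulk_heterogeneous <- function(sc_cpm, fractions, spec = profile_spec(),
                                        seed = NULL) {
  sc <- .require_cpm(sc_cpm)
  validate_fraction_matrix(fractions)
  cts <- colnames(fractions$values)
  used <- cts[colSums(fractions$values) > 0]
  missing_ct <- setdiff(used, unique(sc$cell_type))
  if (length(missing_ct))
    .stopf("cell type(s) in fractions but in no patient: %s",
           paste(missing_ct, collapse = ", "))
  .with_seed(seed, {
    patients_of <- lapply(used, function(ct) unique(sc$sample_id[sc$cell_type == ct]))
    names(patients_of) <- used
    Y <- matrix(0, nrow(sc$expression), nrow(fractions$values),
                dimnames = list(rownames(sc$expression), rownames(fractions$values)))
    for (s in seq_len(nrow(fractions$values))) {
      f <- setNames(fractions$values[s, ], colnames(fractions$values))
      acc <- numeric(nrow(sc$expression))
      for (ct in cts) {
        if (f[[ct]] <= 0) next
        pat <- patients_of[[ct]][sample.int(length(patients_of[[ct]]), 1)]
        ck <- build_patient_profile(sc, ct, pat, spec)$profile
        acc <- acc + f[[ct]] * ck
      }
      Y[, s] <- acc
    }
    bulk_dataset(Y, provenance = "heterogeneous", seed = seed)
  })
}

#' Semi-heterogeneous bulk simulation
#'
#' Only the malignant component is patient-restricted: it is
#' `f_mal * C_malignant` for one randomly chosen patient. Each non-malignant
#' type contributes `f_k` times the mean CPM of n_k cells drawn from all
#' patients, with n_k allocated by largest remainder over the non-malignant
#' share of `n_cells` (types with positive fraction get at least one cell).
#'
#' @inheritParams simulate_bulk_homogeneous
#' @return a `BulkDataset` with provenance `semi_heterogeneous`.
#' @export
simulate_bulk_semiheterogeneous <- function(sc_cpm, fractions, spec = profile_spec(),
                                            seed = NULL) {
  sc <- .require_cpm(sc_cpm)
  validate_fraction_matrix(fractions)
  mal <- spec$malignant_label
  if (is.null(mal)) .stopf("spec$malignant_label is required for semi-heterogeneous simulation")
  cts <- colnames(fractions$values)
  if (!mal %in% cts) .stopf("malignant label %s not among fraction cell types", mal)
  missing_ct <- setdiff(cts[colSums(fractions$values) > 0], unique(sc$cell_type))
  if (length(missing_ct))
    .stopf("cell type(s) absent from dataset: %s", paste(missing_ct, collapse = ", "))
  n <- .default_n_cells(sc, spec)
  nonmal <- setdiff(cts, mal)
  .with_seed(seed, {
    mal_patients <- unique(sc$sample_id[sc$cell_type == mal])
    type_idx <- lapply(nonmal, function(ct) which(sc$cell_type == ct))
    names(type_idx) <- nonmal
    G <- nrow(sc$expression)
    Y <- matrix(0, G, nrow(fractions$values),
                dimnames = list(rownames(sc$expression), rownames(fractions$values)))
    for (s in seq_len(nrow(fractions$values))) {
      f <- setNames(fractions$values[s, ], colnames(fractions$values))
      acc <- numeric(G)
      if (f[[mal]] > 0) {
        pat <- mal_patients[sample.int(length(mal_patients), 1)]
        acc <- f[[mal]] * build_patient_profile(sc, mal, pat, spec)$profile
      }
      f_non <- f[nonmal]
      if (sum(f_non) > 0) {
        n_non <- max(sum(f_non > 0), as.integer(round(n * (1 - f[[mal]]))))
        counts <- largest_remainder(n_non, f_non)
        counts[f_non > 0 & counts == 0L] <- 1L
        for (ct in nonmal) {
          if (counts[[ct]] == 0L) next
          idx <- type_idx[[ct]]
          sel <- sample(idx, counts[[ct]], replace = counts[[ct]] > length(idx))
          acc <- acc + f[[ct]] * rowMeans(sc$expression[, sel, drop = FALSE])
        }
      }
      Y[, s] <- acc
    }
    bulk_dataset(Y, provenance = "semi_heterogeneous", seed = seed)
  })
}

#' Sub-cluster cells within each cell type
#'
#' Emulates the usual graph/partition sub-clustering at desk scale: within
#' each cell type, log2(CPM/100 + 1) transform, top-500 variable genes, PCA
#' to at most 30 components, k-means with k = max(1, floor(m/50)); clusters
#' smaller than `min_size` are merged into the nearest larger cluster by
#' centroid Euclidean distance. A type with fewer than `2 * min_size` cells
#' becomes a single sub-cluster.
#'
#' @param sc_cpm CPM-scale `SingleCellDataset`.
#' @param min_size minimum cells per sub-cluster.
#' @param seed RNG seed (k-means initialization).
#' @return the dataset with a `subcluster` label per cell
#'   (`"<cell_type>.<i>"`).
#' @export
subcluster_cells <- function(sc_cpm, min_size = 10, seed = NULL) {
  sc <- .require_cpm(sc_cpm)
  .with_seed(seed, {
    labels <- character(ncol(sc$expression))
    for (ct in unique(sc$cell_type)) {
      idx <- which(sc$cell_type == ct)
      m <- length(idx)
      k <- max(1L, m %/% 50L)
      if (m < 2L * min_size || k == 1L) {
        labels[idx] <- paste0(ct, ".1")
        next
      }
      lx <- log2(sc$expression[, idx, drop = FALSE] / 100 + 1)
      vars <- apply(lx, 1, var)
      top <- order(-vars, rownames(lx))[seq_len(min(500L, nrow(lx)))]
      lx <- lx[top, , drop = FALSE]
      lx <- lx[apply(lx, 1, var) > 0, , drop = FALSE]
      npc <- min(30L, m - 1L, nrow(lx))
      pcs <- prcomp(t(lx), center = TRUE, scale. = FALSE, rank. = npc)$x
      cl <- kmeans(pcs, centers = k, nstart = 10, iter.max = 50)$cluster
      cl <- .merge_small_clusters(pcs, cl, min_size)
      labels[idx] <- paste0(ct, ".", cl)
    }
    sc$subcluster <- labels
    validate_single_cell_dataset(sc)
  })
}

# Merge clusters below min_size into the nearest (centroid distance) cluster
# of adequate size; repeat until every cluster has >= min_size members (there
# is always at least one adequate cluster since k <= m/50 and min_size <= 50).
#' @noRd
.merge_small_clusters <- function(pcs, cl, min_size) {
  repeat {
    sizes <- table(cl)
    small <- names(sizes)[sizes < min_size]
    if (!length(small)) break
    big <- names(sizes)[sizes >= min_size]
    if (!length(big)) { cl[] <- cl[1]; break }
    centroids <- vapply(unique(cl), function(g)
      colMeans(pcs[cl == g, , drop = FALSE]), numeric(ncol(pcs)))
    colnames(centroids) <- as.character(unique(cl))
    worst <- small[which.min(sizes[small])]
    d <- colSums((centroids[, big, drop = FALSE] - centroids[, worst])^2)
    cl[cl == worst] <- big[which.min(d)]
  }
  as.integer(factor(cl))
}

#' Sample-ID-independent heterogeneous simulation
#'
#' Identical to [simulate_bulk_heterogeneous()] except the random unit a
#' cell-type component is drawn from is a sub-cluster rather than a patient,
#' removing the dependency on sample-ID annotations while keeping comparable
#' variance. Sub-cluster labels are computed on the fly when absent.
#'
#' @inheritParams simulate_bulk_homogeneous
#' @param min_size minimum sub-cluster size when labels must be computed.
#' @return a `BulkDataset` with provenance `heterogeneous_sampleIDfree`.
#' @export
simulate_bulk_heterogeneous_sampleIDfree <- function(sc_cpm, fractions,
                                                     spec = profile_spec(),
                                                     seed = NULL, min_size = 10) {
  sc <- .require_cpm(sc_cpm)
  validate_fraction_matrix(fractions)
  .with_seed(seed, {
    if (is.null(sc$subcluster)) sc <- subcluster_cells(sc, min_size = min_size)
    cts <- colnames(fractions$values)
    used <- cts[colSums(fractions$values) > 0]
    missing_ct <- setdiff(used, unique(sc$cell_type))
    if (length(missing_ct))
      .stopf("cell type(s) in fractions but in no sub-cluster: %s",
             paste(missing_ct, collapse = ", "))
    clusters_of <- lapply(used, function(ct) unique(sc$subcluster[sc$cell_type == ct]))
    names(clusters_of) <- used
    Y <- matrix(0, nrow(sc$expression), nrow(fractions$values),
                dimnames = list(rownames(sc$expression), rownames(fractions$values)))
    for (s in seq_len(nrow(fractions$values))) {
      f <- setNames(fractions$values[s, ], colnames(fractions$values))
      acc <- numeric(nrow(sc$expression))
      for (ct in cts) {
        if (f[[ct]] <= 0) next
        cli <- clusters_of[[ct]][sample.int(length(clusters_of[[ct]]), 1)]
        pool <- which(sc$subcluster == cli)
        if (length(pool) < spec$threshold) {
          other <- setdiff(clusters_of[[ct]], cli)
          for (oc in sample(other)) {
            if (length(pool) >= spec$threshold) break
            pool <- c(pool, which(sc$subcluster == oc))
          }
        }
        acc <- acc + f[[ct]] * .profile_from_indices(sc, pool, spec)
      }
      Y[, s] <- acc
    }
    bulk_dataset(Y, provenance = "heterogeneous_sampleIDfree", seed = seed)
  })
}
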