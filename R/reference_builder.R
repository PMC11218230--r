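# Signature-matrix and marker-set construction from training single cells,
# and their interconversion. DE testing goes through limma (moderated t with
# BH adjustment) on log2(CPM + 1) values.

#' Per-cell-type mean expression profile (all genes)
#'
#' X\[g, k\] = mean CPM of gene g over cells of type k; every column sums to
#' 1e6. This raw gene-by-cell-type matrix is the starting point for both
#' signature refinement and specificity scoring.
#'
#' @param sc_cpm CPM-scale `SingleCellDataset`.
#' @return a `SignatureMatrix` over all genes.
#' @export
celltype_mean_profile <- function(sc_cpm) {
  sc <- .require_cpm(sc_cpm)
  cts <- sort(unique(sc$cell_type))
  m <- vapply(cts, function(ct)
    rowMeans(sc$expression[, sc$cell_type == ct, drop = FALSE]),
    numeric(nrow(sc$expression)))
  signature_matrix(m)
}

#' @noRd
.limma_onevsrest <- function(lx, is_k) {
  design <- cbind(Intercept = 1, group = as.numeric(is_k))
  fit <- eBayes(lmFit(lx, design))
  topTable(fit, coef = "group", number = Inf, sort.by = "none")
}

#' Differential-expression cell-type markers
#'
#' Runs limma's moderated t-test on log2(CPM+1) values. In `onevsrest` mode
#' each type is contrasted against all remaining cells pooled; the logFC is
#' the mean log difference. In `pairwise` mode a gene is a marker of type k
#' only if, for every other type k', logFC(k vs k') exceeds the threshold
#' with a BH-adjusted p below `alpha` (the minimum pairwise logFC rule).
#' Cell types with fewer than `minimum_n` passing genes are dropped from the
#' result with a warning. For datasets with subdued fold changes the
#' threshold is conventionally relaxed to 1.
#'
#' @param sc_cpm CPM-scale `SingleCellDataset` with >= 2 cell types and >= 3
#'   cells per type.
#' @param mode `"onevsrest"` or `"pairwise"`.
#' @param logfc_threshold minimum log2 fold change (default 2).
#' @param minimum_n minimum passing genes for a type to be kept (default 5).
#' @param alpha BH-adjusted p-value cutoff; `NULL` disables the p filter.
#' @return a `MarkerSet` (lists ordered by decreasing logFC; attribute
#'   `stats` holds the per-gene logFC table). Lists from different types may
#'   overlap in pairwise mode.
#' @export
de_markers <- function(sc_cpm, mode = c("onevsrest", "pairwise"),
                       logfc_threshold = 2, minimum_n = 5, alpha = 0.05) {
  sc <- .require_cpm(sc_cpm)
  mode <- match.arg(mode)
  cts <- sort(unique(sc$cell_type))
  if (length(cts) < 2L) .stopf("need >= 2 cell types")
  n_per <- table(sc$cell_type)
  if (any(n_per < 3L))
    .stopf("cell type(s) with fewer than 3 cells: %s",
           paste(names(n_per)[n_per < 3L], collapse = ", "))
  lx <- .log_tx(sc$expression)
  sets <- list()
  stats_rows <- list()
  for (ct in cts) {
    if (mode == "onevsrest") {
      tt <- .limma_onevsrest(lx, sc$cell_type == ct)
      pass <- tt$logFC > logfc_threshold &
        (if (is.null(alpha)) TRUE else tt$adj.P.Val < alpha)
      lfc <- tt$logFC
    } else {
      per_pair <- lapply(setdiff(cts, ct), function(ct2) {
        sel <- sc$cell_type %in% c(ct, ct2)
        .limma_onevsrest(lx[, sel, drop = FALSE], sc$cell_type[sel] == ct)
      })
      lfc <- do.call(pmin, lapply(per_pair, `[[`, "logFC"))
      p_ok <- Reduce(`&`, lapply(per_pair, function(tt)
        if (is.null(alpha)) rep(TRUE, nrow(tt)) else tt$adj.P.Val < alpha))
      pass <- lfc > logfc_threshold & p_ok
    }
    genes <- rownames(lx)[pass]
    if (length(genes) < minimum_n) {
      .warnf("cell type %s: only %d gene(s) pass logFC > %g (minimum_n = %d); excluded",
             ct, length(genes), logfc_threshold, minimum_n)
      next
    }
    ord <- order(-lfc[pass], genes)
    sets[[ct]] <- genes[ord]
    stats_rows[[ct]] <- data.frame(cell_type = ct, gene = genes[ord],
                                   logfc = lfc[pass][ord])
  }
  if (!length(sets)) .stopf("no cell type retained any markers")
  out <- marker_set(sets, provenance = paste0("de_", mode))
  attr(out, "stats") <- do.call(rbind, c(stats_rows, list(make.row.names = FALSE)))
  out
}

#' Signature matrix from a marker set
#'
#' The per-cell-type mean profile restricted to the union of marker genes.
#' Marker genes absent from the dataset are dropped with a warning.
#'
#' @param sc_cpm CPM-scale `SingleCellDataset`.
#' @param markers a `MarkerSet`.
#' @return a `SignatureMatrix` over the marker genes.
#' @export
signature_from_markers <- function(sc_cpm, markers) {
  sc <- .require_cpm(sc_cpm)
  validate_marker_set(markers)
  genes <- unique(unlist(markers$sets, use.names = FALSE))
  missing_g <- setdiff(genes, rownames(sc$expression))
  if (length(missing_g)) {
    .warnf("%d marker gene(s) absent from dataset, dropped (first: %s)",
           length(missing_g), missing_g[1])
    genes <- setdiff(genes, missing_g)
  }
  if (!length(genes)) .stopf("no marker genes present in the dataset")
  full <- celltype_mean_profile(sc)
  signature_matrix(full$values[genes, , drop = FALSE])
}

#' Marker set from a signature matrix
#'
#' Each gene is assigned to the cell type where it is most expressed (exact
#' ties drop the gene with a warning — a tied gene is not specific). Within
#' each cell type genes are ranked by fold change, defined as (top + 1) /
#' (second-highest + 1), and at most `maximum_n` genes are kept. The
#' resulting lists are pairwise disjoint.
#'
#' @param signature a `SignatureMatrix` with >= 2 cell types.
#' @param maximum_n cap on markers per cell type (default 100).
#' @return a `MarkerSet`.
#' @export
markers_from_signature <- function(signature, maximum_n = 100) {
  validate_signature_matrix(signature)
  v <- signature$values
  if (ncol(v) < 2L) .stopf("fold change undefined for a single-cell-type signature")
  top_idx <- max.col(v, ties.method = "first")
  top_val <- v[cbind(seq_len(nrow(v)), top_idx)]
  second <- vapply(seq_len(nrow(v)), function(i) max(v[i, -top_idx[i]]), numeric(1))
  tied <- top_val == second
  if (any(tied))
    .warnf("%d gene(s) dropped for tied maximal expression (first: %s)",
           sum(tied), rownames(v)[which(tied)[1]])
  fc <- (top_val + 1) / (second + 1)
  sets <- list()
  for (k in seq_len(ncol(v))) {
    sel <- which(top_idx == k & !tied)
    if (!length(sel)) next
    sel <- sel[order(-fc[sel], rownames(v)[sel])]
    sets[[colnames(v)[k]]] <- rownames(v)[head(sel, maximum_n)]
  }
  if (!length(sets)) .stopf("no genes could be assigned to a cell type")
  marker_set(sets, provenance = "from_signature")
}

#' Maximum cell-type specificity score per gene
#'
#' From the all-gene mean profile X, spec\[g, k\] = X\[g, k\] / sum_k' X\[g, k'\]
#' and the score is max_k spec\[g, k\]: 1/K for a uniformly expressed gene, 1
#' for a perfectly specific one. All-zero genes are excluded (undefined).
#'
#' @param sc_cpm CPM-scale `SingleCellDataset`, or a `SignatureMatrix`.
#' @return named numeric vector of scores over genes with nonzero total.
#' @export
max_specificity_scores <- function(sc_cpm) {
  x <- if (is(sc_cpm, "SignatureMatrix")) sc_cpm else celltype_mean_profile(sc_cpm)
  v <- x$values
  tot <- rowSums(v)
  v <- v[tot > 0, , drop = FALSE]
  setNames(apply(v / rowSums(v), 1, max), rownames(v))
}

#' Select highly variable (highly specific) genes
#'
#' Genes whose maximum specificity score exceeds `threshold`; the customary
#' thresholds are 0.5 (signature optimization input) and 0.3 (DE candidate
#' filtering).
#'
#' @param scores named score vector from [max_specificity_scores()].
#' @param threshold selection cutoff in \[0, 1).
#' @return character vector of gene ids.
#' @export
select_hv_genes <- function(scores, threshold = 0.3) {
  names(scores)[scores > threshold]
}
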