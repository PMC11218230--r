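# Biological-variance diagnostics: does a simulated bulk dataset carry as
# much gene-level and sample-level variance as the per-patient pseudobulk
# baseline? All statistics are computed on log2(x + 1)-transformed
# expression (base and pseudocount configurable).

#' @noRd
.log_tx <- function(x, base = 2, pseudocount = 1) log(x + pseudocount, base = base)

#' Per-gene coefficient of variation on log expression
#'
#' For each gene i: mu_i = mean and sigma_i = sample sd (n-1 denominator) of
#' log2(x+1) across samples, and CV_i = sigma_i / mu_i. Genes with mu_i = 0
#' (all-zero on linear scale) are flagged undefined rather than propagated as
#' NaN.
#'
#' @param bulk a `BulkDataset` with >= 2 samples.
#' @param base,pseudocount log transform parameters.
#' @return a `CVTable`: data.frame with columns `gene`, `mu`, `sigma`, `cv`,
#'   `defined`; attribute `label` carries the dataset provenance.
#' @export
gene_cv <- function(bulk, base = 2, pseudocount = 1) {
  validate_bulk_dataset(bulk)
  if (ncol(bulk$expression) < 2L) .stopf("need >= 2 samples to compute CV")
  lx <- .log_tx(bulk$expression, base, pseudocount)
  mu <- rowMeans(lx)
  sigma <- apply(lx, 1, sd)
  defined <- mu > 0
  cv <- ifelse(defined, sigma / mu, NA_real_)
  out <- data.frame(gene = rownames(lx), mu = mu, sigma = sigma, cv = cv,
                    defined = defined, row.names = NULL)
  attr(out, "label") <- bulk$provenance
  class(out) <- c("CVTable", "data.frame")
  out
}

#' Average CV per gene set (pathway-level variance)
#'
#' Mean CV over the member genes that are present and defined; sets with
#' fewer than 3 usable genes are flagged.
#'
#' @param cv a `CVTable` from [gene_cv()].
#' @param sets a `GeneSetCollection`.
#' @return data.frame with columns `set`, `mean_cv`, `n_genes`, `flagged`.
#' @export
pathway_cv <- function(cv, sets) {
  stopifnot(is(cv, "CVTable"))
  usable <- cv[cv$defined, ]
  rows <- lapply(names(sets$sets), function(nm) {
    g <- intersect(sets$sets[[nm]], usable$gene)
    data.frame(set = nm,
               mean_cv = if (length(g)) mean(usable$cv[match(g, usable$gene)]) else NA_real_,
               n_genes = length(g), flagged = length(g) < 3L)
  })
  do.call(rbind, rows)
}

#' Top variable genes of a bulk dataset
#'
#' Genes ranked by variance of log2(x+1) descending, ties broken by gene
#' name; the conventional panel is the top 300 of the baseline pseudobulk.
#'
#' @param bulk a `BulkDataset` with >= 2 samples.
#' @param n panel size.
#' @inheritParams gene_cv
#' @return character vector of gene ids, length `min(n, genes)`.
#' @export
top_variable_genes <- function(bulk, n = 300, base = 2, pseudocount = 1) {
  validate_bulk_dataset(bulk)
  if (ncol(bulk$expression) < 2L) .stopf("need >= 2 samples")
  lx <- .log_tx(bulk$expression, base, pseudocount)
  v <- apply(lx, 1, var)
  if (n > length(v)) {
    .warnf("requested %d genes but only %d available", n, length(v))
    n <- length(v)
  }
  rownames(lx)[order(-v, rownames(lx))[seq_len(n)]]
}

#' Gene-gene Pearson correlation matrix on log expression
#'
#' @param bulk a `BulkDataset`.
#' @param genes gene panel (e.g. from [top_variable_genes()]).
#' @inheritParams gene_cv
#' @return symmetric correlation matrix with unit diagonal; rows/columns of
#'   constant genes are NA and listed in attribute `undefined`.
#' @export
gene_correlation_matrix <- function(bulk, genes, base = 2, pseudocount = 1) {
  validate_bulk_dataset(bulk)
  genes <- intersect(genes, rownames(bulk$expression))
  if (length(genes) < 2L) .stopf("need >= 2 genes present in the bulk")
  lx <- .log_tx(bulk$expression[genes, , drop = FALSE], base, pseudocount)
  const <- apply(lx, 1, sd) == 0
  cc <- suppressWarnings(cor(t(lx)))
  cc[const, ] <- NA_real_; cc[, const] <- NA_real_
  diag(cc) <- ifelse(const, NA_real_, 1)
  attr(cc, "undefined") <- genes[const]
  cc
}

#' Pairwise sample-sample Pearson correlations
#'
#' All s(s-1)/2 pairwise correlations between sample columns on log2(x+1),
#' restricted to the provided gene panel (conventionally the baseline's top
#' 300 variable genes). The distribution summarizes how exchangeable the
#' simulated samples are: homogeneous simulation yields nearly identical
#' samples (high correlations), heterogeneous simulation spreads them out.
#'
#' @param bulk a `BulkDataset` with >= 2 samples.
#' @param genes gene panel; `NULL` uses all genes.
#' @inheritParams gene_cv
#' @return numeric vector of length s(s-1)/2.
#' @export
sample_correlation_distribution <- function(bulk, genes = NULL, base = 2,
                                            pseudocount = 1) {
  validate_bulk_dataset(bulk)
  if (ncol(bulk$expression) < 2L) .stopf("need >= 2 samples")
  x <- bulk$expression
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(x))
    if (!length(genes)) .stopf("gene panel does not intersect the bulk")
    x <- x[genes, , drop = FALSE]
  }
  cc <- cor(.log_tx(x, base, pseudocount))
  cc[upper.tri(cc)]
}

#' Variance comparison report across datasets
#'
#' For every dataset (simulated strategies plus the baseline): mean gene CV
#' (defined genes only), mean pairwise sample correlation on the baseline's
#' top-`top_n` variable genes, and optionally per-pathway mean CVs. Gene
#' universes are intersected first. Warns when a simulated dataset's columns
#' do not sum to 1e6 (scale drift would corrupt CV comparison).
#'
#' @param simulated list of `BulkDataset`s (named; names become labels).
#' @param baseline the baseline `BulkDataset`.
#' @param sets optional `GeneSetCollection` for pathway columns.
#' @param top_n size of the variable-gene panel taken from the baseline.
#' @return data.frame with one row per dataset (baseline last); pathway CVs
#'   in attribute `pathways` (long data.frame) when `sets` is given.
#' @export
variance_report <- function(simulated, baseline, sets = NULL, top_n = 300) {
  if (is(simulated, "BulkDataset")) simulated <- list(simulated)
  if (is.null(names(simulated)) || any(!nzchar(names(simulated))))
    names(simulated) <- vapply(simulated, function(b) b$provenance, character(1))
  validate_bulk_dataset(baseline)
  common <- Reduce(intersect, c(lapply(simulated, gene_ids), list(gene_ids(baseline))))
  if (!length(common)) .stopf("empty gene intersection across datasets")
  subset_bulk <- function(b) {
    b$expression <- b$expression[common, , drop = FALSE]
    b
  }
  base_sub <- subset_bulk(baseline)
  panel <- top_variable_genes(base_sub, min(top_n, length(common)))
  all_ds <- c(simulated, list(baseline = base_sub))
  pathway_rows <- list()
  rows <- lapply(names(all_ds), function(nm) {
    b <- subset_bulk(all_ds[[nm]])
    cs <- colSums(all_ds[[nm]]$expression)
    if (any(abs(cs - CPM_TOTAL) > 1e-3 * CPM_TOTAL))
      .warnf("dataset %s: column sums differ from 1e6; CVs may not be comparable", nm)
    cv <- gene_cv(b)
    if (!is.null(sets)) {
      p <- pathway_cv(cv, sets)
      p$dataset <- nm
      pathway_rows[[nm]] <<- p
    }
    data.frame(dataset = nm, provenance = b$provenance,
               n_samples = ncol(b$expression),
               mean_gene_cv = mean(cv$cv[cv$defined]),
               mean_sample_correlation =
                 mean(sample_correlation_distribution(b, panel)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(sets)) attr(out, "pathways") <- do.call(rbind, pathway_rows)
  out
}
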