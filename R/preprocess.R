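# Quality control and normalization applied before any simulation.
# Default order in this package: filter on counts, then CPM-normalize.

#' Convert counts to counts per million (CPM)
#'
#' Scales every cell column to sum 1e6; expression stays on linear (non-log)
#' scale. All downstream simulation operates on CPM.
#'
#' @param sc a `SingleCellDataset` with scale flag `counts`.
#' @return the dataset with scale flag `cpm`.
#' @export
cpm_normalize <- function(sc) {
  validate_single_cell_dataset(sc)
  if (identical(sc$scale, "cpm")) .stopf("already normalized to CPM")
  cs <- colSums(sc$expression)
  zero <- which(cs == 0)
  if (length(zero))
    .stopf("all-zero cell(s): %s", paste(head(colnames(sc$expression)[zero], 5), collapse = ", "))
  sc$expression <- sweep(sc$expression, 2, cs / CPM_TOTAL, "/")
  sc$scale <- "cpm"
  validate_single_cell_dataset(sc)
}

#' Filter lowly expressed and mitochondrial/ribosomal genes
#'
#' Removes genes with nonzero expression ("expressed" = strictly positive) in
#' fewer than `min_cells` cells, and genes whose symbol matches the
#' mitochondrial (`^MT-`) or ribosomal (`^RP[SL]\\d`, `^MRP[SL]\\d`) prefix
#' patterns (case-insensitive, anchored — `MTOR` survives). Gene order is
#' preserved. On CPM-scale input the surviving columns are renormalized to
#' 1e6, so filtering and CPM normalization commute exactly.
#'
#' @param sc a `SingleCellDataset` (counts or CPM).
#' @param min_cells minimum number of cells a gene must be expressed in.
#' @param drop_mito_ribo remove mitochondrial/ribosomal genes?
#' @param mito_pattern,ribo_pattern overridable regex patterns.
#' @return the filtered dataset.
#' @export
filter_genes <- function(sc, min_cells = 5, drop_mito_ribo = TRUE,
                         mito_pattern = "^MT-",
                         ribo_pattern = "^(RP[SL][0-9]|MRP[SL][0-9])") {
  validate_single_cell_dataset(sc)
  g <- rownames(sc$expression)
  keep <- rowSums(sc$expression > 0) >= min_cells
  if (drop_mito_ribo)
    keep <- keep & !grepl(mito_pattern, g, ignore.case = TRUE) &
      !grepl(ribo_pattern, g, ignore.case = TRUE)
  if (!any(keep)) .stopf("all genes removed by filtering")
  sc$expression <- sc$expression[keep, , drop = FALSE]
  if (identical(sc$scale, "cpm"))
    sc$expression <- sweep(sc$expression, 2, colSums(sc$expression) / CPM_TOTAL, "/")
  validate_single_cell_dataset(sc)
}
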