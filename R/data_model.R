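# Core domain types (S3), validation, and plain-text readers/writers.
#
# Orientation conventions (on disk and in memory):
#   expression matrices  : genes in rows, cells/samples in columns
#   fraction matrices    : samples in rows, cell types in columns

CPM_TOTAL <- 1e6

# -- SingleCellDataset -------------------------------------------------------

#' Construct a SingleCellDataset
#'
#' Gene-by-cell expression with per-cell `cell_type` and `sample_id`
#' (patient) annotations: the substrate for all pseudobulk simulation.
#'
#' @param expression numeric gene x cell matrix with unique rownames (gene
#'   symbols) and unique colnames (cell ids); non-negative and finite.
#' @param cell_type character vector, one non-empty label per cell.
#' @param sample_id character vector, one non-empty patient label per cell.
#' @param subcluster optional character vector of per-cell sub-cluster labels
#'   within cell type (see [subcluster_cells()]).
#' @param scale `"counts"` or `"cpm"`. When `"cpm"`, every cell column must
#'   sum to 1e6 within 1e-6 relative tolerance.
#' @return object of class `SingleCellDataset`.
#' @export
single_cell_dataset <- function(expression, cell_type, sample_id,
                                subcluster = NULL, scale = c("counts", "cpm")) {
  scale <- match.arg(scale)
  sc <- structure(
    list(expression = expression,
         cell_type = as.character(cell_type),
         sample_id = as.character(sample_id),
         subcluster = if (is.null(subcluster)) NULL else as.character(subcluster),
         scale = scale),
    class = "SingleCellDataset")
  validate_single_cell_dataset(sc)
}

#' Validate a SingleCellDataset against its invariants
#' @param sc object to validate.
#' @return `sc`, invisibly checked (errors on violation).
#' @export
validate_single_cell_dataset <- function(sc) {
  x <- sc$expression
  if (!is.matrix(x) || !is.numeric(x)) .stopf("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .stopf("expression must carry gene rownames and cell colnames")
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup)) .stopf("duplicate gene ids: %s", paste(head(dup, 5), collapse = ", "))
  dupc <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dupc)) .stopf("duplicate cell ids: %s", paste(head(dupc, 5), collapse = ", "))
  if (length(sc$cell_type) != ncol(x) || length(sc$sample_id) != ncol(x))
    .stopf("annotation length (%d cell_type, %d sample_id) does not match %d cells",
           length(sc$cell_type), length(sc$sample_id), ncol(x))
  if (!is.null(sc$subcluster) && length(sc$subcluster) != ncol(x))
    .stopf("subcluster length does not match cell count")
  if (anyNA(sc$cell_type) || any(!nzchar(sc$cell_type)))
    .stopf("every cell needs a non-empty cell_type")
  if (anyNA(sc$sample_id) || any(!nzchar(sc$sample_id)))
    .stopf("every cell needs a non-empty sample_id")
  if (any(!is.finite(x))) .stopf("expression contains non-finite values")
  if (any(x < 0)) .stopf("expression contains negative values")
  if (identical(sc$scale, "cpm")) {
    cs <- colSums(x)
    bad <- which(abs(cs - CPM_TOTAL) > 1e-6 * CPM_TOTAL)
    if (length(bad))
      .stopf("scale flag is cpm but %d cell column(s) do not sum to 1e6 (first: %s)",
             length(bad), colnames(x)[bad[1]])
  }
  sc
}

#' @export
print.SingleCellDataset <- function(x, ...) {
  cat(sprintf("SingleCellDataset: %d genes x %d cells (%s scale)\n",
              nrow(x$expression), ncol(x$expression), x$scale))
  cat(sprintf("  cell types: %s\n", paste(sort(unique(x$cell_type)), collapse = ", ")))
  cat(sprintf("  patients:   %d%s\n", length(unique(x$sample_id)),
              if (is.null(x$subcluster)) "" else "  (subclustered)"))
  invisible(x)
}

#' Gene identifiers of a dataset
#' @param x a `SingleCellDataset`, `BulkDataset` or `SignatureMatrix`.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(x) {
  if (is(x, "SingleCellDataset")) rownames(x$expression)
  else if (is(x, "BulkDataset")) rownames(x$expression)
  else if (is(x, "SignatureMatrix")) rownames(x$values)
  else .stopf("no gene ids for class %s", paste(class(x), collapse = "/"))
}

# -- BulkDataset -------------------------------------------------------------

BULK_PROVENANCES <- c("homogeneous", "semi_heterogeneous", "heterogeneous",
                      "heterogeneous_sampleIDfree", "baseline", "external")

#' Construct a BulkDataset
#'
#' Gene-by-sample bulk expression on linear (non-log) scale, tagged with the
#' simulation strategy (or `baseline`/`external`) that produced it. For all
#' simulated provenances every sample column sums to 1e6 (CPM library-size
#' conservation).
#'
#' @param expression numeric gene x sample matrix, dimnames required.
#' @param provenance one of `r paste(BULK_PROVENANCES, collapse = ", ")`.
#' @param seed the seed used to simulate (NULL for baseline/external).
#' @return object of class `BulkDataset`.
#' @export
bulk_dataset <- function(expression, provenance, seed = NULL) {
  provenance <- match.arg(provenance, BULK_PROVENANCES)
  b <- structure(list(expression = expression, provenance = provenance,
                      seed = if (is.null(seed)) NULL else as.integer(seed)),
                 class = "BulkDataset")
  validate_bulk_dataset(b)
}

#' Validate a BulkDataset against its invariants
#' @param b object to validate.
#' @return `b` (errors on violation).
#' @export
validate_bulk_dataset <- function(b) {
  x <- b$expression
  if (!is.matrix(x) || !is.numeric(x)) .stopf("bulk expression must be a numeric matrix")
  if (ncol(x) < 1L) .stopf("bulk dataset has 0 samples")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .stopf("bulk expression must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) .stopf("duplicate gene ids in bulk")
  if (anyDuplicated(colnames(x))) .stopf("duplicate sample ids in bulk")
  if (any(!is.finite(x)) || any(x < 0)) .stopf("bulk expression must be finite and >= 0")
  if (!b$provenance %in% c("baseline", "external")) {
    cs <- colSums(x)
    bad <- which(abs(cs - CPM_TOTAL) > 1e-6 * CPM_TOTAL)
    if (length(bad))
      .stopf("simulated bulk column(s) not summing to 1e6: %s",
             paste(head(colnames(x)[bad], 5), collapse = ", "))
  }
  b
}

#' @export
print.BulkDataset <- function(x, ...) {
  cat(sprintf("BulkDataset [%s]: %d genes x %d samples\n",
              x$provenance, nrow(x$expression), ncol(x$expression)))
  invisible(x)
}

#' Write / read bulk expression as gene x sample TSV
#'
#' The TSV has a header row of sample ids and a first column `gene` of gene
#' ids. Provenance and seed are stored in a JSON sidecar (`<path>.meta.json`)
#' so the TSV stays plain; [read_bulk()] restores them (provenance defaults to
#' `external` when the sidecar is absent).
#'
#' @param bulk a `BulkDataset`.
#' @param path output TSV path.
#' @return `write_bulk`: `path` invisibly; `read_bulk`: a `BulkDataset`.
#' @export
write_bulk <- function(bulk, path) {
  validate_bulk_dataset(bulk)
  df <- data.frame(gene = rownames(bulk$expression), bulk$expression,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(provenance = bulk$provenance, seed = bulk$seed, scale = "linear")
  write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_bulk
#' @export
read_bulk <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .stopf("bulk TSV %s has no sample columns", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta_path <- paste0(path, ".meta.json")
  prov <- "external"; seed <- NULL
  if (file.exists(meta_path)) {
    meta <- read_json(meta_path)
    if (!is.null(meta$provenance)) prov <- meta$provenance
    if (!is.null(meta$seed)) seed <- meta$seed
  }
  bulk_dataset(m, provenance = prov, seed = seed)
}

# -- FractionMatrix ----------------------------------------------------------

#' Construct a FractionMatrix
#'
#' Sample-by-cell-type ground-truth proportions P; every entry in \[0,1\] and
#' every row sums to 1 within 1e-9.
#'
#' @param values numeric sample x cell-type matrix with dimnames.
#' @return object of class `FractionMatrix`.
#' @export
fraction_matrix <- function(values) {
  f <- structure(list(values = values), class = "FractionMatrix")
  validate_fraction_matrix(f)
}

#' Validate a FractionMatrix against its invariants
#' @param f object to validate.
#' @return `f` (errors on violation).
#' @export
validate_fraction_matrix <- function(f) {
  v <- f$values
  if (!is.matrix(v) || !is.numeric(v)) .stopf("fractions must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    .stopf("fractions must carry sample rownames and cell-type colnames")
  if (any(v < 0 | v > 1)) .stopf("fractions must lie in [0, 1]")
  rs <- rowSums(v)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad))
    .stopf("fraction row(s) not summing to 1: %s",
           paste(head(rownames(v)[bad], 5), collapse = ", "))
  f
}

#' @export
print.FractionMatrix <- function(x, ...) {
  cat(sprintf("FractionMatrix: %d samples x %d cell types\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write / read a sample x cell-type fraction TSV
#' @param fractions a `FractionMatrix`.
#' @param path TSV path.
#' @return `write_fractions`: `path` invisibly; `read_fractions`: a `FractionMatrix`.
#' @export
write_fractions <- function(fractions, path) {
  validate_fraction_matrix(fractions)
  df <- data.frame(sample = rownames(fractions$values), fractions$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fractions
#' @export
read_fractions <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  fraction_matrix(m)
}

# -- SignatureMatrix ---------------------------------------------------------

#' Construct a SignatureMatrix
#'
#' Gene-by-cell-type reference X of per-cell-type mean expression on linear
#' scale, used as the design matrix of regression deconvolution.
#'
#' @param values numeric gene x cell-type matrix with dimnames; >= 2 cell
#'   types; finite, non-negative; no duplicate genes.
#' @return object of class `SignatureMatrix`.
#' @export
signature_matrix <- function(values) {
  s <- structure(list(values = values), class = "SignatureMatrix")
  validate_signature_matrix(s)
}

#' Validate a SignatureMatrix against its invariants
#' @param s object to validate.
#' @return `s` (errors on violation).
#' @export
validate_signature_matrix <- function(s) {
  v <- s$values
  if (!is.matrix(v) || !is.numeric(v)) .stopf("signature must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    .stopf("signature must carry gene rownames and cell-type colnames")
  if (anyDuplicated(rownames(v))) .stopf("duplicate genes in signature")
  if (ncol(v) < 2L) .stopf("signature needs at least 2 cell types")
  if (any(!is.finite(v)) || any(v < 0)) .stopf("signature values must be finite and >= 0")
  s
}

#' Write / read a gene x cell-type signature TSV
#' @param signature a `SignatureMatrix`.
#' @param path TSV path.
#' @return `write_signature`: `path` invisibly; `read_signature`: a `SignatureMatrix`.
#' @export
write_signature <- function(signature, path) {
  validate_signature_matrix(signature)
  df <- data.frame(gene = rownames(signature$values), signature$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  signature_matrix(m)
}

# -- MarkerSet ---------------------------------------------------------------

#' Construct a MarkerSet
#'
#' Named list mapping each cell type to an ordered marker gene list. Lists
#' produced by [markers_from_signature()] are pairwise disjoint; lists from
#' differential expression may overlap (recorded in `provenance`).
#'
#' @param sets named list of character vectors (no empty lists; genes unique
#'   within a cell type).
#' @param provenance free-text origin tag (e.g. `"de_onevsrest"`).
#' @return object of class `MarkerSet`.
#' @export
marker_set <- function(sets, provenance = "unspecified") {
  m <- structure(list(sets = sets, provenance = provenance), class = "MarkerSet")
  validate_marker_set(m)
}

#' Validate a MarkerSet against its invariants
#' @param m object to validate.
#' @return `m` (errors on violation).
#' @export
validate_marker_set <- function(m) {
  s <- m$sets
  if (!is.list(s) || is.null(names(s)) || any(!nzchar(names(s))))
    .stopf("marker sets must be a named list")
  if (anyDuplicated(names(s))) .stopf("duplicate cell types in marker set")
  for (ct in names(s)) {
    g <- s[[ct]]
    if (!is.character(g) || length(g) == 0L) .stopf("empty marker list for %s", ct)
    if (anyDuplicated(g)) .stopf("duplicate genes in marker list for %s", ct)
  }
  m
}

#' Write / read markers as a two-column (cell_type, gene) TSV
#' @param markers a `MarkerSet`.
#' @param path TSV path.
#' @return `write_markers`: `path` invisibly; `read_markers`: a `MarkerSet`.
#' @export
write_markers <- function(markers, path) {
  validate_marker_set(markers)
  df <- data.frame(
    cell_type = rep(names(markers$sets), lengths(markers$sets)),
    gene = unlist(markers$sets, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(df)))
    .stopf("marker TSV needs cell_type and gene columns")
  marker_set(split(df$gene, factor(df$cell_type, unique(df$cell_type))),
             provenance = "file")
}

# -- GeneSetCollection -------------------------------------------------------

#' Construct a GeneSetCollection
#' @param sets named list of character vectors (unique set names; unique genes
#'   within a set), e.g. the 50 hallmark pathways.
#' @return object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets) {
  g <- structure(list(sets = sets), class = "GeneSetCollection")
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    .stopf("gene sets must be a named list with unique names")
  for (nm in names(sets))
    if (anyDuplicated(sets[[nm]])) .stopf("duplicate genes in set %s", nm)
  g
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then genes. The description is discarded; duplicate genes within a line are
#' deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return a `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      .stopf("GMT line %d has %d field(s); need name, description, >=1 gene",
             i, length(fields))
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      .warnf("GMT set %s: duplicate genes deduplicated", fields[1])
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
  }
  gene_set_collection(sets)
}

# -- single-cell reader ------------------------------------------------------

#' Read an annotated single-cell dataset
#'
#' Accepts either Matrix Market triplet format (genes x cells, gene ids in a
#' one-column file, cell order given by the annotation table) or a dense TSV
#' with gene rows and cell-id header (then `path_genes` may be `NULL`). The
#' annotation table must have columns `cell_id`, `cell_type`, `sample_id`;
#' cells are reconciled by `cell_id` and reordered to annotation order.
#'
#' @param path_matrix `.mtx` or dense TSV path.
#' @param path_genes one-gene-per-line file (first column used); required for
#'   `.mtx` input.
#' @param path_cell_annotations TSV with `cell_id`, `cell_type`, `sample_id`
#'   (optionally `subcluster`).
#' @return a validated `SingleCellDataset` with scale flag `counts`.
#' @export
read_single_cell <- function(path_matrix, path_genes = NULL, path_cell_annotations) {
  ann <- read.delim(path_cell_annotations, stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_type", "sample_id")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    .stopf("annotation table missing column(s): %s", paste(missing_cols, collapse = ", "))

  if (grepl("\\.mtx$", path_matrix, ignore.case = TRUE)) {
    if (is.null(path_genes)) .stopf("path_genes is required for Matrix Market input")
    m <- as.matrix(readMM(path_matrix))
    genes <- read.delim(path_genes, header = FALSE, stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m))
      .stopf("gene file has %d ids but matrix has %d rows", length(genes), nrow(m))
    if (ncol(m) != nrow(ann))
      .stopf("matrix has %d cells but annotation has %d rows", ncol(m), nrow(ann))
    rownames(m) <- genes
    colnames(m) <- ann$cell_id
  } else {
    df <- read.delim(path_matrix, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    orphans <- setdiff(colnames(m), ann$cell_id)
    if (length(orphans))
      .stopf("cell(s) in matrix but absent from annotations: %s",
             paste(head(orphans, 5), collapse = ", "))
    orphans2 <- setdiff(ann$cell_id, colnames(m))
    if (length(orphans2))
      .stopf("cell(s) annotated but absent from matrix: %s",
             paste(head(orphans2, 5), collapse = ", "))
    m <- m[, ann$cell_id, drop = FALSE]
  }
  single_cell_dataset(m, cell_type = ann$cell_type, sample_id = ann$sample_id,
                      subcluster = if ("subcluster" %in% names(ann)) ann$subcluster,
                      scale = "counts")
}
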