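# Baseline NNLS deconvolution, the external-method plugin contract, and the
# evaluation metrics (per-cell-type Pearson r, global RMSE) plus the linear
# effect model of methodological choices.

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b|| s.t.
# x >= 0. Hand-written because the solver is part of this package's surface;
# cross-checked in the test suite against brute-force simplex search.
#' @noRd
.nnls_solve <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- as.numeric(crossprod(A, b))
  outer_iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol && outer_iter < 30L * n) {
    outer_iter <- outer_iter + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      fix <- passive & z <= tol
      alpha <- suppressWarnings(min(x[fix] / (x[fix] - z[fix]), na.rm = TRUE))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}

#' NNLS deconvolution of bulk mixtures
#'
#' Solves, per bulk sample y over the shared-gene intersection,
#' min ||X p - y||_2 subject to p >= 0 (the basic regression view of
#' Y = X P + E), then normalizes p to sum to one. An all-zero solution falls
#' back to uniform fractions with a warning. The Euclidean residual norm
#' ||E||_2 is reported per sample as a fit diagnostic.
#'
#' @param bulk a `BulkDataset` (linear scale).
#' @param signature a `SignatureMatrix` (linear scale) sharing >= 2 genes
#'   with the bulk.
#' @return list: `fractions` (a `FractionMatrix`, samples x cell types),
#'   `residuals` (named numeric), `n_genes` used.
#' @export
deconvolve_nnls <- function(bulk, signature) {
  validate_bulk_dataset(bulk)
  validate_signature_matrix(signature)
  genes <- intersect(rownames(bulk$expression), rownames(signature$values))
  if (length(genes) < 2L) .stopf("fewer than 2 shared genes between bulk and signature")
  X <- signature$values[genes, , drop = FALSE]
  if (anyDuplicated(t(X)))
    .warnf("signature has duplicate (collinear) cell-type columns")
  Y <- bulk$expression[genes, , drop = FALSE]
  k <- ncol(X)
  P <- matrix(0, ncol(Y), k, dimnames = list(colnames(Y), colnames(X)))
  res <- setNames(numeric(ncol(Y)), colnames(Y))
  for (s in seq_len(ncol(Y))) {
    p <- .nnls_solve(X, Y[, s])
    res[s] <- sqrt(sum((X %*% p - Y[, s])^2))
    if (sum(p) <= 0) {
      .warnf("sample %s: zero NNLS solution; falling back to uniform fractions",
             colnames(Y)[s])
      p <- rep(1 / k, k)
    }
    P[s, ] <- p / sum(p)
  }
  list(fractions = fraction_matrix(P), residuals = res, n_genes = length(genes))
}

#' Score estimated fractions against ground truth
#'
#' Per cell type, the Pearson correlation between estimated and true
#' fractions across samples (undefined when either vector is constant —
#' flagged and excluded from the mean, never zero-filled); globally, RMSE
#' over all (sample, cell type) entries.
#'
#' @param estimates,truth `FractionMatrix` objects over the same samples and
#'   cell types (any order).
#' @return list: `per_type` (data.frame `cell_type`, `pearson_r`, `defined`),
#'   `rmse`, `mean_r` (mean of defined per-type correlations).
#' @export
evaluate_deconvolution <- function(estimates, truth) {
  validate_fraction_matrix(estimates)
  validate_fraction_matrix(truth)
  if (!setequal(rownames(estimates$values), rownames(truth$values)))
    .stopf("sample sets differ between estimates and truth")
  if (!setequal(colnames(estimates$values), colnames(truth$values)))
    .stopf("cell-type sets differ between estimates and truth")
  e <- estimates$values[rownames(truth$values), colnames(truth$values), drop = FALSE]
  t_ <- truth$values
  per_type <- do.call(rbind, lapply(colnames(t_), function(ct) {
    defined <- nrow(e) >= 2L && sd(e[, ct]) > 0 && sd(t_[, ct]) > 0
    data.frame(cell_type = ct,
               pearson_r = if (defined) cor(e[, ct], t_[, ct]) else NA_real_,
               defined = defined)
  }))
  list(per_type = per_type,
       rmse = sqrt(mean((e - t_)^2)),
       mean_r = mean(per_type$pearson_r[per_type$defined]))
}

#' Match unlabeled (reference-free) estimates to truth cell types
#'
#' For each unlabeled estimate column, the Pearson correlation against every
#' truth column is computed and the column is assigned to the best-matching
#' truth type (many-to-one assignments are allowed; ties break by truth
#' cell-type name order with a warning). Constant estimate columns are
#' unassignable and excluded.
#'
#' @param estimates_unlabeled numeric sample x component matrix (components
#'   need no names) — or a `FractionMatrix` whose labels are ignored.
#' @param truth a `FractionMatrix` over the same samples.
#' @return list: `mapping` (data.frame `component`, `assigned`, `r`),
#'   `relabeled` (estimate matrix with assigned cell-type colnames, dropped
#'   undefined columns, rows aligned to truth).
#' @export
match_reference_free <- function(estimates_unlabeled, truth) {
  validate_fraction_matrix(truth)
  e <- if (is(estimates_unlabeled, "FractionMatrix")) estimates_unlabeled$values
       else estimates_unlabeled
  if (!setequal(rownames(e), rownames(truth$values)))
    .stopf("sample sets differ between estimates and truth")
  e <- e[rownames(truth$values), , drop = FALSE]
  tv <- truth$values
  comp_names <- if (is.null(colnames(e))) paste0("component", seq_len(ncol(e)))
                else colnames(e)
  rows <- list(); keep <- integer(0); labels <- character(0)
  for (j in seq_len(ncol(e))) {
    if (sd(e[, j]) == 0) {
      rows[[j]] <- data.frame(component = comp_names[j], assigned = NA_character_,
                              r = NA_real_)
      next
    }
    r <- vapply(colnames(tv), function(ct)
      if (sd(tv[, ct]) == 0) -Inf else cor(e[, j], tv[, ct]), numeric(1))
    best <- which(r == max(r))
    if (length(best) > 1L) {
      .warnf("component %s: correlation tie; assigned by cell-type name order",
             comp_names[j])
      best <- best[order(colnames(tv)[best])][1]
    }
    rows[[j]] <- data.frame(component = comp_names[j],
                            assigned = colnames(tv)[best], r = r[best])
    keep <- c(keep, j); labels <- c(labels, colnames(tv)[best])
  }
  mapping <- do.call(rbind, rows)
  dup <- unique(labels[duplicated(labels)])
  if (length(dup))
    .warnf("multiple components assigned to: %s", paste(dup, collapse = ", "))
  relabeled <- e[, keep, drop = FALSE]
  colnames(relabeled) <- labels
  list(mapping = mapping, relabeled = relabeled)
}

#' Linear effect model of methodological choices on performance
#'
#' Ordinary least squares on per-cell-type Pearson r:
#' `pearson_r ~ 1 + regression_choice + reference_choice + dataset * cell_type`
#' with treatment coding (baselines: `nnls` regression and `no_selection`
#' reference). Terms whose factor has a single level are dropped. Fitted
#' separately per simulation strategy when several are present.
#'
#' @param records data.frame of evaluation records with columns `pearson_r`,
#'   `regression_choice`, `reference_choice`, `dataset`, `cell_type` and
#'   optionally `strategy`.
#' @param conf_level confidence level for the coefficient intervals.
#' @return an `EffectModelFit` data.frame (`term`, `estimate`, `ci_low`,
#'   `ci_high`, and `strategy` when fitted per strategy).
#' @export
fit_effect_model <- function(records, conf_level = 0.95) {
  need <- c("pearson_r", "regression_choice", "reference_choice", "dataset", "cell_type")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    .stopf("records missing column(s): %s", paste(missing_cols, collapse = ", "))
  if ("strategy" %in% names(records) && length(unique(records$strategy)) > 1L) {
    fits <- lapply(split(records, records$strategy), fit_effect_model,
                   conf_level = conf_level)
    out <- do.call(rbind, Map(function(f, s) { f$strategy <- s; f }, fits, names(fits)))
    rownames(out) <- NULL
    return(structure(out, class = c("EffectModelFit", "data.frame")))
  }
  d <- records[!is.na(records$pearson_r), , drop = FALSE]
  relevel_if <- function(x, baseline) {
    f <- factor(x)
    if (baseline %in% levels(f)) stats::relevel(f, baseline) else f
  }
  d$regression_choice <- relevel_if(d$regression_choice, "nnls")
  d$reference_choice <- relevel_if(d$reference_choice, "no_selection")
  d$dataset <- factor(d$dataset)
  d$cell_type <- factor(d$cell_type)
  nlev <- vapply(d[c("regression_choice", "reference_choice", "dataset", "cell_type")],
                 nlevels, integer(1))
  if (all(nlev[c("regression_choice", "reference_choice")] < 2L))
    if (all(nlev < 2L)) {
      # intercept-only data
      m <- lm(pearson_r ~ 1, data = d)
      ci <- confint(m, level = conf_level)
      return(structure(data.frame(term = "(Intercept)", estimate = unname(coef(m)),
                                  ci_low = ci[1], ci_high = ci[2]),
                       class = c("EffectModelFit", "data.frame")))
    }
  terms <- c(
    if (nlev["regression_choice"] >= 2L) "regression_choice",
    if (nlev["reference_choice"] >= 2L) "reference_choice",
    if (nlev["dataset"] >= 2L && nlev["cell_type"] >= 2L) "dataset * cell_type"
    else c(if (nlev["dataset"] >= 2L) "dataset",
           if (nlev["cell_type"] >= 2L) "cell_type"))
  form <- as.formula(paste("pearson_r ~ 1 +", paste(terms, collapse = " + ")))
  m <- lm(form, data = d)
  cf <- stats::coef(m)
  if (anyNA(cf))
    .stopf("rank-deficient design; aliased term(s): %s",
           paste(names(cf)[is.na(cf)], collapse = ", "))
  ci <- confint(m, level = conf_level)
  structure(data.frame(term = names(cf), estimate = unname(cf),
                       ci_low = ci[, 1], ci_high = ci[, 2], row.names = NULL),
            class = c("EffectModelFit", "data.frame"))
}

# -- external deconvolver plugin contract ------------------------------------

.method_registry <- new.env(parent = emptyenv())

#' Register a deconvolution method
#'
#' A method is any R function `f(bulk, signature)` returning a
#' `FractionMatrix` over the bulk's samples. The built-in `"nnls"` method is
#' always available. [external_method_contract()] wraps a shell executable as
#' such a function.
#'
#' @param name method name used in benchmark grids.
#' @param fun function of `(bulk, signature)` returning a `FractionMatrix`.
#' @return `name`, invisibly.
#' @export
register_deconvolution_method <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .method_registry)
  invisible(name)
}

#' Look up a registered deconvolution method
#' @param name method name.
#' @return the method function.
#' @export
get_deconvolution_method <- function(name) {
  if (identical(name, "nnls"))
    return(function(bulk, signature) deconvolve_nnls(bulk, signature)$fractions)
  if (!exists(name, envir = .method_registry))
    .stopf("unknown deconvolution method: %s", name)
  get(name, envir = .method_registry)
}

#' List available deconvolution methods
#' @return character vector of method names.
#' @export
list_deconvolution_methods <- function() {
  sort(unique(c("nnls", ls(envir = .method_registry))))
}

#' Register an external command-line deconvolver
#'
#' The executable receives a gene x sample bulk TSV and a gene x cell-type
#' signature TSV and must write a sample x cell-type fraction TSV. The
#' command template uses placeholders `{bulk}`, `{signature}`, `{out}`.
#' Malformed or missing output is reported as a failed run (an object of
#' class `deconv_failure`), not an R error, so benchmark grids keep going.
#'
#' @param name method name to register.
#' @param command_template e.g. `"mytool --in {bulk} --sig {signature} --out {out}"`.
#' @return `name`, invisibly.
#' @export
external_method_contract <- function(name, command_template) {
  fun <- function(bulk, signature) {
    td <- tempfile(paste0("pseudomix_", name, "_"))
    dir.create(td)
    on.exit(unlink(td, recursive = TRUE), add = TRUE)
    paths <- list(bulk = file.path(td, "bulk.tsv"),
                  signature = file.path(td, "signature.tsv"),
                  out = file.path(td, "fractions.tsv"))
    write_bulk(bulk, paths$bulk)
    write_signature(signature, paths$signature)
    cmd <- command_template
    for (ph in names(paths))
      cmd <- gsub(paste0("{", ph, "}"), paths[[ph]], cmd, fixed = TRUE)
    status <- tryCatch(system(cmd), error = function(e) -1L)
    fail <- function(why) structure(list(method = name, reason = why),
                                    class = "deconv_failure")
    if (!identical(as.integer(status), 0L)) return(fail("non-zero exit status"))
    if (!file.exists(paths$out)) return(fail("no output file written"))
    est <- tryCatch(read_fractions(paths$out), error = function(e) conditionMessage(e))
    if (!is(est, "FractionMatrix")) return(fail(paste("malformed output:", est)))
    if (!setequal(rownames(est$values), colnames(bulk$expression)))
      return(fail("output sample ids do not match the bulk"))
    est
  }
  register_deconvolution_method(name, fun)
}
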