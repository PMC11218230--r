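# Ground-truth cell-type fraction simulation.
#
# The beta route mimics real per-patient composition: observed per-patient
# fractions -> per-cell-type beta fit (method of moments) -> independent draws
# rescaled to the simplex. The Dirichlet route is the conventional
# alternative, parameterized as alpha_k = base_freq_k / dispersion so that a
# larger dispersion gives a wider spread.

#' Observed per-patient cell-type fractions
#'
#' For each patient, the fraction of that patient's cells belonging to each
#' cell type; cell types absent in a patient get 0. These observed fractions
#' approximate the composition of real bulk samples.
#'
#' @param sc a `SingleCellDataset`.
#' @return a `FractionMatrix` (patients x cell types).
#' @export
observed_patient_fractions <- function(sc) {
  validate_single_cell_dataset(sc)
  tab <- table(sc$sample_id, sc$cell_type)
  m <- unclass(tab / rowSums(tab))
  m <- matrix(m, nrow = nrow(tab), dimnames = dimnames(tab))
  fraction_matrix(m)
}

#' Fit per-cell-type beta distributions to observed fractions
#'
#' Method-of-moments fit: with sample mean m and sample variance v,
#' `common = m(1-m)/v - 1`, `alpha = m * common`, `beta = (1-m) * common`.
#' Cell types with `v < 1e-8` or an infeasible moment pair (`common <= 0`)
#' fall back to a degenerate point mass at m.
#'
#' @param fractions a `FractionMatrix` of observed per-patient fractions.
#' @return object of class `BetaParams`: data.frame with columns `cell_type`,
#'   `alpha`, `beta`, `degenerate_value` (NA unless degenerate).
#' @export
fit_beta <- function(fractions) {
  validate_fraction_matrix(fractions)
  v <- fractions$values
  if (nrow(v) < 2L)
    .warnf("single patient: all cell types fitted as degenerate point masses")
  fits <- lapply(colnames(v), function(ct) {
    x <- v[, ct]
    m <- mean(x)
    s2 <- if (length(x) >= 2L) var(x) else 0
    common <- if (s2 > 0) m * (1 - m) / s2 - 1 else -Inf
    if (s2 < 1e-8 || common <= 0) {
      if (s2 >= 1e-8)
        .warnf("cell type %s: variance infeasible for a beta law; using point mass", ct)
      data.frame(cell_type = ct, alpha = NA_real_, beta = NA_real_,
                 degenerate_value = m)
    } else {
      data.frame(cell_type = ct, alpha = m * common, beta = (1 - m) * common,
                 degenerate_value = NA_real_)
    }
  })
  structure(do.call(rbind, fits), class = c("BetaParams", "data.frame"))
}

#' Simulate fractions from fitted beta distributions
#'
#' Per sample, draws one value per cell type from its beta law (or point
#' mass) and rescales the draws to sum to one. A sample whose draws are all
#' zero is redrawn (bounded retries).
#'
#' @param params a `BetaParams` object from [fit_beta()].
#' @param n_samples number of simulated samples.
#' @param seed RNG seed (reproducible output).
#' @return a `FractionMatrix` (`n_samples` x cell types).
#' @export
simulate_fractions_beta <- function(params, n_samples, seed = NULL) {
  stopifnot(is(params, "BetaParams"))
  if (!.is_count(n_samples)) .stopf("n_samples must be a positive integer")
  .with_seed(seed, {
    k <- nrow(params)
    draw_row <- function() {
      x <- vapply(seq_len(k), function(i) {
        if (!is.na(params$degenerate_value[i])) params$degenerate_value[i]
        else rbeta(1, params$alpha[i], params$beta[i])
      }, numeric(1))
      x
    }
    rows <- matrix(0, n_samples, k,
                   dimnames = list(paste0("sim", seq_len(n_samples)), params$cell_type))
    for (s in seq_len(n_samples)) {
      x <- draw_row()
      tries <- 0L
      while (sum(x) == 0 && tries < 100L) { x <- draw_row(); tries <- tries + 1L }
      if (sum(x) == 0) .stopf("all beta draws zero after 100 retries (sample %d)", s)
      rows[s, ] <- x / sum(x)
    }
    fraction_matrix(rows)
  })
}

#' Simulate fractions from a Dirichlet distribution
#'
#' Concentration convention: `alpha_k = base_freq_k / dispersion`, so a larger
#' dispersion yields a wider spread around `base_freqs`. Typical dispersion
#' levels explored in benchmarking: 0.001, 0.01, 0.05.
#'
#' @param base_freqs probability vector of expected cell-type abundances
#'   (named by cell type, or names supplied via `cell_types`).
#' @param dispersion positive scalar spread parameter.
#' @param n_samples number of simulated samples.
#' @param seed RNG seed.
#' @param cell_types optional cell-type names when `base_freqs` is unnamed.
#' @return a `FractionMatrix` (`n_samples` x cell types).
#' @export
simulate_fractions_dirichlet <- function(base_freqs, dispersion, n_samples,
                                         seed = NULL, cell_types = NULL) {
  if (!is.numeric(base_freqs) || any(base_freqs < 0) || abs(sum(base_freqs) - 1) > 1e-6)
    .stopf("base_freqs must be a probability vector summing to 1")
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion <= 0)
    .stopf("dispersion must be a positive scalar")
  if (!.is_count(n_samples)) .stopf("n_samples must be a positive integer")
  if (is.null(cell_types)) cell_types <- names(base_freqs)
  if (is.null(cell_types)) cell_types <- paste0("CT", seq_along(base_freqs))
  .with_seed(seed, {
    alpha <- base_freqs / dispersion
    k <- length(alpha)
    g <- matrix(rgamma(n_samples * k, shape = rep(alpha, each = n_samples), rate = 1),
                n_samples, k)
    m <- g / rowSums(g)
    dimnames(m) <- list(paste0("sim", seq_len(n_samples)), cell_types)
    fraction_matrix(m)
  })
}
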