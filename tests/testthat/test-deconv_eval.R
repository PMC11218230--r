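# NNLS deconvolution, evaluation metrics, reference-free matching,
# effect model, and the external-method plugin contract.

test_that("NNLS solves exact linear mixtures to machine precision", {
  X <- matrix(c(10, 0, 0, 10), 2, dimnames = list(c("g1", "g2"), c("A", "B")))
  y <- X %*% c(0.3, 0.7)
  b <- bulk_dataset(matrix(y, 2, dimnames = list(c("g1", "g2"), "s1")),
                    provenance = "external")
  out <- deconvolve_nnls(b, signature_matrix(X))
  expect_equal(out$fractions$values["s1", ], c(A = 0.3, B = 0.7), tolerance = 1e-9)
  expect_lt(out$residuals[["s1"]], 1e-9)
})

test_that("NNLS agrees with brute-force search over the 2-type simplex", {
  set.seed(191)
  for (i in 1:10) {
    X <- matrix(rlnorm(40 * 2, 3, 1), 40, 2,
                dimnames = list(paste0("g", 1:40), c("A", "B")))
    y <- X %*% runif(2, 0.1, 1) + rnorm(40, 0, 3)
    y <- pmax(as.numeric(y), 0)
    b <- bulk_dataset(matrix(y, 40, dimnames = list(rownames(X), "s1")),
                      provenance = "external")
    est <- deconvolve_nnls(b, signature_matrix(X))$fractions$values[1, ]
    # independent oracle: grid over scaled simplex directions
    grid <- seq(0, 1, by = 1e-3)
    sse <- vapply(grid, function(a) {
      d <- X %*% c(a, 1 - a)
      s <- sum(d * y) / sum(d * d)  # optimal scale for this direction
      sum((s * d - y)^2)
    }, numeric(1))
    best <- grid[which.min(sse)]
    expect_equal(unname(est["A"]), best, tolerance = 2e-3)
  }
})

test_that("NNLS estimates are simplex-valid for arbitrary inputs", {
  set.seed(192)
  X <- matrix(rlnorm(30 * 4, 2, 1), 30, 4,
              dimnames = list(paste0("g", 1:30), paste0("T", 1:4)))
  Y <- matrix(rlnorm(30 * 6, 2, 1.5), 30, 6,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  out <- deconvolve_nnls(bulk_dataset(Y, "external"), signature_matrix(X))
  expect_true(all(out$fractions$values >= 0))
  expect_true(all(abs(rowSums(out$fractions$values) - 1) < 1e-9))
  # duplicate (collinear) signature column draws a warning
  Xd <- cbind(X, T5 = X[, 1])
  expect_warning(deconvolve_nnls(bulk_dataset(Y, "external"),
                                 signature_matrix(Xd)), "collinear")
  expect_error(deconvolve_nnls(
    bulk_dataset(Y, "external"),
    signature_matrix(matrix(1:4, 2, dimnames = list(c("zz1", "zz2"),
                                                    c("A", "B"))))),
    "shared genes")
})

test_that("noiseless mixtures of signature columns are recovered exactly", {
  co <- mild_cohort()
  sig <- celltype_mean_profile(co$sc)
  set.seed(201)
  P <- t(vapply(1:8, function(i) { p <- rgamma(4, 2); p / sum(p) }, numeric(4)))
  dimnames(P) <- list(paste0("s", 1:8), colnames(sig$values))
  Y <- sig$values %*% t(P)
  out <- deconvolve_nnls(bulk_dataset(Y, "external"), sig)
  expect_equal(out$fractions$values, P, tolerance = 1e-6)
})

test_that("evaluation reproduces hand-computed RMSE and correlation behavior", {
  tr <- fraction_matrix(matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("A", "B"))))
  es <- fraction_matrix(matrix(c(0.6, 0.4), 1, dimnames = list("s1", c("A", "B"))))
  ev <- evaluate_deconvolution(es, tr)
  expect_equal(ev$rmse, 0.1)  # sqrt((0.01 + 0.01)/2)
  expect_true(all(!ev$per_type$defined))  # single sample: r undefined

  set.seed(211)
  v <- t(vapply(1:10, function(i) { p <- runif(2); p / sum(p) }, numeric(2)))
  dimnames(v) <- list(paste0("s", 1:10), c("A", "B"))
  truth <- fraction_matrix(v)
  ident <- evaluate_deconvolution(truth, truth)
  expect_equal(ident$mean_r, 1)
  expect_equal(ident$rmse, 0)

  # constant offset on one type: r stays 1, RMSE grows
  shifted <- v; shifted[, "A"] <- shifted[, "A"] * 0.8
  shifted <- sweep(shifted, 1, rowSums(shifted), "/")
  ev2 <- evaluate_deconvolution(fraction_matrix(shifted), truth)
  expect_gt(ev2$rmse, 0)

  # invariance to simultaneous sample permutation
  perm <- sample(rownames(v))
  ev3 <- evaluate_deconvolution(
    fraction_matrix(v[perm, ]), fraction_matrix(v[perm, ]))
  expect_equal(ev3$mean_r, ident$mean_r)
  expect_error(evaluate_deconvolution(
    truth, fraction_matrix(matrix(c(1, 1), 2, 1,
                                  dimnames = list(c("x1", "x2"), "A")))),
    "sample sets")
})

test_that("reference-free matching recovers a planted column permutation", {
  set.seed(221)
  v <- t(vapply(1:20, function(i) { p <- rgamma(4, 2); p / sum(p) }, numeric(4)))
  dimnames(v) <- list(paste0("s", 1:20), c("A", "B", "C", "D"))
  truth <- fraction_matrix(v)
  perm <- c(3, 1, 4, 2)
  unlabeled <- v[, perm]
  colnames(unlabeled) <- NULL
  out <- match_reference_free(unlabeled, truth)
  expect_equal(out$mapping$assigned, colnames(v)[perm])
  expect_equal(unname(out$relabeled), unname(unlabeled))

  # exact-copy column maps to its source
  one <- v[, "B", drop = FALSE]; colnames(one) <- NULL
  expect_equal(match_reference_free(one, truth)$mapping$assigned, "B")

  # two components both best-matching one type: many-to-one with warning
  two <- cbind(v[, "A"] + rnorm(20, 0, 0.01), v[, "A"] + rnorm(20, 0, 0.01))
  expect_warning(m2 <- match_reference_free(two, truth), "multiple components")
  expect_equal(m2$mapping$assigned, c("A", "A"))

  # constant column excluded
  const <- cbind(rep(0.5, 20), v[, "C"])
  rownames(const) <- rownames(v)
  m3 <- match_reference_free(const, truth)
  expect_true(is.na(m3$mapping$assigned[1]))
  expect_equal(ncol(m3$relabeled), 1)
})

test_that("effect model recovers a planted uniform method effect", {
  gen_records <- function(seed) {
    set.seed(seed)
    grid <- expand.grid(dataset = c("d1", "d2"), cell_type = paste0("ct", 1:4),
                        regression_choice = c("nnls", "alt"),
                        reference_choice = c("no_selection", "markers"),
                        repeat_idx = 1:5, stringsAsFactors = FALSE)
    base <- ave(rnorm(nrow(grid), 0.7, 0.05),
                paste(grid$dataset, grid$cell_type), FUN = function(x) x[1])
    grid$pearson_r <- base + 0.1 * (grid$regression_choice == "alt") +
      rnorm(nrow(grid), 0, 0.05)
    grid
  }
  fit <- fit_effect_model(gen_records(1))
  est <- fit$estimate[fit$term == "regression_choicealt"]
  expect_equal(est, 0.1, tolerance = 0.05)
  expect_true(fit$ci_low[fit$term == "regression_choicealt"] <= est &&
                est <= fit$ci_high[fit$term == "regression_choicealt"])

  # intercept-only data
  d0 <- gen_records(2)
  d0$regression_choice <- "nnls"; d0$reference_choice <- "no_selection"
  d0$dataset <- "d1"; d0$cell_type <- "ct1"
  f0 <- fit_effect_model(d0)
  expect_equal(nrow(f0), 1)
  expect_equal(f0$estimate, mean(d0$pearson_r))

  # single-level factor terms are dropped, not aliased
  d1 <- gen_records(3)
  d1$reference_choice <- "no_selection"
  f1 <- fit_effect_model(d1)
  expect_false(any(grepl("reference_choice", f1$term)))
})

test_that("per-strategy fitting splits records as the benchmark requires", {
  d <- expand.grid(dataset = "d1", cell_type = paste0("ct", 1:3),
                   regression_choice = c("nnls", "alt"),
                   reference_choice = "no_selection",
                   strategy = c("homogeneous", "heterogeneous"),
                   repeat_idx = 1:4, stringsAsFactors = FALSE)
  set.seed(231)
  d$pearson_r <- 0.8 + 0.05 * (d$regression_choice == "alt") -
    0.3 * (d$strategy == "heterogeneous") + rnorm(nrow(d), 0, 0.02)
  f <- fit_effect_model(d)
  expect_setequal(unique(f$strategy), c("homogeneous", "heterogeneous"))
  expect_true(all(f$ci_low <= f$estimate & f$estimate <= f$ci_high))
})

test_that("the external method contract wraps executables and tolerates failure", {
  sim_truth <- fraction_matrix(matrix(c(0.4, 0.6, 0.2, 0.8), 2, byrow = TRUE,
                                      dimnames = list(c("s1", "s2"), c("A", "B"))))
  X <- matrix(c(100, 5, 5, 100), 2, dimnames = list(c("g1", "g2"), c("A", "B")))
  Y <- X %*% t(sim_truth$values)
  bulk <- bulk_dataset(Y, "external")
  sig <- signature_matrix(X)

  # a stub that echoes the truth fractions scores perfectly
  td <- withr::local_tempdir()
  truth_path <- file.path(td, "truth.tsv")
  write_fractions(sim_truth, truth_path)
  external_method_contract("echo_truth", paste("cp", truth_path, "{out}"))
  est <- get_deconvolution_method("echo_truth")(bulk, sig)
  expect_s3_class(est, "FractionMatrix")
  expect_equal(evaluate_deconvolution(est, sim_truth)$rmse, 0)

  # a stub with wrong sample ids becomes a failed-run record
  bad <- fraction_matrix(matrix(c(1, 1), 2, 1,
                                dimnames = list(c("x1", "x2"), "A")))
  bad_path <- file.path(td, "bad.tsv")
  write_fractions(bad, bad_path)
  external_method_contract("echo_bad", paste("cp", bad_path, "{out}"))
  fail <- get_deconvolution_method("echo_bad")(bulk, sig)
  expect_s3_class(fail, "deconv_failure")

  # a command that never writes output fails cleanly too
  external_method_contract("no_output", "true")
  expect_s3_class(get_deconvolution_method("no_output")(bulk, sig),
                  "deconv_failure")

  # the built-in exposed through the same contract matches the direct call
  expect_equal(get_deconvolution_method("nnls")(bulk, sig)$values,
               deconvolve_nnls(bulk, sig)$fractions$values)
  expect_true(all(c("nnls", "echo_truth") %in% list_deconvolution_methods()))
  expect_error(get_deconvolution_method("nonexistent"), "unknown")
})
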