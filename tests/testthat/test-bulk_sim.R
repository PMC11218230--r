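# The four bulk simulation strategies and their supporting operations.

test_that("baseline pseudobulk is the per-patient mean CPM profile", {
  sc <- toy_sc("cpm")
  bp <- baseline_pseudobulk(sc)
  expect_identical(bp$provenance, "baseline")
  expect_equal(bp$expression[, "p1"],
               rowMeans(sc$expression[, sc$sample_id == "p1"]))
  expect_true(all(abs(colSums(bp$expression) - 1e6) < 1e-6))

  # two identical cells -> bulk equals that common profile
  m <- matrix(c(1e6, 0, 0, 1e6, 1e6, 0), 3, 2,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  m[, 2] <- m[, 1]
  sc2 <- single_cell_dataset(m, c("A", "A"), c("p1", "p1"), scale = "cpm")
  expect_equal(baseline_pseudobulk(sc2)$expression[, "p1"], m[, 1])

  # opposite one-gene cells average to half/half
  m2 <- matrix(c(1e6, 0, 0, 1e6), 2, 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2")))
  sc3 <- single_cell_dataset(m2, c("A", "A"), c("p1", "p1"), scale = "cpm")
  expect_equal(unname(baseline_pseudobulk(sc3)$expression[, 1]), c(5e5, 5e5))
})

test_that("largest-remainder apportionment matches the hand-derived oracle", {
  expect_equal(largest_remainder(10, c(A = 0.26, B = 0.74)), c(A = 3L, B = 7L))
  expect_equal(sum(largest_remainder(7, c(x = 1, y = 1, z = 1))), 7L)
  # tie on remainders resolved by name order
  expect_equal(largest_remainder(1, c(b = 0.5, a = 0.5)), c(b = 0L, a = 1L))
  # exhaustive conservation property
  set.seed(61)
  for (i in 1:20) {
    f <- runif(4); n <- sample(1:200, 1)
    expect_equal(sum(largest_remainder(n, setNames(f, paste0("t", 1:4)))), n)
  }
})

test_that("patient profiles subsample 50-100% of the pool and sum to 1e6", {
  co <- default_cohort()
  set.seed(71)
  ratios <- replicate(200, {
    p <- build_patient_profile(co$sc, "CT2", "patient01")
    expect_equal(sum(p$profile), 1e6, tolerance = 1e-9)
    p$n_selected / p$n_pool
  })
  expect_true(all(ratios >= 0.5 - 1e-9 & ratios <= 1))
})

test_that("profiles pool extra patients only below the cell threshold", {
  sc <- toy_sc("cpm")  # 2 cells per (patient, type)
  set.seed(72)
  # threshold above patient's own count: pool grows to >= threshold
  p <- build_patient_profile(sc, "A", "p1", profile_spec(threshold = 3))
  expect_gte(p$n_pool, 3)
  # threshold met by the patient alone: pool is exactly the patient's cells
  p2 <- build_patient_profile(sc, "A", "p1", profile_spec(threshold = 2))
  expect_equal(p2$n_pool, 2)
  # forcing u = 1 via a degenerate range uses the whole pool
  p3 <- build_patient_profile(sc, "A", "p1",
                              profile_spec(1, 1, threshold = 2))
  expect_equal(p3$n_selected, 2)
  expect_equal(p3$profile, rowMeans(sc$expression[, c(1, 3)]))
  expect_error(build_patient_profile(sc, "nosuch", "p1"), "no cells")
})

test_that("homogeneous simulation realizes apportioned counts and conserves CPM", {
  co <- default_cohort()
  f <- matrix(c(0.26, 0.74, 0, 0), 1,
              dimnames = list("s1", c("Malignant", "CT2", "CT3", "CT4")))
  out <- simulate_bulk_homogeneous(co$sc, fraction_matrix(f),
                                   profile_spec(n_cells = 10), seed = 81)
  expect_equal(out$fractions$values["s1", ],
               c(Malignant = 0.3, CT2 = 0.7, CT3 = 0, CT4 = 0))
  expect_colsums_cpm(out$bulk)

  # single type: realized fraction is exactly 1
  f1 <- matrix(c(1, 0, 0, 0), 1,
               dimnames = list("s1", c("Malignant", "CT2", "CT3", "CT4")))
  out1 <- simulate_bulk_homogeneous(co$sc, fraction_matrix(f1),
                                    profile_spec(n_cells = 10), seed = 82)
  expect_equal(out1$fractions$values[1, "Malignant"], 1)

  # n_cells below the number of represented types cannot be apportioned
  f2 <- matrix(rep(0.25, 4), 1,
               dimnames = list("s1", c("Malignant", "CT2", "CT3", "CT4")))
  expect_error(simulate_bulk_homogeneous(co$sc, fraction_matrix(f2),
                                         profile_spec(n_cells = 3), seed = 1),
               "cannot represent")
})

test_that("heterogeneous simulation draws each component from one patient", {
  sc <- toy_sc("cpm")
  # one type, one patient, u forced to 1: equals that patient's type-A mean
  scA <- single_cell_dataset(sc$expression[, sc$sample_id == "p1" &
                                             sc$cell_type == "A"],
                             rep("A", 2), rep("p1", 2), scale = "cpm")
  scA$cell_type <- c("A", "A")
  f <- matrix(1, 1, dimnames = list("s1", "A"))
  # need >= 1 cell type... single-type fractions are legal for simulation
  b <- simulate_bulk_heterogeneous(scA, fraction_matrix(f),
                                   profile_spec(1, 1, threshold = 2), seed = 91)
  expect_equal(b$expression[, "s1"], rowMeans(scA$expression))
  expect_identical(b$provenance, "heterogeneous")

  # f = (1, 0): the zero type contributes nothing
  f2 <- matrix(c(1, 0), 1, dimnames = list("s1", c("A", "B")))
  b2 <- simulate_bulk_heterogeneous(toy_sc("cpm"), fraction_matrix(f2),
                                    profile_spec(1, 1, threshold = 2), seed = 92)
  pa <- rowMeans(sc$expression[, sc$cell_type == "A" & sc$sample_id == "p1"])
  pb <- rowMeans(sc$expression[, sc$cell_type == "A" & sc$sample_id == "p2"])
  expect_true(isTRUE(all.equal(b2$expression[, 1], pa)) ||
                isTRUE(all.equal(b2$expression[, 1], pb)))

  expect_error(
    simulate_bulk_heterogeneous(sc, fraction_matrix(
      matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("A", "ghost")))),
      profile_spec(), seed = 1),
    "ghost")
})

test_that("all four strategies conserve the 1e6 library size (seeded grid)", {
  co <- default_cohort()
  spec <- profile_spec(malignant_label = "Malignant")
  fr <- simulate_fractions_beta(fit_beta(observed_patient_fractions(co$sc)),
                                8, seed = 101)
  homo <- simulate_bulk_homogeneous(co$sc, fr, spec, seed = 102)$bulk
  semi <- simulate_bulk_semiheterogeneous(co$sc, fr, spec, seed = 103)
  heter <- simulate_bulk_heterogeneous(co$sc, fr, spec, seed = 104)
  free <- simulate_bulk_heterogeneous_sampleIDfree(co$sc, fr, spec, seed = 105)
  for (b in list(homo, semi, heter, free)) expect_colsums_cpm(b)
  expect_identical(semi$provenance, "semi_heterogeneous")
  expect_identical(free$provenance, "heterogeneous_sampleIDfree")
})

test_that("semi-heterogeneous degenerates correctly at extreme malignant fractions", {
  co <- default_cohort()
  spec <- profile_spec(malignant_label = "Malignant")
  cts <- c("Malignant", "CT2", "CT3", "CT4")
  f_mal1 <- matrix(c(1, 0, 0, 0), 1, dimnames = list("s1", cts))
  b <- simulate_bulk_semiheterogeneous(co$sc, fraction_matrix(f_mal1), spec,
                                       seed = 111)
  expect_colsums_cpm(b)
  f_mal0 <- matrix(c(0, 0.5, 0.3, 0.2), 1, dimnames = list("s1", cts))
  b0 <- simulate_bulk_semiheterogeneous(co$sc, fraction_matrix(f_mal0), spec,
                                        seed = 112)
  expect_colsums_cpm(b0)
  expect_error(simulate_bulk_semiheterogeneous(co$sc, fraction_matrix(f_mal0),
                                               profile_spec(), seed = 1),
               "malignant_label")
})

test_that("subclustering recovers well-separated blobs and respects min_size", {
  # two Gaussian blobs of 50 cells, one cell type — oracle = generating labels
  set.seed(121)
  g <- 40
  blob <- function(center, n) {
    m <- matrix(rnorm(g * n, center, 0.25), g, n)
    pmax(m, 0)
  }
  centers <- c(rep(0, g / 2), rep(6, g / 2))
  centers2 <- rev(centers)
  m <- cbind(blob(centers, 50), blob(centers2, 50))
  m <- sweep(m, 2, colSums(m) / 1e6, "/")
  dimnames(m) <- list(paste0("g", 1:g), paste0("c", 1:100))
  sc <- single_cell_dataset(m, rep("T", 100), rep("p1", 100), scale = "cpm")
  out <- subcluster_cells(sc, min_size = 10, seed = 122)
  truth <- rep(1:2, each = 50)
  tab <- table(out$subcluster, truth)
  purity <- sum(apply(tab, 1, max)) / 100
  expect_gte(purity, 0.95)
  expect_true(all(table(out$subcluster) >= 10))

  # a 12-cell type is a single subcluster
  co <- default_cohort()
  small <- single_cell_dataset(co$sc$expression[, 1:12],
                               rep("X", 12), rep("p1", 12), scale = "cpm")
  small$expression <- sweep(small$expression, 2,
                            colSums(small$expression) / 1e6, "/")
  out2 <- subcluster_cells(small, min_size = 10, seed = 123)
  expect_equal(unique(out2$subcluster), "X.1")
})

test_that("subcluster sizes across the cohort never fall below min_size", {
  co <- default_cohort()
  scc <- cached_fixture("subclustered_cohort",
                        subcluster_cells(co$sc, min_size = 10, seed = 124))
  expect_true(all(table(scc$subcluster) >= 10))
})

test_that("sample-ID-free heterogeneous simulation is seed-deterministic", {
  co <- default_cohort()
  scc <- cached_fixture("subclustered_cohort",
                        subcluster_cells(co$sc, min_size = 10, seed = 124))
  fr <- simulate_fractions_beta(fit_beta(observed_patient_fractions(co$sc)),
                                5, seed = 131)
  a <- simulate_bulk_heterogeneous_sampleIDfree(scc, fr, profile_spec(), seed = 132)
  b <- simulate_bulk_heterogeneous_sampleIDfree(scc, fr, profile_spec(), seed = 132)
  c_ <- simulate_bulk_heterogeneous_sampleIDfree(scc, fr, profile_spec(), seed = 133)
  expect_identical(a$expression, b$expression)
  expect_false(identical(a$expression, c_$expression))
})

test_that("heterogeneity ordering holds: CV heter > semi > homo, correlation reversed", {
  sim <- acceptance_sim()
  cvs <- lapply(list(homo = sim$homo, semi = sim$semi, heter = sim$heter),
                function(b) { cv <- gene_cv(b); cv$cv[cv$defined] })
  one_sided <- function(a, b)  # H1: mean(a) > mean(b), paired by gene
    t.test(a, b, paired = TRUE, alternative = "greater")$p.value
  expect_lt(one_sided(cvs$heter, cvs$semi), 0.01)
  expect_lt(one_sided(cvs$semi, cvs$homo), 0.01)

  panel <- top_variable_genes(baseline_pseudobulk(sim$sc), 300)
  cors <- lapply(list(homo = sim$homo, semi = sim$semi, heter = sim$heter),
                 sample_correlation_distribution, genes = panel)
  gt <- function(a, b) t.test(a, b, alternative = "greater")$p.value
  expect_lt(gt(cors$homo, cors$semi), 0.01)
  expect_lt(gt(cors$semi, cors$heter), 0.01)
})

test_that("with no patient effects the strategies' variance gap collapses", {
  co0 <- generate_cohort(synth_config(patient_effect_sd = 0), seed = 141)
  sc0 <- cpm_normalize(co0$sc)
  spec <- profile_spec(malignant_label = "Malignant")
  fr <- simulate_fractions_beta(fit_beta(observed_patient_fractions(sc0)),
                                60, seed = 142)
  mean_cv <- function(b) { cv <- gene_cv(b); mean(cv$cv[cv$defined]) }
  gap0 <- mean_cv(simulate_bulk_heterogeneous(sc0, fr, spec, seed = 143)) -
    mean_cv(simulate_bulk_homogeneous(sc0, fr, spec, seed = 144)$bulk)
  sim <- acceptance_sim()
  gap_full <- local({
    a <- gene_cv(sim$heter); b <- gene_cv(sim$homo)
    mean(a$cv[a$defined]) - mean(b$cv[b$defined])
  })
  # residual finite-cell sampling gap is small next to the patient-effect gap
  expect_lt(abs(gap0), 0.25 * gap_full)
})
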