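test_that("significance: centered, empirical count and extreme-tail cases", {
  null <- structure(
    list(samples = matrix(c(2, 2, 2, 4), ncol = 1,
                          dimnames = list(NULL, "minimum")),
         mu = c(minimum = 2.5), sigma = c(minimum = 1),
         n_reps = 4L, metric = "minimum", seed = NULL),
    class = "null_model")
  s <- significance(1, null)
  expect_equal(s$empirical_p, 1 / 5)  # (0 + 1) / (4 + 1)

  null$mu <- c(minimum = 2)
  s0 <- significance(2, null)
  expect_equal(s0$z, 0)
  expect_equal(s0$p_value, 0.5)

  g <- generate_interactome(100, 2, seed = 1)
  bins <- build_degree_bins(g, 20)
  set.seed(2)
  s_set <- sample(igraph::V(g)$name, 8)
  t_set <- sample(setdiff(igraph::V(g)$name, s_set), 5)
  big_null <- build_null(g, t_set, s_set, "minimum", n_reps = 200,
                         bins = bins, seed = 11)
  far <- significance(min(big_null$samples) - 10, big_null)
  expect_lt(far$p_value, 0.001)
  expect_equal(far$empirical_p, 1 / 201)
})

test_that("zero-variance nulls fall back to the empirical p and are flagged", {
  null <- structure(
    list(samples = matrix(c(3, 3, 3), ncol = 1, dimnames = list(NULL, "mean")),
         mu = c(mean = 3), sigma = c(mean = 0),
         n_reps = 3L, metric = "mean", seed = NULL),
    class = "null_model")
  s <- significance(3, null)
  expect_true(s$degenerate)
  expect_true(is.na(s$z))
  expect_equal(s$p_value, s$empirical_p)
})

test_that("null model is deterministic under a fixed seed and mu/sigma recompute", {
  g <- generate_interactome(150, 2, seed = 5)
  bins <- build_degree_bins(g, 30)
  set.seed(9)
  t_set <- sample(igraph::V(g)$name, 4)
  s_set <- sample(igraph::V(g)$name, 8)
  n1 <- build_null(g, t_set, s_set, "minimum", n_reps = 25, bins = bins, seed = 3)
  n2 <- build_null(g, t_set, s_set, "minimum", n_reps = 25, bins = bins, seed = 3)
  n3 <- build_null(g, t_set, s_set, "minimum", n_reps = 25, bins = bins, seed = 4)
  expect_identical(n1$samples, n2$samples)
  expect_false(identical(n1$samples, n3$samples))
  expect_equal(n1$mu[["minimum"]], mean(n1$samples[, "minimum"]))
  expect_equal(n1$sigma[["minimum"]], sd(n1$samples[, "minimum"]))
})

test_that("singleton bins force the one-rep null sample onto the observed value", {
  # threshold graph: degrees a=3, b=2, c=2, d=1; with min_bin_size = 1 the
  # bins are {d}, {b,c}, {a}, so modules built from a and d only can never be
  # displaced by the sampler
  g <- as_interactome(data.frame(from = c("a", "a", "a", "b"),
                                 to = c("b", "c", "d", "c")))
  bins <- build_degree_bins(g, 1)
  expect_equal(lengths(bins$bins), c(1L, 2L, 1L))
  t_set <- c("a", "d")
  s_set <- c("a", "d")
  obs <- proximity(g, t_set, s_set, "minimum")
  null <- build_null(g, t_set, s_set, "minimum", n_reps = 1, bins = bins, seed = 1)
  expect_equal(unname(null$samples[1, 1]), obs$proximity)
})

test_that("screen returns sorted records, honours alpha, and logs skips", {
  g <- generate_interactome(120, 2, seed = 7)
  nodes <- igraph::V(g)$name
  set.seed(13)
  disease <- sample(nodes, 10)
  drugs <- list(
    drug_a = sample(nodes, 4),
    drug_b = sample(nodes, 3),
    drug_single = sample(nodes, 1),      # fails min_targets
    drug_foreign = c("nope1", "nope2")   # unmappable
  )
  res <- screen(g, drugs, disease, metrics = c("minimum", "mean"),
                n_reps = 30, alpha = 0.05, seed = 5, min_bin_size = 20)
  expect_s3_class(res, "proximity_screen")
  expect_equal(nrow(res), 4)  # 2 drugs x 2 metrics
  expect_setequal(unique(res$drug), c("drug_a", "drug_b"))
  expect_setequal(skip_log(res)$drug, c("drug_single", "drug_foreign"))
  expect_equal(res$significant, res$p_value <= 0.05)
  # sorted by (metric, p_value, drug) with metrics in requested order
  expect_equal(res$metric, rep(c("minimum", "mean"), each = 2))
  for (m in c("minimum", "mean")) {
    expect_false(is.unsorted(res$p_value[res$metric == m]))
  }
})

test_that("screen is deterministic under a fixed seed", {
  g <- generate_interactome(100, 2, seed = 2)
  nodes <- igraph::V(g)$name
  set.seed(21)
  disease <- sample(nodes, 8)
  drugs <- list(d1 = sample(nodes, 3), d2 = sample(nodes, 4))
  r1 <- screen(g, drugs, disease, metrics = "minimum", n_reps = 20, seed = 99,
               min_bin_size = 20)
  r2 <- screen(g, drugs, disease, metrics = "minimum", n_reps = 20, seed = 99,
               min_bin_size = 20)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("an empty drug list yields an empty screen and a skip log", {
  g <- generate_interactome(100, 2, seed = 2)
  set.seed(1)
  disease <- sample(igraph::V(g)$name, 6)
  res <- screen(g, list(bad = c("zz1", "zz2")), disease, metrics = "minimum",
                n_reps = 5, seed = 1, min_bin_size = 20)
  expect_equal(nrow(res), 0)
  expect_equal(nrow(skip_log(res)), 1)
})

test_that("a drug equal to the disease module screens as significant", {
  g <- generate_interactome(120, 2, seed = 31)
  set.seed(17)
  disease <- sample(igraph::V(g)$name, 10)
  res <- screen(g, list(self = disease), disease, metrics = "minimum",
                n_reps = 100, seed = 4, min_bin_size = 30,
                fix_disease = TRUE)
  expect_equal(res$observed, 0)
  expect_true(res$significant)
})

test_that("z-based and empirical p-values agree in ordering", {
  g <- generate_interactome(200, 2, seed = 12)
  nodes <- igraph::V(g)$name
  set.seed(6)
  disease <- sample(nodes, 12)
  drugs <- lapply(1:25, function(i) sample(nodes, 5))
  names(drugs) <- sprintf("d%02d", 1:25)
  res <- screen(g, drugs, disease, metrics = "minimum", n_reps = 60,
                seed = 8, min_bin_size = 40)
  rho <- cor(res$p_value, res$empirical_p, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("known-indication annotation computes per-metric percentages", {
  records <- tibble::tibble(
    drug = c("a", "b", "c", "d"),
    metric = "minimum",
    significant = c(TRUE, TRUE, TRUE, FALSE)
  )
  ann <- annotate_known_indications(records,
                                    data.frame(drug = c("a", "b"),
                                               indication = "x"))
  expect_equal(ann$has_known_indication, c(TRUE, TRUE, FALSE, FALSE))
  s <- indication_summary(ann)
  expect_equal(s$pct_with_indication, 100 * 2 / 3, tolerance = 1e-12)

  none <- tibble::tibble(drug = "a", metric = "minimum", significant = FALSE)
  s0 <- indication_summary(
    annotate_known_indications(none, data.frame(drug = "a", indication = "x")))
  expect_true(is.na(s0$pct_with_indication))

  expect_warning(
    annotate_known_indications(records,
                               data.frame(drug = "ghost", indication = "x")),
    "ghost")
})
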