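test_that("to_log2_rpm follows the stated formula", {
  m <- matrix(c(10, 0, 4, 8), 2, 2,
              dimnames = list(c("r1", "r2"), c("s1", "s2")))
  out <- to_log2_rpm(m, c(s1 = 2e6, s2 = 1e6), pseudocount = 1)
  expect_equal(out["r1", "s1"], log2(10 * 1e6 / 2e6 + 1))  # log2(6)
  expect_equal(out["r2", "s1"], 0)                          # zero count
  expect_equal(out["r1", "s2"], log2(4 + 1))
  # cell-by-cell recomputation on a random fixture
  set.seed(41)
  counts <- matrix(rpois(30, 40), 5, 6)
  libs <- runif(6, 1e5, 1e6)
  got <- to_log2_rpm(counts, libs, 0.5)
  for (j in 1:6) expect_equal(got[, j], log2(counts[, j] * 1e6 / libs[j] + 0.5))
  expect_error(to_log2_rpm(counts, c(libs[-6], 0)), "positive")
  expect_error(to_log2_rpm(matrix(-1)), "non-negative")
})

test_that("quantile normalization matches the rank-mean definition", {
  # hand-computed 3x2 example
  x <- cbind(c(1, 2, 3), c(4, 5, 6))
  qn <- quantile_normalize(x)
  expect_equal(qn[, 1], c(2.5, 3.5, 4.5))
  expect_equal(qn[, 2], c(2.5, 3.5, 4.5))
  # identical columns are a fixed point
  y <- cbind(c(3, 1, 2), c(3, 1, 2))
  expect_equal(quantile_normalize(y), y)
  # defining property: identical column distributions afterwards
  set.seed(42)
  z <- matrix(rnorm(200), 20, 10)
  qz <- quantile_normalize(z)
  sorted <- apply(qz, 2, sort)
  for (j in 2:10) expect_equal(sorted[, j], sorted[, 1])
  # tie-free random input equals the rank bookkeeping oracle
  expect_equal(unname(qz), unname(oracle_quantile_normalize(z)))
  # ties receive the mean of the tied reference values
  t1 <- cbind(c(1, 1, 5), c(2, 4, 6))
  ref <- rowMeans(apply(t1, 2, sort))
  expect_equal(quantile_normalize(t1)[, 1],
               c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
  # equivariance: permuting samples permutes columns identically
  perm <- c(3, 1, 2, 10, 4:9)
  expect_equal(quantile_normalize(z[, perm]), qz[, perm])
  expect_error(quantile_normalize(cbind(c(1, NA))), "complete")
})

test_that("filter_samples keeps strictly-above-median totals", {
  x <- rbind(c(10, 20, 30, 40))
  expect_equal(colnames(filter_samples(
    matrix(x, 1, 4, dimnames = list("r", paste0("s", 1:4))))),
    c("s3", "s4"))
  # even count of distinct totals -> exactly half retained
  set.seed(43)
  m <- matrix(runif(20 * 8), 20, 8)
  expect_equal(ncol(filter_samples(m)), 4)
  expect_warning(out <- filter_samples(matrix(1, 3, 5)), "equal")
  expect_equal(ncol(out), 5)
  expect_error(filter_samples(matrix(1, 2, 1)), "two samples")
})

test_that("filter_variable uses type-7 quartiles with a strict threshold", {
  m <- rbind(const = c(1, 1, 1, 1), step = c(0, 0, 1, 1))
  expect_equal(rownames(filter_variable(m, 0.5)), "step")  # IQR 1 > 0.5
  expect_equal(nrow(filter_variable(rbind(c(1, 1, 1, 1)), 0)), 0) # IQR 0
  # tightening the threshold never enlarges the retained set
  set.seed(44)
  z <- matrix(rnorm(400, sd = rep(c(0.1, 1), each = 20)), 40, 10,
              dimnames = list(paste0("r", 1:40), NULL))
  soft <- rownames(filter_variable(z, 0.2))
  hard <- rownames(filter_variable(z, 0.8))
  expect_true(all(hard %in% soft))
  expect_error(filter_variable(matrix(1, 2, 3)), "four samples")
})

test_that("bh_adjust equals the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(45)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  }
})

test_that("the row-wise Wilcoxon p matches stats::wilcox.test", {
  set.seed(46)
  for (i in 1:20) {
    x <- round(rnorm(12), 1)   # rounding forces ties
    y <- round(rnorm(15, 0.5), 1)
    expect_equal(circorf:::wilcox_p_normal(x, y),
                 suppressWarnings(stats::wilcox.test(
                   x, y, exact = FALSE, correct = FALSE))$p.value)
  }
})

test_that("differential_expression separates noiseless planted effects", {
  sim <- simulate_de_matrix(n_de = 10, n_null = 10, n_per_group = 10,
                            de_effect = 2, noise_sd = 0, seed = 5)
  de <- differential_expression(sim$matrix, sim$groups)
  planted <- sim$truth$id[sim$truth$de_status != "null"]
  expect_setequal(de$id[de$significant], planted)
  expect_equal(abs(de$log2fc[match(planted, de$id)]), rep(2, 10))
  expect_true(all(abs(de$log2fc[!de$id %in% planted]) < 1e-12))
  expect_error(differential_expression(sim$matrix[, 1:11],
                                       sim$groups[1:11]),
               "two samples")
})

test_that("volcano_table mirrors the DE three-way classification", {
  de <- data.frame(id = c("a", "b", "c"), log2fc = c(2, 0.2, 1.5),
                   p = c(0.001, 0.001, 0.2), p_adj = c(0.01, 0.01, 0.4),
                   significant = c(TRUE, FALSE, FALSE))
  v <- volcano_table(de)
  expect_equal(v$class, c("significant", "low_lfc", "not_significant"))
  expect_equal(sum(v$class == "significant"), sum(de$significant))
  expect_equal(v$neg_log10_padj[1], 2)
})
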