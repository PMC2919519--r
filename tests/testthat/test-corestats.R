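test_that("pearson_correlation matches the direct formula and handles degeneracy", {
  expect_equal(pearson_correlation(paired_replicates(c(1, 3, 2), c(1, 3, 2))), 1)
  # hand evaluation of the sample correlation formula for (1,2,3,4),(1,2,3,5):
  # sum of cross-deviations 6.5, squared deviations 5 and 8.75
  expect_equal(
    pearson_correlation(paired_replicates(c(1, 2, 3, 4), c(1, 2, 3, 5))),
    6.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_error(pearson_correlation(paired_replicates(c(2, 2, 2), c(1, 2, 3))),
               class = "quantcorr_undefined_correlation")
  expect_error(paired_replicates(c(1, NA), c(1, 2)),
               class = "quantcorr_data_error")
})

test_that("spearman_correlation is rank-based with average-rank ties", {
  x <- c(0.2, 1.5, 3.1, 7.9, 8)
  expect_equal(spearman_correlation(paired_replicates(x, exp(x))), 1)
  # tie-free inputs: equals Pearson applied to the rank vectors
  set.seed(3)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(
    spearman_correlation(paired_replicates(a, b)),
    pearson_correlation(paired_replicates(rank(a), rank(b))),
    tolerance = 1e-12)
  # ties get midranks: ranks of (1,1,2) are (1.5,1.5,3) -> r = 1.5/sqrt(3)
  expect_equal(
    spearman_correlation(paired_replicates(c(1, 1, 2), c(3, 5, 9))),
    1.5 / sqrt(3), tolerance = 1e-12)
  expect_error(spearman_correlation(paired_replicates(c(1, 1), c(1, 2))),
               class = "quantcorr_undefined_correlation")
})

test_that("quantize_equal_count forms balanced rank blocks, smallest first", {
  v <- c(0.7, -2, 5, 1.1, 0, 9, -4, 3, 2, 8)
  expect_identical(quantize_equal_count(v, 10L), as.integer(rank(v)))
  # exact equal sizes when n_bins divides n
  lab <- quantize_equal_count(rnorm(300), 100)
  expect_true(all(tabulate(lab, 100) == 3L))
  # ties straddling a block boundary follow stable input order:
  # sorted order of (5,1,5,2,5,3,5) is probes 2,4,6 then 1,3,5,7
  expect_identical(quantize_equal_count(c(5, 1, 5, 2, 5, 3, 5), 3),
                   c(2L, 1L, 2L, 1L, 3L, 1L, 3L))
  expect_error(quantize_equal_count(1:5, 6), class = "quantcorr_parameter_error")
  expect_error(quantize_equal_count(1:5, 1), class = "quantcorr_parameter_error")
})

test_that("bin sizes differ by at most one and bin 1 holds the smallest values", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    B <- sample(2:min(9, n), 1)
    v <- rnorm(n)
    lab <- quantize_equal_count(v, B)
    sizes <- tabulate(lab, B)
    expect_true(all(sizes >= 1))
    expect_lte(diff(range(sizes)), 1L)
    expect_lte(max(v[lab == 1]), min(v[lab == B]))
  }
})

test_that("joint_contingency agrees with nested-loop counting", {
  expect_identical(joint_contingency(c(1L, 2L, 2L), c(1L, 2L, 2L), 2L),
                   matrix(c(1L, 0L, 0L, 2L), 2, 2))
  set.seed(5)
  for (i in 1:10) {
    B <- sample(2:5, 1); n <- sample(10:60, 1)
    lx <- sample.int(B, n, replace = TRUE)
    ly <- sample.int(B, n, replace = TRUE)
    tab <- joint_contingency(lx, ly, B)
    expect_equal(tab, naive_contingency(lx, ly, B))
    expect_identical(sum(tab), n)
    expect_equal(rowSums(tab), tabulate(lx, B), ignore_attr = TRUE)
    expect_equal(colSums(tab), tabulate(ly, B), ignore_attr = TRUE)
  }
  expect_error(joint_contingency(c(1L, 3L), c(1L, 2L), 2L),
               class = "quantcorr_data_error")
})

test_that("pearson_from_contingency equals Pearson on the expanded vectors", {
  expect_equal(pearson_from_contingency(diag(c(3L, 5L, 2L))), 1)
  expect_equal(pearson_from_contingency(matrix(c(0L, 4L, 6L, 0L), 2, 2)), -1)
  set.seed(8)
  for (i in 1:10) {
    tab <- random_table(4, 50)
    ev <- expand_table(tab)
    expect_equal(pearson_from_contingency(tab), stats::cor(ev$x, ev$y),
                 tolerance = 1e-10)
  }
  one_bin <- matrix(c(3L, 4L, 0L, 0L), 2, 2)  # all x-mass in bin 1
  expect_error(pearson_from_contingency(one_bin),
               class = "quantcorr_undefined_correlation")
})

test_that("evaluate_merge_candidates matches full recomputation on relabelled vectors", {
  set.seed(13)
  tab3 <- random_table(3, 40)
  expect_identical(nrow(evaluate_merge_candidates(tab3)), 2L)
  for (i in 1:10) {
    B <- sample(3:6, 1)
    tab <- random_table(B, 80)
    cand <- evaluate_merge_candidates(tab)
    ev <- expand_table(tab)
    for (k in seq_len(B - 1)) {
      up <- setdiff(seq_len(B), k)
      ref <- stats::cor(relabel_oracle(ev$x, up), relabel_oracle(ev$y, up))
      expect_equal(cand$correlation[k], ref, tolerance = 1e-10)
    }
  }
  expect_error(evaluate_merge_candidates(random_table(2, 20)),
               class = "quantcorr_parameter_error")
})

test_that("merging within an uncorrelated background block raises the correlation", {
  # bins 1-2: independent between replicates; bins 3-4: near-perfect agreement
  tab <- matrix(0L, 4, 4)
  tab[1:2, 1:2] <- matrix(c(25L, 25L, 25L, 25L), 2, 2)
  tab[3, 3] <- 50L; tab[4, 4] <- 50L
  base <- pearson_from_contingency(tab)
  cand <- evaluate_merge_candidates(tab)
  expect_gt(cand$correlation[1], base)  # merging the noise bins helps
})

test_that("qcc is exact on identical inputs and validates its parameters", {
  set.seed(2)
  x <- rnorm(200)
  res <- qcc(paired_replicates(x, x), initial_bins = 10)
  expect_equal(res$qcc, 1)
  expect_equal(res$raw_pcc, 1)
  expect_error(qcc(paired_replicates(rep(1, 50), rnorm(50)), 5),
               class = "quantcorr_undefined_correlation")
  expect_error(qcc(paired_replicates(rnorm(10), rnorm(10)), 11),
               class = "quantcorr_parameter_error")
  expect_error(qcc(paired_replicates(rnorm(10), rnorm(10)), 1),
               class = "quantcorr_parameter_error")
})

test_that("qcc result is internally consistent", {
  set.seed(21)
  x <- rnorm(300)
  y <- x * rbinom(300, 1, 0.4) + rnorm(300)
  res <- qcc(paired_replicates(x, y), initial_bins = 12)
  tr <- res$merge_trace$correlation
  expect_true(all(diff(c(res$initial_pcc_quantized, tr)) > 0))
  expect_equal(res$qcc,
               if (length(tr)) tr[length(tr)] else res$initial_pcc_quantized)
  expect_gte(res$qcc, -1); expect_lte(res$qcc, 1)
  expect_lte(nrow(res$merge_trace), res$initial_bins - 2L)
  st <- res$final_state
  expect_identical(sum(st$joint_counts), res$n_probes)
  expect_true(all(tabulate(st$labels_x, st$B) ==
                  rowSums(st$joint_counts)))
  expect_true(all(tabulate(st$labels_y, st$B) ==
                  colSums(st$joint_counts)))
  # the table shortcut agrees with direct Pearson on the final labels
  expect_equal(st$current_pcc, stats::cor(st$labels_x, st$labels_y),
               tolerance = 1e-10)
})

test_that("analytic_expected_pcc evaluates the mixture closed form", {
  expect_equal(analytic_expected_pcc(0, 3), 0)
  expect_equal(analytic_expected_pcc(1, 3), 0)
  expect_equal(analytic_expected_pcc(0.05, 3), 0.4275 / 1.4275,
               tolerance = 1e-12)
  expect_equal(analytic_expected_pcc(0.20, 3), 1.44 / 2.44,
               tolerance = 1e-12)
  # the value is scale-free in the noise sd
  expect_equal(analytic_expected_pcc(0.1, 4, noise_sd = 2.5),
               analytic_expected_pcc(0.1, 4))
  expect_error(analytic_expected_pcc(1.2, 3), class = "quantcorr_parameter_error")
})
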