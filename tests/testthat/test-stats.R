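# Trend statistics: tau-b, rank-sum, correlation suite.

test_that("tau-b handles perfect concordance and discordance", {
  expect_equal(kendall_tau_b(c(1, 2, 3), c(10, 20, 30))$tau_b, 1)
  expect_equal(kendall_tau_b(c(1, 2, 3), c(3, 2, 1))$tau_b, -1)
  expect_error(kendall_tau_b(1:3, 1:4), "length")
  expect_warning(res <- kendall_tau_b(c(1, 1, 1), c(1, 2, 3)), "tied")
  expect_true(is.na(res$tau_b))
})

test_that("tau-b matches the brute-force pairwise oracle on tied data", {
  set.seed(1234)
  for (rep in 1:60) {
    n <- sample(5:30, 1)
    x <- sample(1:6, n, replace = TRUE)   # heavy ties
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(kendall_tau_b(x, y)$tau_b, oracle_tau_b(x, y),
                 tolerance = 1e-12)
  }
})

test_that("tau-b is antisymmetric and monotone-transform invariant", {
  set.seed(55)
  x <- stats::rlnorm(25); y <- stats::rlnorm(25)
  t0 <- kendall_tau_b(x, y)$tau_b
  expect_equal(kendall_tau_b(x, -y)$tau_b, -t0, tolerance = 1e-12)
  expect_equal(kendall_tau_b(exp(x), y)$tau_b, t0, tolerance = 1e-12)
  expect_equal(kendall_tau_b(x, rank(y))$tau_b, t0, tolerance = 1e-12)
})

test_that("rank-sum exact enumeration reproduces hand-enumerated p-values", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 1 / 3)  # 2 of the 6 assignments are as extreme
  expect_equal(w$group_sizes, c(2L, 2L))
  # identical multisets: every deviation is as extreme as the observed 0
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("rank-sum exact p matches full bitmask enumeration, ties included", {
  set.seed(77)
  for (rep in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(1:4, na, replace = TRUE)  # cross-group ties likely
    b <- sample(1:4, nb, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, oracle_ranksum_p(a, b))
  }
})

test_that("the exact null distribution is a proper probability distribution", {
  # all assignment rank sums enumerated: probabilities sum to one and the
  # most extreme two-sided p is at most 1
  r <- rank(c(2, 5, 5, 9, 1, 7))
  combs <- utils::combn(6, 3)
  ws <- colSums(matrix(r[combs], nrow = 3))
  probs <- table(ws) / ncol(combs)
  expect_equal(sum(probs), 1)
  p_all <- vapply(unique(ws), function(w)
    mean(abs(ws - mean(ws)) >= abs(w - mean(ws))), 0)
  expect_true(all(p_all > 0 & p_all <= 1))
})

test_that("rank-sum detects a large lognormal shift", {
  set.seed(2024)
  a <- stats::rlnorm(40, 0, 1)
  b <- stats::rlnorm(40, 1.5, 1)
  res <- wilcoxon_rank_sum(a, b)
  expect_lt(res$p_value, 0.05)
  expect_match(res$method, "normal")
})

test_that("the correlation suite produces the six labelled analyses", {
  # deterministic construction: HI grows with n, MCR grows with n
  n_vals <- rep(5:8, each = 12)
  metrics <- data.frame(
    sample_id = paste0("s", seq_along(n_vals)), policy = "case1_zero",
    hi = 2^n_vals + seq_along(n_vals) * 1e-4,
    mhq = 1, mcr = n_vals / 4 + seq_along(n_vals) * 1e-5,
    missed_fraction = 0.5, n_detected = n_vals, n_analyzed = n_vals,
    n_effective = n_vals, top_chemical = "x", stringsAsFactors = FALSE)
  suite <- correlation_suite(metrics)
  expect_setequal(unique(suite$analysis),
                  c("hi_vs_n", "mcr_vs_n", "mcr_vs_hi", "mcr_vs_hi_above"))
  expect_equal(nrow(suite), 6L)
  per <- suite[suite$level == "per_sample", ]
  expect_equal(per$tau_b[per$analysis == "hi_vs_n"],
               kendall_tau_b(n_vals, metrics$hi)$tau_b)
  grp <- suite[suite$level == "group_median", ]
  expect_equal(nrow(grp), 2L)
  expect_equal(grp$tau_b[grp$analysis == "hi_vs_n"], 1)  # medians monotone in n

  # i.i.d. null: small tau, non-significant
  set.seed(31415)
  null_m <- transform(metrics, hi = stats::rlnorm(nrow(metrics)),
                      mcr = stats::runif(nrow(metrics), 1, 4),
                      n_effective = sample(5:8, nrow(metrics), replace = TRUE))
  ns <- correlation_suite(null_m)
  row <- ns[ns$analysis == "mcr_vs_n" & ns$level == "per_sample", ]
  expect_lt(abs(row$tau_b), 0.25)
  expect_gt(row$p_value, 0.05)

  # constant group medians: undefined tau with a warning
  const_g <- data.frame(policy = "case1_zero", n_value = 5:8,
                        sample_count = 12, median_hi = 2:5, median_mcr = 2)
  expect_warning(cs <- correlation_suite(metrics, const_g), "tied")
  expect_true(is.na(cs$tau_b[cs$analysis == "mcr_vs_n" &
                               cs$level == "group_median"]))
})
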