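# Metric engine: HI, MHQ, MCR, missed toxicity.

test_that("the illustrative HQ pair reproduces the known metrics", {
  p <- hq_example_pair()

  expect_equal(hazard_index(p$individual_1), 3.0)
  expect_equal(hazard_index(p$individual_2), 3.0)

  m1 <- individual_metrics(p$individual_1)
  expect_equal(m1$hi, 3.0)
  expect_equal(m1$mhq, 0.8)
  expect_equal(m1$mcr, 3.75)
  expect_equal(m1$missed_fraction, 1 - 1 / 3.75)
  expect_equal(m1$n, 5L)
  expect_equal(round_half_up(m1$mcr, 1), 3.8)

  m2 <- individual_metrics(p$individual_2)
  expect_equal(m2$mhq, 2.7)
  expect_equal(m2$mcr, 3.0 / 2.7)
  expect_equal(round_half_up(m2$mcr, 1), 1.1)
})

test_that("validation errors name the offending chemical", {
  expect_error(hazard_index(c(a = 0.5, b = -0.1)), "b")
  expect_error(hazard_index(c(a = 0.5, b = Inf)), "b")
  expect_error(hazard_index(c(a = 1, a = 2)), "duplicated")
  expect_error(hazard_index(numeric(0)), "at least one entry")
})

test_that("max HQ ties break to the alphabetically first chemical", {
  mx <- max_hazard_quotient(c(zeta = 0.5, alpha = 0.5, mid = 0.2))
  expect_equal(mx$mhq, 0.5)
  expect_equal(mx$chemical, "alpha")
  expect_equal(max_hazard_quotient(c(only = 0.37))$mhq, 0.37)
})

test_that("missed toxicity follows 1 - 1/MCR with a domain check", {
  expect_equal(missed_toxicity(2), 0.5)
  expect_equal(missed_toxicity(1.25), 0.2)
  expect_equal(missed_toxicity(1), 0)
  expect_error(missed_toxicity(0.9), ">= 1")
  expect_true(is.na(missed_toxicity(NA_real_)))
})

test_that("an all-zero HQ vector has HI 0 and an undefined MCR", {
  expect_equal(hazard_index(c(a = 0)), 0)
  expect_warning(val <- mcr(c(a = 0, b = 0)), "undefined")
  expect_true(is.na(val))
  expect_warning(m <- individual_metrics(c(a = 0, b = 0)), "undefined")
  expect_equal(m$hi, 0)
  expect_true(is.na(m$mcr) && is.na(m$missed_fraction))
  expect_true(is.na(m$top_chemical))
})

test_that("metric invariants hold on random vectors", {
  set.seed(421)
  for (rep in 1:200) {
    n <- sample(1:20, 1)
    hq <- random_hq(n)
    m <- individual_metrics(hq)
    # internal consistency
    expect_true(m$mcr >= 1 - 1e-12 && m$mcr <= n + 1e-12)
    expect_lte(abs(m$hi - m$mhq * m$mcr), 4 * .Machine$double.eps * m$hi)
    expect_equal(m$missed_fraction, 1 - 1 / m$mcr)
    # independent elementwise sum/max oracle (sum to within accumulation
    # order: base sum() carries extended precision, the loop does not)
    s <- 0; mx <- 0
    for (v in hq) { s <- s + v; if (v > mx) mx <- v }
    expect_equal(m$hi, s, tolerance = 1e-14)
    expect_identical(m$mhq, mx)
  }
})

test_that("MCR is scale invariant and HI/MHQ scale linearly", {
  set.seed(99)
  hq <- random_hq(12)
  m <- individual_metrics(hq)
  for (c_scale in c(1e-6, 0.5, 3, 1e5)) {
    ms <- individual_metrics(hq * c_scale)
    expect_equal(ms$mcr, m$mcr, tolerance = 1e-12)
    expect_equal(ms$hi, m$hi * c_scale, tolerance = 1e-12)
    expect_equal(ms$mhq, m$mhq * c_scale, tolerance = 1e-12)
  }
})

test_that("appending an entry below the max strictly increases MCR and HI", {
  set.seed(7)
  for (rep in 1:25) {
    hq <- random_hq(sample(2:15, 1))
    extra <- stats::runif(1, min = 1e-9, max = max(hq))
    hq2 <- c(hq, new_chem = extra)
    expect_gt(mcr(hq2), mcr(hq))
    expect_gt(hazard_index(hq2), hazard_index(hq))
  }
})

test_that("equitoxic vectors attain the upper bound MCR = n", {
  for (n in c(1, 2, 7, 50)) {
    hq <- rep(0.3, n); names(hq) <- paste0("c", seq_len(n))
    expect_equal(mcr(hq), n)
  }
})
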