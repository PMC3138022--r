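# Synthetic monitoring-data generator.

test_that("generation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_samples = 20, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(simulation_config(n_samples = 20, seed = 43))
  expect_false(identical(d1, d3))
  # no hidden global RNG state: the global seed is untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_dataset(cfg))
  expect_identical(before, .Random.seed)
})

test_that("a seed is mandatory and configs are validated", {
  expect_error(simulation_config(n_samples = 5), "seed")
  expect_error(simulation_config(5, 1, detect_probability = 1.5), "range")
  expect_error(simulation_config(5, 1, detection_limit = 0), "range")
  expect_error(simulation_config(5, 1, dominance_factor = 0.5), ">= 1")
  expect_error(simulation_config(5, 1, panel_sizes = 48, panel_weights = c(1, 2)),
               "panel_weights")
  expect_error(generate_dataset(simulation_config(5, 1, panel_sizes = 500)),
               "exceeds")
})

test_that("generated data honor the water-sample invariants and the config", {
  cfg <- simulation_config(n_samples = 40, seed = 9)
  d <- generate_dataset(cfg)
  expect_s3_class(d, "water_samples")  # constructor validated it
  per <- split(d, d$sample_id)
  sizes <- vapply(per, nrow, 0L)
  expect_true(all(sizes %in% c(48L, 80L)))
  nd <- d$status == "nondetect"
  expect_true(all(d$detection_limit[nd] == 0.01))
  expect_true(all(is.finite(d$concentration[!nd]) & d$concentration[!nd] > 0))
})

test_that("zero detection probability leaves nothing past the detect filter", {
  d <- generate_dataset(simulation_config(30, seed = 3, detect_probability = 0))
  expect_true(all(d$status == "nondetect"))
  expect_message(kept <- filter_samples(d, 5), "removed 30 of 30")
  expect_equal(nrow(kept), 0L)
})

test_that("the default world yields about 9 detects per sample", {
  d <- generate_dataset(simulation_config(300, seed = 2718))
  det <- tapply(d$status == "detected", d$sample_id, sum)
  expect_lt(abs(mean(det) - 9), 2)
  expect_true(all(tapply(d$chemical, d$sample_id, anyDuplicated) == 0))
})

test_that("per-chemical overrides steer individual chemicals", {
  cfg <- simulation_config(50, seed = 12,
                           detect_probability = c(Atrazine = 1),
                           detection_limit = c(Diuron = 0.5))
  d <- generate_dataset(cfg)
  atr <- d[d$chemical == "Atrazine", ]
  expect_true(all(atr$status == "detected"))
  diu <- d[d$chemical == "Diuron" & d$status == "nondetect", ]
  expect_true(all(diu$detection_limit == 0.5))
  expect_error(simulation_config(5, 1, detect_probability = c(Nope = 0.2)) |>
                 generate_dataset(), "not in the permitted-dose table")
})

test_that("the illustrative pair fixture is exactly the stated vectors", {
  p <- hq_example_pair()
  expect_equal(unname(p$individual_1), c(0.6, 0.8, 0.4, 0.5, 0.7))
  expect_equal(unname(p$individual_2), c(2.7, 0.29, 0.008, 0.001, 0.001))
  expect_equal(lengths(p), c(individual_1 = 5L, individual_2 = 5L))
  expect_equal(sum(p$individual_1), 3.0)
  expect_equal(max(p$individual_2), 2.7)
})

test_that("equitoxic datasets are exactly equitoxic", {
  for (n in c(1, 7)) {
    m <- suppressMessages(compute_sample_metrics(
      equitoxic_dataset(n, 0.3, n_samples = 2), policy = "case1_zero"))
    expect_equal(m$mcr, rep(n, 2), tolerance = 1e-12)
  }
  m5 <- suppressMessages(compute_sample_metrics(
    equitoxic_dataset(5, hq_level = 0.2), policy = "case1_zero"))
  expect_equal(m5$hi, 1.0)
  expect_error(equitoxic_dataset(500), "exceeds")
})

test_that("generated datasets round-trip losslessly through the long CSV", {
  d <- generate_dataset(simulation_config(15, seed = 101))
  path <- withr::local_tempfile(fileext = ".csv")
  write_monitoring_csv(d, path)
  back <- read_monitoring_csv(path)
  expect_equal(back$sample_id, d$sample_id)
  expect_equal(back$chemical, d$chemical)
  expect_equal(back$status, d$status)
  expect_equal(back$concentration, d$concentration, tolerance = 1e-10)
  expect_equal(back$detection_limit, d$detection_limit, tolerance = 1e-10)
  expect_equal(back$date, d$date)
})

test_that("dominance drives MCR toward 1; its absence lets MCR grow with n", {
  dom <- generate_dataset(simulation_config(120, seed = 606,
                                            dominance_factor = 100))
  mdom <- suppressWarnings(suppressMessages(compute_sample_metrics(
    suppressMessages(filter_samples(dom)), policy = "case1_zero")))
  expect_lt(mean(mdom$mcr, na.rm = TRUE), 1.2)

  plain <- generate_dataset(simulation_config(120, seed = 606))
  mpl <- suppressWarnings(suppressMessages(compute_sample_metrics(
    suppressMessages(filter_samples(plain)), policy = "case1_zero")))
  expect_gt(mean(mpl$mcr, na.rm = TRUE), mean(mdom$mcr, na.rm = TRUE))
  # without dominance, detect count pulls MCR upward
  tau <- kendall_tau_b(mpl$n_effective, mpl$mcr)$tau_b
  expect_gt(tau, 0)
})
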