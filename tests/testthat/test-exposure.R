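# Exposure scenario, dose conversion and the permitted-dose table.

test_that("dose conversion matches hand arithmetic", {
  expect_equal(dose_from_concentration(30), 0.001)      # 0.030 * 2 / 60
  expect_equal(dose_from_concentration(0), 0)
  expect_equal(dose_from_concentration(60, exposure_scenario(1, 60)), 0.001)
  expect_error(dose_from_concentration(-1), "non-negative")
  expect_error(exposure_scenario(ingestion_rate = 0), "positive")
  expect_error(exposure_scenario(body_weight = -5), "positive")
})

test_that("hazard quotient is dose / PD with a positive-PD domain", {
  expect_equal(hazard_quotient(0.0019, 0.0019), 1)
  expect_equal(hazard_quotient(0.001, 0.00003), 0.001 / 0.00003) # ~33.33
  expect_equal(hazard_quotient(0, 0.5), 0)
  expect_error(hazard_quotient(0.1, 0), "positive")
  expect_error(hazard_quotient(-0.1, 1), "non-negative")
})

test_that("dose and HQ are linear in concentration", {
  sc <- exposure_scenario(1.5, 72)
  conc <- c(0.3, 7, 150)
  expect_equal(dose_from_concentration(3 * conc, sc),
               3 * dose_from_concentration(conc, sc))
  hq1 <- hazard_quotient(dose_from_concentration(conc, sc), 0.004)
  hq5 <- hazard_quotient(dose_from_concentration(5 * conc, sc), 0.004)
  expect_equal(hq5, 5 * hq1)
})

test_that("the packaged permitted-dose table has 81 validated records", {
  pd <- load_permitted_doses()
  expect_s3_class(pd, "pd_table")
  expect_equal(nrow(pd), 81L)
  expect_true(all(pd$pd_mg_kg_day > 0))
  expect_false(any(duplicated(pd$chemical)))
  expect_equal(resolve_pd("Dieldrin", pd), 0.00005)
  expect_equal(resolve_pd("Atrazine", pd), 0.0019)
  expect_equal(resolve_pd("Chlorpyrifos", pd), 0.00003)
  expect_true(all(pd$molar_basis[pd$chemical %in%
    c("2,6 Diethylaniline", "3-Hydroxycarbofuran", "Diethyl atrazine")]))
})

test_that("PD lookup is case/whitespace insensitive but never fuzzy", {
  pd <- load_permitted_doses()
  expect_equal(resolve_pd("  atrazine ", pd), 0.0019)
  expect_equal(resolve_pd("DIURON", pd), 0.003)
  expect_warning(val <- resolve_pd("Atrazin", pd), "no permitted dose")
  expect_true(is.na(val))
})

test_that("chemicals without a PD resolve to an exclusion marker", {
  pd <- load_permitted_doses()
  expect_warning(vals <- resolve_pd(c("Fenuron", "Neburon", "Atrazine"), pd),
                 "2 chemical")
  expect_true(is.na(vals[1]) && is.na(vals[2]))
  expect_equal(vals[3], 0.0019)
  expect_silent(resolve_pd("Fenuron", pd, warn = FALSE))
})

test_that("malformed permitted-dose tables are rejected", {
  expect_error(load_permitted_doses(data.frame(
    chemical = c("A", "a"), pd_mg_kg_day = c(1, 2), source_code = 1L)),
    "duplicated")
  expect_error(load_permitted_doses(data.frame(
    chemical = "A", pd_mg_kg_day = 0, source_code = 1L)), "non-positive")
  expect_error(load_permitted_doses(data.frame(chemical = "A")), "lacks")
})
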