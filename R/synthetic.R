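# Synthetic monitoring-data generator.
#
# Emulates the structure of a national surface-water pesticide survey:
# per-sample analyte panels clustered around two laboratory method sizes
# (48 and 80 analytes), a minority of analytes detected per sample
# (on average about 9 detects against about 61 non-detects), lognormal
# detected concentrations and per-chemical detection limits. The audit
# trail of every random draw is pinned to a mandatory seed
# (Mersenne-Twister / Inversion / Rejection), so a dataset is reproducible
# across runs and platforms.

#' Configuration for the synthetic monitoring-data generator
#'
#' Per-chemical parameters (`detect_probability`, `log_mean`, `log_sd`,
#' `detection_limit`) may be a single number applied to every chemical or
#' a named vector giving per-chemical overrides on top of the scalar
#' default. Defaults describe the emulated survey: panels of 48 or 80
#' analytes drawn with equal weight, a detection probability of 9/70 (so a
#' 70-analyte average panel yields about 9 detects), detected
#' concentrations lognormal with median 0.05 ug/L and log-sd 1.5 (a
#' population spanning roughly four orders of magnitude), and a detection
#' limit of 0.01 ug/L.
#'
#' `dominance_factor` multiplies the detected concentration of one
#' designated chemical; with a factor well above 1 the generator models a
#' ubiquitous dominant contributor: the designated chemical is included in
#' every panel and always detected. By default the designated chemical is
#' the one with the smallest permitted dose (the most potent), so that the
#' dominance is expressed on the hazard-quotient scale.
#'
#' @param n_samples number of samples to generate.
#' @param seed integer seed; mandatory, no hidden global state.
#' @param panel_sizes candidate analyte-panel sizes (default `c(48, 80)`).
#' @param panel_weights sampling weights for `panel_sizes` (default equal).
#' @param detect_probability scalar or named per-chemical vector in [0,1].
#' @param log_mean scalar or named vector: mean of log concentration
#'   (log ug/L) for detected values.
#' @param log_sd scalar or named vector: sd of log concentration (>= 0).
#' @param detection_limit scalar or named vector of detection limits
#'   (ug/L, > 0).
#' @param dominance_factor concentration multiplier (>= 1) for the
#'   designated dominant chemical (default 1 = no dominance).
#' @param dominant_chemical name of the designated chemical; default
#'   (`NULL`) picks the chemical with the smallest permitted dose when
#'   `dominance_factor > 1`.
#' @param n_sites number of synthetic sites sample ids are spread over.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples, seed,
                              panel_sizes = c(48L, 80L),
                              panel_weights = NULL,
                              detect_probability = 9 / 70,
                              log_mean = log(0.05),
                              log_sd = 1.5,
                              detection_limit = 0.01,
                              dominance_factor = 1,
                              dominant_chemical = NULL,
                              n_sites = 20L) {
  check_positive_scalar(n_samples, "n_samples")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort("a single integer seed is required (reproducibility is not optional)")
  if (!is.numeric(panel_sizes) || any(panel_sizes < 1))
    abort("panel_sizes must be positive integers")
  panel_weights <- panel_weights %||% rep(1, length(panel_sizes))
  if (length(panel_weights) != length(panel_sizes) || any(panel_weights < 0) ||
      sum(panel_weights) == 0)
    abort("panel_weights must be non-negative and match panel_sizes")
  check_param <- function(x, what, lo, hi = Inf, lo_ok = TRUE) {
    if (!is.numeric(x) || !length(x))
      abort("%s must be numeric", what)
    bad <- !is.finite(x) | x > hi | (if (lo_ok) x < lo else x <= lo)
    if (any(bad)) abort("%s out of range", what)
    if (length(x) > 1L && is.null(names(x)))
      abort("per-chemical %s must be a named vector", what)
    x
  }
  check_param(detect_probability, "detect_probability", 0, 1)
  check_param(log_sd, "log_sd", 0)
  check_param(detection_limit, "detection_limit", 0, lo_ok = FALSE)
  if (!is.numeric(log_mean) || (length(log_mean) > 1L && is.null(names(log_mean))))
    abort("log_mean must be a scalar or named numeric vector")
  if (!is.numeric(dominance_factor) || length(dominance_factor) != 1L ||
      dominance_factor < 1)
    abort("dominance_factor must be a single number >= 1")
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 panel_sizes = as.integer(panel_sizes),
                 panel_weights = panel_weights,
                 detect_probability = detect_probability,
                 log_mean = log_mean, log_sd = log_sd,
                 detection_limit = detection_limit,
                 dominance_factor = dominance_factor,
                 dominant_chemical = dominant_chemical,
                 n_sites = as.integer(n_sites)),
            class = "simulation_config")
}

# expand a scalar-or-named-vector parameter to one value per chemical;
# any named vector (length 1 included) is a per-chemical override on top
# of the default
resolve_chem_param <- function(value, chemicals, default) {
  named <- !is.null(names(value))
  out <- rep(if (!named) value else default, length(chemicals))
  names(out) <- chemicals
  if (named) {
    unknown <- setdiff(names(value), chemicals)
    if (length(unknown))
      abort("per-chemical parameter names not in the permitted-dose table: %s",
            paste(unknown, collapse = ", "))
    out[names(value)] <- value
  }
  out
}

# run code under the pinned, seeded RNG without touching global state
with_pinned_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

#' Generate a synthetic monitoring dataset
#'
#' Draws `n_samples` water samples according to a [simulation_config()]:
#' each sample gets an analyte panel (a random subset of the permitted-dose
#' table's chemicals of a size drawn from `panel_sizes`), each panel
#' chemical is independently detected with its detection probability,
#' detected concentrations are lognormal, and non-detects carry their
#' detection limit. See [simulation_config()] for the dominance mechanism.
#'
#' @param config a [simulation_config()].
#' @param pd_table a `pd_table` providing the chemical universe (default:
#'   the packaged table of 81 chemicals).
#' @return a validated `water_samples` table.
#' @examples
#' d <- generate_dataset(simulation_config(n_samples = 5, seed = 42))
#' @export
generate_dataset <- function(config, pd_table = load_permitted_doses()) {
  if (!inherits(config, "simulation_config"))
    abort("config must be created with simulation_config()")
  if (!inherits(pd_table, "pd_table")) pd_table <- load_permitted_doses(pd_table)
  chems <- pd_table$chemical
  if (any(config$panel_sizes > length(chems)))
    abort("panel size exceeds the %d chemicals in the permitted-dose table",
          length(chems))
  p_det <- resolve_chem_param(config$detect_probability, chems, 9 / 70)
  mu <- resolve_chem_param(config$log_mean, chems, log(0.05))
  sg <- resolve_chem_param(config$log_sd, chems, 1.5)
  dl <- resolve_chem_param(config$detection_limit, chems, 0.01)

  dominant <- NULL
  if (config$dominance_factor > 1) {
    dominant <- config$dominant_chemical %||%
      chems[which.min(pd_table$pd_mg_kg_day)]
    if (!dominant %in% chems)
      abort("dominant_chemical %s is not in the permitted-dose table", dominant)
  }

  with_pinned_rng(config$seed, {
    sites <- sprintf("site_%03d", seq_len(config$n_sites))
    dates <- seq(as.Date("1992-01-01"), as.Date("2001-12-31"), by = "day")
    per_sample <- lapply(seq_len(config$n_samples), function(i) {
      size <- if (length(config$panel_sizes) == 1L) config$panel_sizes else
        sample(config$panel_sizes, 1L, prob = config$panel_weights)
      panel <- sort(sample(chems, size))
      detected <- stats::runif(size) < p_det[panel]
      if (!is.null(dominant)) {       # ubiquitous dominant contributor
        if (!dominant %in% panel) panel <- sort(c(panel[-1L], dominant))
        detected <- stats::runif(length(panel)) < p_det[panel]
        detected[panel == dominant] <- TRUE
      }
      conc <- rep(NA_real_, length(panel))
      ndet <- sum(detected)
      if (ndet > 0)
        conc[detected] <- stats::rlnorm(ndet, mu[panel[detected]],
                                        sg[panel[detected]])
      if (!is.null(dominant) && detected[match(dominant, panel)])
        conc[match(dominant, panel)] <-
          conc[match(dominant, panel)] * config$dominance_factor
      data.frame(sample_id = sprintf("SYN_%05d", i),
                 site_id = sample(sites, 1L),
                 date = sample(dates, 1L),
                 chemical = panel,
                 status = ifelse(detected, "detected", "nondetect"),
                 concentration = conc,
                 detection_limit = ifelse(detected, NA_real_, dl[panel]),
                 stringsAsFactors = FALSE)
    })
    water_samples(do.call(rbind, per_sample))
  })
}

#' Two illustrative HQ vectors with equal Hazard Index
#'
#' The classic pair used to motivate the MCR: two individuals each exposed
#' to five chemicals with HI = 3. For the first, the toxicity is spread
#' across chemicals (HQs 0.6, 0.8, 0.4, 0.5, 0.7: no single chemical above
#' 1, MCR 3.75); for the second, one chemical dominates (HQs 2.7, 0.29,
#' 0.008, 0.001, 0.001: MCR about 1.11), so a chemical-by-chemical
#' assessment already finds the problem.
#'
#' @return a list of two named HQ vectors, `individual_1` and
#'   `individual_2`.
#' @examples
#' sapply(hq_example_pair(), hazard_index) # both 3
#' @export
hq_example_pair <- function() {
  nm <- paste0("chem_", 1:5)
  list(individual_1 = hq_vector(c(0.6, 0.8, 0.4, 0.5, 0.7), nm),
       individual_2 = hq_vector(c(2.7, 0.29, 0.008, 0.001, 0.001), nm))
}

#' Equitoxic dataset: every chemical at the same hazard quotient
#'
#' Builds samples in which each of `n_chemicals` chemicals is present at
#' the concentration that makes its HQ exactly `hq_level` under the given
#' scenario (concentration back-solved through the dose conversion and the
#' permitted dose). Such mixtures attain the upper MCR bound: MCR = n.
#'
#' @param n_chemicals number of chemicals (>= 1, taken from the top of the
#'   permitted-dose table).
#' @param hq_level the common hazard quotient (> 0, default 0.2).
#' @param n_samples number of identical samples to emit (default 1).
#' @param pd_table a `pd_table`.
#' @param scenario an [exposure_scenario()].
#' @return a `water_samples` table.
#' @examples
#' d <- equitoxic_dataset(7)
#' @export
equitoxic_dataset <- function(n_chemicals, hq_level = 0.2, n_samples = 1,
                              pd_table = load_permitted_doses(),
                              scenario = exposure_scenario()) {
  check_positive_scalar(n_chemicals, "n_chemicals")
  check_positive_scalar(hq_level, "hq_level")
  check_positive_scalar(n_samples, "n_samples")
  if (!inherits(pd_table, "pd_table")) pd_table <- load_permitted_doses(pd_table)
  if (n_chemicals > nrow(pd_table))
    abort("n_chemicals exceeds the %d chemicals with a permitted dose",
          nrow(pd_table))
  chems <- pd_table$chemical[seq_len(n_chemicals)]
  pd <- pd_table$pd_mg_kg_day[seq_len(n_chemicals)]
  # invert dose_from_concentration: conc [ug/L] giving dose = hq_level * pd
  conc <- hq_level * pd * scenario$body_weight / scenario$ingestion_rate / 1e-3
  one <- function(i) data.frame(
    sample_id = sprintf("EQ_%04d", i), site_id = "site_eq",
    date = as.Date("2000-01-01"), chemical = chems, status = "detected",
    concentration = conc, detection_limit = NA_real_,
    stringsAsFactors = FALSE)
  water_samples(do.call(rbind, lapply(seq_len(n_samples), one)))
}
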