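# Dataset-level processing: the water-sample container, the two
# non-detect substitution policies, the >=5-detect sample filter,
# per-sample mixture metrics under each policy, classification by Hazard
# Index, grouping by n and dataset summaries.
#
# Samples are carried as a long-format data.frame (class "water_samples"):
# one row per sample x analyzed chemical with columns sample_id, site_id,
# date, chemical, status ("detected" | "nondetect" | "not_analyzed"),
# concentration (ug/L, required iff detected) and detection_limit (ug/L,
# required iff nondetect). Chemicals absent from a sample's rows were not
# analyzed for in that sample.

#' Non-detect substitution policies
#'
#' Two conventions for analytes reported below their detection limit (DL):
#' `case1_zero` treats them as absent (concentration 0, and they do not
#' count toward n), `case2_dl_sqrt2` substitutes DL/sqrt(2), the common
#' mid-range imputation for left-censored data (and they count toward n).
#'
#' @return character vector of the two policy labels.
#' @export
nondetect_policies <- function() c("case1_zero", "case2_dl_sqrt2")

check_policy <- function(policy) {
  if (!is.character(policy) || length(policy) != 1L ||
      !policy %in% nondetect_policies())
    abort("policy must be one of: %s", paste(nondetect_policies(), collapse = ", "))
  policy
}

#' Construct and validate a long-format water-sample table
#'
#' Validates the long-format measurement table described above and coerces
#' `date` to `Date` (ISO-8601 input only). Within a sample, chemical names
#' must be unique; detected rows need a finite non-negative concentration;
#' non-detect rows need a strictly positive detection limit.
#'
#' @param df data.frame with columns `sample_id`, `site_id`, `date`,
#'   `chemical`, `status`, `concentration`, `detection_limit`.
#' @return the validated data.frame with class `water_samples`.
#' @export
water_samples <- function(df) {
  need <- c("sample_id", "site_id", "date", "chemical", "status",
            "concentration", "detection_limit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort("water-sample table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) < 1L) abort("water-sample table is empty")
  df <- as.data.frame(df)[need]
  df$sample_id <- as.character(df$sample_id)
  df$site_id <- as.character(df$site_id)
  df$chemical <- as.character(df$chemical)
  df$status <- as.character(df$status)
  df$concentration <- as.numeric(df$concentration)
  df$detection_limit <- as.numeric(df$detection_limit)
  if (!inherits(df$date, "Date")) {
    parsed <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    bad <- is.na(parsed) & !is.na(df$date)
    if (any(bad))
      abort("dates must be ISO-8601 (YYYY-MM-DD); offending value(s): %s",
            paste(unique(df$date[bad]), collapse = ", "))
    df$date <- parsed
  }
  ok_status <- df$status %in% c("detected", "nondetect", "not_analyzed")
  if (!all(ok_status))
    abort("unknown measurement status: %s",
          paste(unique(df$status[!ok_status]), collapse = ", "))
  det <- df$status == "detected"
  bad <- det & (is.na(df$concentration) | df$concentration < 0 |
                  !is.finite(df$concentration))
  if (any(bad))
    abort("detected rows need a finite non-negative concentration (sample %s, chemical %s)",
          df$sample_id[bad][1L], df$chemical[bad][1L])
  nd <- df$status == "nondetect"
  bad <- nd & (is.na(df$detection_limit) | df$detection_limit <= 0 |
                 !is.finite(df$detection_limit))
  if (any(bad))
    abort("non-detect rows need a positive detection limit (sample %s, chemical %s)",
          df$sample_id[bad][1L], df$chemical[bad][1L])
  dup <- duplicated(paste(df$sample_id, normalize_chemical(df$chemical), sep = "\r"))
  if (any(dup))
    abort("duplicated chemical within a sample (sample %s, chemical %s)",
          df$sample_id[dup][1L], df$chemical[dup][1L])
  class(df) <- c("water_samples", "data.frame")
  df
}

#' Effective concentration of measurements under a non-detect policy
#'
#' Detected rows keep their measured concentration. Non-detects become 0
#' under `case1_zero` and DL/sqrt(2) under `case2_dl_sqrt2`. Rows with
#' status `not_analyzed` get `NA` (excluded from the mixture under both
#' policies).
#'
#' @param measurements a `water_samples` table (or any data.frame with
#'   `status`, `concentration`, `detection_limit`, and for error reporting
#'   `sample_id` and `chemical`).
#' @param policy one of [nondetect_policies()].
#' @return numeric vector of effective concentrations in ug/L, `NA` for
#'   rows not analyzed.
#' @examples
#' m <- data.frame(sample_id = "S1", chemical = "Atrazine",
#'                 status = "nondetect", concentration = NA,
#'                 detection_limit = 1)
#' apply_nondetect_policy(m, "case2_dl_sqrt2") # 1/sqrt(2)
#' @export
apply_nondetect_policy <- function(measurements, policy) {
  check_policy(policy)
  status <- measurements$status
  eff <- rep(NA_real_, length(status))
  det <- status == "detected"
  eff[det] <- measurements$concentration[det]
  nd <- status == "nondetect"
  if (policy == "case1_zero") {
    eff[nd] <- 0
  } else {
    dl <- measurements$detection_limit
    bad <- nd & (is.na(dl) | dl <= 0)
    if (any(bad))
      abort("non-detect without a usable detection limit under %s (sample %s, chemical %s)",
            policy, measurements$sample_id[bad][1L], measurements$chemical[bad][1L])
    eff[nd] <- dl[nd] / sqrt(2)
  }
  eff
}

#' Drop samples with too few detected chemicals
#'
#' Retains exactly the samples in which at least `min_detects` chemicals
#' were detected (boundary inclusive), preserving input order. The detect
#' count is taken on raw detections, before any permitted-dose lookup or
#' imputation, so the filter is policy-independent. The number of removed
#' samples is reported via `message()`.
#'
#' @param samples a `water_samples` table.
#' @param min_detects minimum number of detected chemicals (default 5).
#' @return the filtered `water_samples` table.
#' @export
filter_samples <- function(samples, min_detects = 5) {
  if (!is.numeric(min_detects) || length(min_detects) != 1L || min_detects < 0)
    abort("min_detects must be a single non-negative number")
  samples <- water_samples(samples)
  ids <- unique(samples$sample_id)
  det <- tapply(samples$status == "detected", samples$sample_id, sum)
  keep_ids <- ids[det[ids] >= min_detects]
  removed <- length(ids) - length(keep_ids)
  if (removed > 0)
    message(sprintf("filter_samples: removed %d of %d samples with fewer than %g detected chemicals",
                    removed, length(ids), min_detects))
  out <- samples[samples$sample_id %in% keep_ids, , drop = FALSE]
  if (nrow(out)) rownames(out) <- NULL
  class(out) <- c("water_samples", "data.frame")
  out
}

#' Per-sample mixture metrics under a non-detect policy
#'
#' For each sample: effective concentrations are formed under `policy`,
#' converted to doses under `scenario`, divided by each chemical's
#' permitted dose, and the resulting HQ vector is summarized with
#' [individual_metrics()]. Chemicals without a PD are excluded (with a
#' warning counting occurrences) and never contribute to HI, MHQ or n.
#' Under `case1_zero` the mixture consists of the detected chemicals only
#' (n = detects with a PD); under `case2_dl_sqrt2` it also includes the
#' imputed non-detects (n = analytes with a PD). A sample whose effective
#' HQ vector is empty, or all of whose HQs are zero, gets `NA` metrics and
#' is excluded (and counted) in downstream summaries.
#'
#' @param samples a `water_samples` table.
#' @param pd_table a `pd_table` (default: the packaged table).
#' @param scenario an [exposure_scenario()].
#' @param policy one of [nondetect_policies()].
#' @return a data.frame of class `sample_metrics`, one row per sample, with
#'   columns `sample_id`, `policy`, `hi`, `mhq`, `mcr`, `missed_fraction`,
#'   `n_detected`, `n_analyzed`, `n_effective`, `top_chemical`.
#' @export
compute_sample_metrics <- function(samples, pd_table = load_permitted_doses(),
                                   scenario = exposure_scenario(),
                                   policy = "case1_zero") {
  check_policy(policy)
  samples <- water_samples(samples)
  if (!inherits(pd_table, "pd_table")) pd_table <- load_permitted_doses(pd_table)

  pd <- resolve_pd(samples$chemical, pd_table)
  eff <- apply_nondetect_policy(samples, policy)
  in_mix <- !is.na(pd) & if (policy == "case1_zero")
    samples$status == "detected" else samples$status %in% c("detected", "nondetect")
  hq <- rep(NA_real_, nrow(samples))
  hq[in_mix] <- hazard_quotient(
    dose_from_concentration(eff[in_mix], scenario), pd[in_mix])

  ids <- unique(samples$sample_id)
  grp <- split(seq_len(nrow(samples)), factor(samples$sample_id, levels = ids))
  rows <- lapply(ids, function(id) {
    i <- grp[[id]]
    use <- i[in_mix[i]]
    base <- list(sample_id = id, policy = policy,
                 n_detected = sum(samples$status[i] == "detected"),
                 n_analyzed = sum(samples$status[i] != "not_analyzed"),
                 n_effective = length(use))
    if (length(use) == 0L || max(hq[use]) == 0) {
      c(base, list(hi = if (length(use)) sum(hq[use]) else NA_real_,
                   mhq = if (length(use)) 0 else NA_real_,
                   mcr = NA_real_, missed_fraction = NA_real_,
                   top_chemical = NA_character_))
    } else {
      m <- individual_metrics(hq_vector(hq[use], samples$chemical[use]))
      c(base, list(hi = m$hi, mhq = m$mhq, mcr = m$mcr,
                   missed_fraction = m$missed_fraction,
                   top_chemical = m$top_chemical))
    }
  })
  out <- data.frame(
    sample_id = vapply(rows, `[[`, "", "sample_id"),
    policy = policy,
    hi = vapply(rows, `[[`, 0, "hi"),
    mhq = vapply(rows, `[[`, 0, "mhq"),
    mcr = vapply(rows, `[[`, 0, "mcr"),
    missed_fraction = vapply(rows, `[[`, 0, "missed_fraction"),
    n_detected = vapply(rows, `[[`, 0L, "n_detected"),
    n_analyzed = vapply(rows, `[[`, 0L, "n_analyzed"),
    n_effective = vapply(rows, `[[`, 0L, "n_effective"),
    top_chemical = vapply(rows, `[[`, "", "top_chemical"),
    stringsAsFactors = FALSE)
  n_undef <- sum(is.na(out$mcr))
  if (n_undef > 0)
    message(sprintf("compute_sample_metrics: %d sample(s) with undefined MCR under %s",
                    n_undef, policy))
  class(out) <- c("sample_metrics", "data.frame")
  out
}

#' Classify Hazard Index values against a cutoff
#'
#' `"above"` iff HI is strictly greater than the cutoff; HI exactly equal
#' to the cutoff is `"below"` (the screening question is whether cumulative
#' toxicity *exceeds* the level of concern). `NA` HI stays `NA`.
#'
#' @param hi numeric vector of Hazard Index values.
#' @param cutoff classification threshold (default 1).
#' @return character vector of `"above"` / `"below"`.
#' @export
classify_by_hi <- function(hi, cutoff = 1) {
  if (!is.numeric(hi)) abort("hi must be numeric")
  check_positive_scalar(cutoff, "cutoff")
  ifelse(is.na(hi), NA_character_, ifelse(hi > cutoff, "above", "below"))
}

#' Group per-sample metrics by mixture size n
#'
#' Groups a single-policy metrics table by `n_effective` and reports group
#' medians of HI and MCR. Medians are not determined for groups with fewer
#' than `min_group_size` samples (default 10); records with undefined
#' metrics are excluded from the medians (and counted).
#'
#' @param metrics a `sample_metrics` table from [compute_sample_metrics()]
#'   (one policy only).
#' @param min_group_size smallest group for which medians are reported.
#' @return a data.frame of class `group_summary` with columns `policy`,
#'   `n_value`, `sample_count`, `median_hi`, `median_mcr`.
#' @export
group_by_n <- function(metrics, min_group_size = 10) {
  if (length(unique(metrics$policy)) > 1L)
    abort("group_by_n expects metrics computed under a single policy; got: %s",
          paste(unique(metrics$policy), collapse = ", "))
  n_vals <- sort(unique(metrics$n_effective))
  rows <- lapply(n_vals, function(nv) {
    g <- metrics[metrics$n_effective == nv, , drop = FALSE]
    cnt <- nrow(g)
    if (cnt >= min_group_size) {
      data.frame(policy = g$policy[1L], n_value = nv, sample_count = cnt,
                 median_hi = stats::median(g$hi, na.rm = TRUE),
                 median_mcr = stats::median(g$mcr, na.rm = TRUE))
    } else {
      data.frame(policy = g$policy[1L], n_value = nv, sample_count = cnt,
                 median_hi = NA_real_, median_mcr = NA_real_)
    }
  })
  n_undef <- sum(is.na(metrics$mcr))
  if (n_undef > 0)
    message(sprintf("group_by_n: %d record(s) with undefined metrics excluded from medians",
                    n_undef))
  out <- do.call(rbind, rows)
  out$median_mcr[is.nan(out$median_mcr)] <- NA_real_
  out$median_hi[is.nan(out$median_hi)] <- NA_real_
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Summary statistics of HI and MCR, overall and by HI class
#'
#' Minimum, maximum and mean of HI and MCR for the whole dataset and for
#' the samples with HI below/above the cutoff — the layout of the standard
#' results tables of an MCR screening. Records with undefined values are
#' excluded from the corresponding statistics and counted.
#'
#' @inheritParams group_by_n
#' @param hi_cutoff HI classification threshold (default 1).
#' @return a data.frame with one row per scope (`overall`, `hi_below`,
#'   `hi_above`) and columns `policy`, `scope`, `n_samples`, `n_undefined`,
#'   `hi_min`, `hi_max`, `hi_mean`, `mcr_min`, `mcr_max`, `mcr_mean`.
#' @export
summarize_dataset <- function(metrics, hi_cutoff = 1) {
  if (length(unique(metrics$policy)) > 1L)
    abort("summarize_dataset expects metrics computed under a single policy")
  if (all(is.na(metrics$hi)) && all(is.na(metrics$mcr)))
    abort("all records have undefined metrics; nothing to summarize")
  cls <- classify_by_hi(metrics$hi, hi_cutoff)
  scopes <- list(overall = rep(TRUE, nrow(metrics)),
                 hi_below = !is.na(cls) & cls == "below",
                 hi_above = !is.na(cls) & cls == "above")
  stat3 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    c(min(x), max(x), mean(x))
  }
  rows <- lapply(names(scopes), function(sc) {
    g <- metrics[scopes[[sc]], , drop = FALSE]
    h <- stat3(g$hi); m <- stat3(g$mcr)
    data.frame(policy = metrics$policy[1L], scope = sc,
               n_samples = nrow(g), n_undefined = sum(is.na(g$mcr)),
               hi_min = h[1], hi_max = h[2], hi_mean = h[3],
               mcr_min = m[1], mcr_max = m[2], mcr_mean = m[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
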