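# Readers and writers for the monitoring CSV formats, the metrics CSV and
# the key-value scenario config.
#
# Long format (the USGS remark-code convention): columns sample_id,
# site_id, date (ISO-8601), chemical, value_ug_L, remark. A remark of "<"
# marks a non-detect whose value_ug_L is the detection limit; an empty
# remark marks a detection. Chemicals with no row in a sample were not
# analyzed for. Wide format: one row per sample with sample_id, site_id,
# date and one <chemical>_value / <chemical>_remark column pair per
# chemical; an empty value means not analyzed.

#' Read a monitoring CSV into a water-sample table
#'
#' Parses either dialect (see the format notes above) and validates the
#' result with [water_samples()]. Malformed rows (non-numeric values,
#' non-ISO dates, unknown remark codes) are collected and reported
#' together with their line numbers in a single error.
#'
#' @param path path to the CSV file.
#' @param dialect `"long"` (default) or `"wide"`.
#' @return a validated `water_samples` table.
#' @export
read_monitoring_csv <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort("input file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (dialect == "wide") raw <- wide_to_long(raw)
  need <- c("sample_id", "site_id", "date", "chemical", "value_ug_L", "remark")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort("monitoring CSV lacks column(s): %s", paste(miss, collapse = ", "))

  remark <- trimws(ifelse(is.na(raw$remark), "", raw$remark))
  value <- suppressWarnings(as.numeric(raw$value_ug_L))
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  line <- seq_len(nrow(raw)) + 1L  # header is line 1

  problems <- character(0)
  bad <- is.na(value)
  if (any(bad))
    problems <- c(problems, sprintf("line %d: value_ug_L '%s' is not numeric",
                                    line[bad], raw$value_ug_L[bad]))
  bad <- is.na(date)
  if (any(bad))
    problems <- c(problems, sprintf("line %d: date '%s' is not ISO-8601",
                                    line[bad], raw$date[bad]))
  bad <- !remark %in% c("", "<")
  if (any(bad))
    problems <- c(problems, sprintf("line %d: unknown remark code '%s'",
                                    line[bad], remark[bad]))
  if (length(problems))
    abort("invalid monitoring data (%d problem row(s)):\n%s",
          length(problems), paste(utils::head(problems, 20L), collapse = "\n"))

  nd <- remark == "<"
  water_samples(data.frame(
    sample_id = raw$sample_id, site_id = raw$site_id, date = date,
    chemical = raw$chemical, status = ifelse(nd, "nondetect", "detected"),
    concentration = ifelse(nd, NA_real_, value),
    detection_limit = ifelse(nd, value, NA_real_),
    stringsAsFactors = FALSE))
}

# wide dialect -> long rows; empty value cells mean "not analyzed" and are
# dropped
wide_to_long <- function(raw) {
  id_cols <- c("sample_id", "site_id", "date")
  miss <- setdiff(id_cols, names(raw))
  if (length(miss))
    abort("wide monitoring CSV lacks column(s): %s", paste(miss, collapse = ", "))
  vcols <- grep("_value$", names(raw), value = TRUE)
  if (!length(vcols))
    abort("wide monitoring CSV has no <chemical>_value columns")
  chems <- sub("_value$", "", vcols)
  pieces <- lapply(chems, function(ch) {
    val <- raw[[paste0(ch, "_value")]]
    rem <- raw[[paste0(ch, "_remark")]] %||% rep("", nrow(raw))
    keep <- !is.na(val) & nzchar(trimws(val))
    if (!any(keep)) return(NULL)
    data.frame(sample_id = raw$sample_id[keep], site_id = raw$site_id[keep],
               date = raw$date[keep], chemical = ch,
               value_ug_L = val[keep], remark = rem[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) abort("wide monitoring CSV contains no measurements")
  out[order(match(out$sample_id, raw$sample_id)), , drop = FALSE]
}

#' Write a water-sample table as a long-format monitoring CSV
#'
#' Inverse of [read_monitoring_csv()] (long dialect). Numeric values are
#' written with 12 significant digits, so a write/read round trip is
#' lossless to that precision. Rows with status `not_analyzed` are omitted
#' (absence encodes them).
#'
#' @param samples a `water_samples` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_monitoring_csv <- function(samples, path) {
  samples <- water_samples(samples)
  samples <- samples[samples$status != "not_analyzed", , drop = FALSE]
  nd <- samples$status == "nondetect"
  out <- data.frame(
    sample_id = samples$sample_id, site_id = samples$site_id,
    date = format(samples$date, "%Y-%m-%d"), chemical = samples$chemical,
    value_ug_L = format_sig(ifelse(nd, samples$detection_limit,
                                   samples$concentration)),
    remark = ifelse(nd, "<", ""), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

format_sig <- function(x, digits = 12) {
  ifelse(is.na(x), "", formatC(signif(x, digits), digits = digits,
                               format = "g"))
}

#' Write a per-sample metrics table to CSV
#'
#' Full-precision metric columns are written with 12 significant digits;
#' two display columns `mcr_display` and `missed_pct_display` carry the
#' one-decimal reporting convention (half-up rounding).
#'
#' @param metrics a `sample_metrics` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  out <- as.data.frame(metrics)
  for (col in c("hi", "mhq", "mcr", "missed_fraction"))
    out[[col]] <- format_sig(out[[col]])
  out$mcr_display <- ifelse(is.na(metrics$mcr), "",
                            sprintf("%.1f", round_half_up(metrics$mcr, 1)))
  out$missed_pct_display <- ifelse(is.na(metrics$missed_fraction), "",
                                   sprintf("%.1f", round_half_up(100 * metrics$missed_fraction, 1)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample metrics CSV written by [write_metrics_csv()]
#'
#' @param path path to the CSV.
#' @return a `sample_metrics` data.frame.
#' @export
read_metrics_csv <- function(path) {
  if (!file.exists(path)) abort("metrics file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("hi", "mhq", "mcr", "missed_fraction"))
    df[[col]] <- as.numeric(df[[col]])
  df$mcr_display <- NULL
  df$missed_pct_display <- NULL
  class(df) <- c("sample_metrics", "data.frame")
  df
}

#' Read an exposure-scenario key-value config file
#'
#' Plain-text `key = value` lines (comments start with `#`); recognized
#' keys are `ingestion_rate_L_day` and `body_weight_kg`. Missing keys fall
#' back to the defaults of [exposure_scenario()].
#'
#' @param path path to the config file.
#' @return an [exposure_scenario()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort("scenario config not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "[=:]")
  bad <- lengths(kv) != 2L
  if (any(bad))
    abort("malformed config line(s): %s", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals))
    abort("non-numeric config value(s) for: %s", paste(keys[is.na(vals)], collapse = ", "))
  known <- c("ingestion_rate_L_day", "body_weight_kg")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    abort("unknown config key(s): %s", paste(unknown, collapse = ", "))
  args <- list()
  if ("ingestion_rate_L_day" %in% keys)
    args$ingestion_rate <- vals[match("ingestion_rate_L_day", keys)]
  if ("body_weight_kg" %in% keys)
    args$body_weight <- vals[match("body_weight_kg", keys)]
  do.call(exposure_scenario, args)
}
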