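# Metric engine: Hazard Index, maximum Hazard Quotient, Maximum Cumulative
# Ratio and missed-toxicity fraction for one individual's HQ vector.
#
# An HQ vector is a named numeric vector: names are chemical identifiers,
# values are dimensionless hazard quotients (dose / permitted dose). All
# internal arithmetic is at full floating precision; one-decimal display
# values use round_half_up().

#' Construct and validate a hazard-quotient vector
#'
#' An HQ vector holds one individual's (or one water sample's) hazard
#' quotients, one per chemical. Entries must be finite and non-negative and
#' chemical names must be unique. Unnamed input is given placeholder names
#' `chem_1 ... chem_n`.
#'
#' @param hq numeric vector of hazard quotients (dimensionless, >= 0).
#' @param chemicals character vector of chemical names; defaults to
#'   `names(hq)`.
#' @return a named numeric vector, validated.
#' @examples
#' hq_vector(c(atrazine = 0.2, diazinon = 0.05))
#' @export
hq_vector <- function(hq, chemicals = names(hq)) {
  if (length(hq) < 1L)
    abort("an HQ vector must contain at least one entry")
  if (!is.numeric(hq))
    abort("hazard quotients must be numeric")
  force(chemicals)  # before as.numeric() drops the names
  hq <- as.numeric(hq)
  if (is.null(chemicals)) chemicals <- paste0("chem_", seq_along(hq))
  chemicals <- as.character(chemicals)
  if (length(chemicals) != length(hq))
    abort("chemical names and hazard quotients differ in length")
  bad <- !is.finite(hq) | hq < 0
  if (any(bad))
    abort("negative or non-finite hazard quotient for: %s",
          paste(chemicals[bad], collapse = ", "))
  dup <- duplicated(chemicals)
  if (any(dup))
    abort("duplicated chemical in HQ vector: %s",
          paste(unique(chemicals[dup]), collapse = ", "))
  names(hq) <- chemicals
  hq
}

#' Hazard Index of an HQ vector
#'
#' The Hazard Index HI is the sum of the hazard quotients across all
#' chemicals an individual is exposed to -- the dose-additive measure of
#' cumulative toxicity used in Tier 1 mixture screening.
#'
#' @param hqs numeric HQ vector (see [hq_vector()]).
#' @return non-negative number, the sum of all HQs.
#' @examples
#' hazard_index(c(0.6, 0.8, 0.4, 0.5, 0.7)) # 3
#' @export
hazard_index <- function(hqs) {
  sum(hq_vector(hqs))
}

#' Maximum hazard quotient and the chemical attaining it
#'
#' Returns the largest single-chemical HQ (MHQ) together with the name of
#' the chemical attaining it. Ties are broken by taking the alphabetically
#' first tied chemical name; the MHQ value itself is unaffected by ties.
#'
#' @inheritParams hazard_index
#' @return a list with elements `mhq` (non-negative number) and
#'   `chemical` (character).
#' @examples
#' max_hazard_quotient(c(a = 0.6, b = 0.8, c = 0.4))
#' @export
max_hazard_quotient <- function(hqs) {
  hqs <- hq_vector(hqs)
  m <- max(hqs)
  tied <- names(hqs)[hqs == m]
  list(mhq = m, chemical = sort(tied)[1L])
}

#' Maximum Cumulative Ratio
#'
#' MCR = HI / MHQ: the ratio of the cumulative (dose-additive) toxicity to
#' the largest single-chemical toxicity. MCR is bounded below by 1 (one
#' chemical carries all the toxicity) and above by the number of chemicals
#' n (an equitoxic mixture). When every HQ is zero the ratio is undefined;
#' `NA_real_` is returned with a warning, and such records are excluded
#' from downstream summaries rather than coerced.
#'
#' @inheritParams hazard_index
#' @return a number in `[1, n]`, or `NA_real_` when the maximum HQ is zero.
#' @examples
#' mcr(c(0.6, 0.8, 0.4, 0.5, 0.7)) # 3.75, displayed 3.8
#' @export
mcr <- function(hqs) {
  hqs <- hq_vector(hqs)
  m <- max(hqs)
  if (m == 0) {
    warnf("MCR is undefined: all hazard quotients are zero")
    return(NA_real_)
  }
  sum(hqs) / m
}

#' Fraction of cumulative toxicity missed without a cumulative assessment
#'
#' A chemical-by-chemical assessment captures at most the maximum HQ; the
#' missed fraction of the Hazard Index is `1 - 1/MCR`. An MCR of 2 means
#' 50% of the cumulative toxicity would be missed; an MCR of 1.25 means
#' 20%.
#'
#' @param mcr_value numeric vector of MCR values, each >= 1 (NA allowed and
#'   propagated).
#' @return numeric vector in `[0, 1)`.
#' @examples
#' missed_toxicity(2)    # 0.5
#' missed_toxicity(1.25) # 0.2
#' @export
missed_toxicity <- function(mcr_value) {
  if (!is.numeric(mcr_value))
    abort("MCR values must be numeric")
  bad <- !is.na(mcr_value) & (!is.finite(mcr_value) | mcr_value < 1)
  if (any(bad))
    abort("MCR values must be >= 1 (got %s)",
          paste(format(mcr_value[bad]), collapse = ", "))
  1 - 1 / mcr_value
}

#' All per-individual mixture metrics at once
#'
#' Bundles [hazard_index()], [max_hazard_quotient()], [mcr()] and
#' [missed_toxicity()] into a single consistent record. When the maximum HQ
#' is zero, `mcr` and `missed_fraction` are `NA` and `top_chemical` is
#' `NA_character_` (no chemical dominates a zero mixture).
#'
#' @inheritParams hazard_index
#' @return an object of class `individual_metrics`: a list with fields
#'   `hi`, `mhq`, `mcr`, `missed_fraction`, `n` (number of chemicals) and
#'   `top_chemical`.
#' @examples
#' individual_metrics(c(0.6, 0.8, 0.4, 0.5, 0.7))
#' @export
individual_metrics <- function(hqs) {
  hqs <- hq_vector(hqs)
  hi <- sum(hqs)
  mx <- max_hazard_quotient(hqs)
  if (mx$mhq == 0) {
    warnf("MCR is undefined: all hazard quotients are zero")
    out <- list(hi = hi, mhq = 0, mcr = NA_real_,
                missed_fraction = NA_real_, n = length(hqs),
                top_chemical = NA_character_)
  } else {
    mcr_val <- hi / mx$mhq
    out <- list(hi = hi, mhq = mx$mhq, mcr = mcr_val,
                missed_fraction = 1 - 1 / mcr_val, n = length(hqs),
                top_chemical = mx$chemical)
  }
  class(out) <- "individual_metrics"
  out
}

#' @export
print.individual_metrics <- function(x, ...) {
  cat("Mixture metrics for", x$n, "chemicals\n")
  cat(sprintf("  HI  = %.6g\n  MHQ = %.6g (%s)\n", x$hi, x$mhq,
              x$top_chemical %||% NA))
  if (is.na(x$mcr)) {
    cat("  MCR undefined (all hazard quotients zero)\n")
  } else {
    cat(sprintf("  MCR = %.6g (displayed %.1f); missed toxicity = %.1f%%\n",
                x$mcr, round_half_up(x$mcr, 1), 100 * x$missed_fraction))
  }
  invisible(x)
}
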