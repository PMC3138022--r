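# Shared fixtures and independent oracles for the test suite.

# random HQ vector with unique names; guaranteed at least one positive
# entry unless all_zero
random_hq <- function(n, all_zero = FALSE) {
  v <- if (all_zero) rep(0, n) else stats::rlnorm(n, meanlog = -2, sdlog = 2)
  names(v) <- paste0("c", seq_len(n))
  v
}

# tiny in-code permitted-dose table for pipeline tests
tiny_pd <- function() {
  load_permitted_doses(data.frame(
    chemical = c("Alphachem", "Betachem", "Gammachem"),
    pd_mg_kg_day = c(0.001, 0.01, 0.1),
    source_code = c(1L, 2L, 2L)))
}

# build a long-format sample row
mrow <- function(sample_id, chemical, status, conc = NA_real_, dl = NA_real_,
                 site = "siteX", date = as.Date("1998-05-01")) {
  data.frame(sample_id = sample_id, site_id = site, date = date,
             chemical = chemical, status = status, concentration = conc,
             detection_limit = dl, stringsAsFactors = FALSE)
}

# Independent brute-force tau-b oracle: explicit O(n^2) pair enumeration,
# counting concordant/discordant/tied pairs, no reuse of the package code.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- txy <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) txy <- txy + 1
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Independent exact rank-sum oracle: enumerate every subset of pooled
# positions as bitmasks over 2^n, keep those of size na,
# p = P(|W - E| >= |w_obs - E|).
oracle_ranksum_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  e_w <- na * (n + 1) / 2
  masks <- 0:(2^n - 1)
  bits <- vapply(0:(n - 1), function(k) bitwAnd(masks, 2^k) > 0,
                 logical(length(masks)))
  sel <- bits[rowSums(bits) == na, , drop = FALSE]
  ws <- as.vector(sel %*% r)
  mean(abs(ws - e_w) >= abs(w_obs - e_w))
}

# End-to-end flat recomputation of one sample's metrics: inlines policy
# substitution, dose conversion, HQ and the summary formulas without any
# package pipeline code.
oracle_sample_metrics <- function(rows, pd_df, ir, bw, policy) {
  hq <- c(); nm <- c()
  for (i in seq_len(nrow(rows))) {
    pd <- pd_df$pd_mg_kg_day[match(tolower(rows$chemical[i]),
                                   tolower(pd_df$chemical))]
    if (is.na(pd)) next
    st <- rows$status[i]
    if (st == "detected") conc <- rows$concentration[i]
    else if (st == "nondetect") {
      if (policy == "case1_zero") next
      conc <- rows$detection_limit[i] / sqrt(2)
    } else next
    hq <- c(hq, conc * 1e-3 * ir / bw / pd)
    nm <- c(nm, rows$chemical[i])
  }
  if (!length(hq) || max(hq) == 0)
    return(list(hi = NA_real_, mhq = NA_real_, mcr = NA_real_, n = length(hq)))
  list(hi = sum(hq), mhq = max(hq), mcr = sum(hq) / max(hq),
       n = length(hq), top = sort(nm[hq == max(hq)])[1])
}
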