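#' Build a taxon-by-bin range chart
#'
#' Two boolean matrices over taxa x bins: `sampled` (the taxon has an in-bin
#' occurrence) and `range_through` (every bin from the taxon's FAD bin to its
#' LAD bin, gaps filled), plus bin durations. `sampled` is always a subset of
#' `range_through`.
#'
#' @param binned A `binned_occurrences` object (constrained policy).
#' @param rank `"genus"` or `"species"`.
#' @return A `range_chart`: list with `sampled`, `range_through` (logical
#'   matrices, taxa in rows, bins old to young), `durations` (Myr), `scheme`.
#' @export
range_chart <- function(binned, rank = c("genus", "species")) {
  stopifnot(inherits(binned, "binned_occurrences"))
  if (binned$policy != "constrained") stop("range_chart requires constrained binning")
  rank <- match.arg(rank)
  ri <- rank_identity(binned$table, rank)
  tab <- binned$table[ri$keep, , drop = FALSE]
  ids <- ri$id
  taxa <- sort(unique(ids))
  nb <- nrow(binned$scheme)
  sampled <- matrix(FALSE, nrow = length(taxa), ncol = nb,
                    dimnames = list(taxa, binned$scheme$label))
  for (i in seq_along(ids)) sampled[ids[i], tab$bin[i]] <- TRUE
  range_through <- sampled
  for (t in seq_along(taxa)) {
    pres <- which(sampled[t, ])
    if (length(pres)) range_through[t, pres[1L]:pres[length(pres)]] <- TRUE
  }
  structure(list(sampled = sampled, range_through = range_through,
                 durations = bin_durations(binned$scheme), scheme = binned$scheme),
            class = "range_chart")
}

#' Two-timer, three-timer and part-timer counts
#'
#' For each interior bin i: `t2_bot` = taxa sampled in i-1 and i, `t2_top` =
#' sampled in i and i+1, `t3` = sampled in i-1, i and i+1, `pt` = sampled in
#' the flanking bins but not i (part-timers), and the per-bin sampling
#' probability `ps = t3/(t3 + pt)`. Edge bins are undefined.
#'
#' @param chart A [range_chart].
#' @return A `timer_counts` data.frame: `bin`, `t2_bot`, `t2_top`, `t3`,
#'   `pt`, `ps`.
#' @export
timer_counts <- function(chart) {
  stopifnot(inherits(chart, "range_chart"))
  s <- chart$sampled
  nb <- ncol(s)
  if (nb < 3L) stop("timer counts need at least 3 bins")
  t2b <- t2t <- t3 <- pt <- rep(NA_real_, nb)
  for (i in 2L:(nb - 1L)) {
    t2b[i] <- sum(s[, i - 1L] & s[, i])
    t2t[i] <- sum(s[, i] & s[, i + 1L])
    t3[i] <- sum(s[, i - 1L] & s[, i] & s[, i + 1L])
    pt[i] <- sum(s[, i - 1L] & !s[, i] & s[, i + 1L])
  }
  ps <- ifelse(t3 + pt > 0, t3 / (t3 + pt), NA_real_)
  out <- data.frame(bin = colnames(s), t2_bot = t2b, t2_top = t2t, t3 = t3,
                    pt = pt, ps = ps, stringsAsFactors = FALSE)
  class(out) <- c("timer_counts", "data.frame")
  out
}

rate_series <- function(scheme_labels, mu, lambda, method, clamped_mu, clamped_lambda,
                        per_myr = FALSE) {
  out <- data.frame(bin = scheme_labels, mu = mu, lambda = lambda,
                    mu_clamped = clamped_mu, lambda_clamped = clamped_lambda,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "per_myr") <- per_myr
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Three-timer extinction and origination rates
#'
#' Sampling-corrected per-taxon, per-interval rates. Extinction:
#' `mu(i) = ln(t2_bot(i)/t3(i)) + ln(ps(i+1))`; origination:
#' `lambda(i) = ln(t2_top(i)/t3(i)) + ln(ps(i-1))` — the log ratio of
#' consecutive-bin cohort survival corrected for the chance that a lineage
#' present in the adjacent bin simply went unsampled there. With
#' `ps_mode = "pooled"` the correction uses the sampling probability pooled
#' over all interior bins rather than the adjacent bin's. Rates are
#' undefined where any needed count is zero or the correction term is
#' undefined; negative estimates (possible from the log correction) are
#' clamped to zero and flagged.
#'
#' @param tc A [timer_counts] table.
#' @param ps_mode `"adjacent"` (default) or `"pooled"`.
#' @return A `rate_series` data.frame: `bin`, `mu`, `lambda`, clamping
#'   flags.
#' @export
three_timer_rates <- function(tc, ps_mode = c("adjacent", "pooled")) {
  stopifnot(inherits(tc, "timer_counts"))
  ps_mode <- match.arg(ps_mode)
  nb <- nrow(tc)
  ps_pooled <- if (sum(tc$t3, na.rm = TRUE) + sum(tc$pt, na.rm = TRUE) > 0) {
    sum(tc$t3, na.rm = TRUE) / (sum(tc$t3, na.rm = TRUE) + sum(tc$pt, na.rm = TRUE))
  } else NA_real_
  mu <- lambda <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    ps_next <- if (ps_mode == "pooled") ps_pooled else if (i < nb) tc$ps[i + 1L] else NA_real_
    ps_prev <- if (ps_mode == "pooled") ps_pooled else if (i > 1L) tc$ps[i - 1L] else NA_real_
    if (!is.na(tc$t2_bot[i]) && !is.na(tc$t3[i]) && tc$t2_bot[i] > 0 &&
        tc$t3[i] > 0 && !is.na(ps_next) && ps_next > 0) {
      mu[i] <- log(tc$t2_bot[i] / tc$t3[i]) + log(ps_next)
    }
    if (!is.na(tc$t2_top[i]) && !is.na(tc$t3[i]) && tc$t2_top[i] > 0 &&
        tc$t3[i] > 0 && !is.na(ps_prev) && ps_prev > 0) {
      lambda[i] <- log(tc$t2_top[i] / tc$t3[i]) + log(ps_prev)
    }
  }
  cm <- !is.na(mu) & mu < 0
  cl <- !is.na(lambda) & lambda < 0
  mu[cm] <- 0
  lambda[cl] <- 0
  rate_series(tc$bin, mu, lambda, "three_timer", cm, cl)
}

#' Boundary-crosser (per-capita) extinction and origination rates
#'
#' The conservative range-based rates: with `N_bt` the taxa whose
#' range-through crosses both boundaries of bin i, `N_bL` those crossing the
#' bottom boundary and ending within the bin, and `N_Ft` those starting
#' within and crossing the top, extinction is `q(i) = -ln(N_bt/(N_bt+N_bL))`
#' and origination `p(i) = -ln(N_bt/(N_bt+N_Ft))`. Single-interval taxa are
#' ignored, and the fossil record is taken literally (no sampling
#' correction), so these rates back-smear extinctions under incomplete
#' sampling. With `per_myr = TRUE` rates are divided by bin duration —
#' recommended when bins are of unequal length.
#'
#' @param chart A [range_chart].
#' @param per_myr Normalise by bin duration (Myr).
#' @return A `rate_series` data.frame with `mu` (= q) and `lambda` (= p),
#'   plus the underlying counts `n_bt`, `n_bl`, `n_ft`.
#' @export
foote_rates <- function(chart, per_myr = FALSE) {
  stopifnot(inherits(chart, "range_chart"))
  rt <- chart$range_through
  nb <- ncol(rt)
  first <- apply(rt, 1L, function(z) which(z)[1L])
  last <- apply(rt, 1L, function(z) { w <- which(z); w[length(w)] })
  q <- p <- rep(NA_real_, nb)
  n_bt <- n_bl <- n_ft <- rep(NA_integer_, nb)
  for (i in seq_len(nb)) {
    n_bt[i] <- sum(first < i & last > i)
    n_bl[i] <- sum(first < i & last == i)
    n_ft[i] <- sum(first == i & last > i)
    if (n_bt[i] > 0) {
      q[i] <- -log(n_bt[i] / (n_bt[i] + n_bl[i]))
      p[i] <- -log(n_bt[i] / (n_bt[i] + n_ft[i]))
    }
  }
  if (per_myr) {
    q <- q / chart$durations
    p <- p / chart$durations
  }
  out <- rate_series(colnames(rt), q, p, "foote", rep(FALSE, nb), rep(FALSE, nb),
                     per_myr = per_myr)
  out$n_bt <- n_bt
  out$n_bl <- n_bl
  out$n_ft <- n_ft
  out
}
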