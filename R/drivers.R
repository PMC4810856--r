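#' First-order autoregressive detrending
#'
#' Fits `x_t = c + phi * x_{t-1} + e_t` by Gaussian maximum likelihood
#' conditional on the first observation (equivalent to least squares on the
#' lagged pairs) and returns the residual series. Detrending the covariates
#' this way removes the serial correlation that would otherwise inflate
#' apparent correlations between slowly varying time series. The first
#' value's residual is undefined, as is any residual whose pair contains a
#' missing value. A constant series has no identifiable phi: residuals are
#' returned as all zero with `constant = TRUE`.
#'
#' @param x Numeric series ordered old to young; may contain `NA`.
#' @return List with `residuals` (same length as `x`), `phi`, `intercept`,
#'   `sigma2` (ML residual variance), `n` (pairs used), `constant`.
#' @export
ar1_residuals <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  res <- rep(NA_real_, n)
  if (n < 2L) return(list(residuals = res, phi = NA_real_, intercept = NA_real_,
                          sigma2 = NA_real_, n = 0L, constant = FALSE))
  x0 <- x[-n]
  x1 <- x[-1L]
  ok <- !is.na(x0) & !is.na(x1)
  if (sum(ok) < 3L) stop("ar1_residuals needs at least 4 non-missing consecutive values")
  if (stats::sd(x[!is.na(x)]) == 0) {
    res[which(ok) + 1L] <- 0
    return(list(residuals = res, phi = NA_real_, intercept = x[!is.na(x)][1L],
                sigma2 = 0, n = sum(ok), constant = TRUE))
  }
  fit <- stats::lm(x1 ~ x0, subset = ok)
  co <- stats::coef(fit)
  e <- x1 - (co[1L] + co[2L] * x0)
  res[-1L] <- e
  list(residuals = res, phi = unname(co[2L]), intercept = unname(co[1L]),
       sigma2 = sum(e[ok]^2) / sum(ok), n = sum(ok), constant = FALSE)
}

aicc <- function(logL, k, n) -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)

#' Akaike weights from AICc values
#'
#' `w_i = exp(-dAICc_i / 2) / sum_j exp(-dAICc_j / 2)`, the relative support
#' for each candidate in a set; weights sum to one.
#'
#' @param aicc_values Numeric vector of AICc (or AIC) values.
#' @return Numeric vector of weights.
#' @examples
#' akaike_weights(c(100, 102)) # ~0.731, 0.269
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit and compare driver models by AICc
#'
#' Regresses a biodiversity series on candidate environmental predictors by
#' maximum-likelihood Gaussian linear models and ranks the candidates with
#' the small-sample Akaike information criterion,
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`, where `k` counts the intercept,
#' the slopes and the residual variance. Candidates are the intercept-only
#' null, every single predictor and (when `combos = 2`) every pair. Akaike
#' weights `w_i = exp(-dAICc_i/2) / sum_j exp(-dAICc_j/2)` sum to one over
#' the candidate set. Predictors are AR1-detrended first (see
#' [ar1_residuals()]); the response is used as-is unless
#' `detrend_response = TRUE`. Bins where the response is undefined are
#' dropped listwise per candidate, so `n` can differ between rows and is
#' reported per row; candidates with `n <= k + 1` are skipped with a
#' warning.
#'
#' @param response Numeric response series, or a `diversity_series` (its
#'   `value` column is used).
#' @param predictors Named list (or data.frame) of numeric predictor series
#'   aligned to the same bins.
#' @param combos Maximum number of predictors per candidate model (1 or 2).
#' @param detrend Apply AR1 detrending to the predictors (default TRUE).
#' @param detrend_response Also detrend the response (sensitivity runs).
#' @param include_null Include the intercept-only candidate (default TRUE).
#' @return A `model_table` data.frame: `model`, `n`, `k`, `logL`, `AICc`,
#'   `dAICc`, `weight`, `slope` (first slope; both slopes retained in
#'   `slopes` attribute for pairs).
#' @export
fit_models <- function(response, predictors, combos = 2L, detrend = TRUE,
                       detrend_response = FALSE, include_null = TRUE) {
  if (inherits(response, "diversity_series")) response <- response$value
  y <- as.numeric(response)
  if (detrend_response) y <- ar1_residuals(y)$residuals
  preds <- as.list(predictors)
  if (is.null(names(preds)) || any(!nzchar(names(preds)))) {
    stop("predictors must be named")
  }
  if (detrend) preds <- lapply(preds, function(p) ar1_residuals(as.numeric(p))$residuals)
  cand <- if (include_null) list(character(0)) else list()
  cand <- c(cand, lapply(names(preds), identity))
  if (combos >= 2L && length(preds) >= 2L) {
    prs <- utils::combn(names(preds), 2L, simplify = FALSE)
    cand <- c(cand, prs)
  }
  rows <- list()
  slopes <- list()
  for (cc in cand) {
    dat <- data.frame(y = y)
    for (p in cc) dat[[p]] <- preds[[p]]
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    n <- nrow(dat)
    k <- length(cc) + 2L # intercept + slopes + residual variance
    if (n <= k + 1L) {
      warning("candidate {", paste(cc, collapse = "+"),
              "} skipped: n = ", n, " too small for k = ", k)
      next
    }
    fml <- if (length(cc)) stats::as.formula(paste("y ~", paste(cc, collapse = " + ")))
           else stats::as.formula("y ~ 1")
    fit <- stats::lm(fml, data = dat)
    ll <- as.numeric(stats::logLik(fit))
    label <- if (length(cc)) paste(cc, collapse = " + ") else "(null)"
    sl <- if (length(cc)) stats::coef(fit)[-1L] else numeric(0)
    slopes[[label]] <- sl
    rows[[label]] <- data.frame(
      model = label, n = n, k = k, logL = ll, AICc = aicc(ll, k, n),
      slope = if (length(sl)) unname(sl[1L]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no candidate model could be fitted")
  out <- do.call(rbind, rows)
  out$dAICc <- out$AICc - min(out$AICc)
  out$weight <- akaike_weights(out$AICc)
  out <- out[order(out$AICc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "slopes") <- slopes
  class(out) <- c("model_table", "data.frame")
  out
}

#' Correlation tests between a biodiversity series and a covariate
#'
#' Pearson's r (t-distribution p-value) and Spearman's rho on
#' pairwise-complete data.
#'
#' @param response,predictor Numeric series aligned to the same bins.
#' @return List with `r`, `p_r`, `rho`, `p_rho`, `n`, and `degenerate`
#'   (TRUE when either series has zero variance, in which case the
#'   statistics are `NA`).
#' @export
correlate <- function(response, predictor) {
  if (inherits(response, "diversity_series")) response <- response$value
  ok <- !is.na(response) & !is.na(predictor)
  x <- as.numeric(predictor)[ok]
  y <- as.numeric(response)[ok]
  n <- length(x)
  if (n < 3L) stop("correlate needs at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_r = NA_real_, rho = NA_real_, p_rho = NA_real_,
                n = n, degenerate = TRUE))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(r = unname(pe$estimate), p_r = pe$p.value,
       rho = unname(sp$estimate), p_rho = sp$p.value, n = n, degenerate = FALSE)
}

#' Summary table of driver fits across biodiversity metrics
#'
#' One row per (biodiversity metric, predictor): the single-predictor
#' model's log-likelihood and Akaike weight (weights taken from a candidate
#' set that also includes the null and, optionally, predictor pairs),
#' Spearman's and Pearson's correlations with p-values, and a `strong` flag
#' marking results where that predictor carries the highest weight in its
#' candidate set and both correlation p-values fall below `p_cut`.
#'
#' @param responses Named list of response series (numeric or
#'   `diversity_series`).
#' @param predictors Named list of predictor series.
#' @param combos Passed to [fit_models()].
#' @param detrend Passed to [fit_models()].
#' @param p_cut Significance gate for the `strong` flag (default 0.05).
#' @return A data.frame mirroring a drivers summary table: `metric`,
#'   `parameter`, `logL`, `weight`, `rho`, `p_rho`, `r`, `p_r`, `n`,
#'   `strong`.
#' @export
driver_report <- function(responses, predictors, combos = 1L, detrend = TRUE,
                          p_cut = 0.05) {
  if (!length(predictors)) {
    return(data.frame(metric = character(0), parameter = character(0),
                      logL = numeric(0), weight = numeric(0), rho = numeric(0),
                      p_rho = numeric(0), r = numeric(0), p_r = numeric(0),
                      n = integer(0), strong = logical(0)))
  }
  pred_detr <- if (detrend) lapply(predictors, function(p) ar1_residuals(as.numeric(p))$residuals)
               else lapply(predictors, as.numeric)
  rows <- list()
  for (m in names(responses)) {
    mt <- fit_models(responses[[m]], predictors, combos = combos, detrend = detrend)
    top <- mt$model[which.max(mt$weight)]
    for (p in names(predictors)) {
      ct <- correlate(responses[[m]], pred_detr[[p]])
      row_i <- match(p, mt$model)
      rows[[paste(m, p)]] <- data.frame(
        metric = m, parameter = p,
        logL = if (is.na(row_i)) NA_real_ else mt$logL[row_i],
        weight = if (is.na(row_i)) NA_real_ else mt$weight[row_i],
        rho = ct$rho, p_rho = ct$p_rho, r = ct$r, p_r = ct$p_r, n = ct$n,
        strong = identical(top, p) && !is.na(ct$p_rho) && !is.na(ct$p_r) &&
          ct$p_rho < p_cut && ct$p_r < p_cut,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(metric = character(0), parameter = character(0),
                      logL = numeric(0), weight = numeric(0), rho = numeric(0),
                      p_rho = numeric(0), r = numeric(0), p_r = numeric(0),
                      n = integer(0), strong = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an environmental covariate series aligned to a bin scheme
#'
#' Accepts a CSV with either a `bin` column of bin labels or an `age` column
#' of midpoint/boundary ages (Ma), plus a `value` column. Age-keyed rows are
#' assigned to bins by [bin_of_age()]; multiple rows per bin are averaged.
#'
#' @param path CSV file path.
#' @param scheme A [bin_scheme].
#' @return Numeric vector of per-bin values (NA where no data), named by bin
#'   label.
#' @export
read_env_series <- function(path, scheme) {
  if (!file.exists(path)) stop("environmental series file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"value" %in% names(df)) stop("environmental series needs a 'value' column")
  out <- stats::setNames(rep(NA_real_, nrow(scheme)), scheme$label)
  if ("bin" %in% names(df)) {
    idx <- match(df$bin, scheme$label)
  } else if ("age" %in% names(df)) {
    idx <- bin_of_age(scheme, as.numeric(df$age))
  } else {
    stop("environmental series needs a 'bin' or 'age' column")
  }
  ok <- !is.na(idx)
  agg <- tapply(as.numeric(df$value)[ok], idx[ok], mean)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}
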