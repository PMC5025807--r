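#' Rebin a stage-resolution series onto a coarser bin scheme
#'
#' Takes the unweighted arithmetic mean of source points whose midpoint
#' ages fall inside each target bin (closed intervals; a midpoint exactly
#' on a shared boundary goes to the older bin). Target bins with no
#' source points get `NA`.
#'
#' @param series Data frame with columns `midpoint_ma` and `value`.
#' @param scheme Target `bin_scheme`.
#' @return Data frame: `bin`, `name`, `value` aligned to `scheme`.
#' @export
rebin_series <- function(series, scheme) {
  stopifnot(is.data.frame(series),
            all(c("midpoint_ma", "value") %in% names(series)),
            inherits(scheme, "bin_scheme"))
  tol <- 1e-9
  mids <- as.numeric(series$midpoint_ma)
  vals <- as.numeric(series$value)
  idx <- rep(NA_integer_, length(mids))
  for (i in seq_len(nrow(scheme))) {
    hit <- is.na(idx) & !is.na(mids) &
      mids <= scheme$base_ma[i] + tol & mids >= scheme$top_ma[i] - tol
    idx[hit] <- i
  }
  value <- vapply(seq_len(nrow(scheme)), function(i) {
    v <- vals[!is.na(idx) & idx == i & !is.na(vals)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  data.frame(bin = seq_len(nrow(scheme)), name = scheme$name,
             value = value, stringsAsFactors = FALSE)
}

.as_series <- function(x) {
  if (is.data.frame(x)) {
    for (col in c("mean", "value")) {
      if (col %in% names(x)) return(as.numeric(x[[col]]))
    }
    stop("series data frame needs a 'value' or 'mean' column", call. = FALSE)
  }
  as.numeric(x)
}

#' Maximum-likelihood AR(1) detrending with missing values
#'
#' Fits a first-order autoregressive model with intercept by maximum
#' likelihood (`stats::arima`, which handles internal `NA`s through the
#' Kalman filter rather than treating them as zeros) and returns the
#' innovation residuals at observed points. Removes long-term background
#' trend and serial autocorrelation before correlation/regression, which
#' otherwise inflate coefficients.
#'
#' @param x Numeric per-bin series (`NA` allowed), or a curve data frame
#'   with a `value`/`mean` column.
#' @return An `ar1_fit` list: `phi`, `intercept`, `sigma2`, `residuals`
#'   (`NA` exactly where the input is `NA`), `n_obs`.
#' @export
detrend_ar1 <- function(x) {
  x <- .as_series(x)
  obs <- !is.na(x)
  n_obs <- sum(obs)
  if (n_obs < 4L) {
    stop("insufficient data: AR(1) fit needs at least 4 observed points",
         call. = FALSE)
  }
  if (stats::sd(x[obs]) < 1e-12) {
    res <- rep(NA_real_, length(x))
    res[obs] <- 0
    fit <- list(phi = 0, intercept = mean(x[obs]), sigma2 = 0,
                residuals = res, n_obs = n_obs)
    class(fit) <- "ar1_fit"
    return(fit)
  }
  fit_ml <- function(...) {
    stats::arima(x, order = c(1L, 0L, 0L), include.mean = TRUE,
                 method = "ML", ...)
  }
  # near-unit-root series can leave the ML Hessian singular; refitting
  # without the stationarity transform is the standard workaround
  m <- tryCatch(fit_ml(), error = function(e) fit_ml(transform.pars = FALSE))
  if (abs(m$coef["ar1"]) >= 1) {
    m <- stats::arima(x, order = c(1L, 0L, 0L), include.mean = TRUE,
                      method = "CSS-ML")
  }
  res <- as.numeric(stats::residuals(m))
  res[!obs] <- NA_real_
  fit <- list(phi = unname(m$coef["ar1"]),
              intercept = unname(m$coef["intercept"]),
              sigma2 = m$sigma2, residuals = res, n_obs = n_obs,
              model = m)
  class(fit) <- "ar1_fit"
  fit
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`. `NA` entries are excluded from the
#' normalization and returned as `NA`. Weights are invariant to adding a
#' constant to all AICc values.
#'
#' @param aicc Numeric vector of AICc values.
#' @return List with `delta`, `rel_likelihood` (`exp(-Delta/2)`) and
#'   `weight`.
#' @export
akaike_weights <- function(aicc) {
  delta <- aicc - min(aicc, na.rm = TRUE)
  rl <- exp(-delta / 2)
  list(delta = delta, rel_likelihood = rl,
       weight = rl / sum(rl, na.rm = TRUE))
}

.aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare environmental driver models for a diversity curve
#'
#' Detrends the response and each candidate driver with
#' [detrend_ar1()], regresses response residuals on driver residuals
#' (OLS) over jointly observed bins, and ranks drivers by AICc with
#' `k = 3` parameters (intercept, slope, residual variance). Drivers with
#' fewer than `min_n` joint observations (or too few points to detrend)
#' are reported `NA` and excluded from weight normalization; Akaike
#' weights sum to 1 over the remaining candidate set.
#'
#' @param response Per-bin response series (numeric, or an `sqs_estimate`
#'   / `diversity_curve` whose `mean`/`value` column is used).
#' @param drivers Named list (or data frame) of per-bin driver series
#'   aligned to the response.
#' @param min_n Minimum joint observations (default 5, so `n - k - 1 > 0`).
#' @return A `driver_model_set` data frame: `driver`, `n`, `slope`,
#'   `slope_se`, `log_lik`, `aicc`, `delta_aicc`, `rel_likelihood`,
#'   `weight`.
#' @export
compare_driver_models <- function(response, drivers, min_n = 5L) {
  y_res <- detrend_ar1(response)$residuals
  drivers <- .driver_list(drivers, length(y_res))
  k <- 3L
  fit_one <- function(x) {
    out <- list(n = NA_integer_, slope = NA_real_, slope_se = NA_real_,
                log_lik = NA_real_, aicc = NA_real_)
    x_res <- tryCatch(detrend_ar1(x)$residuals, error = function(e) NULL)
    if (is.null(x_res)) return(out)
    idx <- !is.na(y_res) & !is.na(x_res)
    out$n <- sum(idx)
    if (out$n < min_n) return(out)
    fit <- stats::lm(y_res[idx] ~ x_res[idx])
    cf <- summary(fit)$coefficients
    out$slope <- cf[2L, 1L]
    out$slope_se <- cf[2L, 2L]
    out$log_lik <- as.numeric(stats::logLik(fit))
    out$aicc <- .aicc(out$log_lik, k, out$n)
    out
  }
  rows <- lapply(drivers, fit_one)
  aicc <- vapply(rows, `[[`, numeric(1), "aicc")
  if (all(is.na(aicc))) {
    warning("all drivers have insufficient data; empty model set",
            call. = FALSE)
    w <- list(delta = aicc, rel_likelihood = aicc, weight = aicc)
  } else {
    w <- akaike_weights(aicc)
  }
  out <- data.frame(
    driver = names(drivers),
    n = vapply(rows, `[[`, integer(1), "n"),
    slope = vapply(rows, `[[`, numeric(1), "slope"),
    slope_se = vapply(rows, `[[`, numeric(1), "slope_se"),
    k = k,
    log_lik = vapply(rows, `[[`, numeric(1), "log_lik"),
    aicc = aicc,
    delta_aicc = w$delta,
    rel_likelihood = w$rel_likelihood,
    weight = w$weight,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("driver_model_set", "data.frame")
  out
}

.driver_list <- function(drivers, n) {
  if (is.data.frame(drivers)) {
    keep <- vapply(drivers, is.numeric, logical(1))
    drop <- intersect(names(drivers), c("bin", "base_ma", "top_ma"))
    drivers <- as.list(drivers[setdiff(names(drivers)[keep], drop)])
  }
  stopifnot(is.list(drivers), length(drivers) >= 1L)
  if (is.null(names(drivers)) || any(names(drivers) == "")) {
    stop("drivers must be named", call. = FALSE)
  }
  lapply(drivers, function(x) {
    x <- .as_series(x)
    if (length(x) != n) {
      stop("driver series must align with the response (same bin scheme)",
           call. = FALSE)
    }
    x
  })
}

#' Pairwise correlation tests with Benjamini-Hochberg adjustment
#'
#' Pearson's r and Spearman's rho between the AR(1) residuals of the
#' response and of each driver, over jointly observed bins. Raw p-values
#' are BH-adjusted (`stats::p.adjust`, method "BH") within each family of
#' tests; by default all tests against one response curve form one family.
#'
#' @param response Per-bin response series (as in
#'   [compare_driver_models()]).
#' @param drivers Named list or data frame of per-bin driver series.
#' @param family Character vector assigning each driver to a family
#'   (recycled); default one family, labelled by `family_label`.
#' @param family_label Label used for the default single family.
#' @return Data frame: `driver`, `family`, `n`, `pearson_r`, `pearson_p`,
#'   `pearson_p_adj`, `spearman_rho`, `spearman_p`, `spearman_p_adj`.
#'   Statistics are `NA` when fewer than 3 joint observations exist.
#' @export
correlation_tests <- function(response, drivers, family = NULL,
                              family_label = "response") {
  y_res <- detrend_ar1(response)$residuals
  drivers <- .driver_list(drivers, length(y_res))
  nd <- length(drivers)
  if (is.null(family)) family <- rep(family_label, nd)
  family <- rep_len(as.character(family), nd)
  one <- function(x) {
    out <- c(n = NA_real_, pearson_r = NA_real_, pearson_p = NA_real_,
             spearman_rho = NA_real_, spearman_p = NA_real_)
    x_res <- tryCatch(detrend_ar1(x)$residuals, error = function(e) NULL)
    if (is.null(x_res)) return(out)
    idx <- !is.na(y_res) & !is.na(x_res)
    out["n"] <- sum(idx)
    if (out["n"] < 3) return(out)
    pe <- stats::cor.test(y_res[idx], x_res[idx], method = "pearson")
    sp <- suppressWarnings(
      stats::cor.test(y_res[idx], x_res[idx], method = "spearman",
                      exact = FALSE))
    out["pearson_r"] <- unname(pe$estimate)
    out["pearson_p"] <- pe$p.value
    out["spearman_rho"] <- unname(sp$estimate)
    out["spearman_p"] <- sp$p.value
    out
  }
  m <- t(vapply(drivers, one, numeric(5)))
  out <- data.frame(
    driver = names(drivers), family = family,
    n = as.integer(m[, "n"]),
    pearson_r = m[, "pearson_r"], pearson_p = m[, "pearson_p"],
    pearson_p_adj = NA_real_,
    spearman_rho = m[, "spearman_rho"], spearman_p = m[, "spearman_p"],
    spearman_p_adj = NA_real_,
    stringsAsFactors = FALSE
  )
  for (fam in unique(family)) {
    sel <- out$family == fam
    out$pearson_p_adj[sel] <- stats::p.adjust(out$pearson_p[sel],
                                              method = "BH")
    out$spearman_p_adj[sel] <- stats::p.adjust(out$spearman_p[sel],
                                               method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Read environmental series from a long-format CSV
#'
#' Expects columns `series_name`, `midpoint_ma`, `value` (optional
#' `units`). Returns a named list of data frames suitable for
#' [rebin_series()].
#'
#' @param path CSV file path.
#' @return Named list of data frames (`midpoint_ma`, `value`).
#' @export
read_driver_series <- function(path) {
  if (!file.exists(path)) {
    stop("configuration error: driver series file not found: ", path,
         call. = FALSE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_name", "midpoint_ma", "value")
  if (!all(need %in% names(x))) {
    stop("format error: driver CSV must have columns series_name, midpoint_ma, value",
         call. = FALSE)
  }
  split(x[c("midpoint_ma", "value")], x$series_name)
}
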