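#' Moving-average forecast of age-class abundances
#'
#' Projects the standing age structure forward with the moving-average time
#' series model: for a prediction time of n age classes, the forecast size of
#' class t is the mean of the observed counts over the n classes ending at t,
#' `M_t = (1/n) * sum_{k = t-n+1}^{t} X_k`. The forecast is defined only for
#' `t >= n` (earlier windows would reach before the first class); undefined
#' entries are reported `NA`, never zero-filled. `n = 1` reproduces the
#' observation.
#'
#' @param X observed age-class abundances (an `age_distribution` or
#'   non-negative numeric vector).
#' @param horizons prediction times n, each between 1 and `length(X)`
#'   (default `c(2, 4, 6, 8)`, truncated to the class count).
#' @return A `forecast_table` data frame: one row per age class t, the
#'   observed counts, and one `M<n>` column per horizon.
#' @examples
#' time_series_forecast(c(1700, 1600, 1600, 1400, 700, 300, 300, 100))
#' @export
time_series_forecast <- function(X, horizons = c(2, 4, 6, 8)) {
  X <- as.numeric(X)
  k <- length(X)
  if (k < 1) stop("`X` is empty", call. = FALSE)
  if (any(!is.finite(X)) || any(X < 0))
    stop("`X` must be finite and non-negative", call. = FALSE)
  if (any(horizons < 1) || any(horizons != round(horizons)))
    stop("horizons must be integers >= 1", call. = FALSE)
  if (any(horizons > k))
    stop(sprintf("horizon %d exceeds the number of age classes (%d)",
                 max(horizons), k), call. = FALSE)
  out <- data.frame(age_class = seq_len(k), observed = X)
  csum <- c(0, cumsum(X))
  for (n in horizons) {
    m <- rep(NA_real_, k)
    t_ <- n:k
    m[t_] <- (csum[t_ + 1] - csum[t_ - n + 1]) / n
    out[[paste0("M", n)]] <- m
  }
  structure(out, horizons = as.integer(horizons),
            class = c("forecast_table", "data.frame"))
}

#' @export
print.forecast_table <- function(x, digits = 2, ...) {
  cat("Moving-average age-class forecast (horizons",
      paste(attr(x, "horizons"), collapse = ", "), "classes)\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE, na.print = "-")
  invisible(x)
}
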