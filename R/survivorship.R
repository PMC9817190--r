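#' Fit a survivorship curve to standardised survivor numbers
#'
#' Fits one of the two classical survivorship models of Hett & Loucks to the
#' standardised survivors `l_x` of a static life table:
#' \describe{
#'   \item{exponential}{`N_x = N0 * exp(-b x)` — constant mortality rate,
#'     a straight line of `ln l_x` against `x` (Deevey type II).}
#'   \item{power}{`N_x = N0 * x^(-b)` — mortality concentrated early,
#'     a straight line of `ln l_x` against `ln x` (Deevey type III).}
#' }
#' Both are estimated by ordinary least squares on the log scale, i.e.
#' regressing `ln l_x` on `x` (or `ln x`); `b` is minus the slope and `N0`
#' the exponentiated intercept. `r.squared` is the coefficient of
#' determination of that log-scale regression and the model F statistic is
#' `(n - 2) R^2 / (1 - R^2)`.
#'
#' @param lx positive survivor numbers per age class (e.g. the `l` column of
#'   a [static_life_table()], or a whole `life_table`).
#' @param x age-class indices (default `1, 2, ...`); must be >= 1 for the
#'   power model.
#' @param model `"exponential"` or `"power"`.
#' @return An object of class `survivorship_fit` with components `model`,
#'   `N0`, `b`, `r.squared`, `f.statistic`, `fitted` (original scale),
#'   `data`, and the underlying log-scale `lm` fit. Supports `print()`,
#'   `summary()`, `coef()`, `fitted()`, `residuals()` (log scale),
#'   `predict()` and `plot()`.
#' @examples
#' lt <- static_life_table(c(1700, 1600, 1600, 1400, 700, 300, 300, 100))
#' fit <- fit_survivorship(lt)
#' coef(fit) # N0 ~ 2408, b ~ 0.404
#' @export
fit_survivorship <- function(lx, x = seq_along(lx),
                             model = c("exponential", "power")) {
  model <- match.arg(model)
  if (inherits(lx, "life_table")) lx <- lx$l
  lx <- as.numeric(lx)
  if (length(lx) < 3)
    stop("need at least 3 age classes to fit a survivorship curve",
         call. = FALSE)
  if (length(x) != length(lx)) stop("`x` and `lx` lengths differ", call. = FALSE)
  if (any(!is.finite(lx)) || any(lx <= 0))
    stop("all survivor numbers must be positive (log scale fit)", call. = FALSE)
  if (model == "power" && any(x < 1))
    stop("power model needs age-class indices >= 1", call. = FALSE)
  predictor <- if (model == "exponential") x else log(x)
  fit <- stats::lm(log(lx) ~ predictor)
  # R^2 computed directly so an exact fit stays exactly 1 (summary.lm warns)
  tss <- sum((log(lx) - mean(log(lx)))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NaN
  n <- length(lx)
  structure(
    list(model = model,
         N0 = exp(unname(stats::coef(fit)[1])),
         b = -unname(stats::coef(fit)[2]),
         r.squared = r2,
         f.statistic = (n - 2) * r2 / (1 - r2),
         n = n,
         data = data.frame(x = x, lx = lx),
         fitted = exp(stats::fitted(fit)),
         lm = fit),
    class = "survivorship_fit")
}

#' @export
print.survivorship_fit <- function(x, digits = 4, ...) {
  form <- if (x$model == "exponential") "N0 * exp(-b x)" else "N0 * x^-b"
  cat(sprintf("Survivorship curve: %s model  l_x = %s\n", x$model, form))
  cat(sprintf("  N0 = %.*g   b = %.*g   R^2 = %.*g   F = %.*g  (n = %d)\n",
              digits + 1, x$N0, digits, x$b, digits, x$r.squared,
              digits, x$f.statistic, x$n))
  invisible(x)
}

#' @export
coef.survivorship_fit <- function(object, ...) {
  c(N0 = object$N0, b = object$b)
}

#' @export
fitted.survivorship_fit <- function(object, ...) object$fitted

#' @export
residuals.survivorship_fit <- function(object, ...) {
  stats::residuals(object$lm)
}

#' @export
predict.survivorship_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  if (object$model == "exponential") object$N0 * exp(-object$b * x)
  else object$N0 * x^(-object$b)
}

#' @export
summary.survivorship_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.survivorship_fit")
}

#' @export
print.summary.survivorship_fit <- function(x, ...) {
  print(x$fit)
  cat("log-scale regression:\n")
  print(stats::coef(x$lm_summary))
  invisible(x)
}

#' @export
plot.survivorship_fit <- function(x, ...) {
  plot(x$data$x, log(x$data$lx), xlab = "age class x",
       ylab = "ln l_x", pch = 19, ...)
  xs <- seq(min(x$data$x), max(x$data$x), length.out = 100)
  graphics::lines(xs, log(predict(x, xs)))
  invisible(x)
}

#' Choose the better survivorship model and its Deevey type
#'
#' Compares exponential and power fits to the same survivor series by the
#' coefficient of determination (equivalently, by the one-predictor F value,
#' which is monotone in R^2): a winning exponential model means a log-linear
#' curve, Deevey type II (constant mortality); a winning power model means a
#' downward-concave curve, Deevey type III (heavy early mortality). Ties go
#' to the exponential model. Type I (late mortality) is outside the
#' two-model scheme; a log-scale concavity diagnostic (sign of the quadratic
#' coefficient of `ln l_x` on `x`) is reported for information only.
#'
#' @param fit_exponential,fit_power `survivorship_fit` objects on the same
#'   data, or pass `lx` to fit both here.
#' @param lx optional survivor series; when given, both models are fitted
#'   internally and the fit arguments are ignored.
#' @param x age-class indices when `lx` is given.
#' @return A `deevey_classification` with the winning model, Deevey type,
#'   both R^2 values and the concavity diagnostic.
#' @export
classify_deevey <- function(fit_exponential = NULL, fit_power = NULL,
                            lx = NULL, x = seq_along(lx)) {
  if (!is.null(lx)) {
    if (inherits(lx, "life_table")) lx <- lx$l
    fit_exponential <- fit_survivorship(lx, x, "exponential")
    fit_power <- fit_survivorship(lx, x, "power")
  }
  stopifnot(inherits(fit_exponential, "survivorship_fit"),
            inherits(fit_power, "survivorship_fit"))
  if (fit_exponential$model != "exponential" || fit_power$model != "power")
    stop("pass the exponential fit first and the power fit second",
         call. = FALSE)
  if (fit_exponential$n != fit_power$n ||
      !isTRUE(all.equal(fit_exponential$data$lx, fit_power$data$lx)))
    stop("the two fits are not on the same data", call. = FALSE)
  # ties (including degenerate flat series, where R^2 is undefined) resolve
  # to the exponential model
  best <- if (isTRUE(fit_power$r.squared > fit_exponential$r.squared)) "power"
          else "exponential"
  d <- fit_exponential$data
  quad <- stats::lm(log(lx) ~ x + I(x^2), data = d)
  structure(
    list(best_model = best,
         deevey_type = if (best == "exponential") "II" else "III",
         r_squared_exponential = fit_exponential$r.squared,
         r_squared_power = fit_power$r.squared,
         fits = list(exponential = fit_exponential, power = fit_power),
         log_concavity = unname(stats::coef(quad)[3])),
    class = "deevey_classification")
}

#' @export
print.deevey_classification <- function(x, digits = 4, ...) {
  cat(sprintf("Deevey type %s survivorship (best model: %s)\n",
              x$deevey_type, x$best_model))
  cat(sprintf("  R^2 exponential = %.*g, power = %.*g; log-scale concavity %+.3g\n",
              digits, x$r_squared_exponential, digits, x$r_squared_power,
              x$log_concavity))
  invisible(x)
}

#' Survival-function suite of a life table
#'
#' Derives from the per-class survival rates `S_x` of a life table the four
#' dynamics functions evaluated at the end of each age class i:
#' cumulative survival `S(i) = S_1 * S_2 * ... * S_i` (which telescopes to
#' `l_{i+1} / l_1`), cumulative mortality `F(i) = 1 - S(i)`, mortality
#' density `f(i) = (S(i-1) - S(i)) / h` with `S(0) = 1`, and hazard rate
#' `lambda(i) = 2 (1 - S(i)) / (h (1 + S(i)))`, where `h` is the age-class
#' interval.
#'
#' The default (`mode = "cumulative"`) feeds the cumulative `S(i)` into the
#' mortality and hazard formulas; `mode = "per_class"` instead evaluates
#' them with the per-class rate `S_i` itself, a reading some authors use.
#'
#' @param lt a `life_table` with at least two classes, or the per-class
#'   survival-rate vector `S_x` itself.
#' @param h age-class interval (default 1 class unit).
#' @param mode which survival quantity enters `F`, `f` and `lambda`.
#' @return A `survival_function_table` data frame with columns `age_class`,
#'   `S_x`, `S_cum`, `F`, `f`, `lambda`, one row per class with defined
#'   `S_x` (the last life-table class has none).
#' @examples
#' lt <- static_life_table(c(1700, 1600, 1600, 1400, 700, 300, 300, 100))
#' survival_functions(lt)
#' @export
survival_functions <- function(lt, h = 1, mode = c("cumulative", "per_class")) {
  mode <- match.arg(mode)
  if (!is.numeric(h) || length(h) != 1 || h <= 0)
    stop("`h` must be a single value > 0", call. = FALSE)
  Sx <- if (inherits(lt, "life_table")) lt$S[-nrow(lt)] else as.numeric(lt)
  Sx <- Sx[!is.na(Sx)]
  if (length(Sx) < 1)
    stop("need at least one defined per-class survival rate", call. = FALSE)
  S_cum <- cumprod(Sx)
  S_use <- if (mode == "cumulative") S_cum else Sx
  F_ <- 1 - S_use
  f <- (c(1, S_use[-length(S_use)]) - S_use) / h
  lambda <- 2 * (1 - S_use) / (h * (1 + S_use))
  out <- data.frame(age_class = seq_along(Sx), S_x = Sx, S_cum = S_cum,
                    F = F_, f = f, lambda = lambda)
  structure(out, h = h, mode = mode,
            class = c("survival_function_table", "data.frame"))
}

#' @export
print.survival_function_table <- function(x, digits = 4, ...) {
  cat(sprintf("Survival-function suite (h = %g, %s S in F/f/lambda)\n",
              attr(x, "h"), attr(x, "mode")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
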