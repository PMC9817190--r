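#' Basal-diameter age-class scheme (space-for-time substitution)
#'
#' Shrub age cannot be read directly in the field, so contiguous basal
#' diameter (BD) classes stand in for age classes: individuals in larger size
#' classes are taken to be older. The default scheme uses eight 2 cm classes,
#' (0, 2), [2, 4), ..., [14, 16) cm, grouped into four growth stages:
#' seedlings (class 1), small trees (2--3), medium trees (4--5) and large
#' trees (6--8).
#'
#' @param n_classes number of age classes.
#' @param class_width BD class width in cm.
#' @return An `age_class_scheme` with the class boundaries and stage labels.
#' @export
age_class_scheme <- function(n_classes = 8, class_width = 2) {
  if (n_classes < 1 || n_classes != round(n_classes))
    stop("`n_classes` must be a positive integer", call. = FALSE)
  if (class_width <= 0) stop("`class_width` must be > 0", call. = FALSE)
  stage <- rep("large trees", n_classes)
  stage[1] <- "seedlings"
  if (n_classes >= 2) stage[2:min(3, n_classes)] <- "small trees"
  if (n_classes >= 4) stage[4:min(5, n_classes)] <- "medium trees"
  structure(
    list(n_classes = as.integer(n_classes), class_width = class_width,
         lower = (seq_len(n_classes) - 1) * class_width,
         upper = seq_len(n_classes) * class_width,
         stages = stage),
    class = "age_class_scheme")
}

#' @export
print.age_class_scheme <- function(x, ...) {
  cat(sprintf("%d BD age classes of %g cm: ", x$n_classes, x$class_width))
  cat(sprintf("(0, %g)", x$class_width),
      sprintf("[%g, %g)", x$lower[-1], x$upper[-1]), sep = ", ")
  cat("\n")
  invisible(x)
}

#' Assign stems to age classes by basal diameter
#'
#' The first class is the open interval (0, w); later classes are half-open
#' [kw, (k+1)w), so a BD exactly on a boundary belongs to the upper class.
#' Diameters at or beyond the last boundary raise an error by default, or are
#' clamped into the last class with `overflow = "clamp"`.
#'
#' @param bd numeric vector of basal diameters (cm), all > 0.
#' @param scheme an [age_class_scheme()].
#' @param overflow `"error"` or `"clamp"` for BD >= the top boundary.
#' @return Integer vector of class indices in `1:n_classes`.
#' @examples
#' assign_age_class(c(0.5, 2, 4.88)) # 1, 2, 3
#' @export
assign_age_class <- function(bd, scheme = age_class_scheme(),
                             overflow = c("error", "clamp")) {
  overflow <- match.arg(overflow)
  if (!is.numeric(bd) || any(!is.finite(bd)))
    stop("`bd` must be finite numeric", call. = FALSE)
  if (any(bd <= 0)) stop("basal diameter must be > 0 cm", call. = FALSE)
  idx <- as.integer(floor(bd / scheme$class_width)) + 1L
  over <- idx > scheme$n_classes
  if (any(over)) {
    if (overflow == "error")
      stop(sprintf("basal diameter %g cm exceeds the top class boundary %g cm",
                   max(bd), scheme$upper[scheme$n_classes]), call. = FALSE)
    idx[over] <- scheme$n_classes
  }
  idx
}

#' Age-class abundance of one species, in stems per hectare
#'
#' Tallies the focal species' stems into the age-class scheme and scales the
#' counts to a per-hectare basis using the survey's sampled area.
#'
#' @param dataset a `survey_dataset`.
#' @param species focal species name (must occur in the stem table).
#' @param scheme an [age_class_scheme()].
#' @param overflow passed to [assign_age_class()].
#' @return An `age_distribution`: numeric vector of length `n_classes`
#'   (stems per hectare) with the scheme and raw counts attached.
#' @export
age_distribution <- function(dataset, species, scheme = age_class_scheme(),
                             overflow = c("error", "clamp")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  bd <- dataset$stems$bd_cm[dataset$stems$species == species]
  if (length(bd) == 0)
    stop("species not present in the stem table: ", species, call. = FALSE)
  idx <- assign_age_class(bd, scheme, overflow)
  counts <- tabulate(idx, nbins = scheme$n_classes)
  per_ha <- counts / sampled_area(dataset$design) * 1e4
  structure(per_ha, names = paste0("A", seq_len(scheme$n_classes)),
            counts = counts, species = species, scheme = scheme,
            class = "age_distribution")
}

#' @export
print.age_distribution <- function(x, ...) {
  sp <- attr(x, "species")
  if (!is.null(sp)) cat("Age-class abundance of", sp, "(stems/ha)\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Static life table from a single-census age distribution
#'
#' Builds the classic static (time-specific) life table by reading the
#' standing age distribution `A_x` of one census as if it traced a cohort
#' through time. Columns, for age class x with survivors standardised to a
#' radix (`l_1 = radix`):
#' \describe{
#'   \item{l_x}{standardised survivors `A_x / A_1 * radix`, and `ln_l` its log}
#'   \item{d_x}{deaths `l_x - l_{x+1}`}
#'   \item{q_x}{stage-specific mortality rate `d_x / l_x` (a proportion)}
#'   \item{L_x}{survivors alive on average through the class,
#'     `(l_x + l_{x+1}) / 2`}
#'   \item{T_x}{class-units of life remaining, the suffix sum of `L`}
#'   \item{e_x}{life expectancy `T_x / l_x` in class units}
#'   \item{K_x}{killing power `ln l_x - ln l_{x+1}`}
#'   \item{S_x}{per-class survival rate `l_{x+1} / l_x`}
#' }
#' `d, q, K, S` are undefined for the last class (reported `NA`); the last
#' class is closed with `L_n = l_n / 2`, so `T_n = l_n / 2` and `e_n = 0.5`.
#'
#' A static table is only internally consistent when `A_x` declines with age.
#' Non-monotone counts make some `d_x`, `q_x`, `K_x` negative; a warning is
#' issued, and `monotone = TRUE` applies a decreasing isotonic regression to
#' `A` before the table is built.
#'
#' @param A an `age_distribution` or non-negative numeric vector of class
#'   abundances; `A[1]` must be positive.
#' @param radix standardised initial cohort size (default 1000).
#' @param monotone smooth `A` to a non-increasing sequence first?
#' @return A `life_table` data frame with columns `age_class`, `A`, `l`,
#'   `ln_l`, `d`, `q`, `L`, `T`, `e`, `K`, `S`, at full precision (the print
#'   method rounds to 2 decimals).
#' @examples
#' lt <- static_life_table(c(1700, 1600, 1600, 1400, 700, 300, 300, 100))
#' lt$e[1] # 4.03 class units of expected further life in class 1
#' @export
static_life_table <- function(A, radix = 1000, monotone = FALSE) {
  A <- as.numeric(A)
  if (length(A) < 2) stop("need at least two age classes", call. = FALSE)
  if (any(!is.finite(A)) || any(A < 0))
    stop("`A` must be finite and non-negative", call. = FALSE)
  if (A[1] <= 0)
    stop("first age class is empty; standardisation to the radix is undefined",
         call. = FALSE)
  if (radix <= 0) stop("`radix` must be > 0", call. = FALSE)
  if (monotone && is.unsorted(rev(A))) {
    iso <- stats::isoreg(seq_along(A), -A)
    A <- -iso$yf
  }
  if (!monotone && is.unsorted(rev(A)))
    warning("age distribution is not monotone decreasing; ",
            "d, q and K can be negative (see `monotone = TRUE`)",
            call. = FALSE)
  n <- length(A)
  l <- A / A[1] * radix
  l_next <- c(l[-1], NA)
  d <- l - l_next
  q <- d / l
  L <- (l + c(l[-1], 0)) / 2 # last class: L = l/2
  T_ <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T_ / l, NA_real_)
  ln_l <- ifelse(l > 0, log(l), NA_real_)
  K <- ln_l - c(ln_l[-1], NA)
  S <- l_next / l
  out <- data.frame(age_class = seq_len(n), A = A, l = l, ln_l = ln_l,
                    d = d, q = q, L = L, T = T_, e = e, K = K, S = S)
  structure(out, radix = radix, class = c("life_table", "data.frame"))
}

#' @export
print.life_table <- function(x, digits = 2, ...) {
  cat(sprintf("Static life table (%d age classes, radix %g)\n",
              nrow(x), attr(x, "radix")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), NA, round(v, digits)))
  print(df, row.names = FALSE, na.print = "-")
  invisible(x)
}

#' Write a life table as CSV (undefined last-class cells left empty)
#' @param lt a `life_table`.
#' @param path output path.
#' @return Invisibly, `lt`.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, na = "")
  invisible(lt)
}
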