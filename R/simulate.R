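#' Basal-diameter models for synthetic shrub species
#'
#' Three interchangeable BD generators for [species_spec()]:
#' `bd_truncated_exponential(rate, max_bd)` draws from an exponential
#' distribution truncated to `(0, max_bd)`, producing the inverted-J size
#' structure typical of actively recruiting populations;
#' `bd_uniform(min_bd, max_bd)` draws uniformly on an interval; and
#' `bd_fixed_class_counts(counts, class_width)` places an exact per-hectare
#' count in each size class (uniform within the class), so analyses can be
#' checked against known class abundances.
#'
#' @param rate exponential rate per cm (> 0); larger means steeper decline.
#' @param max_bd upper truncation bound, cm.
#' @param min_bd lower bound, cm (> 0 enforced at draw time).
#' @param counts per-hectare stem counts per BD class, smallest class first.
#' @param class_width BD class width in cm.
#' @return A `bd_model` specification list.
#' @export
bd_truncated_exponential <- function(rate, max_bd = 16) {
  if (rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  structure(list(type = "truncated_exponential", rate = rate, max_bd = max_bd),
            class = "bd_model")
}

#' @rdname bd_truncated_exponential
#' @export
bd_uniform <- function(min_bd, max_bd) {
  if (min_bd <= 0 || max_bd <= min_bd)
    stop("need 0 < min_bd < max_bd", call. = FALSE)
  structure(list(type = "uniform", min_bd = min_bd, max_bd = max_bd),
            class = "bd_model")
}

#' @rdname bd_truncated_exponential
#' @export
bd_fixed_class_counts <- function(counts, class_width = 2) {
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (class_width <= 0) stop("`class_width` must be > 0", call. = FALSE)
  structure(list(type = "fixed_class_counts", counts = as.numeric(counts),
                 class_width = class_width),
            class = "bd_model")
}

#' Specify one synthetic species
#'
#' Describes how one species is simulated. Shrub species get a Poisson stem
#' count at `expected_density` (unless the BD model fixes class counts), BDs
#' from `bd_model`, heights linear in BD with Gaussian noise, and crown
#' widths proportional to height with noise. Herb species get a Bernoulli
#' presence per subquadrat, a shifted-Poisson abundance, and truncated
#' Gaussian coverage and height.
#'
#' @param name species name.
#' @param layer `"shrub"` or `"herb"`.
#' @param expected_density shrub: expected stems per hectare (ignored for
#'   `bd_fixed_class_counts`, which pins the density itself).
#' @param bd_model a `bd_model` (see [bd_truncated_exponential()]).
#' @param height_model `c(slope, intercept, sd)` of height (m) on BD (cm);
#'   draws are truncated at 0.05 m.
#' @param crown_model `c(ratio, sd)`: crown width (m) as `ratio * height`
#'   plus noise, truncated at 0.
#' @param presence_prob herb: probability a subquadrat holds the species.
#' @param abundance_mean herb: mean abundance where present (abundance is
#'   `1 + Poisson(abundance_mean - 1)`).
#' @param coverage_model herb: `c(mean, sd)` of per-subquadrat coverage %,
#'   truncated to (0, 100].
#' @param height_mean,height_sd herb: per-record mean height (m), truncated
#'   at 0.01.
#' @return A `species_spec` list.
#' @export
species_spec <- function(name, layer = c("shrub", "herb"),
                         expected_density = 1000,
                         bd_model = bd_truncated_exponential(0.5),
                         height_model = c(slope = 0.3, intercept = 0.2, sd = 0.15),
                         crown_model = c(ratio = 0.6, sd = 0.1),
                         presence_prob = 0.5, abundance_mean = 5,
                         coverage_model = c(mean = 10, sd = 5),
                         height_mean = 0.3, height_sd = 0.1) {
  layer <- match.arg(layer)
  if (!is.character(name) || nchar(trimws(name)) == 0)
    stop("species `name` must be a non-empty string", call. = FALSE)
  if (expected_density < 0) stop("`expected_density` must be >= 0", call. = FALSE)
  if (layer == "shrub" && !inherits(bd_model, "bd_model"))
    stop("`bd_model` must be built with bd_truncated_exponential(), ",
         "bd_uniform() or bd_fixed_class_counts()", call. = FALSE)
  if (presence_prob < 0 || presence_prob > 1)
    stop("`presence_prob` must lie in [0, 1]", call. = FALSE)
  structure(list(name = trimws(name), layer = layer,
                 expected_density = expected_density, bd_model = bd_model,
                 height_model = height_model, crown_model = crown_model,
                 presence_prob = presence_prob, abundance_mean = abundance_mean,
                 coverage_model = coverage_model, height_mean = height_mean,
                 height_sd = height_sd),
            class = "species_spec")
}

#' Configure a synthetic community
#'
#' @param design a [survey_design()].
#' @param species list of [species_spec()]s; at least one shrub species.
#' @param seed integer random seed (mandatory, for reproducibility).
#' @return A `community_config`.
#' @export
community_config <- function(design = survey_design(), species, seed) {
  stopifnot(inherits(design, "survey_design"))
  if (missing(species) || length(species) == 0)
    stop("`species` list is empty", call. = FALSE)
  if (!all(vapply(species, inherits, logical(1), "species_spec")))
    stop("every element of `species` must be a species_spec", call. = FALSE)
  if (!any(vapply(species, function(s) s$layer == "shrub", logical(1))))
    stop("need at least one shrub species", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("an integer `seed` is mandatory", call. = FALSE)
  structure(list(design = design, species = species, seed = as.integer(seed)),
            class = "community_config")
}

draw_bd <- function(model, n_stems_target, area_ha) {
  switch(model$type,
    truncated_exponential = {
      # inverse-CDF sampling of Exp(rate) truncated to (0, max_bd)
      u <- stats::runif(n_stems_target)
      p_max <- stats::pexp(model$max_bd, model$rate)
      stats::qexp(u * p_max, model$rate)
    },
    uniform = stats::runif(n_stems_target, model$min_bd, model$max_bd),
    fixed_class_counts = {
      counts <- round(model$counts * area_ha)
      w <- model$class_width
      unlist(lapply(seq_along(counts), function(k) {
        if (counts[k] == 0) return(numeric(0))
        lo <- (k - 1) * w
        lo + stats::runif(counts[k], min = w * 0.05, max = w * 0.95)
      }))
    },
    stop("unknown bd_model type: ", model$type, call. = FALSE))
}

#' Generate a seeded synthetic quadrat survey
#'
#' Simulates a full stem + herb census under the supplied design. Shrub stem
#' counts are Poisson at the species' expected density over the sampled area
#' (exact for `bd_fixed_class_counts`), stems fall uniformly over quadrats,
#' heights are linear in BD with noise and crown widths proportional to
#' height. Herb records arise per subquadrat from a presence probability.
#' The same seed always yields the identical dataset.
#'
#' @param config a [community_config()].
#' @return A validated `survey_dataset`.
#' @examples
#' cfg <- community_config(species = list(
#'   species_spec("Dominant shrub", expected_density = 4000,
#'                bd_model = bd_truncated_exponential(0.4))), seed = 42)
#' generate_survey(cfg)
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  design <- config$design
  area_ha <- sampled_area(design) / 1e4
  stems <- list()
  herbs <- list()
  for (sp in config$species) {
    if (sp$layer == "shrub") {
      n <- if (sp$bd_model$type == "fixed_class_counts") NA_integer_ else
        stats::rpois(1, sp$expected_density * area_ha)
      bd <- draw_bd(sp$bd_model, n, area_ha)
      n <- length(bd)
      if (n == 0) next
      hm <- sp$height_model
      h <- pmax(0.05, hm[1] * bd + hm[2] + stats::rnorm(n, 0, hm[3]))
      cm <- sp$crown_model
      w1 <- pmax(0, cm[1] * h + stats::rnorm(n, 0, cm[2]))
      w2 <- pmax(0, cm[1] * h + stats::rnorm(n, 0, cm[2]))
      stems[[length(stems) + 1L]] <- data.frame(
        quadrat_id = sample.int(design$n_quadrats, n, replace = TRUE),
        species = sp$name, bd_cm = bd, height_m = h,
        crown_w1_m = w1, crown_w2_m = w2, stringsAsFactors = FALSE)
    } else {
      grid <- expand.grid(quadrat_id = seq_len(design$n_quadrats),
                          subquadrat_id = seq_len(design$n_subquadrats))
      present <- stats::runif(nrow(grid)) < sp$presence_prob
      if (!any(present)) next
      g <- grid[present, , drop = FALSE]
      np <- nrow(g)
      ab <- 1L + stats::rpois(np, max(0, sp$abundance_mean - 1))
      cv <- pmin(100, pmax(0.1, stats::rnorm(np, sp$coverage_model[1],
                                             sp$coverage_model[2])))
      hh <- pmax(0.01, stats::rnorm(np, sp$height_mean, sp$height_sd))
      herbs[[length(herbs) + 1L]] <- data.frame(
        quadrat_id = g$quadrat_id, subquadrat_id = g$subquadrat_id,
        species = sp$name, abundance = ab, coverage_pct = cv,
        height_m = hh, stringsAsFactors = FALSE)
    }
  }
  stems <- if (length(stems)) do.call(rbind, stems) else empty_stems()
  herbs <- if (length(herbs)) do.call(rbind, herbs) else empty_herbs()
  survey_dataset(design, stems, herbs)
}

#' Sample an age distribution from a survivorship model
#'
#' Draws `N0` individuals multinomially over `n_classes` age classes with
#' probabilities proportional to `exp(-b x)` (exponential survivorship) or
#' `x^(-b)` (power survivorship), the inverse of the curve-fitting step:
#' fitting the resulting distribution should recover `b`.
#'
#' @param N0 total cohort size (>= 1).
#' @param b decay coefficient (> 0; `b = 0` gives uniform classes).
#' @param model `"exponential"` or `"power"`.
#' @param n_classes number of age classes.
#' @param seed optional integer seed.
#' @return An `age_distribution` whose values are the sampled class counts.
#' @export
generate_from_survivorship <- function(N0, b, model = c("exponential", "power"),
                                       n_classes = 8, seed = NULL) {
  model <- match.arg(model)
  if (N0 < 1) stop("`N0` must be >= 1", call. = FALSE)
  if (b < 0) stop("`b` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- seq_len(n_classes)
  w <- if (model == "exponential") exp(-b * x) else x^(-b)
  counts <- as.numeric(stats::rmultinom(1, size = round(N0), prob = w / sum(w)))
  structure(counts, names = paste0("A", x), counts = counts,
            species = NULL, scheme = age_class_scheme(n_classes),
            class = "age_distribution")
}
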