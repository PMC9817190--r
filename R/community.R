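#' Per-species shrub-layer summary with relative importance values
#'
#' For each woody species: density (stems per hectare), unweighted mean basal
#' diameter (BD, cm) and height (m), basal area (BA, m^2 per hectare,
#' computed from individual BDs as circle areas) and coverage (% of sampled
#' area). The relative importance value is the arithmetic mean of relative
#' density, relative basal area and relative coverage, each normalised so
#' species sum to 100 %. The totals row carries summed density, stem-weighted
#' mean BD and H, summed BA and coverage, and a RIV total of 100.
#'
#' @param dataset a `survey_dataset` with at least one stem.
#' @param coverage_mode `"crown_ellipse"` derives per-stem cover as the
#'   ellipse area `pi * w1 * w2 / 4` from the two perpendicular crown widths
#'   (no overlap correction); `"recorded"` uses coverages supplied directly.
#' @param recorded_coverage for `coverage_mode = "recorded"`: named numeric
#'   vector of per-species coverage percentages.
#' @return A `shrub_summary`: data frame with one row per species (decreasing
#'   RIV) and a `totals` attribute.
#' @examples
#' cfg <- community_config(species = list(
#'   species_spec("A", expected_density = 2000,
#'                bd_model = bd_truncated_exponential(0.5))), seed = 1)
#' shrub_summary(generate_survey(cfg))
#' @export
shrub_summary <- function(dataset,
                          coverage_mode = c("crown_ellipse", "recorded"),
                          recorded_coverage = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  coverage_mode <- match.arg(coverage_mode)
  stems <- dataset$stems
  if (nrow(stems) == 0)
    stop("shrub_summary() needs at least one stem record", call. = FALSE)
  area <- sampled_area(dataset$design) # m^2
  species <- sort(unique(stems$species))
  n <- tapply(rep(1, nrow(stems)), stems$species, sum)[species]
  density <- as.numeric(n) / area * 1e4
  mean_bd <- as.numeric(tapply(stems$bd_cm, stems$species, mean)[species])
  mean_h <- as.numeric(tapply(stems$height_m, stems$species, mean)[species])
  # BD in cm -> radius in m is bd/200
  ba_stem <- pi * (stems$bd_cm / 200)^2
  basal_area <- as.numeric(tapply(ba_stem, stems$species, sum)[species]) /
    area * 1e4

  if (coverage_mode == "crown_ellipse") {
    if (anyNA(stems$crown_w1_m) || anyNA(stems$crown_w2_m))
      stop("crown widths are missing; record them or use coverage_mode = \"recorded\"",
           call. = FALSE)
    cov_stem <- pi * stems$crown_w1_m * stems$crown_w2_m / 4
    coverage <- as.numeric(tapply(cov_stem, stems$species, sum)[species]) /
      area * 100
  } else {
    if (is.null(recorded_coverage))
      stop("coverage_mode = \"recorded\" needs `recorded_coverage`", call. = FALSE)
    miss <- setdiff(species, names(recorded_coverage))
    if (length(miss))
      stop("recorded_coverage is missing species: ",
           paste(miss, collapse = ", "), call. = FALSE)
    coverage <- as.numeric(recorded_coverage[species])
  }

  rel <- function(v) v / sum(v) * 100
  out <- data.frame(
    species = species, density = density, mean_bd = mean_bd, mean_h = mean_h,
    basal_area = basal_area, coverage = coverage,
    rel_density = rel(density), rel_ba = rel(basal_area),
    rel_coverage = rel(coverage), stringsAsFactors = FALSE)
  out$riv <- (out$rel_density + out$rel_ba + out$rel_coverage) / 3
  out <- out[order(-out$riv), ]
  rownames(out) <- NULL
  totals <- list(
    density = sum(out$density),
    mean_bd = sum(stems$bd_cm) / nrow(stems),
    mean_h = sum(stems$height_m) / nrow(stems),
    basal_area = sum(out$basal_area),
    coverage = sum(out$coverage),
    riv = sum(out$riv))
  structure(out, totals = totals, layer = "shrub",
            class = c("layer_summary", "data.frame"))
}

#' Per-species herb-layer summary with relative importance values
#'
#' For each herbaceous species: abundance-weighted mean height, mean coverage
#' across all subquadrats (absence counted as zero cover), and the relative
#' importance value as the mean of relative abundance, relative coverage and
#' relative frequency (frequency = share of subquadrats occupied). The totals
#' row gives the abundance-weighted layer mean height, summed mean coverage,
#' and 100 for each relative column.
#'
#' @param dataset a `survey_dataset` with at least one herb record.
#' @return A data frame of class `layer_summary` (decreasing RIV) with a
#'   `totals` attribute.
#' @export
herb_summary <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  herbs <- dataset$herbs
  if (nrow(herbs) == 0)
    stop("herb_summary() needs at least one herb record", call. = FALSE)
  design <- dataset$design
  n_sub_total <- design$n_quadrats * design$n_subquadrats
  species <- sort(unique(herbs$species))
  abundance <- as.numeric(tapply(herbs$abundance, herbs$species, sum)[species])
  mean_h <- as.numeric(tapply(herbs$height_m, herbs$species, mean)[species])
  sub_key <- paste(herbs$quadrat_id, herbs$subquadrat_id)
  freq <- vapply(species, function(s)
    length(unique(sub_key[herbs$species == s])), numeric(1)) / n_sub_total
  # mean cover over all subquadrats, occupied or not
  mean_c <- as.numeric(tapply(herbs$coverage_pct, herbs$species, sum)[species]) /
    n_sub_total
  rel <- function(v) v / sum(v) * 100
  out <- data.frame(
    species = species, mean_h = mean_h, mean_c = mean_c,
    abundance = abundance, frequency = freq,
    rel_abundance = rel(abundance), rel_coverage = rel(mean_c),
    rel_frequency = rel(freq), stringsAsFactors = FALSE)
  out$riv <- (out$rel_abundance + out$rel_coverage + out$rel_frequency) / 3
  out <- out[order(-out$riv), ]
  rownames(out) <- NULL
  totals <- list(
    mean_h = sum(out$mean_h * out$abundance) / sum(out$abundance),
    mean_c = sum(out$mean_c),
    rel_abundance = sum(out$rel_abundance),
    rel_coverage = sum(out$rel_coverage),
    rel_frequency = sum(out$rel_frequency),
    riv = sum(out$riv))
  structure(out, totals = totals, layer = "herb",
            class = c("layer_summary", "data.frame"))
}

#' @export
print.layer_summary <- function(x, digits = 2, ...) {
  cat(sprintf("%s-layer species summary (%d species)\n",
              attr(x, "layer"), nrow(x)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  t <- attr(x, "totals")
  cat("totals:", paste(sprintf("%s=%.2f", names(t), unlist(t)),
                       collapse = " "), "\n")
  invisible(x)
}

#' Aggregate relative importance values over species groups
#'
#' Sums per-species RIVs within user-supplied groups (for instance taxonomic
#' families or clades from an external phylogeny). Species absent from the
#' grouping are pooled under `"other"`; the grand total is conserved at 100.
#'
#' @param summaries a `layer_summary`, or any data frame with `species` and
#'   `riv` columns.
#' @param groups named character vector mapping species name to group label,
#'   or a named list of species-name vectors (one element per group).
#' @return Named numeric vector of summed RIV percentages, decreasing.
#' @examples
#' s <- data.frame(species = c("a", "b", "c"), riv = c(60, 30, 10))
#' group_riv(s, c(a = "G1", b = "G1"))
#' @export
group_riv <- function(summaries, groups) {
  df <- as.data.frame(summaries)
  if (!all(c("species", "riv") %in% names(df)))
    stop("`summaries` must have `species` and `riv` columns", call. = FALSE)
  if (is.list(groups)) {
    if (is.null(names(groups)))
      stop("group list must be named by group", call. = FALSE)
    groups <- stats::setNames(
      rep(names(groups), lengths(groups)), unlist(groups))
  }
  unknown <- setdiff(names(groups), df$species)
  if (length(unknown))
    stop("grouping names unknown species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  grp <- groups[df$species]
  grp[is.na(grp)] <- "other"
  out <- tapply(df$riv, grp, sum)
  sort(stats::setNames(as.numeric(out), names(out)), decreasing = TRUE)
}

#' Size- or height-class histogram of woody stems
#'
#' Bins stems into contiguous classes of width `class_width`, following the
#' half-open convention (0, w), [w, 2w), ...: the first class excludes both
#' endpoints, later classes include their lower bound. Classes run from zero
#' up to the largest observation.
#'
#' @param stems a `survey_dataset`, or a stem data frame with `bd_cm` and
#'   `height_m` columns.
#' @param field `"bd"` (basal diameter, cm) or `"height"` (m).
#' @param class_width class width in the field's unit (default 2 cm for BD,
#'   0.5 m for height).
#' @param design optional `survey_design`; when given (or when `stems` is a
#'   dataset) a `density` column scales counts to stems per hectare.
#' @return A `size_histogram` data frame with `class`, `lower`, `upper`,
#'   `count` and optionally `density` columns.
#' @export
size_histogram <- function(stems, field = c("bd", "height"),
                           class_width = NULL, design = NULL) {
  field <- match.arg(field)
  if (inherits(stems, "survey_dataset")) {
    design <- stems$design
    stems <- stems$stems
  }
  if (is.null(class_width)) class_width <- if (field == "bd") 2 else 0.5
  if (!is.numeric(class_width) || class_width <= 0)
    stop("`class_width` must be > 0", call. = FALSE)
  x <- if (field == "bd") stems$bd_cm else stems$height_m
  if (length(x) == 0) stop("no stems to bin", call. = FALSE)
  if (any(x <= 0)) stop("observations must be > 0", call. = FALSE)
  idx <- floor(x / class_width) + 1L # value == k*w lands in class k+1
  n_classes <- max(idx)
  counts <- tabulate(idx, nbins = n_classes)
  out <- data.frame(
    class = seq_len(n_classes),
    lower = (seq_len(n_classes) - 1) * class_width,
    upper = seq_len(n_classes) * class_width,
    count = counts)
  if (!is.null(design))
    out$density <- counts / sampled_area(design) * 1e4
  structure(out, field = field, class_width = class_width,
            class = c("size_histogram", "data.frame"))
}

#' @export
print.size_histogram <- function(x, ...) {
  unit <- if (attr(x, "field") == "bd") "cm" else "m"
  cat(sprintf("%s-class histogram, width %g %s\n", attr(x, "field"),
              attr(x, "class_width"), unit))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
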