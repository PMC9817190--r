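# Shared fixtures: published per-species summaries and the focal species'
# age-class abundances, plus synthetic stem populations reconstructed from
# them. Everything is built in code; no data files.

# Published shrub-layer summary: density (stems/ha), mean BD (cm), mean H (m),
# basal area (m^2/ha; NA where below the 0.01 reporting threshold), RIV (%).
shrub_reference <- function() {
  data.frame(
    species = c("Cydonia oblonga", "Spiraea chinensis", "Rhododendron simsii",
                "Serissa serissoides", "Rubus corchorifolius",
                "Hypericum monogynum", "Lespedeza bicolor", "Rubus parvifolius",
                "Rosa cymosa", "Ilex chinensis", "Mallotus apelta",
                "Castanea seguinii", "Ligustrum leucanthum",
                "Lonicera japonica", "Smilax china", "Viburnum setigerum",
                "Rubus tephrodes"),
    density = c(3850, 2650, 1150, 1550, 1100, 950, 800, 400, 350, 300, 50,
                150, 150, 100, 100, 50, 50),
    mean_bd = c(4.88, 0.77, 1.12, 0.47, 0.60, 0.43, 0.38, 0.44, 0.79, 0.58,
                3.20, 0.80, 0.43, 0.50, 0.30, 0.30, 0.40),
    mean_h = c(1.73, 0.92, 0.99, 0.35, 0.93, 0.40, 0.30, 0.90, 1.06, 0.75,
               1.50, 1.00, 0.47, 0.30, 0.60, 0.30, 0.30),
    basal_area = c(10.93, 0.13, 0.12, 0.03, 0.04, 0.01, 0.01, 0.01, 0.02,
                   0.01, 0.04, 0.01, NA, NA, NA, NA, NA),
    riv = c(67.12, 9.97, 4.97, 4.10, 3.30, 2.49, 2.13, 1.24, 1.19, 0.97,
            0.70, 0.55, 0.47, 0.26, 0.25, 0.15, 0.14),
    stringsAsFactors = FALSE)
}

rosaceae_species <- function() {
  c("Cydonia oblonga", "Spiraea chinensis", "Rubus corchorifolius",
    "Rubus parvifolius", "Rosa cymosa", "Rubus tephrodes")
}

# Published focal-species age-class abundances (stems/ha, classes 1..8).
focal_age_counts <- function() c(1700, 1600, 1600, 1400, 700, 300, 300, 100)

# Published static life table (2 dp; NA where undefined).
life_table_reference <- function() {
  data.frame(
    l = c(1000, 941.18, 941.18, 823.53, 411.76, 176.47, 176.47, 58.82),
    ln_l = c(6.91, 6.85, 6.85, 6.71, 6.02, 5.17, 5.17, 4.07),
    d = c(58.82, 0, 117.65, 411.76, 235.29, 0, 117.65, NA),
    q = c(0.06, 0.00, 0.13, 0.50, 0.57, 0.00, 0.67, NA),
    L = c(970.59, 941.18, 882.35, 617.65, 294.12, 176.47, 117.65, 29.41),
    T = c(4029.41, 3058.82, 2117.65, 1235.29, 617.65, 323.53, 147.06, 29.41),
    e = c(4.03, 3.25, 2.25, 1.50, 1.50, 1.83, 0.83, 0.50),
    K = c(0.06, 0.00, 0.13, 0.69, 0.85, 0.00, 1.10, NA),
    S = c(0.94, 1.00, 0.88, 0.50, 0.43, 1.00, 0.33, NA))
}

# Reconstruct a stem population whose per-species densities, mean BDs, mean
# heights and basal areas reproduce the published summary. Each species gets
# stems at its mean BD; where the published basal area exceeds what a
# constant BD yields (BA reflects the second moment of BD), the stems are
# split into symmetric two-point pairs mean_bd +/- delta, with delta chosen
# so the BD sum of squares matches the published BA. An 80-quadrat design
# (2000 m^2) makes every per-species stem count an even integer.
make_reference_stem_dataset <- function() {
  ref <- shrub_reference()
  design <- survey_design(n_quadrats = 80)
  area <- sampled_area(design)          # 2000 m^2
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    n <- ref$density[i] * area / 1e4    # stems in the sample
    m <- ref$mean_bd[i]
    ba_const <- pi * (m / 200)^2 * ref$density[i]
    ba_target <- ref$basal_area[i]
    if (!is.na(ba_target) && abs(ba_const - ba_target) >= 0.005) {
      ex2 <- ba_target * 4e4 / (pi * ref$density[i]) # target E[BD^2]
      delta <- sqrt(ex2 - m^2)
      bd <- rep(c(m - delta, m + delta), n / 2)
    } else {
      bd <- rep(m, n)
    }
    data.frame(quadrat_id = rep_len(seq_len(design$n_quadrats), n),
               species = ref$species[i], bd_cm = bd,
               height_m = ref$mean_h[i], crown_w1_m = 0.5, crown_w2_m = 0.5,
               stringsAsFactors = FALSE)
  })
  survey_dataset(design, do.call(rbind, rows))
}

# Community-wide BD pool: the published 10,700 stems/ha below 2 cm plus the
# remaining 3,050 stems/ha spread over larger classes in inverted-J fashion.
make_bd_pool_dataset <- function(seed = 11) {
  counts <- c(10700, 1600, 600, 400, 200, 150, 50, 50)
  cfg <- community_config(
    design = survey_design(n_quadrats = 40),
    species = list(species_spec("All shrubs",
                                bd_model = bd_fixed_class_counts(counts))),
    seed = seed)
  generate_survey(cfg)
}

# Small deterministic two-species dataset for hand-computed oracles.
make_tiny_dataset <- function() {
  stems <- data.frame(
    quadrat_id = c(1, 1, 2, 3),
    species = c("A", "A", "A", "B"),
    bd_cm = c(2, 2, 2, 2),
    height_m = c(1, 1, 1, 1),
    crown_w1_m = c(1, 1, 1, 2),
    crown_w2_m = c(1, 1, 1, 2),
    stringsAsFactors = FALSE)
  herbs <- data.frame(
    quadrat_id = c(1, 1, 1, 2, 2, 1),
    subquadrat_id = c(1, 2, 3, 1, 2, 1),
    species = c("h1", "h1", "h1", "h1", "h2", "h2"),
    abundance = c(2, 2, 2, 2, 4, 4),
    coverage_pct = c(10, 10, 10, 10, 20, 20),
    height_m = c(0.2, 0.2, 0.2, 0.2, 0.4, 0.4),
    stringsAsFactors = FALSE)
  survey_dataset(survey_design(n_quadrats = 4), stems, herbs)
}

expect_cells_match <- function(computed, printed, tol = 0.005 + 1e-9) {
  ok <- is.na(printed) == is.na(computed) &
    (is.na(printed) | abs(computed - printed) <= tol)
  expect_true(all(ok), label = paste0(
    "cells within ", tol, " of the printed value (mismatch at ",
    paste(which(!ok), collapse = ", "), ")"))
}
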