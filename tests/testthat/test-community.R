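test_that("shrub summary matches a hand-computed two-species oracle", {
  d <- make_tiny_dataset() # 3 identical stems of A, 1 of B, 100 m^2 sampled
  s <- shrub_summary(d)
  a <- s[s$species == "A", ]
  b <- s[s$species == "B", ]
  expect_equal(a$density, 300)          # 3 / 100 m^2 * 1e4
  expect_equal(b$density, 100)
  expect_equal(a$rel_density, 75)
  expect_equal(b$rel_density, 25)
  # identical BDs: basal area proportional to counts
  expect_equal(a$basal_area, pi * (2 / 200)^2 * 3 / 100 * 1e4)
  expect_equal(a$rel_ba, 75)
  # crown ellipse: A stems cover pi/4 each, B covers pi
  expect_equal(a$coverage, 3 * pi / 4 / 100 * 100)
  expect_equal(a$rel_coverage, 3 * pi / 4 / (3 * pi / 4 + pi) * 100)
  expect_equal(a$riv, (75 + 75 + a$rel_coverage) / 3)
  t <- attr(s, "totals")
  expect_equal(t$density, 400)
  expect_equal(t$basal_area, sum(s$basal_area))
  expect_equal(t$riv, 100)
})

test_that("a monoculture carries all relative measures at 100", {
  d <- make_tiny_dataset()
  d$stems <- d$stems[d$stems$species == "A", ]
  s <- shrub_summary(survey_dataset(d$design, d$stems))
  expect_equal(s$rel_density, 100)
  expect_equal(s$rel_ba, 100)
  expect_equal(s$rel_coverage, 100)
  expect_equal(s$riv, 100)
})

test_that("relative measures and RIV each sum to 100 and survive duplication", {
  cfg <- community_config(species = list(
    species_spec("A", expected_density = 2000),
    species_spec("B", expected_density = 800,
                 bd_model = bd_uniform(0.2, 3)),
    species_spec("h1", layer = "herb", presence_prob = 0.7),
    species_spec("h2", layer = "herb", presence_prob = 0.3)), seed = 5)
  d <- generate_survey(cfg)
  s <- shrub_summary(d)
  expect_equal(sum(s$rel_density), 100, tolerance = 1e-12)
  expect_equal(sum(s$rel_ba), 100, tolerance = 1e-12)
  expect_equal(sum(s$rel_coverage), 100, tolerance = 1e-12)
  expect_equal(sum(s$riv), 100, tolerance = 1e-12)
  h <- herb_summary(d)
  expect_equal(sum(h$riv), 100, tolerance = 1e-12)

  # duplicating every quadrat leaves densities and RIVs unchanged
  dup_design <- survey_design(n_quadrats = 2 * d$design$n_quadrats)
  stems2 <- rbind(d$stems,
                  transform(d$stems, quadrat_id = quadrat_id + 20))
  herbs2 <- rbind(d$herbs,
                  transform(d$herbs, quadrat_id = quadrat_id + 20))
  d2 <- survey_dataset(dup_design, stems2, herbs2)
  s2 <- shrub_summary(d2)
  expect_equal(s2$density, s$density)
  expect_equal(s2$riv, s$riv)
  h2 <- herb_summary(d2)
  expect_equal(h2$riv, h$riv)
})

test_that("herb frequency equals the hand-counted subquadrat ratio", {
  d <- make_tiny_dataset() # 12 subquadrats; h1 in 4, h2 in 2
  h <- herb_summary(d)
  h1 <- h[h$species == "h1", ]
  h2 <- h[h$species == "h2", ]
  expect_equal(h1$frequency, 4 / 12)
  expect_equal(h2$frequency, 2 / 12)
  expect_equal(h1$rel_frequency, 4 / 6 * 100)
  # mean coverage averages over all 12 subquadrats, absences as zero
  expect_equal(h1$mean_c, 40 / 12)
  expect_equal(h2$mean_c, 40 / 12)
  expect_equal(h1$rel_abundance, 8 / 16 * 100)
  # one species everywhere -> all relative measures 100
  solo <- survey_dataset(d$design, d$stems, d$herbs[d$herbs$species == "h1", ])
  hs <- herb_summary(solo)
  expect_equal(hs$riv, 100)
})

test_that("herb RIV composition is internally consistent (RF = 3 RIV - RA - RC)", {
  # published herb-layer values: RA 50.55, RC 62.62, RIV 49.49 for the
  # dominant sedge imply RF = 35.30; rebuild proportions and check closure
  cfg <- community_config(species = list(
    species_spec("shrub", expected_density = 1000),
    species_spec("Carex brunnea", layer = "herb", presence_prob = 0.95,
                 abundance_mean = 9, coverage_model = c(19, 4)),
    species_spec("Dryopteris championii", layer = "herb", presence_prob = 0.4,
                 abundance_mean = 3, coverage_model = c(3, 1)),
    species_spec("Aster ageratoides", layer = "herb", presence_prob = 0.45,
                 abundance_mean = 3, coverage_model = c(2, 1))), seed = 9)
  h <- herb_summary(generate_survey(cfg))
  expect_equal(h$rel_frequency, 3 * h$riv - h$rel_abundance - h$rel_coverage,
               tolerance = 1e-9)
  expect_equal(3 * 49.49 - 50.55 - 62.62, 35.30, tolerance = 0.005 + 1e-9)
})

test_that("group RIV sums conserve the total and flag unknown species", {
  s <- data.frame(species = c("a", "b", "c"), riv = c(60, 30, 10))
  g <- group_riv(s, c(a = "G1", b = "G1"))
  expect_equal(unname(g["G1"]), 90)
  expect_equal(unname(g["other"]), 10)
  expect_equal(sum(g), 100)
  expect_equal(unname(group_riv(s, c(a = "G", b = "G", c = "G"))), 100)
  expect_error(group_riv(s, c(zz = "G")), "zz")
  # list-of-vectors interface
  g2 <- group_riv(s, list(G1 = c("a", "b")))
  expect_equal(g2, g)
})

test_that("size histogram follows the half-open class convention", {
  stems <- data.frame(quadrat_id = 1, species = "A",
                      bd_cm = c(0.5, 1.9, 2.0, 4.88),
                      height_m = 1, crown_w1_m = 0, crown_w2_m = 0)
  h <- size_histogram(stems, "bd", 2)
  expect_equal(h$count, c(2, 1, 1))
  expect_equal(h$lower, c(0, 2, 4))
  one <- size_histogram(data.frame(bd_cm = c(1, 1.5), height_m = 1), "bd", 2)
  expect_equal(one$count, 2)
  expect_error(size_histogram(stems, "bd", 0), "class_width")
})

test_that("histogram inverts the fixed-class-count generator", {
  counts <- c(1700, 1600, 1600, 1400, 700, 300, 300, 100)
  cfg <- community_config(species = list(
    species_spec("A", bd_model = bd_fixed_class_counts(counts))), seed = 13)
  d <- generate_survey(cfg) # 500 m^2 -> counts * 0.05 stems
  h <- size_histogram(d, "bd", 2)
  expect_equal(h$count, counts * 0.05)
  expect_equal(h$density, counts)
})
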