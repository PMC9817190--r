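#' Run the full survey-to-demography pipeline and write a report bundle
#'
#' Executes every analysis stage in order — survey input (read from CSV or
#' generated synthetically), shrub and herb layer summaries, BD and height
#' histograms, focal-species age distribution and static life table,
#' exponential/power survivorship fits with Deevey classification, the
#' survival-function suite, and the moving-average forecast — and writes the
#' results to `outdir` as machine-readable CSV/JSON at full precision plus a
#' human-readable `summary.txt` rounded to 2 decimals. Re-running with the
#' same inputs and configuration reproduces the bundle byte for byte.
#'
#' @param config a named list (or path to a YAML file with the same fields):
#'   \describe{
#'     \item{stems, herbs}{input CSV paths (herbs optional), or}
#'     \item{generator}{a [community_config()] for a synthetic survey}
#'     \item{species}{focal species name for the demographic stages (required)}
#'     \item{design}{list of [survey_design()] arguments (defaults apply)}
#'     \item{scheme}{list of [age_class_scheme()] arguments}
#'     \item{radix}{life-table radix, default 1000}
#'     \item{h}{age-class interval for the survival functions, default 1}
#'     \item{horizons}{forecast horizons, default c(2, 4, 6, 8)}
#'     \item{coverage_mode}{`"crown_ellipse"` (default) or `"recorded"`}
#'     \item{overflow}{BD overflow handling, `"error"` or `"clamp"`}
#'     \item{outdir}{output directory (created if absent; required)}
#'   }
#' @param quiet suppress per-stage progress messages?
#' @return Invisibly, a list with every intermediate result (`dataset`,
#'   `shrub_summary`, `herb_summary`, `bd_histogram`, `height_histogram`,
#'   `age_distribution`, `life_table`, `deevey`, `survival_functions`,
#'   `forecast`) and the written file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  if (is.null(config$outdir)) stop("config needs an `outdir`", call. = FALSE)
  if (is.null(config$species))
    stop("config needs a focal `species` for the demographic stages",
         call. = FALSE)
  say <- function(...) if (!quiet) message(...)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  design <- do.call(survey_design, as.list(config$design))

  if (!is.null(config$generator)) {
    gen <- config$generator
    if (!inherits(gen, "community_config"))
      gen <- build_generator_config(gen, design)
    say("stage survey: generating synthetic survey (seed ", gen$seed, ")")
    dataset <- generate_survey(gen)
    write_survey(dataset, file.path(config$outdir, "stems.csv"),
                 file.path(config$outdir, "herbs.csv"))
  } else {
    if (is.null(config$stems))
      stop("config needs either `stems` (input CSV) or `generator`",
           call. = FALSE)
    say("stage survey: reading ", config$stems)
    dataset <- read_survey(config$stems, config$herbs, design)
  }

  res <- list(dataset = dataset)
  outfile <- function(name) file.path(config$outdir, name)

  say("stage community: shrub layer summary")
  coverage_mode <- if (is.null(config$coverage_mode)) "crown_ellipse" else
    config$coverage_mode
  res$shrub_summary <- shrub_summary(dataset, coverage_mode,
                                     config$recorded_coverage)
  write_summary_csv(res$shrub_summary, outfile("shrub_summary.csv"))
  if (nrow(dataset$herbs) > 0) {
    say("stage community: herb layer summary")
    res$herb_summary <- herb_summary(dataset)
    write_summary_csv(res$herb_summary, outfile("herb_summary.csv"))
  }
  say("stage community: size histograms")
  res$bd_histogram <- size_histogram(dataset, "bd")
  res$height_histogram <- size_histogram(dataset, "height")
  utils::write.csv(res$bd_histogram, outfile("bd_histogram.csv"),
                   row.names = FALSE)
  utils::write.csv(res$height_histogram, outfile("height_histogram.csv"),
                   row.names = FALSE)

  focal <- config$species
  if (!focal %in% dataset$stems$species)
    stop("focal species not present in the stem table: ", focal, call. = FALSE)
  scheme <- do.call(age_class_scheme, as.list(config$scheme))
  overflow <- if (is.null(config$overflow)) "error" else config$overflow
  say("stage demography: age distribution and life table for ", focal)
  res$age_distribution <- age_distribution(dataset, focal, scheme, overflow)
  radix <- if (is.null(config$radix)) 1000 else config$radix
  res$life_table <- static_life_table(res$age_distribution, radix)
  write_life_table(res$life_table, outfile("life_table.csv"))

  say("stage survivorship: model fits and Deevey classification")
  # empty upper classes carry no survivorship information; fit on the
  # occupied classes at their original indices
  occupied <- which(res$life_table$l > 0)
  if (length(occupied) < 3)
    stop("stage survivorship: fewer than 3 occupied age classes", call. = FALSE)
  res$deevey <- classify_deevey(lx = res$life_table$l[occupied], x = occupied)
  fit_json <- list(
    best_model = res$deevey$best_model,
    deevey_type = res$deevey$deevey_type,
    exponential = fit_as_list(res$deevey$fits$exponential),
    power = fit_as_list(res$deevey$fits$power))
  writeLines(jsonlite::toJSON(fit_json, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             outfile("survivorship_fit.json"))

  h <- if (is.null(config[["h"]])) 1 else config[["h"]]
  say("stage survivorship: survival-function suite (h = ", h, ")")
  res$survival_functions <- survival_functions(res$life_table, h)
  utils::write.csv(res$survival_functions, outfile("survival_functions.csv"),
                   row.names = FALSE)

  horizons <- if (is.null(config$horizons)) c(2, 4, 6, 8) else config$horizons
  horizons <- horizons[horizons <= scheme$n_classes]
  say("stage forecast: moving averages (n = ",
      paste(horizons, collapse = ", "), ")")
  res$forecast <- time_series_forecast(res$age_distribution, horizons)
  utils::write.csv(res$forecast, outfile("forecast.csv"), row.names = FALSE)

  writeLines(render_summary(res, focal), outfile("summary.txt"))
  res$files <- list.files(config$outdir, full.names = TRUE)
  say("report bundle written to ", config$outdir)
  invisible(res)
}

# YAML generator blocks carry plain lists; rebuild the classed config.
build_generator_config <- function(gen, design) {
  species <- lapply(gen$species, function(s) {
    args <- s
    if (!is.null(args$bd_model) && !inherits(args$bd_model, "bd_model")) {
      bm <- args$bd_model
      args$bd_model <- switch(bm$type,
        truncated_exponential = bd_truncated_exponential(
          bm$rate, if (is.null(bm$max_bd)) 16 else bm$max_bd),
        uniform = bd_uniform(bm$min_bd, bm$max_bd),
        fixed_class_counts = bd_fixed_class_counts(
          unlist(bm$counts), if (is.null(bm$class_width)) 2 else bm$class_width),
        stop("unknown bd_model type: ", bm$type, call. = FALSE))
    }
    lapply_num <- c("height_model", "crown_model", "coverage_model")
    for (f in lapply_num)
      if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
    do.call(species_spec, args)
  })
  if (is.null(gen$seed)) stop("generator config needs a `seed`", call. = FALSE)
  community_config(design, species, gen$seed)
}

write_summary_csv <- function(x, path) {
  df <- as.data.frame(x)
  t <- attr(x, "totals")
  tot <- df[1, ]
  tot[] <- NA
  tot$species <- "Total"
  for (nm in names(t)) if (nm %in% names(tot)) tot[[nm]] <- t[[nm]]
  utils::write.csv(rbind(df, tot), path, row.names = FALSE, na = "")
}

fit_as_list <- function(fit) {
  list(model = fit$model, N0 = fit$N0, b = fit$b,
       r_squared = fit$r.squared, f_statistic = fit$f.statistic, n = fit$n)
}

render_summary <- function(res, focal) {
  fmt_tbl <- function(x) {
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, 2)
    utils::capture.output(print(df, row.names = FALSE, na.print = "-"))
  }
  t <- attr(res$shrub_summary, "totals")
  out <- c(
    "Quadrat survey demography report",
    sprintf("focal species: %s", focal),
    "",
    "== shrub layer ==",
    fmt_tbl(res$shrub_summary),
    sprintf("totals: density %.2f stems/ha, mean BD %.2f cm, mean H %.2f m, BA %.2f m2/ha, RIV %.2f",
            t$density, t$mean_bd, t$mean_h, t$basal_area, t$riv))
  if (!is.null(res$herb_summary)) {
    th <- attr(res$herb_summary, "totals")
    out <- c(out, "", "== herb layer ==", fmt_tbl(res$herb_summary),
             sprintf("totals: mean H %.2f m, mean C %.2f %%, RIV %.2f",
                     th$mean_h, th$mean_c, th$riv))
  }
  out <- c(out, "", "== static life table ==", fmt_tbl(res$life_table),
           "",
           "== survivorship ==",
           utils::capture.output(print(res$deevey)),
           "",
           "== survival functions ==", fmt_tbl(res$survival_functions),
           "",
           "== forecast ==", fmt_tbl(res$forecast))
  out
}
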