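#' Describe the sampling design of a quadrat survey
#'
#' A survey consists of `n_quadrats` fixed-area quadrats for woody stems, each
#' holding `n_subquadrats` nested subquadrats in which herbaceous species are
#' recorded. The defaults describe the common shrubland design of twenty
#' 5 m x 5 m quadrats with three 1 m x 1 m herb subquadrats each.
#'
#' @param n_quadrats number of woody-stem quadrats (>= 1).
#' @param quadrat_area area of one quadrat in square metres.
#' @param n_subquadrats number of herb subquadrats nested in each quadrat.
#' @param subquadrat_area area of one herb subquadrat in square metres.
#' @return An object of class `survey_design`.
#' @examples
#' d <- survey_design()
#' sampled_area(d) # 500 m^2
#' @export
survey_design <- function(n_quadrats = 20, quadrat_area = 25,
                          n_subquadrats = 3, subquadrat_area = 1) {
  if (!is.numeric(n_quadrats) || length(n_quadrats) != 1 || n_quadrats < 1 ||
      n_quadrats != round(n_quadrats))
    stop("`n_quadrats` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(quadrat_area) || quadrat_area <= 0)
    stop("`quadrat_area` must be > 0", call. = FALSE)
  if (!is.numeric(n_subquadrats) || n_subquadrats < 0 ||
      n_subquadrats != round(n_subquadrats))
    stop("`n_subquadrats` must be a non-negative integer", call. = FALSE)
  if (!is.numeric(subquadrat_area) || subquadrat_area <= 0)
    stop("`subquadrat_area` must be > 0", call. = FALSE)
  structure(
    list(n_quadrats = as.integer(n_quadrats), quadrat_area = quadrat_area,
         n_subquadrats = as.integer(n_subquadrats),
         subquadrat_area = subquadrat_area),
    class = "survey_design")
}

#' Total woody-stem area sampled by a design, in square metres
#' @param design a `survey_design`.
#' @return Numeric scalar, `n_quadrats * quadrat_area`.
#' @export
sampled_area <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  design$n_quadrats * design$quadrat_area
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("Quadrat survey design: %d quadrats x %g m^2 (%g m^2 sampled)\n",
              x$n_quadrats, x$quadrat_area, sampled_area(x)))
  if (x$n_subquadrats > 0)
    cat(sprintf("  herb layer: %d subquadrats x %g m^2 per quadrat\n",
                x$n_subquadrats, x$subquadrat_area))
  invisible(x)
}

stem_columns <- c("quadrat_id", "species", "bd_cm", "height_m",
                  "crown_w1_m", "crown_w2_m")
herb_columns <- c("quadrat_id", "subquadrat_id", "species", "abundance",
                  "coverage_pct", "height_m")

empty_stems <- function() {
  data.frame(quadrat_id = integer(), species = character(),
             bd_cm = numeric(), height_m = numeric(),
             crown_w1_m = numeric(), crown_w2_m = numeric(),
             stringsAsFactors = FALSE)
}

empty_herbs <- function() {
  data.frame(quadrat_id = integer(), subquadrat_id = integer(),
             species = character(), abundance = integer(),
             coverage_pct = numeric(), height_m = numeric(),
             stringsAsFactors = FALSE)
}

# Row-level validation. `what` names the table in error messages; errors carry
# the offending row numbers so bad field sheets are easy to fix.
validate_stems <- function(stems, design, what = "stem table") {
  if (nrow(stems) == 0) return(stems)
  stems$species <- trimws(as.character(stems$species))
  bad <- function(cond, msg) {
    if (any(cond)) stop(sprintf("%s: %s (row %s)", what, msg,
                                paste(which(cond), collapse = ", ")),
                        call. = FALSE)
  }
  bad(is.na(stems$species) | stems$species == "", "species name empty")
  bad(!is.finite(stems$bd_cm), "basal diameter not numeric")
  bad(stems$bd_cm <= 0, "basal diameter must be > 0 cm")
  bad(!is.finite(stems$height_m), "height not numeric")
  bad(stems$height_m <= 0, "height must be > 0 m")
  # crown widths optional; a lone width stands for both perpendicular widths
  only_w2 <- is.na(stems$crown_w1_m) & !is.na(stems$crown_w2_m)
  stems$crown_w1_m[only_w2] <- stems$crown_w2_m[only_w2]
  only_w1 <- !is.na(stems$crown_w1_m) & is.na(stems$crown_w2_m)
  stems$crown_w2_m[only_w1] <- stems$crown_w1_m[only_w1]
  bad(!is.na(stems$crown_w1_m) & stems$crown_w1_m < 0, "crown width < 0")
  bad(!is.na(stems$crown_w2_m) & stems$crown_w2_m < 0, "crown width < 0")
  qid <- suppressWarnings(as.integer(stems$quadrat_id))
  bad(is.na(qid) | qid < 1 | qid > design$n_quadrats,
      sprintf("quadrat_id outside 1..%d", design$n_quadrats))
  stems$quadrat_id <- qid
  stems
}

validate_herbs <- function(herbs, design, what = "herb table") {
  if (nrow(herbs) == 0) return(herbs)
  herbs$species <- trimws(as.character(herbs$species))
  bad <- function(cond, msg) {
    if (any(cond)) stop(sprintf("%s: %s (row %s)", what, msg,
                                paste(which(cond), collapse = ", ")),
                        call. = FALSE)
  }
  bad(is.na(herbs$species) | herbs$species == "", "species name empty")
  bad(!is.finite(herbs$abundance) | herbs$abundance < 1 |
        herbs$abundance != round(herbs$abundance),
      "abundance must be an integer >= 1")
  bad(!is.finite(herbs$coverage_pct) | herbs$coverage_pct < 0 |
        herbs$coverage_pct > 100, "coverage must lie in [0, 100] %")
  bad(!is.finite(herbs$height_m) | herbs$height_m <= 0,
      "mean height must be > 0 m")
  qid <- suppressWarnings(as.integer(herbs$quadrat_id))
  bad(is.na(qid) | qid < 1 | qid > design$n_quadrats,
      sprintf("quadrat_id outside 1..%d", design$n_quadrats))
  sid <- suppressWarnings(as.integer(herbs$subquadrat_id))
  bad(is.na(sid) | sid < 1 | sid > design$n_subquadrats,
      sprintf("subquadrat_id outside 1..%d", design$n_subquadrats))
  herbs$quadrat_id <- qid
  herbs$subquadrat_id <- sid
  herbs$abundance <- as.integer(herbs$abundance)
  herbs
}

#' Assemble a validated survey dataset
#'
#' Bundles a sampling design with the woody-stem and herb record tables and
#' validates every row against the field bounds (positive basal diameter and
#' height, coverage within 0--100 %, abundance a positive integer, quadrat and
#' subquadrat identifiers within the design). Validation rejects offending
#' rows by number; it never drops them silently.
#'
#' @param design a [survey_design()].
#' @param stems data frame with columns `quadrat_id`, `species`, `bd_cm`,
#'   `height_m`, `crown_w1_m`, `crown_w2_m` (crown widths may be `NA`; a
#'   single recorded width is taken for both perpendicular directions).
#' @param herbs data frame with columns `quadrat_id`, `subquadrat_id`,
#'   `species`, `abundance`, `coverage_pct`, `height_m`. May be empty.
#' @return An object of class `survey_dataset`.
#' @export
survey_dataset <- function(design, stems = empty_stems(), herbs = empty_herbs()) {
  stopifnot(inherits(design, "survey_design"))
  stems <- as.data.frame(stems, stringsAsFactors = FALSE)
  herbs <- as.data.frame(herbs, stringsAsFactors = FALSE)
  miss <- setdiff(stem_columns, names(stems))
  if (length(miss))
    stop("stem table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(herb_columns, names(herbs))
  if (length(miss))
    stop("herb table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stems <- validate_stems(stems[stem_columns], design)
  herbs <- validate_herbs(herbs[herb_columns], design)
  rownames(stems) <- NULL
  rownames(herbs) <- NULL
  structure(list(design = design, stems = stems, herbs = herbs),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  print(x$design)
  cat(sprintf("  %d stems of %d woody species; %d herb records of %d species\n",
              nrow(x$stems), length(unique(x$stems$species)),
              nrow(x$herbs), length(unique(x$herbs$species))))
  invisible(x)
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s file %s is missing column(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  numeric_cols <- setdiff(required, c("quadrat_id", "subquadrat_id", "species"))
  for (col in numeric_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      v[v == ""] <- NA
      conv <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & is.na(conv)
      if (any(bad))
        stop(sprintf("%s file %s: non-numeric value in `%s` (line %s)", what,
                     path, col, paste(which(bad) + 1L, collapse = ", ")),
             call. = FALSE)
      df[[col]] <- conv
    }
  }
  df[required]
}

#' Read a stem/herb CSV pair into a validated survey dataset
#'
#' Files are comma-separated UTF-8 with one header row. The stem file needs
#' columns `quadrat_id,species,bd_cm,height_m,crown_w1_m,crown_w2_m` (crown
#' widths may be blank) and the herb file
#' `quadrat_id,subquadrat_id,species,abundance,coverage_pct,height_m`.
#' Row order is preserved.
#'
#' @param stem_path path to the stem CSV.
#' @param herb_path path to the herb CSV, or `NULL` for a shrub-only survey.
#' @param design a [survey_design()] describing the sampling layout.
#' @return A validated `survey_dataset`.
#' @seealso [write_survey()] for the inverse operation.
#' @export
read_survey <- function(stem_path, herb_path = NULL, design = survey_design()) {
  stems <- read_table_checked(stem_path, stem_columns, "stem")
  herbs <- if (is.null(herb_path)) empty_herbs() else
    read_table_checked(herb_path, herb_columns, "herb")
  # header-only files read as untyped empty frames; restore the schema
  if (nrow(stems) == 0) stems <- empty_stems()
  if (nrow(herbs) == 0) herbs <- empty_herbs()
  survey_dataset(design, stems, herbs)
}

#' Write a survey dataset to a stem/herb CSV pair
#'
#' Numeric fields are written at full precision so that
#' `read_survey(write_survey(d))` reproduces `d` exactly.
#'
#' @param dataset a `survey_dataset`.
#' @param stem_path,herb_path output CSV paths; `herb_path = NULL` skips the
#'   herb table.
#' @return Invisibly, the dataset.
#' @export
write_survey <- function(dataset, stem_path, herb_path = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  utils::write.csv(dataset$stems, stem_path, row.names = FALSE, quote = FALSE,
                   na = "")
  if (!is.null(herb_path))
    utils::write.csv(dataset$herbs, herb_path, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(dataset)
}
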