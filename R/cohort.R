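# Cohort assembly: questionnaire-derived analysis variables, outlier
# truncation, and complete-case filtering.

#' Analysis-variable caps and constants
#'
#' Pack-years are capped at 140 and BMI at 40 to limit the influence of
#' extreme outlying observations; ethanol grams per drink follow the
#' standard questionnaire conversion (beer 12.8 g, 4 oz wine 11.0 g, shot of
#' liquor 14.0 g). One pound is 0.45359237 kg.
#'
#' @name cohort-constants
#' @keywords internal
NULL

PACK_YEARS_CAP <- 140
BMI_CAP <- 40
LB_TO_KG <- 0.45359237
ETHANOL_G <- c(beer = 12.8, wine = 11.0, liquor = 14.0)

GENOTYPE_LEVELS <- list(
  cfh_genotype = c("CC", "CT", "TT"),
  arms2_genotype = c("CC", "TC", "TT")
)
SEX_LEVELS <- c("male", "female")

# Analysis variables every PatientRecord must carry (complete-case rule).
ANALYSIS_VARS <- c(
  "age_years", "sex", "pack_years", "alcohol_decades", "bmi",
  "htn_history", "chol_history", "cfh_genotype", "arms2_genotype"
)

#' Cumulative smoking exposure in pack-years
#'
#' One pack-year is one pack of cigarettes (20 cigarettes) per day smoked
#' for one year. Exposure runs from the age smoking started to the age of
#' quitting, or to the reference age (age at study entry) for current
#' smokers. Values are capped at 140 pack-years to limit the influence of
#' extreme outliers; never-smokers (no start age) score 0.
#'
#' @param start_age Age smoking began, or `NA` for a never-smoker.
#' @param quit_age Age smoking stopped, or `NA` if still smoking at the
#'   reference age.
#' @param packs_per_day Average packs smoked per day while smoking.
#' @param reference_age Age at study entry; the exposure cutoff.
#'
#' @return Pack-years in `[0, 140]`. The `"truncated"` attribute is `TRUE`
#'   when the raw value exceeded the cap.
#'
#' @examples
#' compute_pack_years(20, 60, 1, 73) # 40 pack-years
#' compute_pack_years(NA, NA, NA, 73) # never-smoker: 0
#' @export
compute_pack_years <- function(start_age, quit_age, packs_per_day, reference_age) {
  if (is.na(start_age)) {
    return(structure(0, truncated = FALSE))
  }
  if (is.na(packs_per_day)) return(NA_real_)
  if (packs_per_day < 0) stop_domain("packs_per_day must be non-negative")
  if (start_age > reference_age)
    stop_domain("smoking start age exceeds the reference age")
  end_age <- if (is.na(quit_age)) reference_age else quit_age
  if (end_age < start_age)
    stop_domain("quit age precedes start age (invalid smoking interval)")
  if (end_age > reference_age)
    stop_domain("quit age exceeds the reference age")
  raw <- packs_per_day * (end_age - start_age)
  structure(min(raw, PACK_YEARS_CAP), truncated = raw > PACK_YEARS_CAP)
}

#' Decades-of-life alcohol consumption score
#'
#' Alcohol use is coded as the number of decades of life (teens through the
#' decade of study entry) in which the patient drank at all: a patient who
#' consumed alcohol in three decades scores 3.
#'
#' @param drank_by_decade Logical vector, one entry per decade from the
#'   teens to the decade of the reference age.
#' @return Integer count of decades with any drinking.
#' @examples
#' compute_alcohol_decades(c(TRUE, TRUE, TRUE, FALSE, FALSE)) # 3
#' @export
compute_alcohol_decades <- function(drank_by_decade) {
  if (length(drank_by_decade) == 0L)
    stop_domain("decade sequence is empty")
  if (anyNA(drank_by_decade)) return(NA_integer_)
  sum(as.logical(drank_by_decade))
}

#' Weekly ethanol intake in grams
#'
#' Converts weekly drink counts into grams of ethanol using the standard
#' equivalences: one can/glass/bottle of beer = 12.8 g, one 4 oz glass of
#' wine = 11.0 g, one drink or shot of liquor = 14.0 g.
#'
#' @param beers,wine_glasses,liquor_shots Drinks per week (non-negative).
#' @return Grams of ethanol per week.
#' @examples
#' alcohol_grams_per_week(1, 0, 0) # 12.8
#' @export
alcohol_grams_per_week <- function(beers, wine_glasses, liquor_shots) {
  counts <- c(beers, wine_glasses, liquor_shots)
  if (any(counts < 0)) stop_domain("drink counts must be non-negative")
  sum(counts * ETHANOL_G)
}

#' Body mass index with outlier truncation
#'
#' BMI is current weight (kg) divided by the square of height (m) as
#' self-reported at age 25, capped at 40 to limit the influence of extreme
#' outliers.
#'
#' @param weight_kg Current weight in kilograms.
#' @param height_m_at_25 Height in meters at age 25.
#' @return BMI in `(0, 40]`; attribute `"truncated"` flags capped values.
#' @examples
#' compute_bmi(80, 1.75) # 26.12
#' compute_bmi(130, 1.6) # capped at 40
#' @export
compute_bmi <- function(weight_kg, height_m_at_25) {
  if (is.na(weight_kg) || is.na(height_m_at_25)) return(NA_real_)
  if (weight_kg <= 0 || height_m_at_25 <= 0)
    stop_domain("weight and height must be positive")
  raw <- weight_kg / height_m_at_25^2
  structure(min(raw, BMI_CAP), truncated = raw > BMI_CAP)
}

parse_genotype <- function(x, levels) {
  x <- toupper(trimws(as.character(x)))
  x[!nzchar(x)] <- NA_character_
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    stop_domain("invalid genotype value(s): ", paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = levels)
}

parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[!nzchar(x)] <- NA_character_
  x[x == "m"] <- "male"
  x[x == "f"] <- "female"
  bad <- !is.na(x) & !(x %in% SEX_LEVELS)
  if (any(bad))
    stop_domain("invalid sex value(s): ", paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = SEX_LEVELS)
}

parse_binary <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true")] <- TRUE
  out[x %in% c("0", "FALSE", "false")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop_domain("invalid 0/1 value(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Assemble an analysis cohort from raw patient input
#'
#' Derives the analysis variables (pack-years, alcohol decades, BMI) where
#' they are not already present, applies the outlier caps, and keeps
#' complete cases only: any record missing any analysis variable is dropped
#' and logged with the missing field names. Accepts either the
#' preprocessed-record table (columns `alcohol_decades`, `bmi_raw`) or the
#' raw questionnaire dialect with per-decade drinking/weight columns
#' (`drank_decade_1`, ..., `weight_lb_decade_1`, ..., `height_m_at_25`,
#' `htn_treated_6mo`, `chol_treated_6mo`); see [read_cohort_csv()].
#'
#' @param raw A data frame in either input dialect.
#' @return An object of class `"amd_cohort"`: a list with `records` (one
#'   row per complete case, all analysis variables non-missing) and
#'   `exclusions` (data frame `patient_id`, `missing_fields`).
#' @export
build_cohort <- function(raw) {
  stopifnot(is.data.frame(raw))
  if (!"patient_id" %in% names(raw)) stop_domain("missing patient_id column")
  ids <- as.character(raw$patient_id)
  if (anyDuplicated(ids))
    stop_domain("duplicate patient_id: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- nrow(raw)
  if (n == 0L) stop_domain("empty input")

  age <- as.numeric(raw$age_years)
  sex <- parse_sex(raw$sex)

  if ("pack_years" %in% names(raw)) {
    # already-derived exposure (e.g. simulated cohorts): cap and use as is
    pack_years <- pmin(as.numeric(raw$pack_years), PACK_YEARS_CAP)
  } else {
    start <- as.numeric(raw$smoke_start_age %||% rep(NA_real_, n))
    quit <- as.numeric(raw$smoke_quit_age %||% rep(NA_real_, n))
    ppd <- as.numeric(raw$packs_per_day %||% rep(NA_real_, n))
    pack_years <- vapply(seq_len(n), function(i) {
      if (is.na(age[i])) return(NA_real_)
      as.numeric(compute_pack_years(start[i], quit[i], ppd[i], age[i]))
    }, numeric(1))
  }

  drank_cols <- grep("^drank_decade_", names(raw), value = TRUE)
  if ("alcohol_decades" %in% names(raw)) {
    alcohol <- as.integer(raw$alcohol_decades)
  } else if (length(drank_cols)) {
    drank_cols <- drank_cols[order(as.integer(sub("^drank_decade_", "", drank_cols)))]
    alcohol <- apply(raw[drank_cols], 1L, function(r) {
      r <- suppressWarnings(as.numeric(r))
      r <- r[!is.na(r)]
      if (!length(r)) NA_integer_ else sum(r > 0)
    })
  } else {
    alcohol <- rep(NA_integer_, n)
  }

  weight_cols <- grep("^weight_lb_decade_", names(raw), value = TRUE)
  if ("bmi_raw" %in% names(raw) || "bmi" %in% names(raw)) {
    bmi <- pmin(as.numeric(raw$bmi_raw %||% raw$bmi), BMI_CAP)
  } else if (length(weight_cols) && "height_m_at_25" %in% names(raw)) {
    weight_cols <- weight_cols[order(as.integer(sub("^weight_lb_decade_", "", weight_cols)))]
    height <- as.numeric(raw$height_m_at_25)
    bmi <- vapply(seq_len(n), function(i) {
      w <- suppressWarnings(as.numeric(raw[i, weight_cols]))
      w <- w[!is.na(w)]
      if (!length(w) || is.na(height[i])) return(NA_real_)
      # current weight = most recent decade reported
      as.numeric(compute_bmi(w[length(w)] * LB_TO_KG, height[i]))
    }, numeric(1))
  } else {
    bmi <- rep(NA_real_, n)
  }

  htn <- parse_binary(raw$htn_history %||% raw$htn_treated_6mo %||% rep(NA, n))
  chol <- parse_binary(raw$chol_history %||% raw$chol_treated_6mo %||% rep(NA, n))
  cfh <- parse_genotype(raw$cfh_rs1061170 %||% raw$cfh_genotype %||% rep(NA, n),
                        GENOTYPE_LEVELS$cfh_genotype)
  arms2 <- parse_genotype(raw$arms2_rs1049331 %||% raw$arms2_genotype %||% rep(NA, n),
                          GENOTYPE_LEVELS$arms2_genotype)

  records <- data.frame(
    patient_id = ids,
    age_years = age,
    sex = sex,
    pack_years = pack_years,
    alcohol_decades = alcohol,
    bmi = bmi,
    htn_history = htn,
    chol_history = chol,
    cfh_genotype = cfh,
    arms2_genotype = arms2,
    stringsAsFactors = FALSE
  )

  missing_by_row <- lapply(seq_len(n), function(i) {
    ANALYSIS_VARS[vapply(ANALYSIS_VARS, function(v) is.na(records[[v]][i]), logical(1))]
  })
  complete <- lengths(missing_by_row) == 0L
  exclusions <- data.frame(
    patient_id = ids[!complete],
    missing_fields = vapply(missing_by_row[!complete], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  out <- list(records = records[complete, , drop = FALSE], exclusions = exclusions)
  rownames(out$records) <- NULL
  class(out) <- "amd_cohort"
  out
}

#' @export
print.amd_cohort <- function(x, ...) {
  cat("Neovascular AMD analysis cohort\n")
  cat(sprintf("  complete cases: %d (excluded %d of %d evaluated)\n",
              nrow(x$records), nrow(x$exclusions),
              nrow(x$records) + nrow(x$exclusions)))
  invisible(x)
}

#' Read a patient-record CSV
#'
#' Reads either input dialect (preprocessed records with
#' `alcohol_decades`/`bmi_raw`, or the raw questionnaire table with
#' per-decade columns). Empty cells are missing; booleans are 0/1;
#' genotypes are two-letter strings.
#'
#' @param path CSV path.
#' @return A raw-input data frame suitable for [build_cohort()].
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  check.names = FALSE)
}

#' Write cohort records and the exclusion log
#'
#' @param cohort An `"amd_cohort"` object.
#' @param records_path,exclusions_path Output CSV paths (`NULL` to skip).
#' @return The cohort, invisibly.
#' @export
write_cohort_csv <- function(cohort, records_path, exclusions_path = NULL) {
  stopifnot(inherits(cohort, "amd_cohort"))
  if (!is.null(records_path))
    utils::write.csv(cohort$records, records_path, row.names = FALSE, quote = FALSE)
  if (!is.null(exclusions_path))
    utils::write.csv(cohort$exclusions, exclusions_path, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}
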