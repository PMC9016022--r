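# Item definitions for the 22-line IDDA2.1 visit record and the fixed
# 17-axis kaleidoscope order.

# columns holding the 14 graded organ/feature items (lines 1-14)
ORGAN_COLS <- sprintf("p%02d", 1:14)

ORGAN_LABELS <- c(
  "AI cytopenia",
  "Hemophagocytosis / HLH",
  "Enteropathy / IBD",
  "Lymphoproliferation / organomegaly",
  "Parenchymal lung disease (LIP/GLILD)",
  "Skin or eye manifestations",
  "Granulomatous disease (non-GLILD)",
  "Endocrinopathy",
  "Arthritis / musculoskeletal",
  "AI hepatitis / cholangitis / pancreatitis",
  "Glomerulonephritis / nephropathy",
  "Neurologic manifestations",
  "Failure to thrive",
  "Severe infections"
)

# tokens accepted for line 18 and their numeric score contributions
IGG_LEVELS <- c(none = 0, sporadic = 2, iv = 3, sc = 3)

VISIT_COLUMNS <- c(
  "patient_id", "visit_date", "therapy_phase",
  ORGAN_COLS,
  "p15_performance", "p16_hosp", "p17_icu", "p18_igg",
  "p19", "p20", "p21", "p22_malignancy", "p22_note"
)

#' IDDA2.1 item catalogue
#'
#' Returns the 22-line parameter list of the IDDA2.1 score: line number,
#' the visit-table column that stores it, a short label, and its role in
#' the score (graded organ item, percentage, supportive item, or the
#' separately noted malignancy flag).
#'
#' @return A data frame with columns `line`, `column`, `label`, `role`.
#' @export
#' @examples
#' idda_items()
idda_items <- function() {
  data.frame(
    line = 1:22,
    column = c(ORGAN_COLS, "p15_performance", "p16_hosp", "p17_icu",
               "p18_igg", "p19", "p20", "p21", "p22_malignancy"),
    label = c(
      ORGAN_LABELS,
      "Karnofsky/Lansky performance scale (%)",
      "Hospitalization (days out of 100, non-ICU)",
      "Mechanical ventilation / ICU (days out of 100)",
      "IgG substitution / hypogammaglobulinemia",
      "Chronic or recurring infestation/infection",
      "Any other organ dysfunction / malady",
      "Nutrition / dietary status",
      "Malignancy (noted, not scored)"
    ),
    role = c(rep("organ", 14), "performance", "hospital", "icu",
             "igg", rep("supportive", 3), "malignancy"),
    stringsAsFactors = FALSE
  )
}

#' Kaleidoscope axis catalogue
#'
#' The cohort radar chart plots presence frequencies of 17 of the 22
#' IDDA2.1 items in a fixed circular order: the 14 graded organ items
#' (lines 1-14), then "any other organ dysfunction" (line 20), then
#' hypogammaglobulinemia/IgG substitution (line 18), then malignancy
#' (line 22). The performance scale, hospitalization and ICU percentages
#' (lines 15-17), asymptomatic chronic infestation (line 19) and
#' nutrition status (line 21) are excluded.
#'
#' @return A data frame with columns `axis` (1-17), `line` (the IDDA2.1
#'   line number), `column` (visit-table column), and `label`.
#' @export
#' @examples
#' kaleidoscope_axes()$line
kaleidoscope_axes <- function() {
  items <- idda_items()
  lines <- c(1:14, 20L, 18L, 22L)
  idx <- match(lines, items$line)
  data.frame(
    axis = 1:17,
    line = lines,
    column = items$column[idx],
    label = c(ORGAN_LABELS,
              "Any other organ dysfunction",
              "Hypogammaglobulinemia / IgG substitution",
              "Malignancy / lymphoma"),
    stringsAsFactors = FALSE
  )
}

#' Numeric score value of the IgG substitution item (line 18)
#'
#' Maps the line-18 coding to its score contribution: no substitution
#' scores 0, sporadic substitution 2, and regular intravenous or
#' subcutaneous substitution both score 3.
#'
#' @param code Character vector of tokens from `"none"`, `"sporadic"`,
#'   `"iv"`, `"sc"` (case-insensitive). `NA` is propagated.
#' @return Integer vector of score values in {0, 2, 3}.
#' @export
#' @examples
#' igg_numeric(c("none", "sporadic", "iv", "sc"))
igg_numeric <- function(code) {
  code <- tolower(as.character(code))
  out <- unname(IGG_LEVELS[code])
  bad <- !is.na(code) & is.na(out)
  if (any(bad)) {
    stop("unknown IgG substitution code(s) for line 18: ",
         paste(unique(code[bad]), collapse = ", "),
         " (expected none, sporadic, iv, sc)", call. = FALSE)
  }
  as.integer(out)
}

#' Construct an IDDA2.1 visit table
#'
#' Builds a one-row-per-visit data frame in the standard column layout.
#' All arguments are recycled to the length of `patient_id`. Graded items
#' may be `NA` to mark a value as not assessed (distinct from grade 0).
#'
#' @param patient_id Character patient identifiers.
#' @param visit_date Visit dates (`Date` or ISO-8601 strings).
#' @param therapy_phase Optional free-text phase labels (e.g. "pre-HSCT").
#' @param organ_grades Either a length-14 integer vector (grades for
#'   lines 1-14, applied to every visit) or a matrix/data frame with 14
#'   columns and one row per visit. Grades are integers 0-4.
#' @param performance Karnofsky/Lansky performance scale, integer percent
#'   in \[10, 100\] (line 15).
#' @param hosp_days Non-ICU hospitalization days out of the last 100 days
#'   (line 16), in \[0, 100\].
#' @param icu_days ICU/mechanical-ventilation days out of 100 (line 17).
#' @param igg IgG substitution token: `"none"`, `"sporadic"`, `"iv"`,
#'   or `"sc"` (line 18).
#' @param infestation Chronic infestation/infection grade 0-4 (line 19).
#' @param other_organ Any-other-organ-dysfunction grade 0-4 (line 20).
#' @param nutrition Nutrition status grade 0-4 (line 21).
#' @param malignancy Logical malignancy flag (line 22; never scored).
#' @param malignancy_note Optional free-text note for line 22.
#' @return A data frame with the standard visit columns.
#' @export
#' @examples
#' v <- idda_visit("P1", "2024-03-01", performance = 100)
#' validate_visits(v)
idda_visit <- function(patient_id, visit_date, therapy_phase = NA_character_,
                       organ_grades = rep(0L, 14), performance = 100L,
                       hosp_days = 0, icu_days = 0, igg = "none",
                       infestation = 0L, other_organ = 0L, nutrition = 0L,
                       malignancy = FALSE, malignancy_note = NA_character_) {
  n <- length(patient_id)
  if (is.null(dim(organ_grades))) {
    stopifnot(length(organ_grades) == 14)
    organ_grades <- matrix(rep(as.numeric(organ_grades), each = n),
                           nrow = n, ncol = 14)
  } else {
    organ_grades <- as.matrix(organ_grades)
    stopifnot(ncol(organ_grades) == 14, nrow(organ_grades) == n)
  }
  colnames(organ_grades) <- ORGAN_COLS
  df <- data.frame(
    patient_id = as.character(patient_id),
    visit_date = as.Date(visit_date),
    therapy_phase = rep_len(as.character(therapy_phase), n),
    organ_grades,
    p15_performance = rep_len(as.numeric(performance), n),
    p16_hosp = rep_len(as.numeric(hosp_days), n),
    p17_icu = rep_len(as.numeric(icu_days), n),
    p18_igg = rep_len(tolower(as.character(igg)), n),
    p19 = rep_len(as.numeric(infestation), n),
    p20 = rep_len(as.numeric(other_organ), n),
    p21 = rep_len(as.numeric(nutrition), n),
    p22_malignancy = rep_len(as.logical(malignancy), n),
    p22_note = rep_len(as.character(malignancy_note), n),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

finding <- function(row, line, column, severity, message) {
  data.frame(row = row, line = line, column = column,
             severity = severity, message = message,
             stringsAsFactors = FALSE)
}

empty_findings <- function() {
  finding(integer(0), integer(0), character(0), character(0), character(0))
}

#' Validate IDDA2.1 visit records
#'
#' Checks every row of a visit table against the IDDA2.1 grading rubric
#' and returns one finding per violated rule, each naming the offending
#' parameter line. Findings are data, not errors: a conforming table
#' yields a zero-row result. Rules checked:
#' \itemize{
#'   \item lines 1-14, 19, 20, 21: integer grades in 0-4 (`NA` = not
#'     assessed is allowed);
#'   \item line 15: integer performance percent in 10-100 (required); a
#'     non-decile value yields a `"warning"`-severity finding only;
#'   \item lines 16-17: days in \[0, 100\], jointly at most 100 of the
#'     100-day window (required);
#'   \item line 18: token from none/sporadic/iv/sc (required);
#'   \item line 22: logical flag (required).
#' }
#'
#' @param visits Visit table as returned by [idda_visit()] or
#'   [read_visits()].
#' @return A data frame of findings with columns `row`, `line`, `column`,
#'   `severity` (`"error"` or `"warning"`), `message`.
#' @export
#' @examples
#' v <- idda_visit("P1", "2024-03-01", performance = 105)
#' validate_visits(v)
validate_visits <- function(visits) {
  stopifnot(is.data.frame(visits))
  missing_cols <- setdiff(VISIT_COLUMNS, names(visits))
  if (length(missing_cols) > 0) {
    stop("visit table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- list(empty_findings())
  add <- function(rows, line, column, severity, msg) {
    if (length(rows) > 0) {
      out[[length(out) + 1L]] <<- finding(rows, line, column, severity, msg)
    }
  }
  graded <- rbind(
    data.frame(column = ORGAN_COLS, line = 1:14),
    data.frame(column = c("p19", "p20", "p21"), line = 19:21)
  )
  for (k in seq_len(nrow(graded))) {
    col <- graded$column[k]; line <- graded$line[k]
    x <- visits[[col]]
    bad <- which(!is.na(x) & (x < 0 | x > 4 | x != round(x)))
    add(bad, line, col, "error",
        sprintf("line %d (%s): grade must be an integer in 0-4", line, col))
  }
  kps <- visits$p15_performance
  add(which(is.na(kps)), 15L, "p15_performance", "error",
      "line 15 (p15_performance): performance scale is required")
  add(which(!is.na(kps) & (kps < 10 | kps > 100 | kps != round(kps))),
      15L, "p15_performance", "error",
      "line 15 (p15_performance): must be an integer percent in 10-100")
  add(which(!is.na(kps) & kps >= 10 & kps <= 100 & kps == round(kps) &
              kps %% 10 != 0),
      15L, "p15_performance", "warning",
      "line 15 (p15_performance): not a multiple of 10 (Karnofsky/Lansky is conventionally decile-stepped)")
  for (spec in list(list("p16_hosp", 16L), list("p17_icu", 17L))) {
    col <- spec[[1]]; line <- spec[[2]]
    x <- visits[[col]]
    add(which(is.na(x)), line, col, "error",
        sprintf("line %d (%s): days out of 100 is required", line, col))
    add(which(!is.na(x) & (x < 0 | x > 100)), line, col, "error",
        sprintf("line %d (%s): must be in [0, 100] days", line, col))
  }
  both <- visits$p16_hosp + visits$p17_icu
  add(which(!is.na(both) & both > 100), 16L, "p16_hosp", "error",
      "lines 16+17 (p16_hosp + p17_icu): exceed the 100-day observation window")
  igg <- tolower(as.character(visits$p18_igg))
  add(which(is.na(igg)), 18L, "p18_igg", "error",
      "line 18 (p18_igg): IgG substitution status is required")
  add(which(!is.na(igg) & !(igg %in% names(IGG_LEVELS))), 18L, "p18_igg",
      "error",
      "line 18 (p18_igg): token must be one of none, sporadic, iv, sc")
  add(which(is.na(visits$p22_malignancy)), 22L, "p22_malignancy", "error",
      "line 22 (p22_malignancy): malignancy flag is required")
  res <- do.call(rbind, out)
  res <- res[order(res$row, res$line), , drop = FALSE]
  rownames(res) <- NULL
  res
}
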