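# The IDDA2.1 total evaluates, per visit,
#   (sum(lines 1-14) + hosp term + ICU term + sum(lines 18-21)) * multiplier
# with the hospitalization term capped at 4, the ICU term at 8, and the
# performance-scale multiplier floored/capped to [1.5, 6]. All three
# branch conditions are strict, matching the published spreadsheet
# expression.

#' Hospitalization term of the IDDA2.1 score (line 16)
#'
#' Non-ICU hospitalization days out of the last 100 days contribute
#' `days * 0.1`, capped at 4 points from 40 days on. The cap branch uses
#' a strict `days < 40` test; the term is continuous at 40 (both
#' branches give 4).
#'
#' @param days Numeric vector of days in \[0, 100\].
#' @return Numeric vector of score points in \[0, 4\].
#' @export
#' @examples
#' idda_hosp_term(c(0, 20, 40, 60))
idda_hosp_term <- function(days) {
  if (any(!is.na(days) & (days < 0 | days > 100))) {
    stop("line 16 (hospitalization days) must be in [0, 100]", call. = FALSE)
  }
  ifelse(days < 40, days * 0.1, 4)
}

#' ICU term of the IDDA2.1 score (line 17)
#'
#' ICU / mechanical-ventilation days out of the last 100 days contribute
#' `days * 0.8`, capped at 8 points from 10 days on (strict `days < 10`
#' branch; continuous at 10).
#'
#' @param days Numeric vector of days in \[0, 100\].
#' @return Numeric vector of score points in \[0, 8\].
#' @export
#' @examples
#' idda_icu_term(c(0, 5, 25))
idda_icu_term <- function(days) {
  if (any(!is.na(days) & (days < 0 | days > 100))) {
    stop("line 17 (ICU days) must be in [0, 100]", call. = FALSE)
  }
  ifelse(days < 10, days * 0.8, 8)
}

#' Performance-scale multiplier of the IDDA2.1 score (line 15)
#'
#' The additive subtotal is multiplied by `150 / performance` for
#' performance scales above 29%, and by a fixed 6 at or below 29%
#' (correcting for very low performance scales, where division would
#' inflate the score without bound). The multiplier therefore lies in
#' \[1.5, 6\] and jumps from 5.0 at 30% to 6 at 29%.
#'
#' @param kps Integer Karnofsky/Lansky percent in \[10, 100\].
#' @return Numeric multiplier in \[1.5, 6\].
#' @export
#' @examples
#' idda_multiplier(c(100, 30, 29, 20))
idda_multiplier <- function(kps) {
  if (any(!is.na(kps) & (kps < 10 | kps > 100))) {
    stop("line 15 (performance scale) must be in [10, 100]", call. = FALSE)
  }
  ifelse(kps > 29, 150 / kps, 6)
}

#' Compute IDDA2.1 scores with component breakdown
#'
#' Evaluates the IDDA2.1 total for every visit row and returns the full
#' component breakdown: the organ sum (lines 1-14, range 0-56), the
#' capped hospitalization and ICU terms, the supportive-care sum (lines
#' 18-21, range 0-15), the performance-scale multiplier, and the total
#' `(organ_sum + hosp_term + icu_term + supportive_sum) * multiplier`
#' (range 0-498). The malignancy flag (line 22) is carried alongside but
#' never enters the total.
#'
#' Graded items marked `NA` (not assessed) make a visit unscoreable
#' under the default `missing_policy = "refuse"`; with
#' `missing_policy = "zero"` they are imputed as absent, which makes the
#' resulting total a lower bound.
#'
#' @param visits Visit table ([idda_visit()] / [read_visits()]).
#' @param missing_policy `"refuse"` (default) to error on `NA` graded
#'   items, `"zero"` to impute them as 0.
#' @return A data frame with one row per visit: `patient_id`,
#'   `visit_date`, `therapy_phase`, `organ_sum`, `hosp_term`, `icu_term`,
#'   `supportive_sum`, `multiplier`, `total`, `malignancy`.
#' @export
#' @examples
#' v <- idda_visit("P1", "2024-03-01",
#'                 organ_grades = c(2, 0, 3, 2, 0, 1, 0, 0, 0, 2, 0, 0, 1, 2),
#'                 performance = 70, hosp_days = 20, igg = "iv",
#'                 infestation = 2, other_organ = 1, nutrition = 2)
#' idda_score(v)
idda_score <- function(visits, missing_policy = c("refuse", "zero")) {
  missing_policy <- match.arg(missing_policy)
  findings <- validate_visits(visits)
  errors <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errors) > 0) {
    stop("invalid visit record(s); first finding: ", errors$message[1],
         " (row ", errors$row[1], ")", call. = FALSE)
  }
  graded_cols <- c(ORGAN_COLS, "p19", "p20", "p21")
  graded <- as.matrix(visits[, graded_cols, drop = FALSE])
  if (anyNA(graded)) {
    if (missing_policy == "refuse") {
      na_cols <- graded_cols[colSums(is.na(graded)) > 0]
      items <- idda_items()
      lines <- items$line[match(na_cols, items$column)]
      stop("visit(s) contain items not assessed (NA) on line(s) ",
           paste(sort(lines), collapse = ", "),
           "; use missing_policy = \"zero\" to score anyway", call. = FALSE)
    }
    graded[is.na(graded)] <- 0
  }
  organ_sum <- rowSums(graded[, ORGAN_COLS, drop = FALSE])
  hosp <- idda_hosp_term(visits$p16_hosp)
  icu <- idda_icu_term(visits$p17_icu)
  supportive <- igg_numeric(visits$p18_igg) +
    graded[, "p19"] + graded[, "p20"] + graded[, "p21"]
  mult <- idda_multiplier(visits$p15_performance)
  data.frame(
    patient_id = visits$patient_id,
    visit_date = visits$visit_date,
    therapy_phase = visits$therapy_phase,
    organ_sum = as.integer(organ_sum),
    hosp_term = hosp,
    icu_term = icu,
    supportive_sum = as.integer(supportive),
    multiplier = mult,
    total = (organ_sum + hosp + icu + supportive) * mult,
    malignancy = visits$p22_malignancy,
    stringsAsFactors = FALSE
  )
}

#' Longitudinal score trajectory for one patient
#'
#' Scores all visits of a single patient, orders them chronologically
#' and labels the change between consecutive visits (`"improving"` for a
#' strictly lower total than the previous visit, `"worsening"` for a
#' strictly higher one, `"stable"` for a tie). The result carries a
#' `"summary"` attribute: `"improving"`/`"worsening"` when every step
#' moves in that direction, `"stable"` when all totals tie, otherwise
#' `"mixed"` (`"single-visit"` for one visit).
#'
#' @param visits Visit table; either already restricted to one patient or
#'   filtered with `patient`.
#' @param patient Optional patient identifier to select.
#' @param missing_policy Passed to [idda_score()].
#' @return Scored visits sorted by `visit_date`, with a `change` column;
#'   attribute `"summary"` holds the overall trajectory label.
#' @export
score_trajectory <- function(visits, patient = NULL,
                             missing_policy = c("refuse", "zero")) {
  if (!is.null(patient)) {
    visits <- visits[visits$patient_id == patient, , drop = FALSE]
  }
  if (nrow(visits) == 0) stop("no visits for this patient", call. = FALSE)
  ids <- unique(visits$patient_id)
  if (length(ids) > 1) {
    stop("visits belong to multiple patients (",
         paste(ids, collapse = ", "),
         "); pass `patient` to select one", call. = FALSE)
  }
  if (anyDuplicated(visits$visit_date)) {
    stop("duplicate visit dates for patient ", ids, call. = FALSE)
  }
  scores <- idda_score(visits, missing_policy)
  scores <- scores[order(scores$visit_date), , drop = FALSE]
  rownames(scores) <- NULL
  d <- diff(scores$total)
  scores$change <- c(NA_character_,
                     ifelse(d < 0, "improving",
                            ifelse(d > 0, "worsening", "stable")))
  summary_label <- if (nrow(scores) == 1) "single-visit"
    else if (all(d < 0)) "improving"
    else if (all(d > 0)) "worsening"
    else if (all(d == 0)) "stable"
    else "mixed"
  attr(scores, "summary") <- summary_label
  scores
}

#' Per-item change between two therapy phases
#'
#' Compares the per-item mean grades of all visits in phase `phase_a`
#' with those in phase `phase_b` (useful e.g. before vs. after a
#' therapeutic measure). For each of the 22 items the delta is
#' `mean(phase_b) - mean(phase_a)`; line 18 is compared on its numeric
#' score value and line 22 on the malignancy proportion. A final
#' `total` row compares mean IDDA2.1 totals.
#'
#' @param visits Visit table with `therapy_phase` labels.
#' @param phase_a,phase_b Phase labels present in `visits$therapy_phase`.
#' @param missing_policy Passed to [idda_score()]; per-item means are
#'   taken over non-missing values.
#' @return Data frame with columns `line`, `item`, `mean_a`, `mean_b`,
#'   `delta`; the last row (`line = NA`, `item = "total"`) compares
#'   mean totals.
#' @export
phase_delta <- function(visits, phase_a, phase_b,
                        missing_policy = c("refuse", "zero")) {
  for (ph in c(phase_a, phase_b)) {
    if (!ph %in% visits$therapy_phase) {
      stop("therapy phase not found: ", ph, call. = FALSE)
    }
  }
  a <- visits[visits$therapy_phase %in% phase_a, , drop = FALSE]
  b <- visits[visits$therapy_phase %in% phase_b, , drop = FALSE]
  items <- idda_items()
  item_values <- function(df, col) {
    switch(items$role[items$column == col],
           igg = igg_numeric(df[[col]]),
           malignancy = as.numeric(df[[col]]),
           as.numeric(df[[col]]))
  }
  mean_a <- vapply(items$column, function(col)
    mean(item_values(a, col), na.rm = TRUE), numeric(1))
  mean_b <- vapply(items$column, function(col)
    mean(item_values(b, col), na.rm = TRUE), numeric(1))
  out <- data.frame(
    line = items$line,
    item = items$label,
    mean_a = unname(mean_a),
    mean_b = unname(mean_b),
    stringsAsFactors = FALSE
  )
  tot <- data.frame(
    line = NA_integer_, item = "total",
    mean_a = mean(idda_score(a, missing_policy)$total),
    mean_b = mean(idda_score(b, missing_policy)$total),
    stringsAsFactors = FALSE
  )
  out <- rbind(out, tot)
  out$delta <- out$mean_b - out$mean_a
  rownames(out) <- NULL
  out
}
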