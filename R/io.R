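# Readers/writers for the visit CSV dialect, frequency TSVs and
# archetype configuration files. Visits travel as CSV (comma, UTF-8,
# header required, empty cell = missing); matrices as TSV.

#' Read a visit table from CSV
#'
#' Reads the standard visit CSV dialect: one row per visit, columns
#' `patient_id, visit_date, therapy_phase, p01..p14, p15_performance,
#' p16_hosp, p17_icu, p18_igg, p19, p20, p21, p22_malignancy, p22_note`.
#' Empty cells are missing values. The table is validated on read;
#' error-severity findings are reported as a warning naming the rows
#' (scoring will refuse such rows later), unknown line-18 tokens are an
#' immediate error.
#'
#' @param path CSV file path.
#' @param validate Report validation findings on read (default `TRUE`).
#' @return Visit table (data frame); validation findings attached as
#'   attribute `"findings"`.
#' @export
read_visits <- function(path, validate = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  missing_cols <- setdiff(VISIT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("visit CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(x))
    if (length(bad) > 0) {
      stop("non-numeric ", what, " in column ", col, " at data row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    x
  }
  out <- data.frame(patient_id = df$patient_id,
                    visit_date = as.Date(df$visit_date),
                    therapy_phase = df$therapy_phase,
                    stringsAsFactors = FALSE)
  if (anyNA(out$visit_date) || anyNA(out$patient_id)) {
    stop("patient_id and ISO-8601 visit_date are required on every row",
         call. = FALSE)
  }
  for (col in c(ORGAN_COLS, "p19", "p20", "p21")) out[[col]] <- num(col, "grade")
  out$p15_performance <- num("p15_performance", "percent")
  out$p16_hosp <- num("p16_hosp", "days")
  out$p17_icu <- num("p17_icu", "days")
  igg <- tolower(df$p18_igg)
  bad <- which(!is.na(igg) & !(igg %in% names(IGG_LEVELS)))
  if (length(bad) > 0) {
    stop("unknown IgG substitution token(s) in p18_igg at data row(s) ",
         paste(bad, collapse = ", "), " (expected none, sporadic, iv, sc)",
         call. = FALSE)
  }
  out$p18_igg <- igg
  mal <- num("p22_malignancy", "flag")
  if (any(!is.na(mal) & !(mal %in% c(0, 1)))) {
    stop("p22_malignancy must be 0 or 1", call. = FALSE)
  }
  out$p22_malignancy <- mal == 1
  out$p22_note <- df$p22_note
  # reorder defensively; extra columns (e.g. cohort) are preserved at the end
  extra <- setdiff(names(df), VISIT_COLUMNS)
  for (col in extra) out[[col]] <- df[[col]]
  out <- out[, c(VISIT_COLUMNS, extra), drop = FALSE]
  if (validate) {
    findings <- validate_visits(out)
    errs <- findings[findings$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0) {
      warning("visit CSV has ", nrow(errs), " validation error finding(s), ",
              "first: ", errs$message[1], " (data row ", errs$row[1], ")")
    }
    attr(out, "findings") <- findings
  }
  out
}

#' Write a visit table to CSV
#'
#' Inverse of [read_visits()]: missing values become empty cells, the
#' malignancy flag is stored as 0/1, dates as ISO-8601.
#'
#' @param visits Visit table.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_visits <- function(visits, path) {
  out <- visits
  out$visit_date <- format(as.Date(out$visit_date), "%Y-%m-%d")
  out$p22_malignancy <- as.integer(out$p22_malignancy)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write cohort profiles as a frequency TSV
#'
#' Long-format TSV with one row per cohort x axis: columns `cohort`,
#' `n_patients`, `axis`, `line`, `axis_label`, `presence_count`,
#' `denominator`, `frequency_pct`. Unavailable axes (denominator 0)
#' have an empty `frequency_pct` cell. Output is byte-stable for
#' identical input.
#'
#' @param profiles An `idda_profile` or list of them.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_frequency_table <- function(profiles, path) {
  if (inherits(profiles, "idda_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(cohort = p$label, n_patients = p$n_patients,
               axis = p$table$axis, line = p$table$line,
               axis_label = p$table$label,
               presence_count = p$table$presence_count,
               denominator = p$table$denominator,
               frequency_pct = p$table$frequency_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a frequency TSV into a phenotype matrix
#'
#' Reads the long-format TSV of [write_frequency_table()] back into a
#' diseases x 17-feature matrix of proportions in \[0, 1\] suitable for
#' [cluster_phenotypes()]. Frequencies are canonically percentages in
#' \[0, 100\]; if every non-missing value is <= 1 the file is assumed to
#' hold proportions already and is taken as-is, with a warning.
#'
#' @param path TSV path.
#' @param eps Imputation value for unavailable axes (empty
#'   `frequency_pct`), as in [as_phenotype_matrix()].
#' @return Numeric matrix of proportions with `n_patients` attribute.
#' @export
read_frequency_table <- function(path, eps = 0.01) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  needed <- c("cohort", "n_patients", "axis", "frequency_pct")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("frequency TSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(df$frequency_pct) &
            (df$frequency_pct < 0 | df$frequency_pct > 100))) {
    stop("frequency_pct values must be in [0, 100]", call. = FALSE)
  }
  vals <- df$frequency_pct
  if (all(is.na(vals)) || max(vals, na.rm = TRUE) <= 1) {
    warning("all frequencies <= 1; interpreting them as proportions, ",
            "not percentages")
  } else {
    vals <- vals / 100
  }
  axes <- kaleidoscope_axes()
  cohorts <- unique(df$cohort)
  mat <- matrix(NA_real_, nrow = length(cohorts), ncol = 17,
                dimnames = list(cohorts, axes$label))
  n_pat <- integer(length(cohorts))
  for (i in seq_along(cohorts)) {
    sub <- df[df$cohort == cohorts[i], , drop = FALSE]
    if (!setequal(sub$axis, 1:17)) {
      stop("cohort ", cohorts[i], " does not have exactly axes 1-17",
           call. = FALSE)
    }
    mat[i, sub$axis] <- vals[df$cohort == cohorts[i]]
    n_pat[i] <- sub$n_patients[1]
  }
  rownames(mat) <- sprintf("%s (n=%d)", cohorts, n_pat)
  if (anyNA(mat)) {
    warning(sum(is.na(mat)), " unavailable axis value(s) imputed at ", eps)
    mat[is.na(mat)] <- eps
  }
  attr(mat, "n_patients") <- n_pat
  mat
}

#' Read archetype specifications from YAML or JSON
#'
#' The configuration holds a list of archetypes, each with the fields of
#' [archetype_spec()] (only `name` and `presence_probs` are required).
#' Unknown fields are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of `idda_archetype` objects.
#' @export
read_archetypes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE,
                                                    simplifyDataFrame = FALSE)
         else stop("archetype config must be .yaml/.yml or .json",
                   call. = FALSE)
  if (!is.null(raw$archetypes)) raw <- raw$archetypes
  allowed <- names(formals(archetype_spec))
  specs <- lapply(raw, function(a) {
    unknown <- setdiff(names(a), allowed)
    if (length(unknown) > 0) {
      stop("unknown archetype field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    a <- lapply(a, unlist)
    do.call(archetype_spec, a)
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Write archetype specifications to YAML or JSON
#'
#' @param archetypes List of [archetype_spec()] objects.
#' @param path Output `.yaml`/`.yml` or `.json` path.
#' @return Invisibly, `path`.
#' @export
write_archetypes <- function(archetypes, path) {
  if (inherits(archetypes, "idda_archetype")) archetypes <- list(archetypes)
  plain <- lapply(archetypes, function(a) lapply(unclass(a), unname))
  names(plain) <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(list(archetypes = plain), path)
  } else if (ext == "json") {
    jsonlite::write_json(list(archetypes = plain), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else stop("archetype config must be .yaml/.yml or .json", call. = FALSE)
  invisible(path)
}
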