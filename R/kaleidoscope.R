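# Cohort-level "kaleidoscope" profiles: each of the 17 axes reports the
# percentage of patients in whom the feature is present, reduced from
# the graded visit record to qualitative presence/absence.

#' Feature-presence vector of a visit (17 kaleidoscope axes)
#'
#' Reduces graded visit rows to qualitative presence on the 17 fixed
#' kaleidoscope axes: the graded items (lines 1-14 and 20) are present
#' at any grade >= 1, the IgG axis (line 18) is present when the numeric
#' line-18 value is > 0 (i.e. any substitution), and the malignancy axis
#' (line 22) follows the flag. `NA` graded items propagate as `NA`
#' (feature not assessed).
#'
#' @param visits Visit table.
#' @return Logical matrix, one row per visit, 17 columns named by axis
#'   label in the fixed kaleidoscope order.
#' @export
#' @examples
#' v <- idda_visit("P1", "2024-03-01", igg = "sporadic", malignancy = TRUE)
#' presence_matrix(v)[1, ]
presence_matrix <- function(visits) {
  findings <- validate_visits(visits)
  errors <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errors) > 0) {
    stop("invalid visit record(s); first finding: ", errors$message[1],
         call. = FALSE)
  }
  axes <- kaleidoscope_axes()
  out <- matrix(NA, nrow = nrow(visits), ncol = 17,
                dimnames = list(NULL, axes$label))
  for (k in 1:17) {
    col <- axes$column[k]
    out[, k] <- switch(as.character(axes$line[k]),
                       "18" = igg_numeric(visits[[col]]) > 0,
                       "22" = as.logical(visits[[col]]),
                       visits[[col]] >= 1)
  }
  out
}

#' Select one representative visit per patient
#'
#' Cohort profiles are patient-level: each patient contributes one
#' presence vector. Policy `"latest"` (default) takes each patient's
#' most recent visit. Policy `"worst"` builds a lifetime phenotype: for
#' every item the maximum grade across all of the patient's visits (for
#' line 18 the highest-scoring substitution status, for line 22 "ever
#' malignant"), with identifiers and date taken from the latest visit.
#'
#' @param visits Visit table (possibly several visits per patient).
#' @param policy `"latest"` or `"worst"`.
#' @return Visit table with exactly one row per patient.
#' @export
select_patient_visits <- function(visits, policy = c("latest", "worst")) {
  policy <- match.arg(policy)
  split_idx <- split(seq_len(nrow(visits)), visits$patient_id)
  rows <- lapply(split_idx, function(idx) {
    sub <- visits[idx, , drop = FALSE]
    latest <- sub[which.max(as.numeric(sub$visit_date)), , drop = FALSE]
    if (policy == "latest" || nrow(sub) == 1) return(latest)
    max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    for (col in c(ORGAN_COLS, "p19", "p20", "p21")) {
      latest[[col]] <- max_or_na(sub[[col]])
    }
    latest$p16_hosp <- max(sub$p16_hosp)
    latest$p17_icu <- max(sub$p17_icu)
    latest$p15_performance <- min(sub$p15_performance)
    latest$p18_igg <- sub$p18_igg[which.max(igg_numeric(sub$p18_igg))]
    latest$p22_malignancy <- any(sub$p22_malignancy)
    latest
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort feature-frequency profile
#'
#' Aggregates one visit per patient into the presence frequency (%) of
#' the 17 kaleidoscope features. Each axis uses its own denominator: the
#' number of patients in whom the feature was assessed (non-`NA`), so
#' partially documented cohorts do not fabricate absence. An axis
#' assessed in no patient has denominator 0 and frequency `NA`
#' (unavailable).
#'
#' @param visits Visit table with one row per patient (see
#'   [select_patient_visits()] to reduce multi-visit data).
#' @param label Cohort / diagnosis label.
#' @return An object of class `idda_profile`: a list with `label`,
#'   `n_patients`, and `table` (data frame with `axis`, `line`, `label`,
#'   `presence_count`, `denominator`, `frequency_pct`).
#' @export
#' @examples
#' v <- idda_visit(c("P1", "P2"), "2024-03-01",
#'                 organ_grades = rbind(c(1, rep(0, 13)), rep(0, 14)))
#' cohort_frequencies(v, "example")$table[1, ]
cohort_frequencies <- function(visits, label) {
  if (nrow(visits) == 0) stop("empty cohort: ", label, call. = FALSE)
  if (anyDuplicated(visits$patient_id)) {
    stop("cohort has multiple visits per patient; reduce with ",
         "select_patient_visits() first", call. = FALSE)
  }
  pres <- presence_matrix(visits)
  axes <- kaleidoscope_axes()
  count <- colSums(pres, na.rm = TRUE)
  denom <- colSums(!is.na(pres))
  freq <- ifelse(denom > 0, 100 * count / denom, NA_real_)
  structure(list(
    label = label,
    n_patients = nrow(visits),
    table = data.frame(
      axis = axes$axis, line = axes$line, label = axes$label,
      presence_count = as.integer(count),
      denominator = as.integer(denom),
      frequency_pct = unname(freq),
      stringsAsFactors = FALSE
    )
  ), class = "idda_profile")
}

#' @export
print.idda_profile <- function(x, ...) {
  cat(sprintf("IDDA2.1 kaleidoscope profile: %s (n=%d)\n",
              x$label, x$n_patients))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Build cohort profiles grouped by diagnosis
#'
#' @param visits Visit table.
#' @param group Character vector (length `nrow(visits)`) of cohort
#'   labels, e.g. a diagnosis column.
#' @param visit_policy Passed to [select_patient_visits()].
#' @return Named list of [cohort_frequencies()] profiles.
#' @export
cohort_profiles <- function(visits, group,
                            visit_policy = c("latest", "worst")) {
  visit_policy <- match.arg(visit_policy)
  stopifnot(length(group) == nrow(visits))
  idx <- split(seq_len(nrow(visits)), group)
  lapply(idx, function(i) {
    one <- select_patient_visits(visits[i, , drop = FALSE], visit_policy)
    cohort_frequencies(one, unique(group[i]))
  })
}

radar_coords <- function(values, r_max = 100) {
  n <- length(values)
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n  # axis 1 at top, clockwise
  list(x = values / r_max * cos(theta), y = values / r_max * sin(theta),
       theta = theta)
}

#' Render kaleidoscope radar chart(s)
#'
#' Draws one or more cohort profiles as a radar (spider) chart with the
#' 17 axes in the fixed kaleidoscope order, radial scale 0-100%.
#' Unavailable axes (denominator 0) are drawn as gaps, not zeros. Also
#' writes the underlying frequency table as TSV next to the image
#' (byte-stable across re-runs).
#'
#' @param profiles A single `idda_profile` or a list of them (overlaid).
#' @param out_path Output image path; format from extension (`.svg` or
#'   `.png`).
#' @param tsv_path Path for the frequency TSV; defaults to `out_path`
#'   with a `.tsv` extension. `NA` suppresses it.
#' @param colors Optional vector of polygon colors.
#' @return Invisibly, the TSV path (or `NA`).
#' @export
render_kaleidoscope <- function(profiles, out_path, tsv_path = NULL,
                                colors = NULL) {
  if (inherits(profiles, "idda_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "idda_profile")))
  if (is.null(tsv_path)) tsv_path <- sub("\\.[a-zA-Z]+$", ".tsv", out_path)
  if (!is.na(tsv_path)) write_frequency_table(profiles, tsv_path)

  ext <- tolower(tools::file_ext(out_path))
  if (ext == "png") grDevices::png(out_path, width = 900, height = 800)
  else grDevices::svg(out_path, width = 9, height = 8)
  on.exit(grDevices::dev.off())

  axes <- kaleidoscope_axes()
  if (is.null(colors)) {
    colors <- grDevices::hcl.colors(max(3, length(profiles)), "Dark 3")
  }
  graphics::par(mar = c(1, 1, 3, 1))  # device-local; dies with dev.off()
  graphics::plot(NA, xlim = c(-1.7, 1.7), ylim = c(-1.5, 1.5), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  for (r in c(25, 50, 75, 100) / 100) {
    ang <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(r * cos(ang), r * sin(ang), col = "grey80", lty = 3)
  }
  spokes <- radar_coords(rep(100, 17))
  graphics::segments(0, 0, spokes$x, spokes$y, col = "grey85")
  lab_r <- 1.12
  graphics::text(lab_r * cos(spokes$theta), lab_r * sin(spokes$theta),
                 labels = paste0(axes$axis, ". ", axes$label),
                 cex = 0.55, col = "grey30",
                 adj = ifelse(cos(spokes$theta) < -0.1, 1,
                              ifelse(cos(spokes$theta) > 0.1, 0, 0.5)))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    freq <- p$table$frequency_pct
    cc <- radar_coords(freq)
    ok <- !is.na(freq)
    # draw contiguous runs so unavailable axes leave a visible gap
    runs <- split(which(ok), cumsum(!ok)[ok])
    for (run in runs) {
      if (length(run) == 1) {
        graphics::points(cc$x[run], cc$y[run], col = colors[i], pch = 16)
      } else {
        graphics::lines(cc$x[run], cc$y[run], col = colors[i], lwd = 2)
      }
    }
    if (all(ok)) {
      graphics::polygon(cc$x, cc$y, border = colors[i], lwd = 2,
                        col = grDevices::adjustcolor(colors[i], alpha.f = 0.15))
    }
    if (any(!ok)) {
      graphics::points(1.02 * cos(cc$theta[!ok]), 1.02 * sin(cc$theta[!ok]),
                       pch = 4, col = "grey50", cex = 0.8)
    }
  }
  titles <- vapply(profiles, function(p)
    sprintf("%s (n=%d)", p$label, p$n_patients), character(1))
  if (length(profiles) == 1) {
    graphics::title(main = titles)
  } else {
    graphics::title(main = "IDDA2.1 kaleidoscope profiles")
    graphics::legend("topleft", legend = titles, col = colors[seq_along(profiles)],
                     lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(tsv_path)
}
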