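# Shared fixtures and independent oracles.

# Random admissible visit records spanning the full ranges of every item.
random_visits <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  organ <- matrix(sample(0:4, n * 14, replace = TRUE), nrow = n)
  hosp <- round(runif(n, 0, 100), 2)
  icu <- pmin(round(runif(n, 0, 100), 2), 100 - hosp)
  idda_visit(
    patient_id = sprintf("R%05d", seq_len(n)),
    visit_date = as.Date("2020-01-01") + sample(0:2000, n, replace = TRUE),
    organ_grades = organ,
    performance = sample(10:100, n, replace = TRUE),
    hosp_days = hosp, icu_days = icu,
    igg = sample(c("none", "sporadic", "iv", "sc"), n, replace = TRUE),
    infestation = sample(0:4, n, replace = TRUE),
    other_organ = sample(0:4, n, replace = TRUE),
    nutrition = sample(0:4, n, replace = TRUE),
    malignancy = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
}

# Independent scalar transcription of the published spreadsheet
# expression, evaluated row by row with its own line-18 lookup. Kept
# deliberately literal and separate from the package's vectorized path.
excel_total <- function(visits) {
  vapply(seq_len(nrow(visits)), function(i) {
    line <- function(col) visits[[col]][i]
    organ <- sum(vapply(sprintf("p%02d", 1:14), line, numeric(1)))
    l16 <- line("p16_hosp")
    l17 <- line("p17_icu")
    l15 <- line("p15_performance")
    l18 <- switch(line("p18_igg"), none = 0, sporadic = 2, iv = 3, sc = 3)
    subtotal <- organ +
      (if (l16 < 40) l16 * 0.1 else 4) +
      (if (l17 < 10) l17 * 0.8 else 8) +
      l18 + line("p19") + line("p20") + line("p21")
    subtotal * (if (l15 > 29) 150 / l15 else 6)
  }, numeric(1))
}

# Naive O(n^3) agglomerative complete linkage on the rows of a raw
# coordinate matrix. Returns merge heights (in merge order) and the
# partition (membership vector) after each merge. Ties broken by the
# lexicographically lowest cluster-index pair.
naive_complete_linkage <- function(X) {
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  membership <- seq_len(n)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d - 1e-12) {
          best_d <- dij; best <- c(i, j)
        }
      }
    }
    heights[step] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
    partitions[[step]] <- membership
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a membership vector (label-invariant comparison).
canon_partition <- function(m) as.integer(factor(m, levels = unique(m)))

# Ground-truth archetype label per profile row of a sample_study() result.
study_truth_labels <- function(study, mat) {
  cohorts <- sub(" \\(n=\\d+\\)$", "", rownames(mat))
  study$truth$archetype[match(cohorts, study$truth$cohort)]
}
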