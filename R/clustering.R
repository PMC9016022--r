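# "Phenotype expression array": diseases x 17-feature frequency matrices
# are logit-transformed after clamping to [eps, 1-eps] and clustered in
# both dimensions by complete linkage on Euclidean distances.

#' Truncated logit transform
#'
#' Maps presence proportions to the real line via the natural-log logit
#' after clamping to `[eps, 1 - eps]` ("truncated at 1%" for the default
#' `eps = 0.01`), so that cohorts in which a feature is absent (0%) or
#' universal (100%) remain finite. The transform is strictly monotone on
#' the clamped range and antisymmetric about 0.5:
#' `logit_truncate(1 - p) == -logit_truncate(p)`.
#'
#' @param p Numeric vector/matrix of proportions in \[0, 1\].
#' @param eps Truncation bound in (0, 0.5); default 0.01.
#' @return Transformed values in `[logit(eps), logit(1 - eps)]`.
#' @export
#' @examples
#' logit_truncate(c(0, 0.5, 1))
logit_truncate <- function(p, eps = 0.01) {
  stopifnot(is.numeric(eps), length(eps) == 1, eps > 0, eps < 0.5)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("proportions must be in [0, 1]", call. = FALSE)
  }
  q <- pmin(pmax(p, eps), 1 - eps)
  out <- log(q / (1 - q))
  if (is.matrix(p)) out <- matrix(out, nrow(p), ncol(p), dimnames = dimnames(p))
  out
}

#' Assemble a phenotype frequency matrix from cohort profiles
#'
#' Stacks cohort profiles into a diseases x 17-feature matrix of presence
#' proportions in \[0, 1\] (row labels carry the cohort size as
#' `"label (n=...)"`). Unavailable axes (denominator 0) are imputed at
#' the clamp floor `eps` with a warning, so that sparse cohorts remain
#' clusterable without pretending the feature was observed absent.
#'
#' @param profiles List of `idda_profile` objects.
#' @param eps Imputation value for unavailable axes (matches the
#'   truncation bound of [logit_truncate()]).
#' @return Numeric matrix of proportions with an `n_patients` attribute.
#' @export
as_phenotype_matrix <- function(profiles, eps = 0.01) {
  if (inherits(profiles, "idda_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  axes <- kaleidoscope_axes()
  mat <- t(vapply(profiles, function(p) p$table$frequency_pct / 100,
                  numeric(17)))
  rownames(mat) <- vapply(profiles, function(p)
    sprintf("%s (n=%d)", p$label, p$n_patients), character(1))
  colnames(mat) <- axes$label
  if (anyNA(mat)) {
    warning(sum(is.na(mat)), " unavailable axis value(s) imputed at ", eps)
    mat[is.na(mat)] <- eps
  }
  attr(mat, "n_patients") <- vapply(profiles, `[[`, integer(1), "n_patients")
  mat
}

#' Cluster a phenotype frequency matrix in both dimensions
#'
#' Applies the truncated logit transform to the proportion matrix, then
#' clusters rows (diseases) and columns (features) independently by
#' agglomerative complete linkage on Euclidean distances. Complete
#' linkage takes the maximum pairwise distance between clusters, so
#' merge heights are non-decreasing. Optional feature scaling
#' (`"rows"`/`"cols"`: center and scale that dimension of the
#' transformed matrix) is off by default.
#'
#' @param mat Numeric matrix of proportions in \[0, 1\] (diseases x
#'   features), e.g. from [as_phenotype_matrix()] or
#'   [read_frequency_table()].
#' @param eps Truncation bound for [logit_truncate()].
#' @param scale One of `"none"` (default), `"rows"`, `"cols"`.
#' @return An object of class `idda_clustering`: list with `row_hclust`,
#'   `col_hclust` (stats::hclust trees), `row_order`, `col_order` (leaf
#'   orders), and `transformed` (the matrix actually clustered).
#' @export
#' @examples
#' m <- matrix(runif(34), nrow = 2,
#'             dimnames = list(c("A (n=5)", "B (n=8)"),
#'                             kaleidoscope_axes()$label))
#' cluster_phenotypes(m)$row_hclust$height
cluster_phenotypes <- function(mat, eps = 0.01,
                               scale = c("none", "rows", "cols")) {
  scale <- match.arg(scale)
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  tr <- logit_truncate(mat, eps)
  if (scale == "rows") tr <- t(base::scale(t(tr)))
  if (scale == "cols") tr <- base::scale(tr)
  tr[is.nan(tr)] <- 0  # constant rows/cols under scaling
  attr(tr, "scaled:center") <- NULL
  attr(tr, "scaled:scale") <- NULL
  row_hc <- stats::hclust(stats::dist(tr), method = "complete")
  col_hc <- stats::hclust(stats::dist(t(tr)), method = "complete")
  structure(list(
    row_hclust = row_hc, col_hclust = col_hc,
    row_order = row_hc$order, col_order = col_hc$order,
    transformed = tr, eps = eps, scale = scale
  ), class = "idda_clustering")
}

#' @export
print.idda_clustering <- function(x, ...) {
  cat("IDDA2.1 phenotype clustering (complete linkage, Euclidean,",
      sprintf("logit truncated at %g)\n", x$eps))
  cat("rows:", nrow(x$transformed), "cohorts; leaf order:",
      paste(rownames(x$transformed)[x$row_order], collapse = ", "), "\n")
  cat("cols:", ncol(x$transformed), "features\n")
  invisible(x)
}

#' Cut the disease dendrogram into k groups
#'
#' @param result An `idda_clustering` object.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships (one per row).
#' @export
cut_phenotype_clusters <- function(result, k) {
  stats::cutree(result$row_hclust, k = k)
}

#' Export a dendrogram as Newick
#'
#' Writes either tree of a clustering result in Newick format with merge
#' heights converted to branch lengths (ultrametric tree).
#'
#' @param result An `idda_clustering` object.
#' @param which `"rows"` (diseases) or `"cols"` (features).
#' @param path Optional file path; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(result, which = c("rows", "cols"),
                              path = NULL) {
  which <- match.arg(which)
  hc <- if (which == "rows") result$row_hclust else result$col_hclust
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Render the clustered phenotype heatmap
#'
#' Draws the transformed matrix as a heatmap with rows and columns
#' permuted to the dendrogram leaf orders, dendrograms on the margins,
#' and a red-high / blue-low diverging palette (high frequency red, low
#' frequency blue). Row labels carry the cohort size.
#'
#' @param mat The proportion matrix passed to [cluster_phenotypes()].
#' @param result The matching `idda_clustering` object.
#' @param out_path Output image path (`.svg`, `.pdf` or `.png`).
#' @return Invisibly, `out_path`.
#' @export
render_heatmap <- function(mat, result, out_path) {
  stopifnot(inherits(result, "idda_clustering"))
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  ph <- pheatmap::pheatmap(
    result$transformed,
    cluster_rows = result$row_hclust,
    cluster_cols = result$col_hclust,
    color = pal,
    border_color = "grey90",
    silent = TRUE
  )
  ext <- tolower(tools::file_ext(out_path))
  switch(ext,
         png = grDevices::png(out_path, width = 1000, height = 700),
         pdf = grDevices::pdf(out_path, width = 11, height = 7.5),
         grDevices::svg(out_path, width = 11, height = 7.5))
  on.exit(grDevices::dev.off())
  grid::grid.newpage()
  grid::grid.draw(ph$gtable)
  invisible(out_path)
}
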