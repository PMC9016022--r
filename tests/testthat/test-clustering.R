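test_that("truncated logit clamps at eps and is antisymmetric", {
  expect_identical(logit_truncate(0.5), 0)
  expect_equal(logit_truncate(0), log(0.01 / 0.99))
  expect_equal(logit_truncate(1), -log(0.01 / 0.99))
  expect_equal(logit_truncate(0.005), logit_truncate(0))  # inside the clamp
  expect_equal(logit_truncate(0.3, eps = 0.1), log(0.3 / 0.7))
  expect_error(logit_truncate(1.2), "\\[0, 1\\]")
  expect_error(logit_truncate(0.5, eps = 0.6))

  p <- seq(0, 1, length.out = 1001)
  expect_equal(logit_truncate(p), -logit_truncate(1 - p), tolerance = 1e-12)
  inner <- seq(0.01, 0.99, length.out = 1001)
  expect_true(all(diff(logit_truncate(inner)) > 0))  # strictly monotone
})

test_that("profiles assemble into a proportion matrix with imputation", {
  st <- sample_study(example_archetypes(), 1, 20, seed = 3)
  m <- as_phenotype_matrix(st$profiles)
  expect_identical(dim(m), c(3L, 17L))
  expect_true(all(m >= 0 & m <= 1))
  expect_match(rownames(m)[1], "\\(n=20\\)")
  # unavailable axes imputed at the clamp floor, with a warning
  p <- st$profiles[[1]]
  p$table$frequency_pct[4] <- NA
  expect_warning(m2 <- as_phenotype_matrix(list(p, st$profiles[[2]])),
                 "imputed")
  expect_equal(m2[1, 4], 0.01)
})

test_that("two rows merge at their transformed Euclidean distance", {
  m <- rbind(a = c(0.2, 0.8), b = c(0.6, 0.4))
  res <- cluster_phenotypes(m)
  expect_equal(res$row_hclust$height,
               sqrt(sum((logit_truncate(m[1, ]) - logit_truncate(m[2, ]))^2)))
})

test_that("complete linkage merges by maximum distance", {
  # transformed coordinates (0,0), (0,1), (0,3): first merge at 1, then 3
  m <- cbind(rep(0.5, 3), stats::plogis(c(0, 1, 3)))
  res <- cluster_phenotypes(m)
  expect_equal(res$row_hclust$height, c(1, 3), tolerance = 1e-9)
  expect_identical(canon_partition(stats::cutree(res$row_hclust, 2)),
                   canon_partition(c(1, 1, 2)))

  # duplicated rows merge at height 0 before anything else
  dup <- rbind(c(0.2, 0.7), c(0.9, 0.1), c(0.2, 0.7))
  res <- cluster_phenotypes(dup)
  expect_equal(res$row_hclust$height[1], 0)
  expect_identical(canon_partition(stats::cutree(res$row_hclust, 2)),
                   canon_partition(c(1, 2, 1)))

  # constant matrix: all merges at height 0, still a valid tree
  const <- matrix(0.4, 3, 4)
  res <- cluster_phenotypes(const)
  expect_equal(res$row_hclust$height, c(0, 0))
  expect_true(all(diff(res$col_hclust$height) >= 0))
})

test_that("merge heights and partitions match a naive O(n^3) oracle", {
  set.seed(101)
  for (trial in 1:60) {
    n <- sample(2:6, 1)
    m <- matrix(runif(n * 5), nrow = n)
    res <- cluster_phenotypes(m)
    oracle <- naive_complete_linkage(logit_truncate(m))
    expect_equal(res$row_hclust$height, oracle$heights, tolerance = 1e-9)
    for (step in seq_len(n - 1)) {
      k <- n - step
      expect_identical(canon_partition(stats::cutree(res$row_hclust, k)),
                       canon_partition(oracle$partitions[[step]]))
    }
  }
})

test_that("clustering is invariant to row permutation", {
  set.seed(111)
  m <- matrix(runif(6 * 17), nrow = 6,
              dimnames = list(paste0("d", 1:6), kaleidoscope_axes()$label))
  perm <- sample(6)
  r1 <- cluster_phenotypes(m)
  r2 <- cluster_phenotypes(m[perm, ])
  c1 <- stats::cophenetic(r1$row_hclust)
  c2 <- stats::cophenetic(r2$row_hclust)
  expect_equal(as.matrix(c2)[rownames(m), rownames(m)], as.matrix(c1),
               tolerance = 1e-12)
  expect_equal(sort(r1$row_hclust$height), sort(r2$row_hclust$height))
})

test_that("merge heights are non-decreasing (ultrametric property)", {
  set.seed(121)
  for (trial in 1:20) {
    m <- matrix(runif(8 * 6), nrow = 8)
    res <- cluster_phenotypes(m)
    expect_true(all(diff(res$row_hclust$height) >= -1e-12))
    expect_true(all(diff(res$col_hclust$height) >= -1e-12))
  }
})

test_that("optional scaling modes run and default leaves values unscaled", {
  m <- matrix(runif(5 * 4), nrow = 5)
  res <- cluster_phenotypes(m)
  expect_equal(res$transformed, logit_truncate(m), ignore_attr = TRUE)
  for (sc in c("rows", "cols")) {
    rs <- cluster_phenotypes(m, scale = sc)
    expect_true(all(is.finite(rs$transformed)))
  }
})

test_that("dendrograms export to Newick with merge-height branch lengths", {
  set.seed(131)
  m <- matrix(runif(4 * 6), nrow = 4,
              dimnames = list(paste0("dis", 1:4), paste0("f", 1:6)))
  res <- cluster_phenotypes(m)
  nwk <- dendrogram_newick(res, "rows")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("dis", 1:4))
  # ultrametric: root-to-tip depth equals half... depth equals max height
  expect_true(ape::is.ultrametric(phy, tol = 1e-8))
  path <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(res, "cols", path)
  expect_identical(ape::read.tree(path)$Nnode, 5L)
})

test_that("heatmap rendering writes the clustered figure", {
  dir <- withr::local_tempdir()
  st <- sample_study(example_archetypes(), 2, 25, seed = 17)
  m <- as_phenotype_matrix(st$profiles)
  res <- cluster_phenotypes(m)
  out <- file.path(dir, "heat.svg")
  render_heatmap(m, res, out)
  expect_true(file.exists(out) && file.size(out) > 0)
  # planted structure: leaf order keeps archetype blocks contiguous
  truth <- study_truth_labels(st, m)
  ordered <- truth[res$row_order]
  expect_identical(length(rle(ordered)$values), length(unique(truth)))
})
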