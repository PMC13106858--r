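toy_matrix <- function() {
  counts <- matrix(c(5, 2, NA,
                     6, 3, NA,
                     7, 1, NA,
                     8, 4, 2,
                     9, 5, 3), nrow = 5, byrow = TRUE,
                   dimnames = list(NULL, c("A", "B", "C")))
  cell_matrix(counts, tibble::tibble(cell = paste0("c", 1:5),
                                     x = 1:5, y = 1:5))
}

test_that("missingness filter drops genes at the threshold, then cells", {
  cm <- toy_matrix()
  # gene C missing in 3 cells; threshold 3 drops it (missing >= 3)
  out <- suppressMessages(filter_matrix(cm, max_missing_per_gene = 3,
                                        min_counts_per_cell = 0))
  expect_equal(colnames(out$counts), c("A", "B"))
  expect_false(anyNA(out$counts))
  # threshold 4 keeps gene C and imputes missing to 0
  out2 <- suppressMessages(filter_matrix(cm, max_missing_per_gene = 4,
                                         min_counts_per_cell = 0))
  expect_equal(unname(out2$counts[1, "C"]), 0)
  # cell boundary: total 19 dropped, total 20 kept
  counts <- matrix(c(19, 0, 20, 0, 30, 5), nrow = 3, byrow = TRUE,
                   dimnames = list(NULL, c("A", "B")))
  cm2 <- cell_matrix(counts, tibble::tibble(cell = paste0("c", 1:3),
                                            x = 1:3, y = 1:3))
  out3 <- suppressMessages(filter_matrix(cm2, min_counts_per_cell = 20))
  expect_equal(out3$cells$cell, c("c2", "c3"))
  rep <- attr(out3, "filter_report")
  expect_equal(rep$cells_kept + rep$cells_dropped, rep$cells_in)
  expect_equal(rep$genes_kept + rep$genes_dropped, rep$genes_in)
  # identity when nothing is missing and all cells pass
  out4 <- suppressMessages(filter_matrix(cm2, min_counts_per_cell = 1))
  expect_equal(out4$counts, cm2$counts)
  expect_error(suppressMessages(filter_matrix(cm2, min_counts_per_cell = 100)),
               "100")
})

test_that("Pearson residuals match the hand example and the Poisson limit", {
  m <- matrix(c(2, 0, 0, 2), 2, 2, dimnames = list(NULL, c("g1", "g2")))
  r <- pearson_residuals(m, theta = 100)
  expect_equal(abs(as.vector(r)), rep(1 / sqrt(1.01), 4), tolerance = 1e-9)
  expect_equal(unname(r[1, 1]), 0.99504, tolerance = 1e-5)
  # rank-1 integer matrix: x equals mu, all residuals zero
  a <- c(1, 2, 3); b <- c(2, 1, 4)
  m2 <- outer(a, b)
  colnames(m2) <- paste0("g", 1:3)
  expect_true(all(abs(pearson_residuals(m2)) < 1e-12))
  # theta -> Inf recovers Poisson residuals
  set.seed(3)
  m3 <- matrix(rpois(200, 5) + 1, 20, 10,
               dimnames = list(NULL, paste0("g", 1:10)))
  rs <- rowSums(m3); cs <- colSums(m3)
  mu <- outer(rs, cs) / sum(m3)
  pois <- (m3 - mu) / sqrt(mu)
  expect_lt(max(abs(unclass(pearson_residuals(m3, theta = 1e9)) - pois)), 1e-6)
  # clipping bound sqrt(n_cells)
  m4 <- matrix(c(1, 1, 1, 1, 1, 1, 500, 1, 1), 3, 3,
               dimnames = list(NULL, paste0("g", 1:3)))
  r4 <- pearson_residuals(m4)
  expect_lte(max(abs(r4)), sqrt(3))
  expect_equal(attr(r4, "clip_bound"), sqrt(3))
  # degenerate inputs
  m5 <- cbind(g1 = c(1, 1), g2 = c(0, 0))
  expect_error(pearson_residuals(m5), "g2")
})

test_that("Pearson residuals are permutation-equivariant", {
  set.seed(5)
  m <- matrix(rpois(60, 4) + 1, 6, 10, dimnames = list(NULL, paste0("g", 1:10)))
  r <- unclass(pearson_residuals(m))
  pr <- sample(6); pc <- sample(10)
  r2 <- unclass(pearson_residuals(m[pr, pc]))
  expect_equal(r2, r[pr, pc], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("clustering separates planted types and is stable to duplication", {
  d <- make_two_type_data(seed = 1)
  cmf <- suppressMessages(filter_matrix(d$mc$cells, 1, 20))
  res <- pearson_residuals(cmf$counts)
  cl <- reduce_and_cluster(res, n_pcs = 10, seed = 1)
  expect_equal(length(unique(cl)), 2)
  expect_gt(adjusted_rand(cl, d$mc$true_labels), 0.9)
  # duplicating every cell leaves the induced partition intact (modularity
  # resolution is scale-dependent, so the perturbation check fixes it)
  cl_fix <- reduce_and_cluster(res, n_pcs = 10, resolution = 0.25, seed = 1)
  res2 <- rbind(res, res)
  cl2 <- reduce_and_cluster(res2, n_pcs = 10, resolution = 0.25, seed = 1)
  n <- nrow(res)
  expect_equal(cl2[1:n], cl2[(n + 1):(2 * n)])   # copies co-cluster
  expect_gt(adjusted_rand(cl2[1:n], cl_fix), 0.9)
  expect_error(reduce_and_cluster(res[1:10, ], k = 30), "fewer cells")
})

test_that("a single cell type collapses to one cluster at low resolution", {
  img <- make_plaque_image(n_plaques = 2, image_size = 150, seed = 1)
  panel <- c(paste0("Mk", 1:5), paste0("Bg", 1:15))
  ok <- 0
  for (s in 1:5) {
    mc <- make_cells(list(cell_type_spec("t", paste0("Mk", 1:5))), 250,
                     panel, img$mask, seed = s)
    res <- pearson_residuals(suppressMessages(filter_matrix(mc$cells, 1, 20))$counts)
    cl <- reduce_and_cluster(res, n_pcs = 10, resolution = 0.1, seed = 1)
    if (length(unique(cl)) == 1) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("gene-set scores separate planted high cells and centre the null", {
  d <- make_two_type_data(seed = 2)
  cmf <- suppressMessages(filter_matrix(d$mc$cells, 1, 20))
  res <- pearson_residuals(cmf$counts)
  sc <- score_gene_set(res, paste0("Mk", 1:5), seed = 1)
  truth <- d$mc$true_labels == "typeA"
  expect_gt(auroc(sc, truth), 0.95)
  # whole panel scored against itself: centred at zero
  for (s in 1:10) {
    sc0 <- score_gene_set(res, colnames(res), seed = s)
    expect_lt(max(abs(sc0)), 0.05)
  }
  # constant expression matrix: score exactly zero
  cm <- matrix(3, 50, 10, dimnames = list(NULL, paste0("g", 1:10)))
  expect_true(all(score_gene_set(cm, c("g1", "g2"), seed = 1) == 0))
  expect_error(suppressWarnings(score_gene_set(res, c("Zz1", "Zz2"))),
               "no set gene")
  expect_warning(score_gene_set(res, c("Mk1", "Zz1"), seed = 1), "Zz1")
})

test_that("annotation separation matches the worked example and its invariances", {
  scores <- data.frame(ct = c(1.0, 1.2, 0.8, 0.0, 0.1, -0.1, 0.0))
  clusters <- c(1, 1, 1, 2, 2, 2, 2)
  ann <- annotate_clusters(scores, clusters)
  s <- ann$table$separation[ann$table$cluster == "1"]
  expect_equal(s, 4.27, tolerance = 0.01)
  expect_equal(ann$assignment$assigned_type[ann$assignment$cluster == "1"], "ct")
  # affine invariance: shift by any c, scale by any c > 0
  for (tf in list(function(x) x + 17.3, function(x) x * 4.2,
                  function(x) 2.5 * x - 3)) {
    ann2 <- annotate_clusters(data.frame(ct = tf(scores$ct)), clusters)
    expect_equal(ann2$table$separation[ann2$table$cluster == "1"], s,
                 tolerance = 1e-12)
  }
  # scores indistinguishable between cluster and rest: unannotated
  set.seed(1)
  flat <- data.frame(ct = rnorm(100))
  ann3 <- annotate_clusters(flat, rep(1:2, 50))
  expect_true(all(ann3$assignment$assigned_type == "unannotated"))
  # the whole dataset as one cluster has no reference pool
  expect_error(annotate_clusters(flat, rep(1, 100)), "other cells")
})

test_that("ambiguous clusters report every qualifying type, assign argmax", {
  scores <- data.frame(t1 = c(rep(5, 10), rep(0, 20)),
                       t2 = c(rep(3, 10), rep(0, 20)))
  scores <- scores + matrix(rnorm(60, sd = 0.1), 30, 2)
  ann <- annotate_clusters(scores, c(rep(1, 10), rep(2, 20)))
  row <- ann$assignment[ann$assignment$cluster == "1", ]
  expect_equal(row$assigned_type, "t1")
  expect_equal(row$n_qualifying, 2)
  expect_match(row$qualifying_types, "t1;t2")
})

test_that("plaque-adjacent types concentrate their distance histogram", {
  d <- make_two_type_data(seed = 3)
  f <- distance_field(plaque_field_from_mask(d$img$mask, pixel_scale(1)))
  cells <- dplyr::mutate(d$mc$cells$cells, type = d$mc$true_labels)
  h <- celltype_distance_histogram(cells, f, bin_width = 5, max_range = 200)
  mass_near <- function(ty) {
    sub <- h[h$type == ty, ]
    sum(sub$density[sub$bin_hi <= 69]) / sum(sub$density)
  }
  expect_gte(mass_near("typeA"), 0.7)      # planted adjacent
  expect_lt(mass_near("typeB"), mass_near("typeA"))
  # no plaques: empty result with a warning
  f0 <- distance_field(plaque_field_from_mask(matrix(0, 50, 50), pixel_scale(1)))
  expect_warning(h0 <- celltype_distance_histogram(cells, f0), "no plaques|infinite")
  expect_equal(nrow(h0), 0)
})

test_that("uniformly placed cells give a flat renormalized histogram", {
  img <- make_plaque_image(n_plaques = 1, radius_range = c(8, 10),
                           image_size = c(500, 500), seed = 4)
  f <- distance_field(plaque_field_from_mask(img$mask, pixel_scale(1)))
  set.seed(11)
  cells <- tibble::tibble(x = runif(20000, 0, 499), y = runif(20000, 0, 499),
                          type = "u")
  h <- celltype_distance_histogram(cells, f, bin_width = 10, max_range = 150)
  # annulus renormalization flattens the quadratic growth near the plaque
  inner <- h$density[h$bin_lo >= 20 & h$bin_hi <= 150]
  expect_lt(max(inner) / min(inner), 2)
})
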