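# Independent oracles used across test files.

# Brute-force Euclidean distance of every pixel to the nearest labeled pixel.
brute_force_distance <- function(labels, s = 1) {
  fg <- which(labels > 0, arr.ind = TRUE)
  nr <- nrow(labels); nc <- ncol(labels)
  out <- matrix(Inf, nr, nc)
  if (nrow(fg) == 0) return(out)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      out[r, c] <- sqrt(min((fg[, 1] - r)^2 + (fg[, 2] - c)^2)) * s
    }
  }
  out
}

# Rank-based AUROC of score for binary labels.
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small two-type synthetic cell data used by several cell-typing tests.
make_two_type_data <- function(seed, n_per_type = 200) {
  panel <- c(paste0("Mk", 1:10), paste0("Bg", 1:20))
  img <- make_plaque_image(n_plaques = 4, image_size = c(300, 300), seed = 2)
  types <- list(
    cell_type_spec("typeA", paste0("Mk", 1:5), spatial_rule = "plaque_adjacent"),
    cell_type_spec("typeB", paste0("Mk", 6:10))
  )
  mc <- make_cells(types, n_per_type, panel, img$mask, seed = seed)
  list(panel = panel, img = img, mc = mc)
}

# Adjusted Rand index (agreement of two partitions, chance-corrected).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
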