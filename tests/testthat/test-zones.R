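make_line_field <- function() {
  m <- matrix(0, 120, 700)
  m[, 1] <- 1
  distance_field(plaque_field_from_mask(m, pixel_scale(1)))
}

test_that("zone boundaries follow the closed-upper-bound rule", {
  f <- make_line_field()
  pts <- tibble::tibble(x = c(0, 30, 69, 69.5, 600), y = rep(50, 5),
                        gene = "g")
  z <- assign_zones(f, pts, zone_radius = 69)
  expect_equal(as.character(z$zone),
               c("inside", "adjacent", "adjacent", "outside", "outside"))
})

test_that("a point at sqrt(60^2 + 40^2) = 72.11 um is outside", {
  m <- matrix(0, 100, 100)
  m[1, 1] <- 1
  f <- distance_field(plaque_field_from_mask(m, pixel_scale(1)))
  z <- assign_zones(f, tibble::tibble(x = 60, y = 40, gene = "g"))
  expect_equal(round(z$distance, 2), 72.11)
  expect_equal(as.character(z$zone), "outside")
})

test_that("no plaques means everything is outside, with a warning", {
  f <- distance_field(plaque_field_from_mask(matrix(0, 50, 50), pixel_scale(1)))
  expect_warning(
    z <- assign_zones(f, tibble::tibble(x = c(5, 20), y = c(5, 20), gene = "g")),
    "no plaques")
  expect_true(all(z$zone == "outside"))
})

test_that("zone areas partition the window exactly", {
  img <- make_plaque_image(n_plaques = 5, image_size = c(250, 250), seed = 3)
  f <- distance_field(plaque_field_from_mask(img$mask, pixel_scale(1)))
  ar <- zone_areas(f, zone_radius = 69)
  expect_equal(sum(ar$area_um2), 250 * 250)
  expect_equal(ar$area_um2[ar$zone == "inside"], sum(img$mask > 0))
  # per-plaque areas partition the window too
  app <- zone_areas(f, zone_radius = 69, per_plaque = TRUE)
  expect_equal(sum(app$area_um2), 250 * 250)
  # no plaques: everything outside
  f0 <- distance_field(plaque_field_from_mask(matrix(0, 30, 30), pixel_scale(1)))
  a0 <- zone_areas(f0)
  expect_equal(a0$area_um2, c(0, 0, 900))
})

test_that("adjacent area of a single plaque pixel matches brute force", {
  m <- matrix(0, 200, 200)
  m[100, 100] <- 1
  f <- distance_field(plaque_field_from_mask(m, pixel_scale(1)))
  ar <- zone_areas(f, zone_radius = 69)
  bf <- brute_force_distance(m)
  expect_equal(ar$area_um2[ar$zone == "adjacent"], sum(bf > 0 & bf <= 69))
})

test_that("densities are count/area and counts are conserved", {
  f <- make_line_field()
  set.seed(4)
  pts <- tibble::tibble(x = runif(400, 0, 699), y = runif(400, 0, 119),
                        gene = sample(c("A", "B"), 400, replace = TRUE))
  z <- assign_zones(f, pts)
  ar <- zone_areas(f)
  zd <- zone_density(z, ar)
  # partition: per-gene counts sum to in-window totals (exact integers)
  tot <- dplyr::count(z[z$in_bounds, ], gene)
  agg <- dplyr::summarise(dplyr::group_by(zd, gene),
                          n = sum(transcript_count))
  expect_identical(sort(agg$n), sort(as.integer(tot$n)))
  expect_equal(zd$density, zd$transcript_count / zd$zone_area_um2)
  # union-density identity: weighted average equals total/window
  for (g in c("A", "B")) {
    sub <- zd[zd$gene == g, ]
    expect_equal(sum(sub$density * sub$zone_area_um2) / sum(sub$zone_area_um2),
                 sum(sub$transcript_count) / sum(sub$zone_area_um2),
                 tolerance = 1e-12)
  }
})

test_that("simple density arithmetic: 10 transcripts in 50 um^2 is 0.2", {
  ar <- tibble::tibble(zone = factor(c("inside", "adjacent", "outside"),
                                     levels = c("inside", "adjacent", "outside")),
                       area_um2 = c(10, 50, 100))
  z <- tibble::tibble(gene = "g", zone = factor(rep("adjacent", 10),
                                                levels = levels(ar$zone)),
                      in_bounds = TRUE, nearest_plaque_id = 1L)
  zd <- zone_density(z, ar)
  expect_equal(zd$density[zd$zone == "adjacent"], 0.2)
  expect_equal(zd$transcript_count[zd$zone == "inside"], 0)
})

test_that("requesting an absent gene yields zero rows plus a warning", {
  f <- make_line_field()
  pts <- tibble::tibble(x = c(10, 20), y = c(10, 20), gene = "A")
  z <- assign_zones(f, pts)
  ar <- zone_areas(f)
  expect_warning(zd <- zone_density(z, ar, genes = c("A", "Zzz")), "Zzz")
  expect_equal(sum(zd$transcript_count[zd$gene == "Zzz"]), 0)
})

test_that("zone assignment matches brute-force classification on random masks", {
  set.seed(12)
  for (i in 1:5) {
    mk <- matrix(rbinom(32 * 32, 1, 0.05), 32, 32)
    if (sum(mk) == 0) next
    f <- distance_field(plaque_field_from_mask(mk, pixel_scale(1)))
    pts <- tibble::tibble(x = round(runif(200, 0, 31)), y = round(runif(200, 0, 31)),
                          gene = "g")
    z <- assign_zones(f, pts, zone_radius = 8)
    bf <- brute_force_distance(mk)
    d_oracle <- bf[cbind(pts$y + 1, pts$x + 1)]
    zone_oracle <- ifelse(d_oracle == 0, "inside",
                          ifelse(d_oracle <= 8, "adjacent", "outside"))
    expect_equal(as.character(z$zone), zone_oracle)
  }
})

test_that("planted adjacent enrichment is recovered as a density ratio", {
  img <- make_plaque_image(n_plaques = 8, image_size = c(500, 500), seed = 21)
  f <- distance_field(plaque_field_from_mask(img$mask, pixel_scale(1)))
  ar <- zone_areas(f)
  ratios <- vapply(1:5, function(s) {
    tr <- make_transcripts(img$mask,
                           enrichment_spec("g", 0.002, fold_adjacent = 5),
                           seed = s)
    zd <- zone_density(assign_zones(f, tr$transcripts), ar)
    zd$density[zd$zone == "adjacent"] / zd$density[zd$zone == "outside"]
  }, numeric(1))
  expect_true(all(ratios >= 3.5 & ratios <= 6.5))
})

test_that("uniform null gene has near-equal densities across zones", {
  img <- make_plaque_image(n_plaques = 8, image_size = c(500, 500), seed = 22)
  f <- distance_field(plaque_field_from_mask(img$mask, pixel_scale(1)))
  ar <- zone_areas(f)
  # baseline high enough for >= 300 expected points in the smallest zone
  lam <- 320 / min(ar$area_um2)
  for (s in 1:5) {
    tr <- make_transcripts(img$mask, enrichment_spec("g", lam), seed = 100 + s)
    zd <- zone_density(assign_zones(f, tr$transcripts), ar)
    expect_lt(max(zd$density) / min(zd$density), 1.3)
  }
})

test_that("Kruskal-Wallis/Dunn reproduces hand-computed examples", {
  # no ties, three separated groups: H = 7.2 by the rank formula
  d <- tibble::tibble(v = as.numeric(1:9), g = rep(c("a", "b", "c"), each = 3))
  kd <- kruskal_dunn(d, v, g)
  expect_equal(kd$H, 7.2)
  expect_equal(nrow(kd$pairwise), 3)
  # identical groups: H = 0, p = 1
  d2 <- tibble::tibble(v = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  kd2 <- kruskal_dunn(d2, v, g)
  expect_equal(kd2$H, 0)
  expect_equal(kd2$p_value, 1)
  expect_true(all(abs(kd2$pairwise$z) < 1e-12))
  # Dunn z oracle for the 1..9 case: mean ranks 2, 5, 8; se = sqrt(7.5 * 2/3)
  se <- sqrt((9 * 10 / 12) * (2 / 3))
  expect_equal(sort(abs(kd$pairwise$z)),
               sort(abs(c(-3, -6, -3) / se)), tolerance = 1e-12)
  # a group with no observations is an error naming the group
  d3 <- tibble::tibble(v = c(1, 2, NA), g = factor(c("a", "a", "b")))
  expect_error(kruskal_dunn(d3, v, g), "at least 2 groups|no observations")
  expect_error(kruskal_dunn(tibble::tibble(v = 1:3, g = "a"), v, g), "2 groups")
})

test_that("tidy and glance expose the Kruskal-Dunn results", {
  d <- tibble::tibble(v = as.numeric(1:9), g = rep(c("a", "b", "c"), each = 3))
  kd <- kruskal_dunn(d, v, g)
  td <- tidy(kd)
  expect_true(all(c("comparison", "z", "p_raw", "p_adj") %in% names(td)))
  gl <- glance(kd)
  expect_equal(gl$statistic, 7.2)
  expect_equal(gl$df, 2)
})
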