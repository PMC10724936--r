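test_that("toy profile reproduces the hand-computed feature values", {
  p <- radii_profile(c(1, 1, 0.5, 1, 1), lesion_start = 1, lesion_end = 3,
                     frame_spacing = 0.2)
  f <- compute_geometric_features(p)
  expect_equal(f$mean_lumen_radius, 0.9)
  expect_equal(f$minimum_lumen_radius, 0.5)
  expect_equal(f$maximum_lumen_radius, 1.0)
  expect_equal(f$mean_lumen_radius_stenosis, 0.8333333, tolerance = 1e-6)
  expect_equal(f$mean_radius_per_length, 1.125)
  expect_equal(f$maximum_radius_rapport, 0.5)
  expect_equal(f$stenosis_lesion_length, 0.4)
  expect_equal(f$percentage_diameter_reduction, 10)
  expect_equal(f$proximal_radius_rapport, 0)
  expect_equal(f$radius_rapport, 0.5)
  expect_equal(f$proximal_area, pi)
  expect_equal(f$distal_area, pi)
})

test_that("constant profiles zero out the shape features", {
  p <- radii_profile(rep(1.3, 9), lesion_start = 2, lesion_end = 6)
  f <- compute_geometric_features(p)
  expect_equal(f$percentage_diameter_reduction, 0)
  expect_equal(f$radius_rapport, 0)
  expect_equal(f$maximum_radius_rapport, 0)
  expect_equal(f$proximal_radius_rapport, 0)
})

test_that("rapport features are scale-invariant, areas scale quadratically", {
  set.seed(4)
  p1 <- random_profile()
  p2 <- p1
  p2$radii <- 2 * p1$radii
  f1 <- compute_geometric_features(p1)
  f2 <- compute_geometric_features(p2)
  for (f in c("maximum_radius_rapport", "percentage_diameter_reduction",
              "proximal_radius_rapport", "radius_rapport")) {
    expect_equal(f2[[f]], f1[[f]], tolerance = 1e-12)
  }
  expect_equal(f2$proximal_area, 4 * f1$proximal_area)
  expect_equal(f2$distal_area, 4 * f1$distal_area)
})

test_that("features agree with a literal per-frame oracle on random profiles", {
  set.seed(1234)
  for (i in 1:250) {
    p <- random_profile()
    expect_equal(compute_geometric_features(p), oracle_geometric_features(p),
                 tolerance = 1e-12)
  }
})

test_that("profile reversal swaps proximal and distal quantities", {
  set.seed(99)
  for (i in 1:25) {
    p <- random_profile()
    n <- length(p$radii)
    q <- radii_profile(rev(p$radii),
                       segment_start = n - 1 - p$segment_end,
                       lesion_start = n - 1 - p$lesion_end,
                       lesion_end = n - 1 - p$lesion_start,
                       segment_end = n - 1 - p$segment_start,
                       frame_spacing = p$frame_spacing)
    f <- compute_geometric_features(p)
    g <- compute_geometric_features(q)
    expect_equal(g$proximal_area, f$distal_area)
    expect_equal(g$distal_area, f$proximal_area)
    expect_equal(g$mean_lumen_radius, f$mean_lumen_radius)
    expect_equal(g$minimum_lumen_radius, f$minimum_lumen_radius)
    expect_equal(g$maximum_lumen_radius, f$maximum_lumen_radius)
    expect_equal(g$stenosis_lesion_length, f$stenosis_lesion_length)
    # the rapport numerator changes sign up to the denominator swap
    expect_equal(sign(g$proximal_radius_rapport),
                 -sign(f$proximal_radius_rapport))
  }
})

test_that("diameter reduction and radius rapport coincide only when r_mean = r_min", {
  # lesion floor profile: mean over segment equals min
  p <- radii_profile(c(1, 0.6, 0.6, 0.6, 1), lesion_start = 0, lesion_end = 4)
  f <- compute_geometric_features(p)
  # r_mean != r_min here, so the two formulas differ
  expect_false(isTRUE(all.equal(f$percentage_diameter_reduction / 100,
                                f$radius_rapport)))
  # force r_mean == r_min: constant segment inside the lesion markers
  q <- radii_profile(rep(0.8, 6), lesion_start = 0, lesion_end = 5)
  g <- compute_geometric_features(q)
  expect_equal(g$percentage_diameter_reduction / 100, g$radius_rapport)
})

test_that("feature matrix assembly enforces the 26-column schema", {
  co <- small_cohort()
  fm <- assemble_feature_matrix(co)
  expect_equal(dim(fm), c(26L, 26L))
  expect_identical(colnames(fm), feature_names())
  expect_identical(rownames(fm), co$lesions$lesion_id)
  expect_false(anyNA(fm))
  # MLD is the physician annotation, not the computed minimum radius
  expect_false(isTRUE(all.equal(fm[, "minimal_lumen_diameter"],
                                2 * fm[, "minimum_lumen_radius"])))

  broken <- co
  broken$patients$hb[3] <- NA
  expect_error(assemble_feature_matrix(broken), "hb")
})

test_that("L1 normalization behaves like a per-column Manhattan rescale", {
  m <- structure(cbind(a = c(1, 1, 2), b = c(-1, 2, 1)),
                 normalized = FALSE,
                 class = c("feature_matrix", "matrix", "array"))
  nm <- l1_normalize(m)
  expect_equal(unname(nm[, "a"]), c(0.25, 0.25, 0.5))
  expect_equal(colSums(abs(nm)), c(a = 1, b = 1), tolerance = 1e-12)
  expect_error(l1_normalize(nm), "already normalized")

  z <- structure(cbind(a = c(1, 2), b = c(0, 0)), normalized = FALSE,
                 class = c("feature_matrix", "matrix", "array"))
  expect_error(l1_normalize(z), "all-zero")

  # normalization preserves Pearson correlation
  set.seed(8)
  r <- structure(matrix(rnorm(60) + 3, ncol = 3,
                        dimnames = list(NULL, c("x", "y", "z"))),
                 normalized = FALSE,
                 class = c("feature_matrix", "matrix", "array"))
  expect_equal(pearson_correlation_matrix(l1_normalize(r)),
               pearson_correlation_matrix(r), tolerance = 1e-12)
})

test_that("pearson correlation handles exact and degenerate structure", {
  set.seed(21)
  x <- rnorm(50)
  m <- cbind(x = x, y = -2 * x + 5, z = rnorm(50), c = rep(1, 50))
  expect_warning(cc <- pearson_correlation_matrix(m), "constant")
  expect_equal(cc["x", "x"], 1)
  expect_equal(cc["x", "y"], -1)
  expect_equal(cc["c", "z"], 0)
  expect_lt(max(abs(cc - t(cc))), 1e-12)
  expect_error(pearson_correlation_matrix(m[1:2, ]), "3 rows")

  # independent columns at large n have near-zero correlation
  set.seed(22)
  big <- cbind(a = rnorm(10000), b = rnorm(10000))
  expect_lt(abs(pearson_correlation_matrix(big)["a", "b"]), 0.05)
})

test_that("collinearity pruning keeps the earlier-ranked feature", {
  set.seed(31)
  x <- rnorm(40)
  m <- cbind(a = x, b = rnorm(40), c = 3 * x + 1)
  pr <- prune_perfectly_correlated(m)
  expect_equal(pr$removed, "c")
  expect_identical(colnames(pr$matrix), c("a", "b"))

  # nothing above threshold: unchanged
  m2 <- cbind(a = rnorm(40), b = rnorm(40))
  pr2 <- prune_perfectly_correlated(m2)
  expect_length(pr2$removed, 0)
  expect_equal(dim(pr2$matrix), dim(m2))

  # three mutual duplicates: first-ranked kept, two removed
  m3 <- cbind(a = x, b = 2 * x, c = -x, d = rnorm(40))
  pr3 <- prune_perfectly_correlated(m3)
  expect_equal(sort(pr3$removed), c("b", "c"))

  # rank order decides the survivor
  pr3b <- prune_perfectly_correlated(m3, rank_order = c("b", "a", "c", "d"))
  expect_equal(sort(pr3b$removed), c("a", "c"))

  # idempotence
  pr4 <- prune_perfectly_correlated(pr3$matrix)
  expect_length(pr4$removed, 0)
})
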