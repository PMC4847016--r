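test_that("patch delineation matches a flood-fill oracle", {
  g <- land_grid(matrix(1, 5, 5))
  expect_equal(nrow(delineate_patches(g)$patches), 1)

  cb <- land_grid(outer(1:6, 1:6, function(r, c) (r + c) %% 2 + 1))
  p4 <- delineate_patches(cb, connectivity = 4)
  expect_equal(nrow(p4$patches), 36) # every cell its own patch
  p8 <- delineate_patches(cb, connectivity = 8)
  expect_equal(nrow(p8$patches), 2)

  set.seed(20)
  for (rep in 1:5) {
    for (conn in c(4, 8)) {
      g <- random_grid(20, 20, 3)
      got <- delineate_patches(g, conn)
      want <- oracle_components(g$values, conn)
      expect_equal(nrow(got$patches), max(want, na.rm = TRUE))
      # identical partition up to relabeling
      expect_equal(length(unique(paste(got$labels, want))),
                   nrow(got$patches))
    }
  }
  expect_error(delineate_patches(land_grid(matrix(NA_real_, 2, 2))),
               "empty")
})

test_that("mean patch size and CV follow their closed forms", {
  g <- land_grid(rbind(c(1, 1, 2), c(3, 3, 2)))
  p <- delineate_patches(g)
  expect_equal(mean_patch_size(p), 2)
  expect_equal(patch_size_cv(p), 0)
  g2 <- land_grid(rbind(c(1, 2, 2), c(2, 2, 2))) # patch areas (1, 5)
  p2 <- delineate_patches(g2)
  expect_equal(mean_patch_size(p2), 3)
  expect_equal(patch_size_cv(p2), 100 * 2 / 3)
  single <- delineate_patches(land_grid(matrix(1, 2, 2)))
  expect_equal(mean_patch_size(single), 4)
  expect_error(patch_size_cv(single), "at least 2")
})

test_that("landscape shape index is 1 for a solid square and grows with edge", {
  expect_equal(landscape_shape_index(
    delineate_patches(land_grid(matrix(1, 8, 8)))), 1)
  m <- matrix(1, 8, 8)
  m[3, 4] <- 2 # one internal boundary
  lsi2 <- landscape_shape_index(delineate_patches(land_grid(m)))
  expect_gt(lsi2, 1)
  m[5, 6] <- 2
  expect_gt(landscape_shape_index(delineate_patches(land_grid(m))), lsi2)
  # 2x2 landscape split into two 1x2 patches: E* = 8 + 2 sides by hand
  half <- land_grid(rbind(c(1, 2), c(1, 2)))
  expect_equal(landscape_shape_index(delineate_patches(half)),
               0.25 * 10 * 100 / sqrt(4e4))
})

test_that("contiguity honours its closed-form anchors", {
  one <- matrix(2, 3, 3); one[2, 2] <- 1
  p <- delineate_patches(land_grid(one))
  i <- p$patches$patch_id[p$patches$class == 1]
  # area-weighted landscape value mixes both patches; isolate the pixel
  contig_px <- (1 - 1) / 12
  expect_equal(contig_px, 0)
  # direct template arithmetic for a 1x3 patch: scores 3, 5, 3
  row3 <- land_grid(matrix(c(1, 1, 1), 1, 3))
  expect_equal(contiguity_am(delineate_patches(row3)),
               (11 / 3 - 1) / 12)
  # large solid squares approach the limit 1 from below
  c20 <- contiguity_am(delineate_patches(land_grid(matrix(1, 20, 20))))
  c60 <- contiguity_am(delineate_patches(land_grid(matrix(1, 60, 60))))
  expect_gt(c60, c20)
  expect_gt(c60, 0.95)
  expect_lt(c60, 1)
})

test_that("contagion orders disaggregation below aggregation", {
  # random salt-and-pepper mixing (many small dispersed patches) scores
  # below two solid halves of the same proportions
  set.seed(3)
  mixed <- land_grid(matrix(sample(rep(1:2, 32)), 8, 8))
  halves <- land_grid(cbind(matrix(1, 8, 4), matrix(2, 8, 4)))
  expect_lt(contagion(mixed), contagion(halves))
  # a 2-class checkerboard concentrates all adjacency in the two
  # off-diagonal cells: closed form (1 - ln 2 / (2 ln 2)) * 100 = 50
  cb <- land_grid(outer(1:8, 1:8, function(r, c) (r + c) %% 2 + 1))
  expect_equal(contagion(cb), 50)
  expect_equal(contagion(land_grid(matrix(3, 5, 5))), 100)
  # 4x4 two-class fixture against hand adjacency tabulation
  fix <- land_grid(rbind(c(1, 1, 2, 2), c(1, 2, 2, 2),
                         c(1, 1, 1, 2), c(2, 2, 1, 1)))
  expect_equal(contagion(fix), oracle_contagion(fix$values))
})

test_that("nearest-neighbor distances come from closest cell pairs", {
  m <- matrix(2, 3, 5)
  m[2, 1] <- 1; m[2, 5] <- 1 # two single-cell patches 4 columns apart
  g <- land_grid(m)
  p <- delineate_patches(g)
  # class-2 background is one patch; only class 1 has neighbors
  expect_equal(enn_mn(p), 400)
  m2 <- matrix(1, 2, 2)
  expect_error(enn_mn(delineate_patches(land_grid(m2))), "undefined")
  # joining the two nearest patches cannot decrease the remaining mean
  a <- matrix(9, 5, 9)
  a[3, 1] <- 1; a[3, 3] <- 1; a[3, 8] <- 1
  sep <- enn_mn(delineate_patches(land_grid(a)))
  a2 <- a; a2[3, 2] <- 1 # bridge the closest pair
  expect_gte(enn_mn(delineate_patches(land_grid(a2))), sep)
})

test_that("connectance counts joined pairs against all same-class pairs", {
  m <- matrix(9, 4, 9)
  m[2, 1] <- 1; m[2, 4] <- 1; m[2, 9] <- 1
  p <- delineate_patches(land_grid(m))
  # pair distances by hand: 300, 500, 800 m
  expect_equal(connectance(p, 100), 0)
  expect_equal(connectance(p, 1000), 100)
  expect_equal(connectance(p, 400), 100 * 1 / 3)
  expect_equal(connectance(p, 500), 100 * 2 / 3)
})

test_that("Shannon indices follow their closed forms", {
  expect_equal(shdi(land_grid(matrix(1, 4, 4))), 0)
  expect_equal(shei(land_grid(matrix(1, 4, 4))), 0)
  half <- land_grid(cbind(matrix(1, 4, 2), matrix(2, 4, 2)))
  expect_equal(shdi(half), log(2))
  expect_equal(shei(half), 1)
  mix <- land_grid(matrix(c(rep(1, 8), rep(2, 4), rep(3, 4)), 4, 4))
  expect_equal(shdi(mix), 1.5 * log(2))
})

test_that("all nine metrics match the brute-force oracle on small rasters", {
  set.seed(77)
  for (rep in 1:6) {
    g <- random_grid(sample(6:10, 1), sample(6:10, 1), sample(2:4, 1))
    want <- oracle_metrics(g, threshold = 450)
    got <- landscape_metrics(g, connect_threshold = 450)
    expect_equal(got$mean_patch_size, want$mean_patch_size)
    expect_equal(got$patch_size_cv, want$patch_size_cv)
    expect_equal(got$landscape_shape_index, want$lsi)
    expect_equal(got$contiguity_am, want$contiguity_am)
    expect_equal(got$contagion, want$contagion)
    expect_equal(got$enn_mn, want$enn_mn)
    expect_equal(got$connectance, want$connectance)
    expect_equal(got$shdi, want$shdi)
    expect_equal(got$shei, want$shei)
  }
})

test_that("metrics are invariant to class relabeling", {
  set.seed(99)
  g <- random_grid(12, 12, 4)
  perm <- sample(4)
  g2 <- land_grid(matrix(perm[g$values], 12, 12))
  m1 <- landscape_metrics(g, connect_threshold = 300)
  m2 <- landscape_metrics(g2, connect_threshold = 300)
  expect_equal(m1[, -1], m2[, -1])
})

test_that("index bounds hold on random rasters", {
  set.seed(123)
  for (rep in 1:100) {
    g <- random_grid(7, 7, sample(2:5, 1))
    expect_gte(shei(g), 0); expect_lte(shei(g), 1)
    expect_gte(shdi(g), 0)
    ct <- contagion(g)
    expect_gte(ct, 0); expect_lte(ct, 100)
    cg <- contiguity_am(delineate_patches(g))
    expect_gte(cg, 0); expect_lte(cg, 1)
  }
})
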