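# Synthetic parcellation and cohort generator.

test_that("parcellation tiles the interior with contiguous labelled blocks", {
  parc <- make_parcellation(c(8, 8, 8), 8, seed = 1)
  lab <- parc$labels
  # one-voxel background shell
  expect_true(all(lab[1, , ] == 0) && all(lab[8, , ] == 0))
  expect_true(all(lab[, 1, ] == 0) && all(lab[, , 8] == 0))
  interior <- lab[2:7, 2:7, 2:7]
  expect_true(all(interior %in% 1:8))
  expect_true(all(1:8 %in% interior))        # every region non-empty
  # blocks are axis-aligned cuboids: each region's bounding box is full
  for (r in 1:8) {
    w <- which(lab == r, arr.ind = TRUE)
    expect_equal(nrow(w), prod(apply(w, 2, function(v) diff(range(v)) + 1)))
  }
})

test_that("parcellation is deterministic and errors on impossible sizes", {
  a <- make_parcellation(c(9, 8, 10), 6, seed = 5)
  b <- make_parcellation(c(9, 8, 10), 6, seed = 5)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, make_parcellation(c(9, 8, 10), 6, seed = 6)$labels))
  expect_error(make_parcellation(c(2, 2, 2), 64), "too small")
  expect_error(make_parcellation(c(8, 8, 8), 1), "n_regions")
})

test_that("cohort spec validates inputs", {
  expect_error(cohort_spec(c(5, 5, 5), c(8, 8, 8), 4, integer(0)), "non-empty")
  expect_error(cohort_spec(c(5, 5, 5), c(8, 8, 8), 4, 9), "subset")
  expect_error(cohort_spec(c(5, 5, 5), c(8, 8, 8), 4, 1, effect_size = -1),
               "non-negative")
  bad <- rbind(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0), c(0.5, 0.4, 0, 0))
  expect_error(cohort_spec(c(5, 5, 5), c(8, 8, 8), 4, 1,
                           grade_distributions = bad), "row-stochastic")
})

test_that("cohorts are byte-identical under a fixed seed", {
  a <- tiny_cohort(seed = 42)
  b <- tiny_cohort(seed = 42)
  expect_identical(a$samples, b$samples)
  expect_identical(a$grade_records, b$grade_records)
  expect_false(identical(a$samples[[1]]$volume, tiny_cohort(seed = 43)$samples[[1]]$volume))
})

test_that("noise-free disease-region means are ordered NC > MCI > AD and match the generative formula", {
  coh <- tiny_cohort(n_per_class = c(40, 40, 40), effect_size = 0.1, noise_sd = 0)
  dis <- coh$effect_map
  labels <- cohort_labels(coh)
  base_mean <- mean(coh$base_volume[dis])
  cls_mean <- vapply(0:2, function(cl) {
    mean(vapply(coh$samples[labels == cl], function(s) mean(s$volume[dis]),
                numeric(1)))
  }, numeric(1))
  expect_true(cls_mean[1] > cls_mean[2] && cls_mean[2] > cls_mean[3])
  # oracle: mean intensity = base mean - effect_size * voxel-weighted mean grade
  parc <- coh$parcellation
  vox <- vapply(coh$spec$disease_regions, function(r) sum(parc$labels == r), numeric(1))
  oracle <- vapply(0:2, function(cl) {
    g <- vapply(coh$samples[labels == cl],
                function(s) sum(s$grades * vox) / sum(vox), numeric(1))
    base_mean - coh$spec$effect_size * mean(g)
  }, numeric(1))
  expect_equal(cls_mean, oracle, tolerance = 1e-12)
})

test_that("effect_size = 0 removes the class signal", {
  coh <- tiny_cohort(n_per_class = c(10, 10, 10), effect_size = 0, noise_sd = 0)
  vols <- lapply(coh$samples, function(s) s$volume)
  for (v in vols) expect_identical(v, vols[[1]])
})

test_that("realized attenuation equals effect_size * grade when noise-free", {
  coh <- tiny_cohort(n_per_class = c(3, 3, 3), effect_size = 0.1, noise_sd = 0)
  for (s in coh$samples) {
    tab <- grade_signal_consistency(s, coh$parcellation, coh$base_volume)
    expect_equal(tab$attenuation, 0.1 * tab$grade, tolerance = 1e-12)
    # voxel-loop oracle on one region
    r <- tab$region_id[1]
    vox <- which(coh$parcellation$labels == r)
    expect_equal(mean(coh$base_volume[vox] - s$volume[vox]),
                 tab$attenuation[1], tolerance = 1e-12)
  }
})

test_that("grades and realized signal are perfectly rank-correlated when noise-free", {
  coh <- tiny_cohort(n_per_class = c(6, 6, 6), effect_size = 0.1, noise_sd = 0)
  g <- unlist(lapply(coh$samples, function(s) s$grades))
  att <- unlist(lapply(coh$samples, function(s)
    grade_signal_consistency(s, coh$parcellation, coh$base_volume)$attenuation))
  expect_equal(cor(rank(g), rank(att)), 1, tolerance = 1e-12)
})

test_that("NC-AD separation is non-decreasing in effect_size", {
  gap <- vapply(c(0, 0.05, 0.1, 0.2), function(es) {
    coh <- tiny_cohort(n_per_class = c(30, 0, 30), effect_size = es,
                       noise_sd = 0.01, seed = 9)
    labels <- cohort_labels(coh)
    dis <- coh$effect_map
    m <- function(cl) mean(vapply(coh$samples[labels == cl],
                                  function(s) mean(s$volume[dis]), numeric(1)))
    m(0) - m(2)
  }, numeric(1))
  expect_true(all(diff(gap) >= -1e-6))
})

test_that("stain grades stay within the ordinal scale and track latent severity", {
  coh <- tiny_cohort(n_per_class = c(10, 10, 10))
  gr <- coh$grade_records
  expect_true(all(gr$grade %in% 0:3))
  expect_setequal(unique(gr$stain), c("amyloid_beta", "NFT", "NP"))
  latent <- unlist(lapply(coh$samples, function(s) s$grades))
  for (st in unique(gr$stain)) {
    sub <- gr[gr$stain == st, ]
    sub <- sub[order(sub$subject_id, sub$region_id), ]
    expect_gt(cor(sub$grade, latent), 0.7)
  }
})
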