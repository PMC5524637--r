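# Boundary tracing, dyad distances, skeleton orientation, clusters.

test_that("boundary tracing matches hand-enumerated shapes", {
  m <- matrix(0, 9, 9); m[3:7, 3:7] <- 1
  b <- trace_boundaries(m)
  expect_length(b, 1)
  expect_equal(nrow(unique(b[[1]])), 16)   # perimeter of a 5x5 square

  s <- matrix(0, 5, 5); s[3, 3] <- 1
  bs <- trace_boundaries(s)
  expect_equal(unique(bs[[1]]), matrix(c(3L, 3L), 1, 2,
                                       dimnames = list(NULL, c("row", "col"))))

  two <- matrix(0, 12, 12); two[2:4, 2:4] <- 1; two[8:10, 8:10] <- 1
  expect_length(trace_boundaries(two), 2)

  expect_error(trace_boundaries(matrix(0, 4, 4)), "empty")
})

test_that("dyad distances reproduce simple geometries", {
  par <- generate(generator_spec("dyad_masks", seed = 1,
                                 geometry = "parallel", gap_px = 15,
                                 pixel_size_nm = 1))
  r <- dyad_distances(par$data)
  expect_equal(r$mean_nm, 15)
  expect_equal(r$min_nm, 15)

  # pixel size scales distances
  par2 <- new_mask_pair(par$data$jsr_mask, par$data$tt_mask, 2.5)
  expect_equal(dyad_distances(par2)$mean_nm, 37.5)

  con <- generate(generator_spec("dyad_masks", seed = 2,
                                 geometry = "concentric", r_out = 25,
                                 r_in = 15, size = 64))
  rc <- dyad_distances(con$data)
  expect_equal(rc$mean_nm, 10, tolerance = 1 / 10)
  expect_true(rc$min_nm <= rc$mean_nm)
})

brute_force_nn <- function(a, b) {
  # independent O(N*M) double loop over boundary point sets
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

test_that("dyad distances agree exactly with the brute-force oracle", {
  for (rep in 1:20) {
    g <- generate(generator_spec("dyad_masks", seed = 10, replicate = rep,
                                 geometry = "random", size = 32))
    r <- dyad_distances(g$data)
    bt <- unique(do.call(rbind, trace_boundaries(g$data$tt_mask)))
    bj <- unique(do.call(rbind, trace_boundaries(g$data$jsr_mask)))
    expect_identical(sort(r$distances_nm),
                     sort(brute_force_nn(bt, bj) * g$data$pixel_size_nm))
  }
})

test_that("distance report is invariant under axis swap and rotation", {
  g <- generate(generator_spec("dyad_masks", seed = 11, geometry = "random",
                               size = 32))
  r0 <- dyad_distances(g$data)
  sw <- new_mask_pair(t(g$data$jsr_mask), t(g$data$tt_mask), 1)
  expect_equal(sort(dyad_distances(sw)$distances_nm),
               sort(r0$distances_nm))
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  rt <- new_mask_pair(rot90(g$data$jsr_mask), rot90(g$data$tt_mask), 1)
  expect_equal(sort(dyad_distances(rt)$distances_nm),
               sort(r0$distances_nm))
})

hist_mass_near <- function(h, angle, tol = 6) {
  mids <- (h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2
  # fold distance on the 180-degree circle
  d <- abs((mids - angle + 90) %% 180 - 90)
  sum(h$weights[d <= tol])
}

test_that("skeleton orientation finds the dominant angle and is equivariant", {
  g0 <- generate(generator_spec("tt_network", seed = 21, angles_deg = 0,
                                n_lines_per_angle = 8))
  h0 <- skeleton_orientation(g0$data)
  expect_gt(hist_mass_near(h0, 0), 0.9)

  g90 <- generate(generator_spec("tt_network", seed = 21, angles_deg = 90,
                                 n_lines_per_angle = 8))
  h90 <- skeleton_orientation(g90$data)
  expect_gt(hist_mass_near(h90, 90), 0.9)

  # rotating the reference long axis shifts the histogram accordingly
  h45 <- skeleton_orientation(g0$data, long_axis_deg = 45)
  expect_gt(hist_mass_near(h45, -45), 0.9)

  g30 <- generate(generator_spec("tt_network", seed = 22, angles_deg = 30,
                                 n_lines_per_angle = 8))
  h30 <- skeleton_orientation(g30$data)
  expect_gt(hist_mass_near(h30, 30), 0.85)

  expect_error(skeleton_orientation(matrix(0, 10, 10)), "empty")
})

test_that("a 50/50 two-angle mixture yields two equal modes", {
  g <- generate(generator_spec("tt_network", seed = 23,
                               angles_deg = c(0, 45),
                               n_lines_per_angle = 8))
  h <- skeleton_orientation(g$data)
  m0 <- hist_mass_near(h, 0, tol = 10)
  m45 <- hist_mass_near(h, 45, tol = 10)
  expect_gt(m0 + m45, 0.75)
  expect_equal(m0 / (m0 + m45), 0.5, tolerance = 0.05 / 0.5)
})

test_that("cluster detection honours threshold and minimum area", {
  g <- generate(generator_spec("cluster_pair", seed = 31, n_a = 2, n_b = 2,
                               overlap_frac = 0))
  cs <- detect_clusters(g$data$channel_a, threshold = 0.3, smooth_sigma = 0)
  expect_equal(nrow(cs$clusters), 2)
  got <- cs$clusters[order(cs$clusters$centroid_row),
                     c("centroid_row", "centroid_col")]
  want <- g$truth$centres_a[order(g$truth$centres_a[, 1]), , drop = FALSE]
  expect_true(all(abs(as.matrix(got) - want) <= 1))

  flat <- matrix(0.1, 32, 32)
  expect_equal(nrow(detect_clusters(flat, threshold = 0.5)$clusters), 0)

  tiny <- matrix(0, 16, 16); tiny[5, 5:6] <- 1
  expect_equal(nrow(detect_clusters(tiny, threshold = 0.5, smooth_sigma = 0,
                                    min_area = 4)$clusters), 0)
  expect_equal(nrow(detect_clusters(tiny, threshold = 0.5, smooth_sigma = 0,
                                    min_area = 2)$clusters), 1)
})

test_that("overlap areas match hand-counted intersections and are symmetric", {
  a <- matrix(0, 30, 30); a[6:15, 6:15] <- 1
  b <- matrix(0, 30, 30); b[11:20, 6:15] <- 1    # offset by 5 rows
  ca <- detect_clusters(a, threshold = 0.5, smooth_sigma = 0)
  cb <- detect_clusters(b, threshold = 0.5, smooth_sigma = 0)
  ov <- overlap_area(ca, cb)
  expect_equal(ov$pairs$overlap_px, 50)

  self <- overlap_area(ca, ca)
  expect_equal(self$pairs$overlap_px, ca$clusters$area_px)

  d <- matrix(0, 30, 30); d[25:28, 25:28] <- 1
  cd <- detect_clusters(d, threshold = 0.5, smooth_sigma = 0)
  expect_equal(nrow(overlap_area(ca, cd)$pairs), 0)

  # total overlap is symmetric
  ba <- overlap_area(cb, ca)
  expect_equal(sum(ov$pairs$overlap_px), sum(ba$pairs$overlap_px))

  cbad <- detect_clusters(matrix(0.9, 10, 10), threshold = 0.5,
                          smooth_sigma = 0)
  expect_error(overlap_area(ca, cbad), "grid")
})
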