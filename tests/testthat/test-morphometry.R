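test_that("image frames normalise colour and scale to 8-bit", {
  gray01 <- matrix(stats::runif(100), 10, 10)
  fr <- image_frame(gray01, 2)
  expect_true(max(fr$pixels) <= 255 && max(fr$pixels) > 1)
  rgb <- array(stats::runif(300), dim = c(10, 10, 3))
  fr2 <- image_frame(rgb, 2)
  expect_true(is.matrix(fr2$pixels))
  expect_error(image_frame(gray01, -1))
})

test_that("vessel segmentation removes particles and fills holes", {
  # uniform background: empty mask
  bg <- image_frame(matrix(20, 50, 50), 2)
  expect_false(any(binarize_vessels(bg, intensity_threshold = 20.5,
                                    min_particle_area = 0)))
  # a bright speck below the particle threshold disappears
  sp <- matrix(20, 50, 50); sp[25:26, 25:26] <- 200   # 4 px = 16 um^2
  m <- binarize_vessels(image_frame(sp, 2), 100, min_particle_area = 100)
  expect_false(any(m))
  # a dark speck inside a tube is filled
  tube <- matrix(20, 50, 80); tube[20:30, 10:70] <- 200
  tube[24:25, 40:41] <- 20                            # 4 px hole = 16 um^2
  m2 <- binarize_vessels(image_frame(tube, 2), 100, max_hole_area = 100)
  expect_true(all(m2[20:30, 10:70]))
  # threshold outside the dynamic range errors
  expect_error(binarize_vessels(bg, 300), "dynamic range")
  expect_error(binarize_vessels(bg, -4), "dynamic range")
})

test_that("skeleton topology of simple shapes is exact", {
  tube <- matrix(FALSE, 60, 120); tube[28:33, 10:110] <- TRUE
  vm <- vessel_metrics(tube, 2)
  expect_equal(vm$n_junctions, 0L)
  expect_equal(vm$n_endpoints, 2L)
  expect_equal(vm$total_area, sum(tube) * 4 / 1e6)

  plus <- matrix(FALSE, 121, 121)
  plus[58:64, 11:111] <- TRUE; plus[11:111, 58:64] <- TRUE
  vp <- vessel_metrics(plus, 2)
  expect_equal(vp$n_junctions, 1L)
  expect_equal(vp$n_endpoints, 4L)

  expect_equal(vessel_metrics(matrix(FALSE, 10, 10), 2)$total_length, 0)
})

test_that("synthetic network metrics match the generator's graph truth", {
  for (s in c(7, 23, 42)) {
    g <- generate_network_image(network_spec(seed = s))
    mask <- binarize_vessels(g$frame)
    vm <- vessel_metrics(mask, g$frame$pixel_size)
    expect_equal(vm$n_junctions, g$truth$n_junctions)
    expect_equal(vm$n_endpoints, g$truth$n_endpoints)
    expect_lt(abs(vm$total_length / g$truth$total_length - 1), 0.05)
    # area at least length x minimum width (sanity bound on the mask)
    expect_gt(vm$total_area + 1e-9,
              vm$total_length * min(g$truth$widths_um) / 1000 * 0.9)
  }
})

test_that("metrics are invariant under translation and 180-degree rotation", {
  g <- generate_network_image(network_spec(seed = 11))
  m <- binarize_vessels(g$frame)
  v0 <- vessel_metrics(m, 4)
  # translation by padding
  shifted <- matrix(FALSE, nrow(m) + 15, ncol(m) + 9)
  shifted[16:(15 + nrow(m)), 10:(9 + ncol(m))] <- m
  vt <- vessel_metrics(shifted, 4)
  expect_equal(vt$n_junctions, v0$n_junctions)
  expect_equal(vt$n_endpoints, v0$n_endpoints)
  expect_lt(abs(vt$total_length / v0$total_length - 1), 0.01)
  # 180-degree rotation
  rot <- m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  vr <- vessel_metrics(rot, 4)
  expect_equal(vr$n_junctions, v0$n_junctions)
  expect_equal(vr$n_endpoints, v0$n_endpoints)
  expect_lt(abs(vr$total_length / v0$total_length - 1), 0.01)
})

test_that("doubling resolution preserves topology and nearly preserves length", {
  base <- network_spec(n_seeds = 16, seed = 31, noise_sd = 0, sp_prob = 0)
  fine <- network_spec(n_seeds = 16, seed = 31, noise_sd = 0, sp_prob = 0,
                       pixel_size = base$pixel_size / 2)
  g1 <- generate_network_image(base)
  g2 <- generate_network_image(fine)
  v1 <- vessel_metrics(g1$truth$mask, base$pixel_size)
  v2 <- vessel_metrics(g2$truth$mask, fine$pixel_size)
  expect_equal(v1$n_junctions, v2$n_junctions)
  expect_equal(v1$n_endpoints, v2$n_endpoints)
  expect_lt(abs(v2$total_length / v1$total_length - 1), 0.03)
})

test_that("vessel diameters are read off the distance transform", {
  tube <- matrix(FALSE, 80, 200); tube[36:44, 20:180] <- TRUE  # 9 px wide
  d <- vessel_diameter(tube, 2)
  expect_lt(abs(d$mean - 18), 2)           # within one 2-um pixel
  # two tubes sampled together average their widths
  two <- matrix(FALSE, 120, 200)
  two[20:24, 20:180] <- TRUE               # 5 px
  two[80:90, 20:180] <- TRUE               # 11 px
  d2 <- vessel_diameter(two, 2)
  expect_lt(abs(d2$mean - 16), 2)
  # minimal 1-px tube reads one pixel
  one <- matrix(FALSE, 40, 100); one[20, 10:90] <- TRUE
  expect_equal(vessel_diameter(one, 2)$mean, 2, tolerance = 1e-6)
  expect_error(vessel_diameter(matrix(FALSE, 5, 5), 2), "empty")
})

test_that("rendered tube diameters match the generator widths", {
  g <- generate_network_image(network_spec(seed = 7))
  d <- vessel_diameter(g$truth$mask, g$frame$pixel_size)
  # length-weighted mean of rendered widths, within one pixel
  w <- stats::weighted.mean(g$truth$widths_um, g$truth$edge_lengths_um)
  expect_lt(abs(d$mean - w), g$frame$pixel_size + 1e-9)
})

test_that("time-lapse subsampling analyses every n-th frame", {
  frame <- image_frame(matrix(20, 24, 24), 2)
  stack478 <- rep(list(frame), 478)
  # default mode keeps only complete groups of n: 47 analysed frames
  tm <- timeseries_metrics(stack478, subsample = 10, min_particle_area = 0)
  expect_equal(nrow(tm), 47L)
  expect_equal(tm$frame, (0:46) * 10 + 1)
  # inclusive mode also analyses the frame starting the trailing group
  tm2 <- timeseries_metrics(stack478, subsample = 10, endpoint_mode = "all",
                            min_particle_area = 0)
  expect_equal(nrow(tm2), 48L)
  # n = 1 analyses everything
  tm3 <- timeseries_metrics(rep(list(frame), 5), subsample = 1,
                            min_particle_area = 0)
  expect_equal(nrow(tm3), 5L)
  expect_error(timeseries_metrics(list(), 1), "empty")
})

test_that("a constant stack yields identical metrics on every frame", {
  g <- generate_network_image(network_spec(n_seeds = 9, domain_um = 400,
                                           seed = 3))
  stack <- rep(list(g$frame), 6)
  tm <- timeseries_metrics(stack, subsample = 2)
  expect_equal(nrow(tm), 3L)
  expect_equal(length(unique(tm$n_junctions)), 1L)
  expect_equal(length(unique(tm$total_length)), 1L)
})

test_that("lipid coverage recovers the rendered dark-area fraction", {
  # trivial extremes
  bright <- image_frame(matrix(220, 40, 60), 5)
  expect_equal(lipid_coverage(bright, c(0, 128))$whole, 0)
  dark_roi <- matrix(220, 40, 60); dark_roi[10:20, 10:20] <- 40
  prof <- lipid_coverage(image_frame(dark_roi, 5), c(0, 128),
                         roi = c(12, 18, 12, 18))
  expect_equal(prof$whole, 100)
  # generated droplet image, known fraction
  L <- generate_lipid_image(25, seed = 9)
  lc <- lipid_coverage(L$frame, c(0, 128))
  expect_lt(abs(lc$whole - L$truth$fraction_pct), 2)
  expect_error(lipid_coverage(L$frame, roi = c(0, 10, 1, 10)), "roi")
})

test_that("third-wise coverage averages back to the whole", {
  L <- generate_lipid_image(20, seed = 5)
  lc <- lipid_coverage(L$frame, c(0, 128))
  nc <- ncol(L$frame$pixels)
  cuts <- round(nc * c(1, 2) / 3)
  w <- c(cuts[1], cuts[2] - cuts[1], nc - cuts[2])
  expect_equal(sum(lc$thirds * w) / nc, lc$whole, tolerance = 1e-9)
  expect_named(lc$thirds, c("vasculogenesis", "middle", "adipogenesis"))
  # flipping the orientation swaps the outer thirds
  flipped <- lipid_coverage(L$frame, c(0, 128),
                            vasculogenesis_side = "right")
  expect_equal(unname(flipped$thirds["adipogenesis"]),
               unname(lc$thirds["vasculogenesis"]))
})

test_that("370-um bins span the analysed region", {
  L <- generate_lipid_image(15, seed = 2)   # 1000 um wide, 4 um px
  lc <- lipid_coverage(L$frame, c(0, 128))
  expect_equal(nrow(lc$bins), ceiling(1000 / 370))
  expect_equal(lc$bins$start_um[2] - lc$bins$start_um[1], 368) # 92 px bins
  expect_true(all(lc$bins$coverage_pct >= 0 & lc$bins$coverage_pct <= 100))
  # bin widths x coverages recombine to the whole-region coverage
  widths <- lc$bins$end_um - lc$bins$start_um
  expect_equal(sum(lc$bins$coverage_pct * widths) / sum(widths), lc$whole,
               tolerance = 1e-9)
})
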