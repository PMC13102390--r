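test_that("homography estimation recovers known projective maps", {
  set.seed(51)
  src <- cbind(runif(6, 10, 600), runif(6, 10, 400))
  # identity: identical point sets
  Hi <- estimate_homography(src, src)
  expect_equal(unclass(Hi), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  # a known projective matrix is recovered to near machine precision
  H <- matrix(c(0.98, 0.05, 3, -0.04, 1.02, -5, 1e-4, -8e-5, 1),
              3, 3, byrow = TRUE)
  dst <- apply_homography(H, src)
  Hh <- estimate_homography(src, dst)
  expect_lt(max(abs(unclass(Hh) - H)) / max(abs(H)), 1e-6)
  expect_lt(attr(Hh, "rms"), 1e-8)
  # underdetermined and degenerate configurations are rejected
  expect_error(estimate_homography(src[1:3, ], dst[1:3, ]), "at least 4")
  line <- cbind(1:6, 2 * (1:6) + 3)
  expect_error(estimate_homography(line, line), "collinear")
})

test_that("homography recovery tolerates control-point jitter", {
  set.seed(52)
  H <- matrix(c(1.01, 0.03, -4, -0.02, 0.99, 6, 5e-5, -4e-5, 1),
              3, 3, byrow = TRUE)
  worst <- 0
  for (i in 1:10) {
    src <- cbind(runif(6, 20, 580), runif(6, 20, 380))
    dst <- apply_homography(H, src) + matrix(rnorm(12, 0, 0.2), ncol = 2)
    worst <- max(worst, attr(estimate_homography(src, dst), "rms"))
  }
  expect_lte(worst, 0.5)
})

test_that("registration is exact for identity and integer translations", {
  set.seed(53)
  img <- nest_image(array(runif(60 * 80 * 3), c(60, 80, 3)), 0.1)
  same <- register(img, structure(diag(3), class = "homography"))
  expect_equal(same$img, img$img, tolerance = 1e-12)
  H <- matrix(c(1, 0, 5, 0, 1, -3, 0, 0, 1), 3, 3, byrow = TRUE)
  shifted <- register(img, H)
  # output pixel (r, c) samples source (c - 5, r + 3)
  expect_equal(shifted$img[20:40, 20:40, 2],
               img$img[20:40 + 3, 20:40 - 5, 2])
})

test_that("warp and unwarp round-trips away from the borders", {
  set.seed(54)
  base <- array(0.5, c(80, 100, 3))
  base[30:50, 40:70, ] <- 0.9
  img <- nest_image(base, 0.1)
  H <- matrix(c(1.02, 0.01, 2, -0.01, 0.98, 1, 2e-5, 1e-5, 1),
              3, 3, byrow = TRUE)
  there <- register(img, H)
  back <- register(there, solve(H))
  inner <- abs(back$img[20:60, 20:80, ] - img$img[20:60, 20:80, ])
  expect_lt(mean(inner), 0.02)
})

test_that("binarization recovers a bright cavity and ignores no-change pairs", {
  set.seed(55)
  nr <- 240; nc <- 300
  sand <- array(0.35 + rnorm(nr * nc * 3, 0, 0.02), c(nr, nc, 3))
  sand <- pmin(pmax(sand, 0), 1)
  initial <- nest_image(sand, 0.1)
  expect_equal(area_cm2(binarize(initial, initial)), 0)
  cav <- synth_nest_mask(
    data.frame(class = "chamber", x_cm = 15, y_cm = 12, orientation_deg = 0,
               width_cm = 3.6, length_cm = 3.6),
    canvas_cm = c(30, 24), pixel_scale = 0.1)$mask$mask
  cur <- sand
  for (ch in 1:3) {
    tmp <- cur[, , ch]; tmp[cav] <- 0.9; cur[, , ch] <- tmp
  }
  current <- nest_image(cur, 0.1)
  measured <- area_cm2(binarize(current, initial))
  truth <- sum(cav) * 0.01
  expect_lt(abs(measured - truth) / truth, 0.05)
  # all-dark pair: nothing excavated
  dark <- nest_image(array(0, c(20, 20, 3)), 0.1)
  expect_equal(area_cm2(binarize(dark, dark)), 0)
  expect_error(binarize(current, dark), "shape")
})

test_that("mask area is white-pixel count times squared pixel scale", {
  empty <- nest_mask(matrix(FALSE, 10, 10), 0.1)
  expect_equal(area_cm2(empty), 0)
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(area_cm2(nest_mask(m, 0.1)), 1.0)
})

test_that("skeletonization yields the expected branch structure", {
  # single straight strip 1 cm wide -> one branch of width ~1 cm
  strip <- synth_nest_mask(
    data.frame(class = "tunnel", x_cm = 10, y_cm = 5, orientation_deg = 0,
               width_cm = 1, length_cm = 14),
    canvas_cm = c(20, 10), pixel_scale = 0.1)
  seg <- skeletonize_and_segment(strip$mask)
  expect_equal(nrow(seg$branches), 1)
  expect_equal(seg$branches$mean_width_cm, 1, tolerance = 0.15)
  expect_lt(seg$branches$orientation_deg, 2)

  # plus-shaped mask: the two crossing strips are recovered (collinear arm
  # pairs reconnect across the junction; perpendicular arms never merge)
  plus <- synth_nest_mask(
    data.frame(class = c("tunnel", "tunnel"),
               x_cm = c(10, 10), y_cm = c(8, 8),
               orientation_deg = c(0, 90), width_cm = c(1, 1),
               length_cm = c(12, 12)),
    canvas_cm = c(20, 16), pixel_scale = 0.1)
  segp <- skeletonize_and_segment(plus$mask)
  expect_equal(nrow(segp$branches), 2)
  expect_equal(sort(segp$branches$orientation_deg), c(0, 90), tolerance = 2)

  # disk degenerates to a single branch about as wide as its diameter
  disk <- synth_nest_mask(
    data.frame(class = "chamber", x_cm = 6, y_cm = 6, orientation_deg = 0,
               width_cm = 4, length_cm = 4),
    canvas_cm = c(12, 12), pixel_scale = 0.1)
  segd <- skeletonize_and_segment(disk$mask)
  expect_equal(nrow(segd$branches), 1)
  expect_equal(segd$branches$mean_width_cm, 4, tolerance = 0.25)

  # empty mask: no branches
  seg0 <- skeletonize_and_segment(nest_mask(matrix(FALSE, 10, 10), 0.1))
  expect_equal(nrow(seg0$branches), 0)
})

test_that("branch orientation is the folded principal-axis angle", {
  horiz <- cbind(rep(5, 20), 1:20)        # (row, col)
  expect_equal(branch_orientation(horiz), 0)
  vert <- cbind(1:20, rep(5, 20))
  expect_equal(branch_orientation(vert), 90)
  diag45 <- cbind(1:20, 1:20)
  expect_equal(branch_orientation(diag45), 45, tolerance = 1)
  # mirroring left-right leaves the folded angle unchanged
  mirrored <- cbind(1:20, 21 - (1:20))
  expect_equal(branch_orientation(mirrored), branch_orientation(diag45))
  expect_error(branch_orientation(cbind(1, 1)), "single pixel")
})

test_that("classification applies the width and orientation rules", {
  seg <- structure(list(branches = data.frame(
    branch_id = 1:4,
    mean_width_cm = c(3, 0.9, 1.5, 3),
    orientation_deg = c(10, 50, 40, 50),
    area_cm2 = c(10, 5, 6, 9), path_px = c(10, 10, 10, 10))),
    class = "nest_segmentation")
  cls <- classify_branches(seg)$branches$class
  expect_equal(cls, c("chamber", "tunnel", "wide_tunnel", "tunnel"))
})

test_that("orientation histograms are area-weighted and sum to one", {
  seg <- structure(list(branches = data.frame(
    branch_id = 1:3, mean_width_cm = c(1, 1, 3),
    orientation_deg = c(45, 83, 12),
    area_cm2 = c(6, 2, 9), path_px = c(10, 10, 10),
    class = c("tunnel", "tunnel", "chamber"))),
    class = "nest_segmentation")
  h <- orientation_histogram(seg, "tunnel")
  expect_equal(sum(h$fraction), 1)
  expect_equal(h$fraction[h$bin_lo == 40], 0.75)   # 6 / (6 + 2)
  expect_equal(h$fraction[h$bin_lo == 80], 0.25)
  hc <- orientation_histogram(seg, "tunnel", weight = "count")
  expect_equal(hc$fraction[hc$bin_lo == 40], 0.5)
  hw <- orientation_histogram(seg, "wide_tunnel")
  expect_true(attr(hw, "empty"))
  expect_equal(sum(hw$fraction), 0)
})

test_that("synthetic masks are deterministic with analytic areas", {
  spec <- data.frame(class = "chamber", x_cm = 10, y_cm = 8,
                     orientation_deg = 0, width_cm = 2, length_cm = 6)
  a <- synth_nest_mask(spec, canvas_cm = c(20, 16), pixel_scale = 0.05)
  expect_equal(area_cm2(a$mask), pi * 3 * 1, tolerance = 0.02)
  b <- synth_nest_mask(spec, canvas_cm = c(20, 16), pixel_scale = 0.05)
  expect_identical(a$mask$mask, b$mask$mask)
  noisy1 <- synth_nest_mask(spec, canvas_cm = c(20, 16), pixel_scale = 0.05,
                            edge_noise = 0.2, seed = 3)
  noisy2 <- synth_nest_mask(spec, canvas_cm = c(20, 16), pixel_scale = 0.05,
                            edge_noise = 0.2, seed = 3)
  expect_identical(noisy1$mask$mask, noisy2$mask$mask)
  empty <- synth_nest_mask(NULL)
  expect_equal(area_cm2(empty$mask), 0)
})

test_that("segmentation recovers ground truth on a composite nest", {
  syn <- synth_nest_mask(demo_nest_primitives(), canvas_cm = c(40, 30),
                         pixel_scale = 0.1)
  seg <- classify_branches(skeletonize_and_segment(syn$mask))
  # per-class areas partition the mask area exactly
  expect_equal(sum(seg$branches$area_cm2), area_cm2(syn$mask))
  # pixel-level class accuracy against ground truth
  pred <- predicted_class_matrix(seg)
  inmask <- syn$labels > 0
  acc <- mean(pred[inmask] == syn$labels[inmask])
  expect_gte(acc, 0.90)
  # branch orientations match the generating primitives
  err <- vapply(seq_len(nrow(seg$branches)), function(i) {
    px <- seg$labels == i & inmask
    abs(seg$branches$orientation_deg[i] -
          median(syn$orientation[px], na.rm = TRUE))
  }, numeric(1))
  expect_lte(mean(err, na.rm = TRUE), 5)
  # orientation is invariant under left-right mirroring
  mir <- nest_mask(syn$mask$mask[, rev(seq_len(ncol(syn$mask$mask)))],
                   syn$mask$pixel_scale)
  segm <- skeletonize_and_segment(mir)
  expect_equal(sort(segm$branches$orientation_deg),
               sort(seg$branches$orientation_deg), tolerance = 0.1)
})
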