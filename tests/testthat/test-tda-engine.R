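aligned_phantom <- function(...) {
  ph <- generate_phantom(phantom_spec(...))
  align_vertical(ph$apical_mask, ph$coronal_mask)
}

test_that("canal midlines sit at the center of symmetric canals", {
  # two vertical wall bands flanking an empty canal about column 64:
  # the outer band coronal, the inner band apical, as in a root canal
  cor <- blank_mask(128)
  api <- blank_mask(128)
  cor[20:100, 50:57] <- TRUE
  api[40:100, 71:78] <- TRUE
  cor[10:19, 50:78] <- TRUE   # bridge making barycenters distinct columns
  al <- structure(list(apical = api, coronal = cor, rotation_deg = 0,
                       rotation_center = c(row = 60, col = 64),
                       apical_barycenter = barycenter(api),
                       coronal_barycenter = barycenter(cor)),
                  class = "aligned_tooth_masks")
  mls <- canal_midlines(al)
  expect_length(mls, 1)
  expect_true(all(abs(mls[[1]]$points[, "col"] - 64) <= 0.5))
  expect_true(all(diff(mls[[1]]$points[, "row"]) >= 0))
  expect_equal(unname(mls[[1]]$apex_middle["row"]), 100)
})

test_that("phantom midlines track the analytic canal centers and end mid-apex", {
  for (seed in 1:3) {
    ph <- generate_phantom(phantom_spec(a_px = 10, b_px = 14, c_px = 160,
                                        rotation_deg = c(-12, 0, 9)[seed],
                                        seed = seed))
    al <- align_vertical(ph$apical_mask, ph$coronal_mask)
    mls <- canal_midlines(al)
    expect_length(mls, 2)
    for (k in 1:2) {
      # analytic centerline, mapped through the generator and alignment rotations
      truth <- t(apply(ph$analytic_midlines[[k]], 1, rotate_rc,
                       angle_deg = al$rotation_deg, center = al$rotation_center))
      got <- mls[[k]]$points
      # compare over the rows the analytic curve covers (the measured
      # polyline may pick up a mouth row or two above the curve start)
      got <- got[got[, 1] >= min(truth[, 1]) + 1 &
                   got[, 1] <= max(truth[, 1]) - 1, , drop = FALSE]
      expect_gt(nrow(got), 50)
      dev <- vapply(seq_len(nrow(got)), function(i) {
        min(sqrt((truth[, 1] - got[i, 1])^2 + (truth[, 2] - got[i, 2])^2))
      }, numeric(1))
      expect_lt(max(dev), 1.5)
      # terminal point is the middle of the apex
      apex_true <- rotate_rc(truth[nrow(truth), ], 0, c(0, 0))
      expect_lt(sqrt(sum((mls[[k]]$apex_middle - truth[nrow(truth), ])^2)), 2)
    }
  }
})

test_that("closed geometries raise ClosedApexError", {
  # solid apical disk under a crown: no enclosed background gap
  api <- disk_mask(256, c(170, 128), 25)
  cor <- blank_mask(256); cor[60:100, 100:156] <- TRUE
  al <- align_vertical(api, cor)
  expect_error(canal_midlines(al), class = "i3m_closed_apex_error")
  expect_error(measure_tda(al), class = "i3m_closed_apex_error")
})

test_that("radii partition splits an annulus into its two circle boundaries", {
  api <- annulus_mask(64, c(32, 32), 8, 14)
  ml <- i3m:::new_canal_midline(data.frame(
    row = 32, mid = 32, left_col = 24, right_col = 40,
    left_instance = "apical", right_instance = "apical"))
  part <- radii_partition(api, ml)
  inner_got <- rbind(part$left$inner, part$right$inner)
  outer_got <- rbind(part$left$outer, part$right$outer)
  # oracle: wall-surface (4-boundary) pixels side-adjacent to the enclosed
  # hole vs to the outside
  nb4 <- function(m) {
    i3m:::nb_shift(m, -1L, 0L) | i3m:::nb_shift(m, 1L, 0L) |
      i3m:::nb_shift(m, 0L, -1L) | i3m:::nb_shift(m, 0L, 1L)
  }
  bnd <- i3m:::boundary4(api)
  hole <- !api & disk_mask(64, c(32, 32), 10)
  outside <- !api & !hole
  inner_want <- which(bnd & nb4(hole), arr.ind = TRUE)
  outer_want <- which(bnd & nb4(outside), arr.ind = TRUE)
  key <- function(px) sort(paste(px[, 1], px[, 2]))
  expect_identical(key(inner_got), key(inner_want))
  expect_identical(key(outer_got), key(outer_want))
})

test_that("degenerate walls without an outward boundary are rejected", {
  ring <- blank_mask(16)
  ring[7:9, 7:9] <- TRUE
  ring[8, 8] <- FALSE  # single-pixel ring of radius 1: every pixel canal-facing
  ml <- i3m:::new_canal_midline(data.frame(
    row = 8, mid = 8, left_col = 7, right_col = 9,
    left_instance = "apical", right_instance = "apical"))
  expect_error(radii_partition(ring, ml),
               class = "i3m_degenerate_geometry_error")
})

test_that("measure_tda recovers phantom ground truth within landmark tolerance", {
  ph <- generate_phantom(phantom_spec(a_px = 10, b_px = 12, c_px = 150, seed = 21))
  m <- measure_phantom(ph)
  expect_lt(abs(m$a_px - 10), 2)
  expect_lt(abs(m$b_px - 12), 2)
  expect_lt(abs(m$c_px - 150), 2)

  # the same tooth pre-rotated by 25 degrees, after internal alignment
  ph2 <- generate_phantom(phantom_spec(a_px = 10, b_px = 12, c_px = 150,
                                       rotation_deg = 25, seed = 21))
  m2 <- measure_phantom(ph2)
  expect_lt(abs(m2$a_px - 10), 2)
  expect_lt(abs(m2$b_px - 12), 2)
  expect_lt(abs(m2$c_px - 150), 2)
})

test_that("horizontal flips swap a and b and preserve their sum", {
  ph <- generate_phantom(phantom_spec(a_px = 8, b_px = 16, c_px = 140, seed = 31))
  m <- measure_phantom(ph)
  flip <- function(x) x[, rev(seq_len(ncol(x)))]
  mf <- measure_masks(flip(ph$apical_mask), flip(ph$coronal_mask),
                      method = "tda")$tda$measurement
  expect_equal(mf$a_px, m$b_px, tolerance = 1e-6)
  expect_equal(mf$b_px, m$a_px, tolerance = 1e-6)
  expect_equal(mf$a_px + mf$b_px, m$a_px + m$b_px, tolerance = 1e-6)
})

test_that("midline points are equidistant to their two walls (property)", {
  ph <- generate_phantom(phantom_spec(a_px = 9, b_px = 13, c_px = 170,
                                      rotation_deg = -8, seed = 4))
  al <- align_vertical(ph$apical_mask, ph$coronal_mask)
  walls <- mask_pixels(al$apical | al$coronal)
  for (ml in canal_midlines(al)) {
    for (i in seq_len(nrow(ml$points))) {
      p <- ml$points[i, ]
      d <- sqrt((walls[, 1] - p[1])^2 + (walls[, 2] - p[2])^2)
      left <- walls[, 2] < p[2]
      expect_lt(abs(min(d[left]) - min(d[!left])), 1)
    }
  }
})

test_that("measurements are covariant with scale and leave I3M invariant", {
  small <- generate_phantom(phantom_spec(a_px = 8, b_px = 10, c_px = 120,
                                         wall_thickness_px = 6,
                                         canal_top_width_px = 14,
                                         cervical_gap_px = 4, seed = 12))
  big <- generate_phantom(phantom_spec(a_px = 12, b_px = 15, c_px = 180,
                                       wall_thickness_px = 9,
                                       canal_top_width_px = 21,
                                       cervical_gap_px = 6, seed = 12))
  ms <- measure_phantom(small); mb <- measure_phantom(big)
  expect_lt(abs(mb$a_px / ms$a_px - 1.5), 0.045)
  expect_lt(abs(mb$b_px / ms$b_px - 1.5), 0.045)
  expect_lt(abs(mb$c_px / ms$c_px - 1.5), 0.045)
  expect_lt(abs(compute_i3m(mb) - compute_i3m(ms)), 0.01)
})
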