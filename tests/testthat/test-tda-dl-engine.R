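test_that("apical_skeleton traces the band centerline with tips at the apices", {
  ph <- generate_phantom(phantom_spec(a_px = 12, b_px = 12, c_px = 160, seed = 8))
  sk <- apical_skeleton(ph$apical_mask)
  cp <- sk$control_points
  expect_equal(nrow(cp), 5)
  expect_true(all(diff(cp[, "col"]) > 0))
  # endpoints near the analytic band-tip centers, symmetric about the axis
  expect_lt(sqrt(sum((cp[1, ] - ph$landmarks$skeleton_left)^2)), 2.5)
  expect_lt(sqrt(sum((cp[5, ] - ph$landmarks$skeleton_right)^2)), 2.5)
  axis <- (ph$landmarks$skeleton_left[["col"]] + ph$landmarks$skeleton_right[["col"]]) / 2
  expect_lte(abs((axis - cp[1, "col"]) - (cp[5, "col"] - axis)), 2)
  # skeleton and control points lie inside the band
  expect_true(all(ph$apical_mask[sk$polyline]))
  expect_true(all(ph$apical_mask[round(cp)]))
})

test_that("skeleton keeps its medial distance from the boundary (property)", {
  ph <- generate_phantom(phantom_spec(seed = 14))
  w <- ph$spec$wall_thickness_px
  sk <- apical_skeleton(ph$apical_mask)
  # distance transform of the band: medial pixels are >= w/2 - 1 from background
  dm <- t(as.matrix(EBImage::distmap(t(ph$apical_mask))))
  interior <- sk$polyline[sk$polyline[, "row"] < max(sk$polyline[, "row"]) - w, ,
                          drop = FALSE]
  expect_true(all(dm[interior] >= w / 2 - 1))
})

test_that("solid blobs have no band-like skeleton", {
  expect_error(apical_skeleton(disk_mask(64, c(32, 32), 14)),
               class = "i3m_degenerate_geometry_error")
})

test_that("coronal limit points are the lowest pixels on each side of the axis", {
  rect <- blank_mask(20)
  rect[5:10, 4:15] <- TRUE
  lp <- coronal_limit_points(rect, 9.5)
  expect_equal(lp$left, c(row = 10, col = 9))
  expect_equal(lp$right, c(row = 10, col = 10))

  # phantom: the lowest coronal points are the outer wall tips
  ph <- generate_phantom(phantom_spec(a_px = 10, b_px = 14, c_px = 150, seed = 5))
  lp2 <- coronal_limit_points(ph$coronal_mask, 128.5)
  expect_lt(sqrt(sum((lp2$left - ph$landmarks$mesial_outer_tip)^2)), 2)
  expect_lt(sqrt(sum((lp2$right - ph$landmarks$distal_outer_tip)^2)), 2)

  onesided <- blank_mask(20)
  onesided[5:10, 2:8] <- TRUE
  expect_error(coronal_limit_points(onesided, 15),
               class = "i3m_degenerate_geometry_error")
})

test_that("measure_tda_dl matches the phantom's analytic landmark gaps", {
  ph <- generate_phantom(phantom_spec(a_px = 10, b_px = 14, c_px = 160, seed = 6))
  m <- measure_phantom(ph, "tda_dl")
  expect_lt(abs(m$a_px - ph$truth_tda_dl[["a"]]), 3)
  expect_lt(abs(m$b_px - ph$truth_tda_dl[["b"]]), 3)

  # flips swap a and b (within the raster parity of the thinning pass),
  # c unchanged exactly
  flip <- function(x) x[, rev(seq_len(ncol(x)))]
  mf <- measure_masks(flip(ph$apical_mask), flip(ph$coronal_mask),
                      method = "tda_dl")$tda_dl$measurement
  expect_lt(abs(mf$a_px - m$b_px), 1.5)
  expect_lt(abs(mf$b_px - m$a_px), 1.5)
  expect_equal(mf$c_px, m$c_px)
})

test_that("both engines share the tooth-height definition exactly", {
  for (seed in c(3, 9)) {
    ph <- generate_phantom(phantom_spec(rotation_deg = 11, seed = seed))
    res <- measure_masks(ph$apical_mask, ph$coronal_mask, method = "both")
    expect_identical(res$tda$measurement$c_px, res$tda_dl$measurement$c_px)
  }
})

test_that("an external skeleton backend can replace the thinning default", {
  ph <- generate_phantom(phantom_spec(seed = 10))
  backend <- function(apical) {
    rbind(ph$landmarks$skeleton_left,
          c(150, 120), c(145, 128), c(150, 137),
          ph$landmarks$skeleton_right)
  }
  al <- align_vertical(ph$apical_mask, ph$coronal_mask)
  m <- measure_tda_dl(al, skeleton_backend = backend)
  expect_s3_class(m, "i3m_measurement")
  expect_equal(m$method, "TDA_DL")
  m_builtin <- measure_tda_dl(al)
  expect_lt(abs(m$a_px - m_builtin$a_px), 3)
})

test_that("TDA-DL reads looser landmarks than TDA on average (cohort trend)", {
  co <- generate_cohort(15, seed = 99)
  tda <- measure_cohort(co, "tda")
  dl <- measure_cohort(co, "tda_dl")
  ok <- !is.na(tda$i3m) & !is.na(dl$i3m)
  expect_gt(mean(dl$a_px[ok] + dl$b_px[ok]), mean(tda$a_px[ok] + tda$b_px[ok]))
})
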