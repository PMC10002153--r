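test_that("phantoms are bit-reproducible from their seed", {
  s <- phantom_spec(a_px = 11, b_px = 9, c_px = 170, rotation_deg = 8, seed = 5)
  p1 <- generate_phantom(s)
  p2 <- generate_phantom(s)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$apical_mask, p2$apical_mask)
  expect_identical(p1$coronal_mask, p2$coronal_mask)
})

test_that("stored landmarks reproduce the analytic ground truth exactly", {
  for (rot in c(0, -17, 23)) {
    ph <- generate_phantom(phantom_spec(a_px = 10, b_px = 12, c_px = 150,
                                        rotation_deg = rot, seed = 1))
    lm <- ph$landmarks
    d <- function(p, q) sqrt(sum((p - q)^2))
    expect_equal(d(lm$mesial_outer_tip, lm$mesial_inner_tip), 10, tolerance = 1e-6)
    expect_equal(d(lm$distal_inner_tip, lm$distal_outer_tip), 12, tolerance = 1e-6)
    expect_equal(d(lm$top, lm$bottom), 150, tolerance = 1e-6)
    expect_equal(ph$truth$a_px, 10, tolerance = 1e-6)
    expect_equal(ph$truth$b_px, 12, tolerance = 1e-6)
    expect_equal(ph$truth$c_px, 150)
    expect_equal(ph$truth_decision,
                 classify_age(compute_i3m(ph$truth), 0.08))
    expect_equal(sum(ph$apical_mask & ph$coronal_mask), 0)
  }
})

test_that("unsatisfiable geometries are rejected", {
  expect_error(phantom_spec(a_px = 0, b_px = 0),
               class = "i3m_phantom_geometry_error")
  expect_error(phantom_spec(a_px = 40, b_px = 40, c_px = 120),
               class = "i3m_phantom_geometry_error")
  expect_error(phantom_spec(c_px = 300),
               class = "i3m_phantom_geometry_error")
  expect_error(phantom_spec(wall_thickness_px = 1),
               class = "i3m_phantom_geometry_error")
})

test_that("cohorts are reproducible and their minor fraction tracks the ranges", {
  c1 <- generate_cohort(12, seed = 7)
  c2 <- generate_cohort(12, seed = 7)
  expect_identical(cohort_truth(c1), cohort_truth(c2))

  # ranges forcing I3M > 0.08 everywhere: all minors
  all_minor <- generate_cohort(20, ranges = list(a_px = c(10, 20), b_px = c(10, 20),
                                                 c_px = c(120, 160)), seed = 8)
  expect_true(all(cohort_truth(all_minor)$decision == "minor"))

  # ranges centered so ~57% of draws exceed the cut-off: the realized minor
  # fraction stays within a 10-point binomial band at n = 100
  mid <- generate_cohort(100, ranges = list(a_px = c(3.8, 9.6), b_px = c(3.8, 9.6),
                                            c_px = c(120, 200)), seed = 9)
  frac <- mean(cohort_truth(mid)$decision == "minor")
  expect_gt(frac, 0.47)
  expect_lt(frac, 0.67)
})

test_that("degrade_mask is a seeded no-op at severity 0 and monotone in severity", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  m <- ph$apical_mask
  expect_identical(degrade_mask(m, 0, 1), m)

  iou_at <- function(sev, seeds) {
    mean(vapply(seeds, function(s) {
      segmentation_eval(m, degrade_mask(m, sev, s))$iou
    }, numeric(1)))
  }
  seeds <- 1:50
  i1 <- iou_at(0.2, seeds); i2 <- iou_at(0.5, seeds); i3 <- iou_at(0.9, seeds)
  expect_gt(i1, i2)
  expect_gt(i2, i3)

  # full severity on a compact ~100 px mask is clearly visible in IoU
  blob <- disk_mask(64, c(32, 32), 5.6)
  expect_equal(sum(blob) >= 90 && sum(blob) <= 110, TRUE)
  expect_lt(mean(vapply(1:20, function(s) {
    segmentation_eval(blob, degrade_mask(blob, 1, s))$iou
  }, numeric(1))), 0.9)
})

test_that("severity calibration hits a target mean IoU", {
  co <- generate_cohort(8, seed = 13)
  sev <- calibrate_degrade_severity(co, target_iou = 0.9, seed = 5, tol = 0.01)
  miou <- mean(vapply(seq_along(co), function(i) {
    truth <- co[[i]]$apical_mask | co[[i]]$coronal_mask
    deg <- degrade_mask(co[[i]]$apical_mask, sev, seed = 5 + 2 * i) |
      degrade_mask(co[[i]]$coronal_mask, sev, seed = 5 + 2 * i + 1)
    segmentation_eval(truth, deg)$iou
  }, numeric(1)))
  expect_lt(abs(miou - 0.9), 0.03)
})

test_that("phantom datasets round-trip through the labelme I/O path", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(3, seed = 21)
  truth <- write_phantom_dataset(co, dir)
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  expect_length(files, 3)
  ann <- read_labelme(files[1])
  masks <- annotation_masks(ann)
  # rasterizing the stored polygons reproduces the generator's masks
  expect_equal(masks$apical, co[[1]]$apical_mask)
  expect_equal(masks$coronal, co[[1]]$coronal_mask)
  csv <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  expect_equal(nrow(csv), 3)
  expect_equal(csv$i3m, cohort_truth(co)$i3m, tolerance = 1e-9)
})
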