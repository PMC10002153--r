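# Synthetic third-molar phantoms with analytic ground truth.
#
# A phantom is a stylized crop of a two-rooted mandibular third molar with
# open apices. The coronal instance is the crown plus the two outer root
# walls; the apical instance is the central inter-radicular band, an
# inverted U whose two lower tips are the inner sides of the two apices.
# Each root canal is the open gap between an outer (coronal) wall and one
# branch of the apical band, so the canal midline is the line equidistant to
# the two instances, and every apex is flanked by one coronal and one apical
# wall tip whose distance is the analytic apex width.

#' Phantom specification
#'
#' All lengths are in pixels on the `image_size` grid. The geometric layout
#' derives from the targets: crown height is 0.30 c, the root spans the
#' remaining height, canals open from just below the crown to the apices.
#'
#' @param a_px,b_px Target mesial / distal apex widths (>= 3 px: narrower
#'   apices are closed at raster resolution and are rejected, mirroring the
#'   exclusion of radiographs without two open apices).
#' @param c_px Target tooth height.
#' @param image_size Square grid side.
#' @param wall_thickness_px Dentine wall thickness (>= 2).
#' @param crown_width_px Crown width; default `0.55 c`.
#' @param cervical_gap_px Vertical gap separating the two instances below
#'   the crown.
#' @param canal_top_width_px Canal width at its coronal end.
#' @param rotation_deg In-plane rotation of the whole scene about the grid
#'   center.
#' @param noise_sd Gaussian gray-level noise SD (on the `[0, 1]` scale).
#' @param seed Integer seed; generation is bit-reproducible.
#' @export
phantom_spec <- function(a_px = 12, b_px = 12, c_px = 160, image_size = 256L,
                         wall_thickness_px = 6, crown_width_px = NULL,
                         cervical_gap_px = 4, canal_top_width_px = 16,
                         rotation_deg = 0, noise_sd = 0.03, seed = 1L) {
  if (is.null(crown_width_px)) crown_width_px <- round(0.55 * c_px)
  spec <- list(a_px = a_px, b_px = b_px, c_px = c_px,
               image_size = as.integer(image_size),
               wall_thickness_px = wall_thickness_px,
               crown_width_px = crown_width_px,
               cervical_gap_px = cervical_gap_px,
               canal_top_width_px = canal_top_width_px,
               rotation_deg = rotation_deg, noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$a_px < 3 || s$b_px < 3) {
    abort_phantom_geometry("apex widths below 3 px cannot be rendered as open apices")
  }
  if (s$a_px >= s$c_px || s$b_px >= s$c_px || s$c_px > s$image_size) {
    abort_phantom_geometry("need a, b < c <= image_size")
  }
  if (s$wall_thickness_px < 2) abort_phantom_geometry("wall thickness must be >= 2 px")
  geo <- phantom_layout(s)
  if (geo$sep - (s$a_px + s$b_px) / 2 - 2 * s$wall_thickness_px < 3) {
    abort_phantom_geometry("root walls overlap: apices too wide for the canal separation")
  }
  if (geo$x0 - s$crown_width_px / 2 < 2 || geo$r_top < 2 ||
      geo$r_bot > s$image_size - 1) {
    abort_phantom_geometry("tooth does not fit on the grid")
  }
  invisible(s)
}

# Deterministic continuous layout (upright, before rotation).
phantom_layout <- function(s) {
  x0 <- (s$image_size + 1) / 2
  r_top <- round((s$image_size + 1) / 2 - s$c_px / 2)
  r_bot <- r_top + s$c_px
  h_crown <- round(0.30 * s$c_px)
  r_cerv <- r_top + h_crown
  r_arch <- r_cerv + s$cervical_gap_px
  g <- s$canal_top_width_px
  t <- s$wall_thickness_px
  sep <- max(2 * t + g + 8, round(0.28 * s$c_px))
  list(x0 = x0, r_top = r_top, r_bot = r_bot, r_cerv = r_cerv, r_arch = r_arch,
       g = g, t = t, sep = sep, x_m = x0 - sep / 2, x_d = x0 + sep / 2,
       w2 = s$crown_width_px / 2, h_crown = h_crown)
}

phantom_polygons <- function(s) {
  L <- phantom_layout(s)
  a2 <- s$a_px / 2; b2 <- s$b_px / 2
  tip <- 2  # outer-wall tip width
  ell_c_row <- L$r_top + L$h_crown / 2
  phi <- seq(pi, 0, length.out = 25)
  crown_arc <- cbind(x = L$x0 + L$w2 * cos(phi),
                     y = ell_c_row - (L$h_crown / 2) * sin(phi))
  coronal <- rbind(
    c(L$x_m - a2 - tip, L$r_bot),
    c(L$x_m - L$g / 2 - L$t, L$r_cerv),
    crown_arc,
    c(L$x_d + L$g / 2 + L$t, L$r_cerv),
    c(L$x_d + b2 + tip, L$r_bot),
    c(L$x_d + b2, L$r_bot),
    c(L$x_d + L$g / 2, L$r_cerv),
    c(L$x_m - L$g / 2, L$r_cerv),
    c(L$x_m - a2, L$r_bot))
  apical <- rbind(
    c(L$x_m + L$g / 2, L$r_arch),
    c(L$x_d - L$g / 2, L$r_arch),
    c(L$x_d - b2, L$r_bot),
    c(L$x_d - b2 - L$t, L$r_bot),
    c(L$x_d - L$g / 2 - L$t, L$r_arch + L$t),
    c(L$x_m + L$g / 2 + L$t, L$r_arch + L$t),
    c(L$x_m + a2 + L$t, L$r_bot),
    c(L$x_m + a2, L$r_bot))
  colnames(coronal) <- colnames(apical) <- c("x", "y")
  list(coronal = coronal, apical = apical, layout = L)
}

phantom_landmarks <- function(s, L) {
  a2 <- s$a_px / 2; b2 <- s$b_px / 2; t <- L$t
  list(
    mesial_outer_tip = point_rc(L$r_bot, L$x_m - a2),
    mesial_inner_tip = point_rc(L$r_bot, L$x_m + a2),
    distal_inner_tip = point_rc(L$r_bot, L$x_d - b2),
    distal_outer_tip = point_rc(L$r_bot, L$x_d + b2),
    mesial_apex_middle = point_rc(L$r_bot, L$x_m),
    distal_apex_middle = point_rc(L$r_bot, L$x_d),
    top = point_rc(L$r_top, L$x0),
    bottom = point_rc(L$r_bot, L$x0),
    # band-end centers of the apical band (TDA-DL apical endpoints)
    skeleton_left = point_rc(L$r_bot, L$x_m + a2 + t / 2),
    skeleton_right = point_rc(L$r_bot, L$x_d - b2 - t / 2))
}

#' Generate a tooth phantom
#'
#' Builds the coronal and apical instance polygons, rasterizes them, renders
#' a radiograph-like gray image with Gaussian noise, rotates the whole scene
#' (masks by nearest neighbor, landmarks analytically) and stores the
#' analytic ground truth: apex widths `a`, `b` as the distances between the
#' stored wall-tip landmarks, tooth height `c` as the pre-rotation vertical
#' extent, plus the canal centerlines and the landmark set used by the
#' TDA-DL construction.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom_tooth`: `image`, `apical_mask`,
#'   `coronal_mask`, polygons, `landmarks`, `analytic_midlines`, `truth`
#'   (an `i3m_measurement`), `truth_tda_dl` (`c(a, b)` expected under the
#'   TDA-DL landmark construction), `truth_decision`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  polys <- phantom_polygons(spec)
  L <- polys$layout
  shape <- c(spec$image_size, spec$image_size)
  lm <- phantom_landmarks(spec, L)
  midlines <- list(
    mesial = cbind(row = seq(L$r_arch, L$r_bot), col = L$x_m),
    distal = cbind(row = seq(L$r_arch, L$r_bot), col = L$x_d))
  poly_out <- polys[c("coronal", "apical")]
  if (abs(spec$rotation_deg) > 1e-12) {
    # rotate the continuous geometry, then rasterize: the rotated scene is
    # rendered exactly instead of resampling an upright raster
    ctr <- point_rc((shape[1] + 1) / 2, (shape[2] + 1) / 2)
    lm <- lapply(lm, rotate_point, angle_deg = spec$rotation_deg, center = ctr)
    midlines <- lapply(midlines, function(m) {
      out <- t(apply(m, 1, function(p) rotate_point(p, spec$rotation_deg, ctr)))
      colnames(out) <- c("row", "col")
      out
    })
    poly_out <- lapply(poly_out, function(p) {
      out <- t(apply(p, 1, function(v) {
        q <- rotate_point(point_rc(v["y"], v["x"]), spec$rotation_deg, ctr)
        c(x = q[["col"]], y = q[["row"]])
      }))
      colnames(out) <- c("x", "y")
      out
    })
  }
  coronal <- rasterize_polygon(poly_out$coronal, shape)
  apical <- rasterize_polygon(poly_out$apical, shape)
  if (any(coronal & apical)) abort_phantom_geometry("instance polygons overlap")
  image <- withr::with_seed(spec$seed, {
    img <- matrix(0.18, shape[1], shape[2])
    img[coronal] <- 0.82
    img[apical] <- 0.70
    if (spec$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    matrix(pmin(pmax(img, 0), 1), shape[1], shape[2])
  })
  truth <- new_measurement(
    a_px = point_distance(lm$mesial_outer_tip, lm$mesial_inner_tip),
    b_px = point_distance(lm$distal_inner_tip, lm$distal_outer_tip),
    c_px = spec$c_px,
    method = "truth",
    landmarks = lm)
  truth_tda_dl <- c(
    a = point_distance(lm$mesial_outer_tip, lm$skeleton_left),
    b = point_distance(lm$skeleton_right, lm$distal_outer_tip))
  structure(list(image = image, apical_mask = apical, coronal_mask = coronal,
                 apical_polygon = poly_out$apical, coronal_polygon = poly_out$coronal,
                 landmarks = lm, analytic_midlines = midlines,
                 truth = truth, truth_tda_dl = truth_tda_dl,
                 truth_decision = classify_age(compute_i3m(truth)),
                 spec = spec),
            class = "phantom_tooth")
}

#' @export
print.phantom_tooth <- function(x, ...) {
  cat(sprintf("<phantom_tooth> a = %.1f, b = %.1f, c = %.1f px, rotation %.1f deg, I3M = %.4f (%s)\n",
              x$truth$a_px, x$truth$b_px, x$truth$c_px, x$spec$rotation_deg,
              compute_i3m(x$truth), x$truth_decision))
  invisible(x)
}

#' Default cohort parameter ranges
#'
#' The study conditions for phantom cohorts: apex widths 6-20 px, tooth
#' heights 120-200 px and in-plane rotations within +/- 20 degrees on the
#' 256 px grid.
#' @export
cohort_ranges <- function() {
  list(a_px = c(6, 20), b_px = c(6, 20), c_px = c(120, 200),
       rotation_deg = c(-20, 20))
}

#' Generate a phantom cohort
#'
#' Draws `n` phantoms with parameters uniform over `ranges`; a draw whose
#' geometry is unsatisfiable is resampled up to 10 times before failing.
#'
#' @param n Cohort size.
#' @param ranges Named list of `c(min, max)` intervals over any subset of
#'   `a_px`, `b_px`, `c_px`, `rotation_deg` (defaults from [cohort_ranges()]).
#' @param seed Integer seed.
#' @return List of `phantom_tooth` objects.
#' @export
generate_cohort <- function(n, ranges = cohort_ranges(), seed = 1L) {
  stopifnot(n >= 1)
  ranges <- utils::modifyList(cohort_ranges(), ranges)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      for (attempt in 1:10) {
        draw <- lapply(ranges, function(rg) stats::runif(1, rg[1], rg[2]))
        ph <- tryCatch(
          generate_phantom(phantom_spec(
            a_px = draw$a_px, b_px = draw$b_px, c_px = round(draw$c_px),
            rotation_deg = draw$rotation_deg,
            seed = sample.int(.Machine$integer.max, 1))),
          i3m_phantom_geometry_error = function(e) NULL)
        if (!is.null(ph)) return(ph)
      }
      abort_phantom_geometry("could not draw a feasible phantom in 10 attempts")
    })
  })
}

#' Cohort ground truth as a tibble
#'
#' @param cohort List of `phantom_tooth` objects.
#' @return Tibble with one row per phantom: truth a, b, c, I3M, decision.
#' @export
cohort_truth <- function(cohort) {
  dplyr::bind_rows(lapply(seq_along(cohort), function(i) {
    ph <- cohort[[i]]
    tibble::tibble(id = i, a_px = ph$truth$a_px, b_px = ph$truth$b_px,
                   c_px = ph$truth$c_px, i3m = compute_i3m(ph$truth),
                   decision = ph$truth_decision,
                   rotation_deg = ph$spec$rotation_deg)
  }))
}

#' Simulate segmentation error on a mask
#'
#' Flips pixels in a band around the mask boundary (erosion/dilation
#' patches) and adds sparse speckle, with both the band depth and the flip
#' probability growing with `severity`, so the expected IoU against the
#' input decreases monotonically.
#'
#' @param mask Non-empty logical mask.
#' @param severity Degradation level in `[0, 1]`; 0 returns the input.
#' @param seed Integer seed.
#' @return Degraded logical mask.
#' @export
degrade_mask <- function(mask, severity, seed = 1L) {
  assert_mask(mask)
  if (!any(mask)) abort_empty_mask()
  stopifnot(severity >= 0, severity <= 1)
  if (severity == 0) return(mask)
  withr::with_seed(as.integer(seed), {
    depth <- 1L + round(2 * severity)
    band <- mask
    grown <- mask
    for (k in seq_len(depth)) grown <- dilate8(grown)
    shrunk <- mask
    for (k in seq_len(depth)) shrunk <- shrunk & !boundary8(shrunk)
    band <- grown & !shrunk
    flip <- band & matrix(stats::runif(length(mask)) < 0.35 * severity,
                          nrow(mask), ncol(mask))
    out <- xor(mask, flip)
    # sparse speckle near the structure
    n_speck <- round(6 * severity)
    if (n_speck > 0) {
      px <- mask_pixels(grown)
      pick <- px[sample.int(nrow(px), min(n_speck, nrow(px))), , drop = FALSE]
      out[pick] <- !out[pick]
    }
    out
  })
}

#' Calibrate degrade_mask severity to a target mean IoU
#'
#' Bisects the severity so that the mean overall IoU between pristine and
#' degraded instance pairs over the given phantoms is close to `target_iou`.
#'
#' @param phantoms List of `phantom_tooth` objects.
#' @param target_iou Target mean IoU of the degraded masks.
#' @param seed Integer seed for the degradations.
#' @param tol Acceptable deviation from the target.
#' @return Severity in `[0, 1]`.
#' @export
calibrate_degrade_severity <- function(phantoms, target_iou = 0.9, seed = 1L,
                                       tol = 0.01) {
  miou_at <- function(sev) {
    mean(vapply(seq_along(phantoms), function(i) {
      ph <- phantoms[[i]]
      truth <- ph$apical_mask | ph$coronal_mask
      deg <- degrade_mask(ph$apical_mask, sev, seed = seed + 2L * i) |
        degrade_mask(ph$coronal_mask, sev, seed = seed + 2L * i + 1L)
      segmentation_eval(truth, deg)$iou
    }, numeric(1)))
  }
  lo <- 0; hi <- 1
  if (miou_at(1) > target_iou) return(1)
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    m <- miou_at(mid)
    if (abs(m - target_iou) <= tol) return(mid)
    if (m > target_iou) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Measure every phantom of a cohort
#'
#' Runs the full pipeline (alignment + the requested engine) on each
#' phantom's instance masks and returns a tidy per-tooth table next to the
#' ground truth.
#'
#' @param cohort List of `phantom_tooth` objects.
#' @param method `"tda"` or `"tda_dl"`.
#' @param masks Optional function `function(phantom, id)` returning the
#'   `list(apical =, coronal =)` masks to measure (e.g. degraded ones);
#'   defaults to the pristine masks.
#' @param threshold Decision cut-off.
#' @return Tibble with measured and true a, b, c, I3M and decisions; rows
#'   whose measurement failed carry the error class in `error`.
#' @export
measure_cohort <- function(cohort, method = c("tda", "tda_dl"), masks = NULL,
                           threshold = 0.08) {
  method <- match.arg(method)
  dplyr::bind_rows(lapply(seq_along(cohort), function(i) {
    ph <- cohort[[i]]
    mk <- if (is.null(masks)) {
      list(apical = ph$apical_mask, coronal = ph$coronal_mask)
    } else {
      masks(ph, i)
    }
    base <- tibble::tibble(
      id = i, method = toupper(method),
      truth_a = ph$truth$a_px, truth_b = ph$truth$b_px, truth_c = ph$truth$c_px,
      truth_i3m = compute_i3m(ph$truth), truth_decision = ph$truth_decision)
    res <- tryCatch({
      pair <- prepare_mask_pair(mk$apical, mk$coronal)
      aligned <- align_vertical(pair$apical, pair$coronal)
      m <- if (method == "tda") measure_tda(aligned) else measure_tda_dl(aligned)
      s <- i3m_result(m, threshold)
      tibble::tibble(a_px = m$a_px, b_px = m$b_px, c_px = m$c_px,
                     i3m = s$i3m, decision = s$decision, error = NA_character_)
    }, i3m_error = function(e) {
      tibble::tibble(a_px = NA_real_, b_px = NA_real_, c_px = NA_real_,
                     i3m = NA_real_, decision = NA_character_,
                     error = class(e)[1])
    })
    dplyr::bind_cols(base, res)
  }))
}

#' Write a phantom dataset through the real I/O path
#'
#' One PNG, one labelme-dialect JSON and one shared truth CSV per cohort, so
#' phantom data can exercise [read_labelme()] and the measurement CLI.
#'
#' @param cohort List of `phantom_tooth` objects.
#' @param dir Output directory (created if needed).
#' @return Tibble of written truth rows, invisibly.
#' @export
write_phantom_dataset <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- cohort_truth(cohort)
  truth$source_id <- sprintf("phantom_%03d", truth$id)
  for (i in seq_along(cohort)) {
    ph <- cohort[[i]]
    ann <- tooth_annotation(ph$image, ph$apical_polygon, ph$coronal_polygon,
                            source_id = truth$source_id[i],
                            expert_i3m = compute_i3m(ph$truth),
                            expert_decision = ph$truth_decision)
    write_labelme(ann, file.path(dir, paste0(truth$source_id[i], ".json")))
  }
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  invisible(truth)
}

# Light mask cleanup applied before measurement: drop speckle components
# that are tiny relative to the largest one, but keep substantial fragments
# (segmentation noise can sever a thin wall tip; discarding it would lose
# the wall). Holes are left alone: canals must stay open.
clean_mask <- function(mask, min_px = 12L) {
  if (!any(mask)) return(mask)
  lab <- as.integer(EBImage::bwlabel(t(mask)))
  tab <- tabulate(lab)
  keep <- which(tab >= min_px)
  t(matrix(lab %in% keep, ncol(mask), nrow(mask)))
}
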