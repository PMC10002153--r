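# Radii-partition measurement engine (TDA).
#
# Pipeline: vertical alignment -> row-scan canal midlines (the lines
# equidistant to the structures flanking each open canal) -> polar first-hit
# partition of each instance boundary into a canal-facing (pulp-dentine) and
# an outward-facing (tooth-environment) part -> apex extremities at the most
# apical transition between the two parts -> a, b as extremity distances and
# c as the vertical extent of the aligned union.

nb_shift <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  ri <- max(1L, 1L - di):min(H, H - di)
  cj <- max(1L, 1L - dj):min(W, W - dj)
  out[ri, cj] <- m[ri + di, cj + dj]
  out
}

boundary8 <- function(m) {
  inner <- nb_shift(m, -1L, 0L) & nb_shift(m, 1L, 0L) &
    nb_shift(m, 0L, -1L) & nb_shift(m, 0L, 1L) &
    nb_shift(m, -1L, -1L) & nb_shift(m, -1L, 1L) &
    nb_shift(m, 1L, -1L) & nb_shift(m, 1L, 1L)
  m & !inner
}

# 4-connected boundary: the wall surface proper. The 8-connected variant is
# two pixels thick across diagonal edges, and the shadowed second layer
# would be misread as outward-facing by the ray partition.
boundary4 <- function(m) {
  inner <- nb_shift(m, -1L, 0L) & nb_shift(m, 1L, 0L) &
    nb_shift(m, 0L, -1L) & nb_shift(m, 0L, 1L)
  m & !inner
}

dilate8 <- function(m) {
  m | nb_shift(m, -1L, 0L) | nb_shift(m, 1L, 0L) |
    nb_shift(m, 0L, -1L) | nb_shift(m, 0L, 1L) |
    nb_shift(m, -1L, -1L) | nb_shift(m, -1L, 1L) |
    nb_shift(m, 1L, -1L) | nb_shift(m, 1L, 1L)
}

# Background gaps per row: for each image row, maximal runs of background
# flanked on both sides by foreground, with the flanking pixels and the
# instance (apical/coronal) each flank belongs to.
row_gaps <- function(apical, coronal) {
  union <- apical | coronal
  rows_with <- which(rowSums(union) > 0L)
  out <- vector("list", length(rows_with))
  for (k in seq_along(rows_with)) {
    r <- rows_with[k]
    cols <- which(union[r, ])
    if (length(cols) < 2L) next
    d <- diff(cols)
    gi <- which(d > 1L)
    if (!length(gi)) next
    left <- cols[gi]; right <- cols[gi + 1L]
    out[[k]] <- data.frame(
      row = r, mid = (left + right) / 2, left_col = left, right_col = right,
      left_instance = ifelse(apical[cbind(r, left)], "apical", "coronal"),
      right_instance = ifelse(apical[cbind(r, right)], "apical", "coronal"))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Drop end rows whose midpoint is a lateral outlier against the adjacent
# polyline trend: at the canal mouth (and occasionally the terminal row)
# the flanking pixel is a wall corner, not the canal wall, and the gap
# midpoint jumps sideways there.
trim_polyline_ends <- function(df, jump = 1, max_trim = 6L) {
  med_w <- stats::median(df$right_col - df$left_col)
  for (k in seq_len(max_trim)) {
    n <- nrow(df)
    if (n < 6L) break
    w1 <- df$right_col[1] - df$left_col[1]
    if (w1 > 1.5 * med_w || w1 < 0.5 * med_w ||
        abs(df$mid[1] - stats::median(df$mid[2:6])) > jump) {
      df <- df[-1, , drop = FALSE]
    } else break
  }
  for (k in seq_len(max_trim)) {
    n <- nrow(df)
    if (n < 6L) break
    if (abs(df$mid[n] - stats::median(df$mid[(n - 5):(n - 1)])) > jump) {
      df <- df[-n, , drop = FALSE]
    } else break
  }
  df
}

new_canal_midline <- function(df) {
  df <- trim_polyline_ends(df)
  pts <- cbind(row = df$row, col = df$mid)
  structure(list(points = pts,
                 apex_middle = point_rc(pts[nrow(pts), 1], pts[nrow(pts), 2]),
                 gaps = df),
            class = "canal_midline")
}

#' Detect root-canal midlines
#'
#' Scans the aligned masks row by row; every background gap flanked left and
#' right by tooth pixels contributes its midpoint, and midpoints are linked
#' across rows into per-canal polylines by nearest-column linkage. A polyline
#' is a root canal when its gap separates the two instances (one flank
#' apical, one coronal, in the majority of rows) and it reaches the apical
#' mask's lowest rows; its terminal point is the middle of the apex. When
#' more than two canal polylines survive, the two with the most apical
#' terminal rows are kept.
#'
#' @param aligned An [align_vertical()] result.
#' @param link_tol Maximum column jump linked between consecutive rows (px).
#' @param reach_tol How close (rows) to the apical mask's lowest row a
#'   polyline must end to count as an open apex.
#' @param min_len Minimum polyline length in rows.
#' @return List of `canal_midline` objects ordered left to right, each with
#'   `points` (rows non-decreasing) and `apex_middle`.
#' @export
canal_midlines <- function(aligned, link_tol = 5, reach_tol = 8, min_len = 5) {
  stopifnot(inherits(aligned, "aligned_tooth_masks"))
  if (!any(aligned$apical)) abort_empty_mask("apical mask")
  gaps <- row_gaps(aligned$apical, aligned$coronal)
  if (is.null(gaps) || nrow(gaps) == 0L) {
    abort_closed_apex("no background gap enclosed by the segmentation")
  }
  polylines <- merge_fragments(link_gap_midpoints(gaps, link_tol), link_tol)
  apical_bottom <- max(mask_pixels(aligned$apical)[, 1])
  is_canal <- vapply(polylines, function(df) {
    nrow(df) >= min_len &&
      mean(df$left_instance != df$right_instance) >= 0.5 &&
      max(df$row) >= apical_bottom - reach_tol
  }, logical(1))
  canals <- polylines[is_canal]
  if (!length(canals)) {
    abort_closed_apex("no open canal reaches the apical extent of the segmentation")
  }
  if (length(canals) > 2L) {
    # keep the two most apical polylines whose terminal columns are well
    # separated (a speckle-split gap yields several polylines in one canal)
    term <- vapply(canals, function(df) max(df$row), numeric(1))
    len <- vapply(canals, nrow, integer(1))
    canals <- canals[order(-term, -len)]
    kept <- canals[1]
    for (cand in canals[-1]) {
      cols <- vapply(kept, function(df) df$mid[nrow(df)], numeric(1))
      if (all(abs(cand$mid[nrow(cand)] - cols) > 6)) kept <- c(kept, list(cand))
      if (length(kept) == 2L) break
    }
    canals <- kept
  }
  ord <- order(vapply(canals, function(df) df$mid[nrow(df)], numeric(1)))
  walls <- mask_pixels(aligned$apical | aligned$coronal)
  lapply(canals[ord], function(df) refine_equidistant(new_canal_midline(df), walls))
}

# The row-gap midpoint equalizes the horizontal in-row distances; near wall
# tips the Euclidean nearest wall can sit in an adjacent row and pull one
# side closer. A couple of Newton steps on the distance difference makes
# every point equidistant to its left and right wall in the Euclidean
# sense, which is the defining property of the canal centerline.
refine_equidistant <- function(ml, walls, iters = 3L) {
  pts <- ml$points
  for (i in seq_len(nrow(pts))) {
    r <- pts[i, 1]
    nearby <- abs(walls[, 1] - r) <= 12
    w <- walls[nearby, , drop = FALSE]
    if (nrow(w) < 2L) next
    x <- pts[i, 2]
    lo <- ml$gaps$left_col[i] + 0.5
    hi <- ml$gaps$right_col[i] - 0.5
    for (k in seq_len(iters)) {
      d <- sqrt((w[, 1] - r)^2 + (w[, 2] - x)^2)
      left <- w[, 2] < x
      if (!any(left) || all(left)) break
      x <- min(max(x + (min(d[!left]) - min(d[left])) / 2, lo), hi)
    }
    pts[i, 2] <- x
  }
  ml$points <- pts
  ml$apex_middle <- point_rc(pts[nrow(pts), 1], pts[nrow(pts), 2])
  ml
}

link_gap_midpoints <- function(gaps, link_tol, max_hiatus = 3L) {
  gaps <- gaps[order(gaps$row, gaps$mid), ]
  open <- list()   # each: list(df, last_row, last_mid)
  done <- list()
  for (r in unique(gaps$row)) {
    g <- gaps[gaps$row == r, , drop = FALSE]
    used <- rep(FALSE, nrow(g))
    still <- vapply(open, function(p) r - p$last_row <= max_hiatus, logical(1))
    done <- c(done, lapply(open[!still], `[[`, "df"))
    open <- open[still]
    if (length(open)) {
      # nearest-column assignment, one midpoint per polyline
      for (pi in order(vapply(open, function(p) p$last_row, numeric(1)))) {
        dcol <- abs(g$mid - open[[pi]]$last_mid)
        dcol[used] <- Inf
        j <- which.min(dcol)
        if (length(j) && is.finite(dcol[j]) && dcol[j] <= link_tol) {
          open[[pi]]$df <- rbind(open[[pi]]$df, g[j, ])
          open[[pi]]$last_row <- r
          open[[pi]]$last_mid <- g$mid[j]
          used[j] <- TRUE
        }
      }
    }
    for (j in which(!used)) {
      open[[length(open) + 1L]] <- list(df = g[j, , drop = FALSE],
                                        last_row = r, last_mid = g$mid[j])
    }
  }
  c(done, lapply(open, `[[`, "df"))
}

# Re-join polyline fragments split by a blocked stretch of rows (noise
# pixels bridging a canal interrupt the row gaps for several rows; the
# canal continues below with an aligned midpoint).
merge_fragments <- function(polys, link_tol, max_break = 12L) {
  repeat {
    merged <- FALSE
    n <- length(polys)
    if (n < 2L) return(polys)
    last_row <- vapply(polys, function(df) max(df$row), numeric(1))
    first_row <- vapply(polys, function(df) min(df$row), numeric(1))
    last_mid <- vapply(polys, function(df) df$mid[nrow(df)], numeric(1))
    first_mid <- vapply(polys, function(df) df$mid[1], numeric(1))
    for (i in seq_len(n)) {
      j <- which(first_row > last_row[i] & first_row <= last_row[i] + max_break &
                   abs(first_mid - last_mid[i]) <= link_tol)
      if (length(j)) {
        j <- j[which.min(abs(first_mid[j] - last_mid[i]))]
        polys[[i]] <- rbind(polys[[i]], polys[[j]])
        polys <- polys[-j]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(polys)
  }
}

# First foreground pixel hit along rays cast from each origin point at
# `angle_step`-degree steps over 360 degrees. Returns linear indices into
# `occluder` of all first-hit pixels.
polar_first_hits <- function(points, occluder, angle_step = 1,
                             max_radius = NULL, radial_step = 0.5) {
  H <- nrow(occluder); W <- ncol(occluder)
  if (is.null(max_radius)) max_radius <- sqrt(H^2 + W^2)
  th <- seq(0, 360 - angle_step, by = angle_step) * pi / 180
  dr <- cos(th); dc <- sin(th)
  radii <- seq(radial_step, max_radius, by = radial_step)
  hit <- logical(H * W)
  for (i in seq_len(nrow(points))) {
    rr <- round(points[i, 1] + outer(radii, dr))
    cc <- round(points[i, 2] + outer(radii, dc))
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    lin <- (cc - 1L) * H + rr
    occ <- matrix(FALSE, length(radii), length(th))
    occ[ok] <- occluder[lin[ok]]
    has <- colSums(occ) > 0L
    if (!any(has)) next
    first <- max.col(t(occ[, has, drop = FALSE]), ties.method = "first")
    hit[lin[cbind(first, which(has))]] <- TRUE
  }
  hit
}

midline_col_at <- function(midline, rows) {
  pts <- midline$points
  if (nrow(pts) == 1L) return(rep(pts[1, 2], length(rows)))
  stats::approx(pts[, 1], pts[, 2], xout = rows, rule = 2, ties = mean)$y
}

#' Partition an instance boundary by simulated radii
#'
#' Rays are cast from every midline point at `angle_step`-degree steps over
#' 360 degrees; rays stop at the first pixel of `occluder` (by default the
#' mask itself; pass the union of both instances so one instance can shadow
#' the other). Boundary pixels of `mask` that are first-hit by some ray form
#' the canal-facing (pulp-dentine) boundary; boundary pixels never first-hit
#' form the outward-facing (tooth-environment) boundary. On each side of the
#' midline, the wall extremity is the most apical (largest-row) canal-facing
#' pixel 8-adjacent to an outward-facing pixel.
#'
#' @param mask Logical instance mask.
#' @param midline A `canal_midline`.
#' @param occluder Logical mask at which rays terminate (default `mask`).
#' @param angle_step Ray angular resolution in degrees.
#' @param max_radius Ray reach in pixels (default: whole grid).
#' @return Object of class `wall_partition`: list with `left` and `right`,
#'   each holding `inner` / `outer` pixel coordinate matrices and the
#'   `extremity` point (or `NULL` when the side has no transition).
#' @export
radii_partition <- function(mask, midline, occluder = mask, angle_step = 1,
                            max_radius = NULL) {
  assert_mask(mask)
  stopifnot(inherits(midline, "canal_midline"))
  if (!any(mask)) abort_empty_mask()
  hit <- polar_first_hits(midline$points, occluder, angle_step = angle_step,
                          max_radius = max_radius)
  partition_from_hits(mask, hit, midline)
}

partition_from_hits <- function(mask, hit, midline) {
  bnd <- boundary4(mask)
  inner <- bnd & matrix(hit, nrow(mask), ncol(mask))
  if (!any(inner)) {
    abort_degenerate_geometry("radii partition yields an empty canal-facing boundary")
  }
  outer_b <- bnd & !inner
  if (!any(outer_b)) {
    abort_degenerate_geometry("radii partition yields an empty outward boundary")
  }
  transition <- inner & dilate8(outer_b)
  px_side <- function(m) {
    px <- mask_pixels(m)
    if (nrow(px) == 0L) return(list(left = px, right = px))
    mid <- midline_col_at(midline, px[, 1])
    list(left = px[px[, 2] < mid, , drop = FALSE],
         right = px[px[, 2] >= mid, , drop = FALSE])
    }
  inner_s <- px_side(inner); outer_s <- px_side(outer_b); trans_s <- px_side(transition)
  side <- function(s) {
    tr <- trans_s[[s]]
    extremity <- if (nrow(tr) > 0L) {
      best <- tr[tr[, 1] == max(tr[, 1]), , drop = FALSE]
      # among ties take the pixel nearest the midline
      mid <- midline_col_at(midline, best[1, 1])
      best <- best[which.min(abs(best[, 2] - mid)), ]
      point_rc(best[1], best[2])
    } else NULL
    list(inner = inner_s[[s]], outer = outer_s[[s]], extremity = extremity,
         transitions = tr)
  }
  structure(list(left = side("left"), right = side("right")),
            class = "wall_partition")
}

point_distance <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))

vertical_extent <- function(aligned) {
  rows <- mask_pixels(aligned$apical | aligned$coronal)[, 1]
  max(rows) - min(rows)
}

new_measurement <- function(a_px, b_px, c_px, method, landmarks, detail = list()) {
  if (!is.finite(c_px) || c_px <= 0) abort_invalid_measurement("tooth height c must be positive")
  if (a_px < 0 || b_px < 0) abort_invalid_measurement("apex widths must be non-negative")
  structure(list(a_px = a_px, b_px = b_px, c_px = c_px, method = method,
                 landmarks = landmarks, detail = detail),
            class = "i3m_measurement")
}

#' @export
print.i3m_measurement <- function(x, ...) {
  cat(sprintf("<i3m_measurement %s> a = %.2f px, b = %.2f px, c = %.2f px, (a+b)/c = %.4f\n",
              x$method, x$a_px, x$b_px, x$c_px, (x$a_px + x$b_px) / x$c_px))
  invisible(x)
}

# Wall extremity flanking this canal's own apex: the terminal point of the
# canal-facing (inner) boundary on one side of the midline. Both instances
# contribute candidates (each apex is flanked by one coronal wall and one
# apical branch); candidates are kept local to the wall pixel flanking the
# canal's terminal background gap, so a ragged pixel of the *other* apex,
# visible below the wall tips, cannot capture the landmark. The landmark is
# localized sub-pixel by regressing the inner-edge column on the row over
# the last rows of the wall and extrapolating to the terminal row, which
# averages out raster quantization of the converging wall edge.
apex_extremity <- function(parts, side, flank, locality = 6, fit_rows = 10) {
  inner <- do.call(rbind, lapply(parts, function(p) p[[side]]$inner))
  rT <- flank[1]
  win <- inner[inner[, 1] >= rT - fit_rows & inner[, 1] <= rT &
                 abs(inner[, 2] - flank[2]) <= locality, , drop = FALSE]
  if (is.null(win) || nrow(win) == 0L) return(point_rc(rT, flank[2]))
  # per-row canal-side edge sample (the innermost wall pixel of this side)
  agg <- if (side == "left") {
    stats::aggregate(win[, 2], list(row = win[, 1]), max)
  } else {
    stats::aggregate(win[, 2], list(row = win[, 1]), min)
  }
  # the continuous wall edge lies half a pixel beyond the innermost sampled
  # pixel center, toward the canal
  shift <- if (side == "left") 0.5 else -0.5
  if (nrow(agg) < 3L) return(point_rc(rT, mean(agg$x) + shift))
  fit <- stats::lm.fit(cbind(1, agg$row - rT), agg$x)
  point_rc(rT, fit$coefficients[1] + shift)
}

#' Measure a, b, c with the radii-partition engine (TDA)
#'
#' Aligns nothing further (expects [align_vertical()] output), detects the
#' two root-canal midlines, partitions both instance boundaries by radii cast
#' from each midline, and reads each apex width as the Euclidean distance
#' between the two wall extremities flanking that canal. `a` is the mesial
#' (left) apex width, `b` the distal (right); `c` is the difference between
#' the largest and smallest occupied row of the aligned mask union.
#'
#' @param aligned An [align_vertical()] result with two detectable canals.
#' @param angle_step Ray angular resolution in degrees.
#' @param max_radius Ray reach in pixels; the default covers the apex region
#'   around every midline point while keeping the scan affordable.
#' @return An `i3m_measurement` with `method = "TDA"` and all landmarks.
#' @export
measure_tda <- function(aligned, angle_step = 1, max_radius = 60) {
  stopifnot(inherits(aligned, "aligned_tooth_masks"))
  midlines <- canal_midlines(aligned)
  if (length(midlines) < 2L) {
    abort_closed_apex("fewer than two open apices were detected")
  }
  occ <- aligned$apical | aligned$coronal
  measure_one <- function(ml) {
    hit <- polar_first_hits(ml$points, occ, angle_step = angle_step,
                            max_radius = max_radius)
    parts <- list(apical = partition_from_hits(aligned$apical, hit, ml),
                  coronal = partition_from_hits(aligned$coronal, hit, ml))
    last_gap <- ml$gaps[nrow(ml$gaps), ]
    list(left = apex_extremity(parts, "left",
                               c(last_gap$row, last_gap$left_col)),
         right = apex_extremity(parts, "right",
                                c(last_gap$row, last_gap$right_col)),
         parts = parts)
  }
  mes <- measure_one(midlines[[1]])
  dis <- measure_one(midlines[[2]])
  px <- mask_pixels(occ)
  top_row <- min(px[, 1]); bot_row <- max(px[, 1])
  landmarks <- list(
    mesial_left = mes$left, mesial_right = mes$right,
    distal_left = dis$left, distal_right = dis$right,
    mesial_apex_middle = midlines[[1]]$apex_middle,
    distal_apex_middle = midlines[[2]]$apex_middle,
    top = point_rc(top_row, mean(px[px[, 1] == top_row, 2])),
    bottom = point_rc(bot_row, mean(px[px[, 1] == bot_row, 2])))
  new_measurement(
    a_px = point_distance(mes$left, mes$right),
    b_px = point_distance(dis$left, dis$right),
    c_px = bot_row - top_row,
    method = "TDA", landmarks = landmarks,
    detail = list(midlines = midlines,
                  partitions = list(mesial = mes$parts, distal = dis$parts)))
}
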