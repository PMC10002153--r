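# Skeleton-based measurement engine (TDA-DL).
#
# The apical instance is band-shaped (an inverted U around the open apices);
# its medial-axis skeleton is extracted by morphological thinning, pruned of
# short spurs, and its two most apical tips (one per side of the band) are
# the apical limit points. The coronal limit points are the lowest coronal
# pixels on each side of the vertical line joining the barycenters. a and b
# are the left and right coronal-to-apical limit-point distances. The
# default skeleton backend is deterministic thinning; any backend returning
# five ordered control points can be plugged in instead (e.g. a learned
# skeleton-inference model).

neighbor_count8 <- function(m) {
  nb_shift(m, -1L, 0L) + nb_shift(m, 1L, 0L) +
    nb_shift(m, 0L, -1L) + nb_shift(m, 0L, 1L) +
    nb_shift(m, -1L, -1L) + nb_shift(m, -1L, 1L) +
    nb_shift(m, 1L, -1L) + nb_shift(m, 1L, 1L)
}

# Zhang-Suen thinning to a 1-px-wide 8-connected skeleton.
thin_mask <- function(m) {
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      P2 <- nb_shift(m, -1L, 0L); P3 <- nb_shift(m, -1L, 1L)
      P4 <- nb_shift(m, 0L, 1L);  P5 <- nb_shift(m, 1L, 1L)
      P6 <- nb_shift(m, 1L, 0L);  P7 <- nb_shift(m, 1L, -1L)
      P8 <- nb_shift(m, 0L, -1L); P9 <- nb_shift(m, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cond <- m & B >= 2 & B <= 6 & A == 1
      cond <- if (phase == 1) {
        cond & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) return(m)
  }
}

skeleton_tips <- function(skel) which(skel & neighbor_count8(skel) == 1L)

# Remove side branches shorter than min_len px (walking tip -> junction).
# Thinned skeletons contain "staircase" pixels whose neighbors are mutually
# adjacent; those are path continuations, not junctions, and the walk must
# not treat them as such (or real endpoints get pruned away).
prune_spurs <- function(skel, min_len = 5L) {
  H <- nrow(skel)
  repeat {
    tips <- which(skel & neighbor_count8(skel) == 1L)
    removed_any <- FALSE
    for (tip in tips) {
      if (!skel[tip]) next
      path <- tip
      cur <- tip
      spur <- FALSE
      repeat {
        r <- (cur - 1L) %% H + 1L; c <- (cur - 1L) %/% H + 1L
        cands <- setdiff(neighbors_of(r, c, skel), path)
        if (length(cands) == 0L) break                      # isolated chain: keep
        if (length(cands) > 1L) {
          pr <- (cands - 1L) %% H + 1L; pc <- (cands - 1L) %/% H + 1L
          mutually_adjacent <- max(dist(cbind(pr, pc), method = "maximum")) <= 1
          if (!mutually_adjacent) { spur <- TRUE; break }   # true junction
        }
        cur <- cands[1]
        path <- c(path, cur)
        if (length(path) > min_len) break                   # long enough: keep
      }
      if (spur && length(path) <= min_len) {
        skel[path] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) return(skel)
  }
}

neighbors_of <- function(r, c, m) {
  H <- nrow(m); W <- ncol(m)
  rr <- r + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  cc <- c + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  idx <- (cc[ok] - 1L) * H + rr[ok]
  idx[m[idx]]
}

skeleton_path <- function(skel, from, to) {
  idx <- which(skel)
  px <- cbind((idx - 1L) %% nrow(skel) + 1L, (idx - 1L) %/% nrow(skel) + 1L)
  id <- match(c(from, to), idx)
  edges <- NULL
  H <- nrow(skel)
  for (d in list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(-1L, 1L))) {
    nb <- idx + d[1] + d[2] * H
    rr <- px[, 1] + d[1]; cc <- px[, 2] + d[2]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= ncol(skel)
    ok[ok] <- skel[nb[ok]]
    if (!any(ok)) next
    j <- match(nb[ok], idx)
    edges <- rbind(edges, cbind(which(ok), j, rep(sqrt(d[1]^2 + d[2]^2), length(j))))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], weight = edges[, 3]),
    directed = FALSE, vertices = data.frame(name = seq_along(idx)))
  sp <- suppressWarnings(igraph::shortest_paths(g, from = as.character(id[1]),
                                                to = as.character(id[2]),
                                                weights = igraph::E(g)$weight))
  v <- sp$vpath[[1]]
  if (length(v) == 0L) {
    abort_degenerate_geometry("skeleton endpoints are not connected")
  }
  px[as.integer(igraph::as_ids(v)), , drop = FALSE]
}

#' Fit the inverted-U skeleton of the apical mask
#'
#' Thins the apical band to its medial-axis skeleton (Zhang-Suen), prunes
#' spurs shorter than `spur_min_px`, and orders the result into a single
#' path. The path endpoints are the two most apical skeleton tips, one on
#' each side of the band's column median; three interior control points are
#' placed at arc-length quartiles (reported for overlays; they do not enter
#' the measurements).
#'
#' @param apical Logical mask of the apical instance (band-like).
#' @param spur_min_px Minimum branch length kept during pruning.
#' @return Object of class `ushape_skeleton`: `polyline` (ordered
#'   `row, col` matrix from the left end to the right end), `control_points`
#'   (5 x 2 matrix: left end, three interior points, right end), `tips`.
#' @export
apical_skeleton <- function(apical, spur_min_px = 5L) {
  assert_mask(apical, "apical")
  if (!any(apical)) abort_empty_mask("apical mask")
  skel <- thin_mask(apical)
  tips <- skeleton_tips(skel)
  if (length(tips) > 2L) {
    # prune only to *select* endpoints; the path is traced on the full
    # (connected) skeleton
    kept <- intersect(skeleton_tips(prune_spurs(skel, spur_min_px)), tips)
    if (length(kept) >= 2L) tips <- kept
  }
  if (length(tips) < 2L) {
    abort_degenerate_geometry("apical mask has no band-like skeleton (fewer than two tips)")
  }
  H <- nrow(apical)
  tip_px <- cbind(row = (tips - 1L) %% H + 1L, col = (tips - 1L) %/% H + 1L)
  med <- stats::median(mask_pixels(apical)[, 2])
  pick <- function(side_idx) {
    if (!length(side_idx)) {
      abort_degenerate_geometry("no skeleton tip on one side of the apical band")
    }
    cand <- tip_px[side_idx, , drop = FALSE]
    cand <- cand[cand[, 1] == max(cand[, 1]), , drop = FALSE]
    cand[which.max(abs(cand[, 2] - med)), ]
  }
  left_end <- pick(which(tip_px[, 2] < med))
  right_end <- pick(which(tip_px[, 2] >= med))
  path <- skeleton_path(skel, (left_end[2] - 1L) * H + left_end[1],
                        (right_end[2] - 1L) * H + right_end[1])
  arc <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  q <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    which.min(abs(arc - f * arc[length(arc)]))
  }, integer(1))
  control <- path[q, , drop = FALSE]
  colnames(path) <- colnames(control) <- c("row", "col")
  # thinning retracts a band's medial axis by about half the band width;
  # move each ending point to the centroid of the band's local end cap so
  # the reported ending points reach the band ends (the apices)
  control[1, ] <- band_end_point(control[1, ], apical)
  control[5, ] <- band_end_point(control[5, ], apical)
  structure(list(polyline = path, control_points = control,
                 tips = tip_px), class = "ushape_skeleton")
}

# Centroid of the most apical mask pixels within `radius` of a skeleton
# tip: the center of the band's end cap. Anchoring the ending point to the
# mask itself (rather than extrapolating the thinned axis) keeps it
# mirror-symmetric and insensitive to thinning parity.
band_end_point <- function(tip, mask, radius = 8) {
  px <- mask_pixels(mask)
  d2 <- (px[, 1] - tip[1])^2 + (px[, 2] - tip[2])^2
  near <- px[d2 <= radius^2, , drop = FALSE]
  if (nrow(near) == 0L) return(tip)
  cap <- near[near[, 1] >= max(near[, 1]) - 1, , drop = FALSE]
  c(mean(cap[, 1]), mean(cap[, 2]))
}

as_ushape <- function(x) {
  if (inherits(x, "ushape_skeleton")) return(x)
  x <- as.matrix(x)
  if (nrow(x) != 5L || ncol(x) != 2L) {
    abort_degenerate_geometry("a skeleton backend must return 5 (row, col) control points")
  }
  colnames(x) <- c("row", "col")
  if (x[1, "col"] > x[5, "col"]) x <- x[5:1, , drop = FALSE]
  structure(list(polyline = x, control_points = x, tips = x[c(1, 5), , drop = FALSE]),
            class = "ushape_skeleton")
}

#' Lowest coronal points on each side of the vertical axis
#'
#' On each side of `axis_col`, returns the coronal pixel with the largest
#' row; ties are broken toward the axis (smallest `|col - axis_col|`).
#'
#' @param coronal Logical coronal mask with pixels on both sides of the axis.
#' @param axis_col Continuous column of the vertical line joining the
#'   barycenters.
#' @return List with points `left` and `right`.
#' @export
coronal_limit_points <- function(coronal, axis_col) {
  assert_mask(coronal, "coronal")
  px <- mask_pixels(coronal)
  if (nrow(px) == 0L) abort_empty_mask("coronal mask")
  pick <- function(sel, side) {
    p <- px[sel, , drop = FALSE]
    if (nrow(p) == 0L) {
      abort_degenerate_geometry(sprintf("coronal mask has no pixel %s of the axis", side))
    }
    p <- p[p[, 1] == max(p[, 1]), , drop = FALSE]
    p <- p[which.min(abs(p[, 2] - axis_col)), ]
    point_rc(p[1], p[2])
  }
  list(left = pick(px[, 2] < axis_col, "left"),
       right = pick(px[, 2] > axis_col, "right"))
}

#' Measure a, b, c with the skeleton engine (TDA-DL)
#'
#' The vertical line joining the (aligned, hence column-identical)
#' barycenters splits the tooth; `a` is the distance between the left
#' coronal limit point and the left endpoint of the apical inverted-U
#' skeleton, `b` the same on the right. `c` is identical to the TDA
#' definition (vertical extent of the aligned union).
#'
#' @param aligned An [align_vertical()] result.
#' @param skeleton_backend `NULL` for the built-in thinning backend
#'   ([apical_skeleton()]), or a function taking the apical mask and
#'   returning either a `ushape_skeleton` or a 5 x 2 matrix of ordered
#'   `(row, col)` control points.
#' @param spur_min_px Passed to the built-in backend.
#' @return An `i3m_measurement` with `method = "TDA_DL"`.
#' @export
measure_tda_dl <- function(aligned, skeleton_backend = NULL, spur_min_px = 5L) {
  stopifnot(inherits(aligned, "aligned_tooth_masks"))
  axis_col <- (aligned$apical_barycenter[["col"]] + aligned$coronal_barycenter[["col"]]) / 2
  limits <- coronal_limit_points(aligned$coronal, axis_col)
  skel <- if (is.null(skeleton_backend)) {
    apical_skeleton(aligned$apical, spur_min_px = spur_min_px)
  } else {
    as_ushape(skeleton_backend(aligned$apical))
  }
  ends <- skel$control_points[c(1, nrow(skel$control_points)), , drop = FALSE]
  left_end <- point_rc(ends[which.min(ends[, "col"]), "row"],
                       min(ends[, "col"]))
  right_end <- point_rc(ends[which.max(ends[, "col"]), "row"],
                        max(ends[, "col"]))
  px <- mask_pixels(aligned$apical | aligned$coronal)
  top_row <- min(px[, 1]); bot_row <- max(px[, 1])
  landmarks <- list(
    coronal_limit_left = limits$left, coronal_limit_right = limits$right,
    apical_end_left = left_end, apical_end_right = right_end,
    top = point_rc(top_row, mean(px[px[, 1] == top_row, 2])),
    bottom = point_rc(bot_row, mean(px[px[, 1] == bot_row, 2])))
  new_measurement(
    a_px = point_distance(limits$left, left_end),
    b_px = point_distance(limits$right, right_end),
    c_px = bot_row - top_row,
    method = "TDA_DL", landmarks = landmarks,
    detail = list(skeleton = skel, axis_col = axis_col))
}
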