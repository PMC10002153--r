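# Overlay rendering and ggplot2 methods. Overlays serve the explicability
# goal: the user can visually validate the masks, the canal midlines or
# skeleton, and the a/b/c segments behind every reported score.

confusion_colors <- c(TP = "#2e9e4f", FP = "#f59420", FN = "#d62728",
                      TN = "#00000000")

blend_px <- function(rgb, px, col, alpha = 0.45) {
  rgbv <- grDevices::col2rgb(col)[, 1] / 255
  for (k in 1:3) {
    ch <- rgb[, , k]
    ch[px] <- (1 - alpha) * ch[px] + alpha * rgbv[k]
    rgb[, , k] <- ch
  }
  rgb
}

draw_segment <- function(rgb, p, q, col) {
  n <- max(2L, ceiling(2 * point_distance(p, q)))
  rr <- round(seq(p[[1]], q[[1]], length.out = n))
  cc <- round(seq(p[[2]], q[[2]], length.out = n))
  ok <- rr >= 1 & rr <= dim(rgb)[1] & cc >= 1 & cc <= dim(rgb)[2]
  blend_px(rgb, cbind(rr[ok], cc[ok]), col, alpha = 1)
}

#' RGB overlay of masks, landmarks and the a/b/c segments
#'
#' @param image Grayscale background matrix.
#' @param apical,coronal Instance masks.
#' @param measurement An `i3m_measurement` (landmarks and midlines/skeleton
#'   are drawn when present).
#' @return `height x width x 3` array in `[0, 1]`.
#' @export
overlay_rgb <- function(image, apical, coronal, measurement = NULL) {
  img <- pmin(pmax(image, 0), 1)
  rgb <- array(rep(img, 3), c(dim(img), 3))
  rgb <- blend_px(rgb, mask_pixels(coronal), "#4c72b0")
  rgb <- blend_px(rgb, mask_pixels(apical), "#dd8452")
  if (!is.null(measurement)) {
    lm <- measurement$landmarks
    if (measurement$method == "TDA") {
      for (ml in measurement$detail$midlines) {
        rgb <- blend_px(rgb, round(ml$points), "#17becf", alpha = 1)
      }
      rgb <- draw_segment(rgb, lm$mesial_left, lm$mesial_right, "#e8e337")
      rgb <- draw_segment(rgb, lm$distal_left, lm$distal_right, "#e8e337")
    } else if (measurement$method == "TDA_DL") {
      skel <- measurement$detail$skeleton
      if (!is.null(skel)) rgb <- blend_px(rgb, round(skel$polyline), "#17becf", alpha = 1)
      rgb <- draw_segment(rgb, lm$coronal_limit_left, lm$apical_end_left, "#e8e337")
      rgb <- draw_segment(rgb, lm$coronal_limit_right, lm$apical_end_right, "#e8e337")
    }
    rgb <- draw_segment(rgb, lm$top, lm$bottom, "#b3e837")
  }
  rgb
}

mask_tile_df <- function(mask, label) {
  px <- mask_pixels(mask)
  if (nrow(px) == 0) return(NULL)
  data.frame(row = px[, 1], col = px[, 2], what = label)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an I3M measurement as an annotated overlay
#'
#' @param object An `i3m_result`.
#' @param apical,coronal Masks to draw behind the landmarks (optional).
#' @param ... Unused.
#' @export
autoplot.i3m_result <- function(object, apical = NULL, coronal = NULL, ...) {
  m <- object$measurement
  lm <- m$landmarks
  pts <- do.call(rbind, lapply(names(lm), function(nm) {
    data.frame(row = lm[[nm]][[1]], col = lm[[nm]][[2]], landmark = nm)
  }))
  df <- rbind(mask_tile_df(coronal, "coronal"), mask_tile_df(apical, "apical"))
  p <- ggplot2::ggplot()
  if (!is.null(df)) {
    p <- p + ggplot2::geom_tile(
      data = df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$what),
      alpha = 0.5) +
      ggplot2::scale_fill_manual(values = c(coronal = "#4c72b0", apical = "#dd8452"))
  }
  p + ggplot2::geom_point(data = pts,
                          ggplot2::aes(x = .data$col, y = .data$row),
                          color = "#e8e337", size = 1.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s: a=%.1f b=%.1f c=%.1f px, I3M=%.4f (%s)",
                                  m$method, m$a_px, m$b_px, m$c_px,
                                  object$i3m, object$decision),
                  x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Plot a phantom with its ground-truth landmarks
#'
#' @param object A `phantom_tooth`.
#' @param ... Unused.
#' @export
autoplot.phantom_tooth <- function(object, ...) {
  df <- rbind(mask_tile_df(object$coronal_mask, "coronal"),
              mask_tile_df(object$apical_mask, "apical"))
  lm <- object$landmarks
  pts <- do.call(rbind, lapply(names(lm), function(nm) {
    data.frame(row = lm[[nm]][[1]], col = lm[[nm]][[2]], landmark = nm)
  }))
  ggplot2::ggplot() +
    ggplot2::geom_tile(data = df,
                       ggplot2::aes(x = .data$col, y = .data$row, fill = .data$what),
                       alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(coronal = "#4c72b0", apical = "#dd8452")) +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$col, y = .data$row),
                        color = "black", size = 1.2) +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("phantom: a=%.1f b=%.1f c=%.1f px (%s)",
                                  object$truth$a_px, object$truth$b_px,
                                  object$truth$c_px, object$truth_decision),
                  x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Confusion-map plot of a segmentation evaluation
#'
#' Green true positives, orange false positives, red false negatives.
#'
#' @param eval A `segmentation_eval`.
#' @return A ggplot object.
#' @export
plot_confusion_map <- function(eval) {
  stopifnot(inherits(eval, "segmentation_eval"))
  cm <- eval$confusion_map
  px <- which(cm != "TN", arr.ind = TRUE)
  df <- data.frame(row = px[, 1], col = px[, 2], label = cm[px])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = confusion_colors[c("TP", "FP", "FN")]) +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s IoU = %.3f", eval$region, eval$iou),
                  x = "column", y = "row", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion map as an RGB overlay array
#'
#' @param eval A `segmentation_eval`.
#' @param image Optional grayscale background.
#' @return `height x width x 3` array.
#' @export
confusion_rgb <- function(eval, image = NULL) {
  cm <- eval$confusion_map
  if (is.null(image)) image <- matrix(0, nrow(cm), ncol(cm))
  rgb <- array(rep(pmin(pmax(image, 0), 1), 3), c(dim(cm), 3))
  for (lab in c("TP", "FP", "FN")) {
    px <- which(cm == lab, arr.ind = TRUE)
    if (nrow(px)) rgb <- blend_px(rgb, px, confusion_colors[[lab]], alpha = 0.8)
  }
  rgb
}
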