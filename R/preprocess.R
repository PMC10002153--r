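#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based contrast enhancement for radiograph crops, with bilinear
#' blending between tiles (Zuiderveld's CLAHE, via EBImage). Defaults
#' (clip limit 2, 8x8 tiles) are common radiography settings.
#'
#' @param image Single-channel numeric matrix in `[0, 1]`.
#' @param clip_limit Positive contrast clip limit.
#' @param tiles Integer pair `c(rows, cols)` of tiles.
#' @param bins Number of gray bins used per tile histogram.
#' @return Numeric matrix of the input shape, values in `[0, 1]`.
#' @export
clahe_enhance <- function(image, clip_limit = 2, tiles = c(8, 8), bins = 256) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_image_format("clahe_enhance() expects a single-channel numeric matrix")
  }
  stopifnot(clip_limit > 0, length(tiles) == 2L, all(tiles >= 1))
  if (any(tiles == 1)) {
    # a single contextual region degenerates to plain global histogram
    # equalization of the binned gray levels
    v <- pmin(pmax(image, 0), 1)
    idx <- pmin(floor(v * bins), bins - 1) + 1
    cdf <- cumsum(tabulate(idx, nbins = bins)) / length(v)
    cdf0 <- min(cdf[cdf > 0])
    out <- (cdf[idx] - cdf0) / (1 - cdf0 + 1e-12)
    return(matrix(pmin(pmax(out, 0), 1), nrow(image), ncol(image)))
  }
  # EBImage lays images out x-first, so transpose in and out.
  out <- EBImage::clahe(t(image), nx = as.integer(tiles[2]),
                        ny = as.integer(tiles[1]), bins = bins,
                        limit = clip_limit)
  matrix(pmin(pmax(as.numeric(t(as.matrix(out))), 0), 1), nrow(image), ncol(image))
}

#' Augmentation policy
#'
#' Random rigid augmentation of an annotated crop: a rotation drawn uniformly
#' in `+/- max_rotation_deg` and, when allowed, a horizontal flip with
#' probability 0.5; the image and both masks receive the identical transform.
#'
#' @param max_rotation_deg Non-negative rotation bound (degrees).
#' @param allow_horizontal_flip Allow mirror flips.
#' @param n_variants Number of variants to draw.
#' @param seed Integer seed making the draw reproducible.
#' @export
augmentation_policy <- function(max_rotation_deg = 15, allow_horizontal_flip = TRUE,
                                n_variants = 1L, seed = 1L) {
  stopifnot(max_rotation_deg >= 0, n_variants >= 1)
  structure(list(max_rotation_deg = max_rotation_deg,
                 allow_horizontal_flip = isTRUE(allow_horizontal_flip),
                 n_variants = as.integer(n_variants), seed = as.integer(seed)),
            class = "augmentation_policy")
}

flip_horizontal <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' Augment an annotated tooth crop
#'
#' @param annotation A [tooth_annotation()].
#' @param policy An [augmentation_policy()].
#' @return List of `policy$n_variants` elements, each a list with `image`,
#'   `apical`, `coronal` (masks), and the applied `angle_deg` / `flipped`.
#' @export
augment_pair <- function(annotation, policy = augmentation_policy()) {
  stopifnot(inherits(annotation, "tooth_annotation"),
            inherits(policy, "augmentation_policy"))
  masks <- annotation_masks(annotation)
  withr::with_seed(policy$seed, {
    lapply(seq_len(policy$n_variants), function(k) {
      angle <- stats::runif(1, -policy$max_rotation_deg, policy$max_rotation_deg)
      flip <- policy$allow_horizontal_flip && stats::runif(1) < 0.5
      img <- annotation$image
      api <- masks$apical
      cor <- masks$coronal
      if (flip) {
        img <- flip_horizontal(img)
        api <- flip_horizontal(api)
        cor <- flip_horizontal(cor)
      }
      if (abs(angle) > 1e-12) {
        img <- rotate_image(img, angle)
        api <- rotate_region(api, angle)
        cor <- rotate_region(cor, angle)
      }
      list(image = img, apical = api, coronal = cor,
           angle_deg = angle, flipped = flip)
    })
  })
}
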