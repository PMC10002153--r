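#' Tooth annotations and the labelme JSON dialect
#'
#' A tooth annotation bundles a 256x256 (or any size) grayscale crop with one
#' apical and one coronal polygon. Polygons are `n x 2` numeric matrices with
#' columns `x` (image column) and `y` (image row) in the 1-based pixel-center
#' convention of [pixel-conventions]; labelme files store the same vertices
#' 0-based, and the reader/writer shift between the two.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param apical_polygon,coronal_polygon `n x 2` matrices, columns `(x, y)`.
#' @param source_id Free-text identifier.
#' @param side `"left"`, `"right"` or `"unknown"`.
#' @param expert_i3m,expert_decision Optional expert reference values.
#' @export
tooth_annotation <- function(image, apical_polygon, coronal_polygon,
                             source_id = "tooth", side = "unknown",
                             expert_i3m = NA_real_, expert_decision = NA_character_) {
  apical_polygon <- as_polygon(apical_polygon, "apical polygon")
  coronal_polygon <- as_polygon(coronal_polygon, "coronal polygon")
  stopifnot(is.matrix(image), is.numeric(image))
  side <- match.arg(side, c("left", "right", "unknown"))
  structure(
    list(image = image, apical_polygon = apical_polygon,
         coronal_polygon = coronal_polygon, source_id = source_id, side = side,
         expert_i3m = expert_i3m, expert_decision = expert_decision),
    class = "tooth_annotation")
}

as_polygon <- function(p, what = "polygon") {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L || !is.numeric(p) || anyNA(p)) {
    abort_annotation_schema(sprintf("%s must be a numeric matrix with >= 3 (x, y) vertices", what))
  }
  colnames(p) <- c("x", "y")
  p
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Rasterize a polygon onto a pixel grid
#'
#' A pixel is foreground iff its center lies inside the polygon under the
#' even-odd rule; pixel centers exactly on the boundary count as inside.
#'
#' @param polygon `n x 2` matrix, columns `(x, y)` = (col, row), 1-based
#'   pixel-center coordinates.
#' @param shape `c(height, width)` of the target grid.
#' @return Logical `height x width` mask.
#' @export
rasterize_polygon <- function(polygon, shape) {
  polygon <- as_polygon(polygon)
  stopifnot(length(shape) == 2L, all(shape >= 1))
  if (polygon_area(polygon) <= 0) {
    abort_degenerate_geometry("polygon has zero area")
  }
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  cc <- rep(seq_len(W), each = H)
  rr <- rep(seq_len(H), times = W)
  inside <- pracma::inpolygon(cc, rr, polygon[, "x"], polygon[, "y"],
                              boundary = TRUE)
  matrix(inside, H, W)
}

default_label_aliases <- function() {
  list(apical = c("apical", "apex", "apical_mask"),
       coronal = c("coronal", "crown", "coronal_mask"))
}

match_region <- function(label, aliases) {
  label <- tolower(trimws(label))
  for (region in names(aliases)) {
    if (label %in% tolower(aliases[[region]])) return(region)
  }
  NA_character_
}

#' Read a labelme-dialect annotation
#'
#' Expects a JSON document with `shapes[].label`, `shapes[].points` (0-based
#' `(x, y)` vertices), and either an embedded base64 PNG (`imageData`) or a
#' sibling `imagePath`. Exactly one shape must map to each of the apical and
#' coronal regions (label matching is case-insensitive and configurable).
#' Multichannel payload images are averaged to a single channel.
#'
#' @param path Path to a `.json` file (or a length-1 JSON string).
#' @param label_aliases Named list of accepted labels per region.
#' @return A [tooth_annotation()].
#' @export
read_labelme <- function(path, label_aliases = default_label_aliases()) {
  is_file <- length(path) == 1L && !grepl("[{]", path) && file.exists(path)
  txt <- if (is_file) paste(readLines(path, warn = FALSE), collapse = "\n") else path
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) abort_annotation_schema(
                    paste("document does not parse as JSON:", conditionMessage(e))))
  shapes <- doc$shapes
  if (is.null(shapes)) abort_annotation_schema("document has no 'shapes' entry")
  found <- list()
  for (sh in shapes) {
    region <- match_region(sh$label %||% "", label_aliases)
    if (is.na(region)) next
    if (!identical(sh$shape_type %||% "polygon", "polygon")) {
      abort_annotation_schema(sprintf("shape '%s' is not a polygon", sh$label))
    }
    if (!is.null(found[[region]])) {
      abort_annotation_schema(sprintf("duplicate '%s' shape", region))
    }
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    found[[region]] <- as_polygon(pts + 1, region)  # 0-based file -> 1-based
  }
  for (region in c("apical", "coronal")) {
    if (is.null(found[[region]])) {
      abort_annotation_schema(sprintf("missing '%s' shape", region))
    }
  }
  img <- read_labelme_image(doc, if (is_file) dirname(path) else ".")
  source_id <- doc$imagePath %||% if (is_file) basename(path) else "annotation"
  flags <- doc$flags %||% list()
  tooth_annotation(
    image = img,
    apical_polygon = found$apical, coronal_polygon = found$coronal,
    source_id = sub("\\.[A-Za-z]+$", "", source_id),
    side = (flags$side %||% "unknown"),
    expert_i3m = suppressWarnings(as.numeric(flags$expert_i3m %||% NA_real_)),
    expert_decision = as.character(flags$expert_decision %||% NA_character_))
}

read_labelme_image <- function(doc, dir) {
  arr <- if (!is.null(doc$imageData) && nzchar(doc$imageData)) {
    png::readPNG(jsonlite::base64_dec(doc$imageData))
  } else if (!is.null(doc$imagePath) && file.exists(file.path(dir, doc$imagePath))) {
    png::readPNG(file.path(dir, doc$imagePath))
  } else {
    abort_annotation_schema("no imageData payload and no readable imagePath")
  }
  to_gray(arr)
}

to_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    return(apply(arr[, , seq_len(min(3L, dim(arr)[3])), drop = FALSE], c(1, 2), mean))
  }
  abort_image_format("unsupported image array layout")
}

#' Write a labelme-dialect annotation
#'
#' Inverse of [read_labelme()]: polygon vertices are stored 0-based, the
#' image as an embedded base64 PNG (unless `embed_image = FALSE`, in which
#' case a sibling PNG named after `imagePath` is written).
#'
#' @param annotation A [tooth_annotation()].
#' @param path Output `.json` path.
#' @param embed_image Embed the raster as base64 (default) or write it beside.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(annotation, path, embed_image = TRUE) {
  stopifnot(inherits(annotation, "tooth_annotation"))
  img <- pmin(pmax(annotation$image, 0), 1)
  image_path <- paste0(annotation$source_id, ".png")
  if (!embed_image) {
    png::writePNG(img, file.path(dirname(path), image_path))
  }
  shape <- function(label, poly) {
    list(label = label,
         points = lapply(seq_len(nrow(poly)),
                         function(i) as.list(unname(poly[i, ] - 1))),
         group_id = NULL, shape_type = "polygon", flags = structure(list(), names = character()))
  }
  doc <- list(
    version = "5.2.1",
    flags = list(side = annotation$side,
                 expert_i3m = annotation$expert_i3m,
                 expert_decision = annotation$expert_decision),
    shapes = list(shape("apical", annotation$apical_polygon),
                  shape("coronal", annotation$coronal_polygon)),
    imagePath = image_path,
    imageData = if (embed_image) jsonlite::base64_enc(png::writePNG(img)) else NULL,
    imageHeight = nrow(img), imageWidth = ncol(img))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 10, null = "null"),
             path)
  invisible(path)
}

#' Rasterize an annotation's polygons into its two instance masks
#'
#' @param annotation A [tooth_annotation()].
#' @return List with logical masks `apical` and `coronal`.
#' @export
annotation_masks <- function(annotation) {
  stopifnot(inherits(annotation, "tooth_annotation"))
  shape <- dim(annotation$image)
  list(apical = rasterize_polygon(annotation$apical_polygon, shape),
       coronal = rasterize_polygon(annotation$coronal_polygon, shape))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
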