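# Structured conditions. Every domain error is an rlang condition whose class
# vector carries both the specific class and "i3m_error", so callers can catch
# either level with tryCatch()/expect_error(class = ...).

i3m_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "i3m_error"), ...)
}

abort_empty_mask <- function(what = "mask") {
  i3m_abort(sprintf("%s contains no foreground pixel", what), "i3m_empty_mask_error")
}

abort_mask_overlap <- function(n) {
  i3m_abort(sprintf("apical and coronal masks overlap on %d pixel(s)", n),
            "i3m_mask_overlap_error")
}

abort_degenerate_geometry <- function(message) {
  i3m_abort(message, "i3m_degenerate_geometry_error")
}

abort_closed_apex <- function(message = "no open root canal reaching the apical extent was found") {
  i3m_abort(message, "i3m_closed_apex_error")
}

abort_annotation_schema <- function(message) {
  i3m_abort(message, "i3m_annotation_schema_error")
}

abort_image_format <- function(message) {
  i3m_abort(message, "i3m_image_format_error")
}

abort_shape_mismatch <- function(message) {
  i3m_abort(message, "i3m_shape_mismatch_error")
}

abort_constant_series <- function(message) {
  i3m_abort(message, "i3m_constant_series_error")
}

abort_label <- function(message) {
  i3m_abort(message, "i3m_label_error")
}

abort_invalid_measurement <- function(message) {
  i3m_abort(message, "i3m_invalid_measurement_error")
}

abort_phantom_geometry <- function(message) {
  i3m_abort(message, "i3m_phantom_geometry_error")
}
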