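# Internal helpers shared across modules.

# Coerce an EBImage Image or plain matrix to a numeric intensity matrix.
as_intensity_matrix <- function(image, arg = "image") {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix or EBImage Image", arg))
  }
  if (length(image) == 0L) stop(sprintf("`%s` is empty", arg))
  if (any(image < 0, na.rm = TRUE)) {
    stop(sprintf("`%s` contains negative intensities", arg))
  }
  image
}

# Odd-diameter disc brush for morphological operations; radius in pixels.
# A radius-1 "disc" is a full 3x3 box, which dilates by ~1.4 px diagonally;
# use the 4-neighbour diamond at radius 1 so a 1-px dilation means 1 px.
disc_brush <- function(radius) {
  radius <- max(1L, as.integer(round(radius)))
  shape <- if (radius == 1L) "diamond" else "disc"
  EBImage::makeBrush(2L * radius + 1L, shape = shape)
}

# Relabel a label matrix so labels are consecutive integers 1..K.
relabel_consecutive <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0L) {
    storage.mode(labels) <- "integer"
    return(labels)
  }
  out <- match(labels, u, nomatch = 0L)
  dim(out) <- dim(labels)
  storage.mode(out) <- "integer"
  out
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive scalar", name))
  }
  invisible(x)
}
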