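# Image preprocessing for inference: aspect-preserving resize + centre crop.

# bilinear resample of a matrix to nr x nc
.bilinear_resize <- function(img, nr, nc) {
  h <- nrow(img); w <- ncol(img)
  if (h == nr && w == nc) return(img)
  # map output pixel centres into input pixel-centre coordinates
  ri <- clamp((seq_len(nr) - 0.5) * h / nr - 0.5, 0, h - 1)
  ci <- clamp((seq_len(nc) - 0.5) * w / nc - 0.5, 0, w - 1)
  r0 <- pmin(floor(ri), h - 2); c0 <- pmin(floor(ci), w - 2)
  fr <- ri - r0; fc <- ci - c0
  a <- img[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  b <- img[cbind(rep(r0 + 2, nc), rep(c0 + 1, each = nr))]
  cc <- img[cbind(rep(r0 + 1, nc), rep(c0 + 2, each = nr))]
  d <- img[cbind(rep(r0 + 2, nc), rep(c0 + 2, each = nr))]
  fr <- rep(fr, nc); fc <- rep(fc, each = nr)
  matrix(a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) +
           cc * (1 - fr) * fc + d * fr * fc, nr, nc)
}

#' Preprocess an image for the network
#'
#' Scales the image so that its shorter side equals `size` pixels (bilinear,
#' preserving the aspect ratio) and centre-crops the longer side to `size`.
#' Intensities are passed through unchanged apart from clamping to `[0, 1]`.
#'
#' @param img 2D grayscale matrix.
#' @param size target side length in pixels.
#' @return A `size` x `size` matrix in `[0, 1]`.
#' @export
preprocess_image <- function(img, size) {
  if (!is.matrix(img) || !all(is.finite(img)))
    stopf("'img' must be a finite 2D matrix")
  h <- nrow(img); w <- ncol(img)
  if (h < 2L || w < 2L) stopf("'img' must be at least 2x2")
  s <- size / min(h, w)
  out <- .bilinear_resize(img, max(size, round(h * s)), max(size, round(w * s)))
  r0 <- floor((nrow(out) - size) / 2)
  c0 <- floor((ncol(out) - size) / 2)
  clamp(out[r0 + seq_len(size), c0 + seq_len(size)], 0, 1)
}
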