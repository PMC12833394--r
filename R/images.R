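# Grayscale images are plain numeric matrices indexed [y, x] (origin at the
# top-left corner, y increasing downward), values nominally in [0, 1].
# Boxes are (x_min, y_min, x_max, y_max) in pixel coordinates, half-open on
# the max edge.

#' Construct a grayscale image
#'
#' Thin wrapper validating a numeric matrix as a y-down pixel raster.
#'
#' @param pixels Numeric matrix, rows = image height, columns = width.
#' @param value_range Representable range, default `c(0, 1)`.
#' @return The matrix with class `gray_image` prepended.
#' @export
gray_image <- function(pixels, value_range = c(0, 1)) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0)
    stop("pixels must be a non-empty numeric matrix", call. = FALSE)
  structure(pixels, value_range = value_range,
            class = c("gray_image", class(pixels)))
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "gray_image")) {
    attr(image, "value_range") <- NULL
    class(image) <- setdiff(class(image), "gray_image")
  }
  if (!is.matrix(image)) stop("expected an image matrix", call. = FALSE)
  image
}

#' Read / write grayscale PNG images
#'
#' @param path File path.
#' @return `read_gray_png()` returns a numeric matrix in \[0, 1\] (multi-channel
#'   PNGs are averaged to luminance).
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                       c(1, 2), mean)
  a
}

#' @rdname read_gray_png
#' @param image Numeric matrix with values in \[0, 1\].
#' @export
write_gray_png <- function(image, path) {
  m <- pmin(pmax(as_pixel_matrix(image), 0), 1)
  png::writePNG(m, path)
  invisible(path)
}

# Bilinear sample of image at (possibly fractional) pixel-centre coordinates.
# x, y are in box coordinates: pixel (i, j) covers [j-1, j) x [i-1, i) and has
# its centre at (j - 0.5, i - 0.5). Out-of-range samples return `fill`.
bilinear_sample <- function(image, x, y, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  # continuous index space: centre of pixel column j is j - 0.5
  fx <- x + 0.5; fy <- y + 0.5
  x0 <- floor(fx - 1) + 1; y0 <- floor(fy - 1) + 1  # lower pixel index
  dx <- fx - x0; dy <- fy - y0
  g <- function(ix, iy) {
    ok <- ix >= 1 & ix <= w & iy >= 1 & iy <= h
    out <- rep(fill, length(ix))
    out[ok] <- image[cbind(iy[ok], ix[ok])]
    out
  }
  v <- g(x0, y0) * (1 - dx) * (1 - dy) + g(x0 + 1, y0) * dx * (1 - dy) +
       g(x0, y0 + 1) * (1 - dx) * dy + g(x0 + 1, y0 + 1) * dx * dy
  v
}

# Warp an image through an affine map taking OUTPUT pixel coordinates to
# INPUT coordinates: (xi, yi) = Minv %*% (xo, yo, 1). Bilinear interpolation.
affine_warp <- function(image, Minv, out_h, out_w, fill = 0) {
  image <- as_pixel_matrix(image)
  xo <- rep(seq_len(out_w) - 0.5, each = out_h)
  yo <- rep(seq_len(out_h) - 0.5, times = out_w)
  xi <- Minv[1, 1] * xo + Minv[1, 2] * yo + Minv[1, 3]
  yi <- Minv[2, 1] * xo + Minv[2, 2] * yo + Minv[2, 3]
  matrix(bilinear_sample(image, xi, yi, fill), out_h, out_w)
}

#' Resize an image by bilinear interpolation
#'
#' @param image Numeric matrix.
#' @param out_h,out_w Output size in pixels.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(image, out_h, out_w) {
  image <- as_pixel_matrix(image)
  sx <- ncol(image) / out_w; sy <- nrow(image) / out_h
  Minv <- matrix(c(sx, 0, 0, 0, sy, 0), 2, 3)
  # clamp sampling to the source extent so edges replicate rather than fade
  xo <- rep(seq_len(out_w) - 0.5, each = out_h)
  yo <- rep(seq_len(out_h) - 0.5, times = out_w)
  xi <- pmin(pmax(sx * xo, 0.5), ncol(image) - 0.5)
  yi <- pmin(pmax(sy * yo, 0.5), nrow(image) - 0.5)
  matrix(bilinear_sample(image, xi, yi), out_h, out_w)
}

# Map box corners through a forward affine matrix M (2x3) and take the
# enclosing axis-aligned box.
transform_box_affine <- function(box, M) {
  xs <- c(box[1], box[3], box[1], box[3])
  ys <- c(box[2], box[2], box[4], box[4])
  xt <- M[1, 1] * xs + M[1, 2] * ys + M[1, 3]
  yt <- M[2, 1] * xs + M[2, 2] * ys + M[2, 3]
  c(min(xt), min(yt), max(xt), max(yt))
}

clip_box <- function(box, w, h) {
  c(max(box[1], 0), max(box[2], 0), min(box[3], w), min(box[4], h))
}

box_valid <- function(box) box[3] > box[1] && box[4] > box[2]
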