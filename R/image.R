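## Raster conventions used throughout the package
##
## A grey image is a plain numeric matrix with values in [0, 255]
## (8-bit intensities, stored as doubles); an RGB image is an
## h x w x 3 array on the same scale. All public coordinates are
## 0-based (row, col) with the origin at the top-left pixel, so the
## pixel at matrix position [i, j] has coordinates (i - 1, j - 1).
## Circle membership is closed: a pixel belongs to a circle when its
## distance to the centre is <= radius.

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` has zero extent", arg), call. = FALSE)
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop(sprintf("`%s` must have values in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an h x w x 3 RGB array", arg), call. = FALSE)
  invisible(img)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

## round half away from zero (half-up for the non-negative intensities
## used here); base round() rounds half to even
round_half_up <- function(x) floor(x + 0.5)

#' Define a circle in pixel coordinates
#'
#' Circles locate the optic disc and the macula region. Coordinates are
#' 0-based `(row, col)` with the origin at the top-left pixel; membership
#' is closed (`distance <= radius`).
#'
#' @param row,col Centre, 0-based pixels.
#' @param radius Radius in pixels, must be positive.
#' @return An object of class `"circle"`: a list with `row`, `col`,
#'   `radius`.
#' @export
circle <- function(row, col, radius) {
  if (!is.finite(radius) || radius <= 0)
    stop("circle radius must be positive", call. = FALSE)
  structure(list(row = as.numeric(row), col = as.numeric(col),
                 radius = as.numeric(radius)),
            class = "circle")
}

#' @export
print.circle <- function(x, ...) {
  cat(sprintf("circle: centre (row %.1f, col %.1f), radius %.1f px\n",
              x$row, x$col, x$radius))
  invisible(x)
}

## logical mask of pixels inside a circle (closed membership, 0-based)
circle_mask <- function(h, w, circ) {
  rows <- matrix(0:(h - 1), h, w)
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  (rows - circ$row)^2 + (cols - circ$col)^2 <= circ$radius^2
}

## EBImage interop: EBImage stores greyscale as [0,1] with dim (x, y),
## i.e. the transpose of our (row, col) matrices.
as_ebimage <- function(img) EBImage::Image(t(img) / 255)
from_ebimage <- function(eb) t(EBImage::imageData(eb)) * 255

## morphological opening with a disc structuring element of given radius
disc_open <- function(img, se_radius) {
  brush <- EBImage::makeBrush(2L * as.integer(se_radius) + 1L, shape = "disc")
  from_ebimage(EBImage::opening(as_ebimage(img), brush))
}

disc_close <- function(img, se_radius) {
  brush <- EBImage::makeBrush(2L * as.integer(se_radius) + 1L, shape = "disc")
  from_ebimage(EBImage::closing(as_ebimage(img), brush))
}

gaussian_blur <- function(img, sigma) {
  from_ebimage(EBImage::gblur(as_ebimage(img), sigma = sigma))
}

## 8-connected component labelling (closed under diagonal adjacency)
label_components <- function(mask) {
  storage.mode(mask) <- "logical"
  cpp_label8(mask)
}

## drop connected components smaller than min_object pixels
remove_small_objects <- function(mask, min_object) {
  if (min_object <= 0) return(mask)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_object)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

## fill masked pixels from their unmasked neighbourhood by normalised
## convolution (Gaussian-weighted mean of clean pixels only)
inpaint_masked <- function(img, mask, sigma) {
  if (!any(mask)) return(img)
  clean <- !mask
  num <- gaussian_blur(img * clean, sigma)
  den <- gaussian_blur(clean * 255, sigma) / 255
  fill <- ifelse(den > 1e-4, num / pmax(den, 1e-4), median(img[clean]))
  out <- img
  out[mask] <- clip255(fill[mask])
  out
}

#' Read and write 8-bit images
#'
#' Thin wrappers over [EBImage::readImage()] / [EBImage::writeImage()]
#' converting to the package's 0--255 `(row, col)` convention. PNG and
#' JPEG are supported.
#'
#' @param path File path.
#' @return `read_fundus()` returns an h x w x 3 RGB array (a greyscale
#'   file is replicated across channels); `read_gray()` a matrix.
#' @export
read_fundus <- function(path) {
  eb <- EBImage::readImage(path)
  d <- dim(eb)
  dat <- EBImage::imageData(eb)
  if (length(d) == 2L) {
    g <- t(dat) * 255
    array(rep(g, 3L), dim = c(dim(g), 3L))
  } else {
    out <- array(0, dim = c(d[2], d[1], 3L))
    for (k in 1:3) out[, , k] <- t(dat[, , min(k, d[3])]) * 255
    out
  }
}

#' @rdname read_fundus
#' @export
read_gray <- function(path) {
  rgb <- read_fundus(path)
  assert_gray(rgb[, , 2])
}

#' @rdname read_fundus
#' @param img Grey matrix, RGB array or logical mask to write.
#' @export
write_image <- function(img, path) {
  if (is.logical(img)) img <- img * 255
  if (is.matrix(img)) {
    EBImage::writeImage(EBImage::Image(t(clip255(img)) / 255), path)
  } else {
    assert_rgb(img)
    d <- dim(img)
    dat <- array(0, dim = c(d[2], d[1], 3L))
    for (k in 1:3) dat[, , k] <- t(clip255(img[, , k])) / 255
    EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path)
  }
  invisible(path)
}
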