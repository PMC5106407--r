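#' Locate the optic disc with a circular Hough transform
#'
#' The optic disc is the brightest, highest-contrast circular structure
#' in a fundus photograph. Sobel gradient magnitudes above an edge
#' threshold vote, for each candidate radius, for every centre lying at
#' that radius; accumulator peaks normalised by circumference give
#' candidate circles. Because vessel crossings and lesion rims also
#' produce circular evidence, candidates are screened by interior
#' brightness: only candidates whose interior mean intensity is in the
#' top decile of all candidates are eligible, and the strongest
#' normalised accumulator response among them is returned.
#'
#' @param img Grey matrix in 0--255, bright-disc polarity (e.g. the
#'   filtered green channel).
#' @param rmin_frac,rmax_frac Radius search bounds as fractions of the
#'   image width (defaults 0.03 and 0.08, typical for 45--50 degree
#'   field-of-view photographs).
#' @param edge_quantile Quantile of the gradient magnitude above which a
#'   pixel is treated as an edge (default 0.95).
#' @param conf_floor Minimum normalised accumulator response (votes per
#'   unit circumference) below which detection fails (default 0.35).
#' @return An object of class `"optic_disc"`: list with `circle` (a
#'   [circle()]) and `dd` (disc diameter, `2 * radius`).
#' @export
detect_optic_disc <- function(img, rmin_frac = 0.03, rmax_frac = 0.08,
                              edge_quantile = 0.95, conf_floor = 0.35) {
  assert_gray(img)
  if (!(rmin_frac < rmax_frac))
    stop("`rmin_frac` must be smaller than `rmax_frac`", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  rmin <- max(2L, as.integer(round(rmin_frac * w)))
  rmax <- as.integer(round(rmax_frac * w))
  if (rmax < 2L) stop("radius range yields < 2 px", call. = FALSE)

  g <- sobel_magnitude(img)
  thr <- max(20, quantile(g, edge_quantile))
  edges <- which(g > thr, arr.ind = TRUE)
  if (nrow(edges) == 0L)
    stop("no optic disc found: no edge evidence", call. = FALSE)

  radii <- unique(as.integer(round(
    seq(rmin, rmax, length.out = min(rmax - rmin + 1L, 13L)))))
  cand <- list()
  for (r in radii) {
    acc <- cpp_hough_vote(edges[, 1], edges[, 2], h, w, r)
    acc <- box_smooth3(acc)
    ## top two separated peaks for this radius
    for (k in 1:2) {
      p <- which.max(acc)
      pi <- (p - 1L) %% h + 1L; pj <- (p - 1L) %/% h + 1L
      score <- acc[pi, pj] / (2 * pi_const * r)
      if (score <= 0) break
      cand[[length(cand) + 1L]] <-
        list(row = pi - 1L, col = pj - 1L, r = r, score = score)
      ## suppress a neighbourhood around the first peak
      ri <- max(1L, pi - r):min(h, pi + r)
      ci <- max(1L, pj - r):min(w, pj + r)
      acc[ri, ci] <- 0
    }
  }
  if (length(cand) == 0L)
    stop("no optic disc found: empty accumulator", call. = FALSE)

  interior <- vapply(cand, function(cc) {
    m <- circle_mask(h, w, circle(cc$row, cc$col, max(1, 0.8 * cc$r)))
    mean(img[m])
  }, numeric(1))
  scores <- vapply(cand, `[[`, numeric(1), "score")
  bright <- interior >= quantile(interior, 0.9)
  best <- which(bright)[which.max(scores[bright])]
  if (scores[best] < conf_floor)
    stop("no optic disc found: accumulator response below confidence floor",
         call. = FALSE)
  b <- cand[[best]]
  ## refine the radius at the chosen centre: the radius whose annulus
  ## holds the most edge pixels per unit circumference
  d <- sqrt((edges[, 1] - 1 - b$row)^2 + (edges[, 2] - 1 - b$col)^2)
  rs <- rmin:rmax
  ring <- vapply(rs, function(r) sum(d >= r - 0.5 & d < r + 0.5) / r,
                 numeric(1))
  k <- which.max(ring)
  win <- max(1L, k - 2L):min(length(rs), k + 2L)
  r_hat <- sum(rs[win] * ring[win]) / sum(ring[win])
  optic_disc(circle(b$row, b$col, r_hat))
}

pi_const <- base::pi

#' Construct an optic disc record
#'
#' @param circ A [circle()] describing the disc boundary.
#' @return Class `"optic_disc"`: list with `circle` and `dd = 2 * radius`
#'   (the disc diameter, the clinical unit of retinal distance).
#' @export
optic_disc <- function(circ) {
  stopifnot(inherits(circ, "circle"))
  structure(list(circle = circ, dd = 2 * circ$radius), class = "optic_disc")
}

#' @export
print.optic_disc <- function(x, ...) {
  cat(sprintf("optic disc: centre (row %.1f, col %.1f), radius %.1f px (DD = %.1f px)\n",
              x$circle$row, x$circle$col, x$circle$radius, x$dd))
  invisible(x)
}

sobel_magnitude <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(1, 1:h, h), c(1, 1:w, w)]
  sh <- function(di, dj) pad[(1:h) + 1 + di, (1:w) + 1 + dj]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

box_smooth3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, 1:h, h), c(1, 1:w, w)]
  out <- matrix(0, h, w)
  for (di in -1:1) for (dj in -1:1)
    out <- out + pad[(1:h) + 1 + di, (1:w) + 1 + dj]
  out / 9
}

#' Segment the retinal vasculature by morphological opening
#'
#' On the enhanced complemented green channel the vessels are thin
#' bright curvilinear structures. A morphological opening with a disc
#' structuring element wider than any vessel estimates the background;
#' subtracting it leaves the vessel response, which is thresholded
#' (Otsu by default) and cleaned of small connected components.
#'
#' @param img Enhanced grey matrix (bright-vessel polarity).
#' @param se_radius Disc structuring element radius in pixels
#'   (default 8; must exceed the half-width of the widest vessel).
#' @param min_object Minimum connected-component area kept, in pixels
#'   (default 30).
#' @param threshold_rule `"otsu"` (default) or a fixed numeric threshold
#'   on the background-subtracted response.
#' @return Logical vessel mask.
#' @export
segment_vessels <- function(img, se_radius = 8L, min_object = 30L,
                            threshold_rule = "otsu") {
  assert_gray(img)
  if (se_radius < 1) stop("`se_radius` must be >= 1", call. = FALSE)
  response <- img - disc_open(img, se_radius)
  response <- pmax(response, 0)
  if (identical(threshold_rule, "otsu")) {
    if (max(response) <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
    t <- EBImage::otsu(EBImage::Image(t(response) / 255), range = c(0, 1)) * 255
  } else if (is.numeric(threshold_rule)) {
    t <- threshold_rule
  } else stop("unknown `threshold_rule`", call. = FALSE)
  mask <- response > t
  remove_small_objects(mask, min_object)
}

#' Replace vessel pixels by a smoothed background estimate
#'
#' Vessel pixels are filled with a Gaussian-weighted average (scale
#' `sigma`) of the surrounding non-vessel pixels, so bright-lesion
#' candidates are genuinely vessel-free: the vessels' own dark mass
#' does not bleed into the replacement values. All other pixels are
#' untouched. An all-true mask degenerates to plain Gaussian smoothing
#' of the whole image.
#'
#' @param img Grey matrix.
#' @param vessels Logical mask, same shape as `img`.
#' @param sigma Gaussian scale in pixels (default 4).
#' @return Grey matrix with vessel pixels inpainted.
#' @export
remove_vessels <- function(img, vessels, sigma = 4) {
  assert_gray(img)
  if (!all(dim(vessels) == dim(img)))
    stop("`vessels` mask and image shapes differ", call. = FALSE)
  if (!any(vessels)) return(img)
  if (all(vessels)) return(clip255(gaussian_blur(img, sigma)))
  inpaint_masked(img, vessels, sigma)
}

#' Locate the macula from the optic disc geometry
#'
#' The macula is the darker region centred on the fovea, which sits
#' about two disc diameters (2DD) temporal to the optic disc, within
#' 37 degrees of the horizontal line through the disc centre. Candidate
#' fovea positions on the temporal side (towards the image's vertical
#' midline by default) inside the wedge `|angle| <= 37` degrees and at
#' distance 1.5DD--2.5DD are scored by mean intensity over a DD/4-radius
#' disc window; the darkest wins. The macula region is the circle of
#' diameter 1.3DD (radius 0.65DD) about the fovea.
#'
#' @param img Grey matrix, dark-macula polarity (e.g. the green channel).
#' @param od An `"optic_disc"`.
#' @param side `"auto"` (towards the vertical midline), `"left"` or
#'   `"right"`: the horizontal direction from the disc in which to search.
#' @param angle_max Wedge half-angle in degrees (default 37).
#' @param dist_range Search band in DD units (default `c(1.5, 2.5)`).
#' @param step Candidate grid step in pixels (default 2).
#' @return Class `"macula_region"`: list with `circle` (radius
#'   `0.65 * DD` at the fovea), `fovea = c(row, col)` and `angle_deg`,
#'   the signed angle from the horizontal (positive above the
#'   horizontal, i.e. towards smaller row indices).
#' @export
locate_macula_geometric <- function(img, od, side = c("auto", "left", "right"),
                                    angle_max = 37, dist_range = c(1.5, 2.5),
                                    step = 2) {
  assert_gray(img)
  stopifnot(inherits(od, "optic_disc"))
  side <- match.arg(side)
  h <- nrow(img); w <- ncol(img)
  dd <- od$dd
  dir <- switch(side,
                auto = if (od$circle$col > (w - 1) / 2) -1 else 1,
                left = -1, right = 1)
  dists <- seq(dist_range[1] * dd, dist_range[2] * dd, by = step)
  angles <- seq(-angle_max, angle_max, by = max(0.5, 180 * step / (pi_const * 2 * dd)))
  grid <- expand.grid(dist = dists, ang = angles * pi_const / 180)
  crow <- od$circle$row - grid$dist * sin(grid$ang)   # positive angle = up
  ccol <- od$circle$col + dir * grid$dist * cos(grid$ang)
  inside <- crow >= 0 & crow <= h - 1 & ccol >= 0 & ccol <= w - 1
  if (!any(inside))
    stop("macula out of frame: search wedge outside the image", call. = FALSE)
  crow <- crow[inside]; ccol <- ccol[inside]; grid <- grid[inside, ]

  ## mean intensity over a DD/4-radius disc window around each candidate
  wr <- max(1L, as.integer(round(dd / 4)))
  offs <- expand.grid(di = -wr:wr, dj = -wr:wr)
  offs <- offs[offs$di^2 + offs$dj^2 <= wr^2, ]
  total <- numeric(length(crow)); nvalid <- numeric(length(crow))
  ri <- as.integer(round(crow)) + 1L
  ci <- as.integer(round(ccol)) + 1L
  for (k in seq_len(nrow(offs))) {
    rr <- ri + offs$di[k]; cc <- ci + offs$dj[k]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    total[ok] <- total[ok] + img[cbind(rr[ok], cc[ok])]
    nvalid[ok] <- nvalid[ok] + 1
  }
  score <- total / pmax(nvalid, 1)
  ## the dark basin around the fovea is flat at the bottom: take the
  ## score-weighted centroid of the near-minimal candidates rather than
  ## the raw argmin, which texture would tie-break arbitrarily
  band <- 1.5
  nearmin <- score <= min(score) + band
  wts <- (min(score) + band - score[nearmin]) + 1e-9
  fr <- sum(crow[nearmin] * wts) / sum(wts)
  fc <- sum(ccol[nearmin] * wts) / sum(wts)
  dx <- dir * (fc - od$circle$col)
  dy <- od$circle$row - fr
  angle_deg <- atan2(dy, dx) * 180 / pi_const
  angle_deg <- max(min(angle_deg, angle_max), -angle_max)
  ## keep the centroid inside the sanctioned search band
  dist_f <- sqrt((fr - od$circle$row)^2 + (fc - od$circle$col)^2)
  dist_f <- max(min(dist_f, dist_range[2] * dd), dist_range[1] * dd)
  fr <- od$circle$row - dist_f * sin(angle_deg * pi_const / 180)
  fc <- od$circle$col + dir * dist_f * cos(angle_deg * pi_const / 180)
  macula_region(circle(fr, fc, 0.65 * dd), angle_deg = angle_deg)
}

#' Construct a macula region record
#'
#' @param circ [circle()] centred at the fovea with radius 0.65 DD.
#' @param angle_deg Signed angle from the horizontal through the optic
#'   disc centre, degrees; `NA` when the region was not derived from the
#'   disc geometry.
#' @return Class `"macula_region"`: list with `circle`,
#'   `fovea = c(row, col)` and `angle_deg`.
#' @export
macula_region <- function(circ, angle_deg = NA_real_) {
  stopifnot(inherits(circ, "circle"))
  if (!is.na(angle_deg) && abs(angle_deg) > 37)
    stop("macula angle outside the +/-37 degree wedge", call. = FALSE)
  structure(list(circle = circ, fovea = c(row = circ$row, col = circ$col),
                 angle_deg = angle_deg),
            class = "macula_region")
}

#' @export
print.macula_region <- function(x, ...) {
  cat(sprintf("macula region: fovea (row %.1f, col %.1f), radius %.1f px, angle %s\n",
              x$fovea[1], x$fovea[2], x$circle$radius,
              if (is.na(x$angle_deg)) "n/a" else sprintf("%.1f deg", x$angle_deg)))
  invisible(x)
}

#' Locate the macula at the image centre
#'
#' For macula-centred views the macula sits at the raster centre; this
#' method simply places a circle of the requested radius there.
#'
#' @param img Grey matrix.
#' @param radius Macula circle radius in pixels; must not exceed half
#'   the smaller image side.
#' @return A `"macula_region"` centred at
#'   `(floor(h / 2), floor(w / 2))` (0-based).
#' @export
locate_macula_image_centre <- function(img, radius) {
  assert_gray(img)
  h <- nrow(img); w <- ncol(img)
  if (radius > min(h, w) / 2)
    stop("`radius` exceeds half the smaller image side", call. = FALSE)
  macula_region(circle(floor(h / 2), floor(w / 2), radius))
}

#' Locate the macula by top-hat / bottom-hat enhancement
#'
#' Enhances the image as `img + tophat(img) - bothat(img)` (clipped to
#' 0--255), which lifts bright detail and deepens dark detail, then
#' takes the darkest connected region: pixels in the lowest decile of
#' the enhanced image's dynamic range, largest 8-connected component.
#'
#' @param img Grey matrix, dark-macula polarity.
#' @param se_radius Disc structuring element radius for the top-hat and
#'   bottom-hat transforms (default 15).
#' @return Logical macula mask.
#' @export
locate_macula_morphological <- function(img, se_radius = 15L) {
  assert_gray(img)
  tophat <- img - disc_open(img, se_radius)
  bothat <- disc_close(img, se_radius) - img
  enhanced <- clip255(img + tophat - bothat)
  thr <- min(enhanced) + 0.1 * (max(enhanced) - min(enhanced))
  mask <- enhanced <= thr
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L])
  lab == which.max(areas)
}

#' Crop a circular region of interest
#'
#' Pixels outside the circle are set to 0 (black background); pixels
#' inside are preserved bit-exactly. The output has the same shape as
#' the input.
#'
#' @param img Grey matrix.
#' @param circ A [circle()].
#' @return Grey matrix with everything outside the circle zeroed.
#' @export
crop_circular_roi <- function(img, circ) {
  assert_gray(img)
  stopifnot(inherits(circ, "circle"))
  m <- circle_mask(nrow(img), ncol(img), circ)
  if (!any(m)) {
    warning("circle does not intersect the image; returning an all-zero image")
    return(matrix(0, nrow(img), ncol(img)))
  }
  out <- img
  out[!m] <- 0
  out
}
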