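#' Segment exudates by global thresholding
#'
#' Exudates are the brightest lesions in an enhanced fundus image, so a
#' fixed global threshold separates them from the background: the mask
#' is `img > t`, with the optic disc (the one anatomical structure
#' brighter than exudates) and the vessel pixels removed. The disc
#' exclusion circle is dilated by 10% of the disc diameter to suppress
#' rim bleed-through.
#'
#' @param img Enhanced grey matrix, bright-lesion polarity.
#' @param od An `"optic_disc"`, or `NULL` to skip disc masking.
#' @param vessels Logical vessel mask, or `NULL` to skip vessel masking.
#' @param t Global threshold, default 135 (strict: a pixel equal to `t`
#'   is off).
#' @return Logical exudate mask.
#' @export
detect_exudates <- function(img, od = NULL, vessels = NULL, t = 135) {
  assert_gray(img)
  if (t < 0 || t > 255) stop("`t` must be in [0, 255]", call. = FALSE)
  mask <- img > t
  if (!is.null(od)) {
    stopifnot(inherits(od, "optic_disc"))
    excl <- circle(od$circle$row, od$circle$col,
                   od$circle$radius + 0.1 * od$dd)
    mask[circle_mask(nrow(img), ncol(img), excl)] <- FALSE
  }
  if (!is.null(vessels)) {
    if (!all(dim(vessels) == dim(img)))
      stop("`vessels` mask and image shapes differ", call. = FALSE)
    mask[vessels] <- FALSE
  }
  mask
}

#' Identify exudative maculopathy
#'
#' Exudates falling inside the macula region constitute exudative
#' maculopathy: the maculopathy mask is the intersection of the exudate
#' mask with the macula circle, and maculopathy is present when that
#' intersection is non-empty.
#'
#' @param exudates Logical exudate mask.
#' @param macula A `"macula_region"`.
#' @return Class `"lesion_maps"`: list with `exudates`, `maculopathy`
#'   (both logical masks, `maculopathy` a subset of `exudates`) and
#'   `maculopathy_present`.
#' @export
detect_maculopathy <- function(exudates, macula) {
  if (!is.matrix(exudates) || !is.logical(exudates))
    stop("`exudates` must be a logical matrix", call. = FALSE)
  stopifnot(inherits(macula, "macula_region"))
  mac <- exudates & circle_mask(nrow(exudates), ncol(exudates), macula$circle)
  structure(list(exudates = exudates, maculopathy = mac,
                 maculopathy_present = any(mac)),
            class = "lesion_maps")
}

#' @export
print.lesion_maps <- function(x, ...) {
  cat(sprintf("lesion maps: %d exudate px, %d maculopathy px, maculopathy %s\n",
              sum(x$exudates), sum(x$maculopathy),
              if (x$maculopathy_present) "PRESENT" else "absent"))
  invisible(x)
}
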