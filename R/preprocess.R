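#' Extract the green channel of a colour fundus photograph
#'
#' The green channel carries most of the structural contrast in fundus
#' photography (the red channel is close to saturation, the blue channel
#' is dark and noisy), so all downstream processing works on it.
#'
#' @param img An h x w x 3 RGB array with values in 0--255.
#' @return A grey matrix equal to the second channel.
#' @export
extract_green_channel <- function(img) {
  assert_rgb(img)
  g <- img[, , 2]
  if (!is.matrix(g)) g <- matrix(g, dim(img)[1], dim(img)[2])
  assert_gray(g)
}

#' Convert an RGB image to greyscale
#'
#' Weighted luma conversion (ITU-R BT.601 coefficients
#' 0.299 R + 0.587 G + 0.114 B), provided for display and comparison with
#' the green-channel image.
#'
#' @inheritParams extract_green_channel
#' @return A grey matrix in 0--255.
#' @export
to_greyscale <- function(img) {
  assert_rgb(img)
  y <- clip255(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  if (!is.matrix(y)) y <- matrix(y, dim(img)[1], dim(img)[2])
  y
}

#' Complement (invert) a grey image
#'
#' `255 - x` pixelwise; an involution. On the complemented green channel
#' the vasculature appears bright, which is what the morphological vessel
#' segmentation expects.
#'
#' @param img Grey matrix in 0--255.
#' @return The complemented grey matrix.
#' @export
complement <- function(img) {
  assert_gray(img)
  255 - img
}

#' Fuzzy switching median filter
#'
#' Impulse (salt-and-pepper) noise removal that only alters pixels with
#' evidence of corruption. For every pixel, the filter computes the
#' window median `m` and the noise evidence `d`, the maximum absolute
#' difference between the pixel and its window neighbours. A fuzzy
#' membership `f` maps `d` to a correction weight: 0 for `d <= t1`, a
#' linear ramp on `(t1, t2)`, and 1 for `d >= t2`. The output is
#' `round((1 - f) x + f m)`. Pixels in flat, noise-free regions
#' (`d <= t1`) pass through untouched, so genuine retinal detail is
#' preserved while impulses are replaced by the local median.
#'
#' @param img Grey matrix in 0--255.
#' @param t1,t2 Lower and upper fuzzy thresholds on the local intensity
#'   difference, `0 <= t1 < t2 <= 255`. Defaults 10 and 30.
#' @param window Odd window side length, default 3.
#' @return Filtered grey matrix.
#' @export
fsm_filter <- function(img, t1 = 10, t2 = 30, window = 3L) {
  assert_gray(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be odd and >= 3", call. = FALSE)
  if (window > min(dim(img)))
    stop("`window` larger than the image", call. = FALSE)
  if (!(t1 >= 0 && t1 < t2 && t2 <= 255))
    stop("need 0 <= t1 < t2 <= 255", call. = FALSE)
  ws <- cpp_window_stats(img, window)
  f <- pmin(pmax((ws$maxdiff - t1) / (t2 - t1), 0), 1)
  clip255(round_half_up((1 - f) * img + f * ws$median))
}

#' Brightness preserving dynamic fuzzy histogram equalisation
#'
#' Contrast enhancement for fundus images that keeps the mean brightness
#' of the input. The procedure: (1) build a fuzzy histogram in which
#' each pixel contributes a triangular membership
#' `max(0, 1 - |x - i| / fuzz_radius)` to every bin `i`, smearing the
#' counts so spurious spikes do not fragment the partitioning;
#' (2) locate the local maxima of the (moving-average smoothed) fuzzy
#' histogram and partition the occupied intensity range at them;
#' (3) equalise each partition independently into an output sub-range
#' allocated across the full 0--255 dynamic range according to
#' `range_rule`; (4) rescale the result multiplicatively so the output
#' mean matches the input mean, round half-up and clip to 0--255.
#' The mapping is monotone non-decreasing within each partition, so the
#' ordering of intensities inside an anatomical structure is preserved.
#'
#' @param img Grey matrix in 0--255.
#' @param fuzz_radius Half-width of the triangular fuzzy membership, in
#'   grey levels (default 4).
#' @param smoothing_width Odd moving-average width, in bins, used before
#'   local-maximum detection (default 5).
#' @param range_rule Dynamic-range allocation for partition `k`:
#'   `"span_log_count"` (default) allocates proportionally to
#'   input span x log10(count + 1); `"span"` proportionally to the
#'   input span alone.
#' @return Enhanced grey matrix; a constant image is returned unchanged.
#' @export
bpdfhe <- function(img, fuzz_radius = 4, smoothing_width = 5L,
                   range_rule = c("span_log_count", "span")) {
  assert_gray(img)
  range_rule <- match.arg(range_rule)
  if (fuzz_radius < 1) stop("`fuzz_radius` must be >= 1", call. = FALSE)
  smoothing_width <- as.integer(smoothing_width)
  if (smoothing_width %% 2L == 0L)
    stop("`smoothing_width` must be odd", call. = FALSE)

  v <- round_half_up(as.vector(img))
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(img)

  crisp <- tabulate(v + 1L, nbins = 256L)          # counts for values 0..255
  ## fuzzy histogram: convolve crisp counts with the triangular kernel
  offs <- seq(-(ceiling(fuzz_radius) - 1L), ceiling(fuzz_radius) - 1L)
  tri <- pmax(0, 1 - abs(offs) / fuzz_radius)
  fh <- numeric(256L)
  for (k in seq_along(offs)) {
    src <- (0:255) - offs[k]
    ok <- src >= 0 & src <= 255
    fh[ok] <- fh[ok] + tri[k] * crisp[src[ok] + 1L]
  }
  ## smooth and find local maxima inside the occupied range
  half <- smoothing_width %/% 2L
  padded <- c(rep(0, half), fh, rep(0, half))
  sm <- vapply(seq_len(256L),
               function(i) mean(padded[i:(i + 2L * half)]), numeric(1))
  idx <- (lo:hi) + 1L
  maxima <- integer(0)
  if (length(idx) > 2L) {
    for (i in idx[-c(1L, length(idx))]) {
      if (sm[i] > sm[i - 1L] && sm[i] >= sm[i + 1L])
        maxima <- c(maxima, i - 1L)                 # back to intensity value
    }
  }
  bounds <- sort(unique(c(lo, maxima, hi)))
  K <- length(bounds) - 1L
  if (K < 1L) return(img)

  ## per-partition crisp mass and allocated output spans over 0..255
  counts <- numeric(K); spans <- numeric(K)
  for (k in seq_len(K)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    sel <- if (k == 1L) a:b else (a + 1L):b
    counts[k] <- sum(crisp[sel + 1L])
    spans[k] <- b - a
  }
  factor <- switch(range_rule,
                   span = spans,
                   span_log_count = spans * log10(counts + 1))
  if (sum(factor) <= 0) factor <- spans
  alloc <- 255 * factor / sum(factor)
  starts <- c(0, cumsum(alloc))[seq_len(K)]

  ## within-partition histogram equalisation onto the allocated sub-range
  map <- numeric(256L)
  for (k in seq_len(K)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    sel <- if (k == 1L) a:b else (a + 1L):b
    cnt <- crisp[sel + 1L]
    tot <- sum(cnt)
    cdf <- if (tot > 0) cumsum(cnt) / tot
           else seq_along(sel) / length(sel)       # empty partition: linear
    map[sel + 1L] <- starts[k] + cdf * alloc[k]
  }
  ## values outside [lo, hi] cannot occur; keep identity there for safety
  map[seq_len(lo)] <- 0
  y <- matrix(map[v + 1L], nrow(img), ncol(img))

  m_in <- mean(img); m_out <- mean(y)
  if (m_out <= 0) return(img)
  clip255(round_half_up(y * m_in / m_out))
}

#' Run the full preprocessing chain
#'
#' Green channel extraction, complement, fuzzy switching median filter,
#' then brightness preserving dynamic fuzzy histogram equalisation.
#' The complement step can be skipped.
#'
#' @inheritParams extract_green_channel
#' @param apply_complement Apply the complement before filtering
#'   (default `TRUE`).
#' @param fsm,bpdfhe_args Named lists of arguments forwarded to
#'   [fsm_filter()] and [bpdfhe()].
#' @return A named list of the intermediate grey images:
#'   `greyscale`, `green`, `complement` (if applied), `filtered`,
#'   `equalised`.
#' @export
preprocess_fundus <- function(img, apply_complement = TRUE,
                              fsm = list(), bpdfhe_args = list()) {
  assert_rgb(img)
  out <- list(greyscale = to_greyscale(img),
              green = extract_green_channel(img))
  x <- out$green
  if (apply_complement) {
    x <- complement(x)
    out$complement <- x
  }
  x <- do.call(fsm_filter, c(list(x), fsm))
  out$filtered <- x
  x <- do.call(bpdfhe, c(list(x), bpdfhe_args))
  out$equalised <- x
  out
}
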