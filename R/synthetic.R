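#' Specify a synthetic colour fundus image
#'
#' The generator emulates the properties of a macula-visible colour
#' fundus photograph that the screening pipeline relies on: a dark
#' frame with a circular field of view, a bright circular optic disc, a
#' darker macula centred two disc diameters (2DD) from the disc within
#' the clinical wedge, a branching vessel tree grown from the disc, a
#' smooth illumination gradient, optional salt-and-pepper noise, and
#' bright soft-edged exudate blobs planted inside or outside the macula
#' region. All intensities describe the green channel; the red and blue
#' channels are derived from it.
#'
#' @param height,width Image size in pixels (defaults 240 x 360).
#' @param od_radius Optic disc radius in pixels (default 5.5% of the
#'   width, typical for a 45--50 degree field of view).
#' @param od_intensity,background_intensity Green-channel levels of the
#'   disc and the retinal background (defaults 200 and 95).
#' @param macula_depth Grey levels by which the macula dips below the
#'   background (default 45).
#' @param macula_angle_deg Signed fovea angle from the horizontal
#'   through the disc centre, degrees in \[-37, 37\] (default 0;
#'   positive = above the horizontal).
#' @param macula_dist_dd Fovea distance from the disc centre in disc
#'   diameters (default 2).
#' @param n_vessel_branches Number of vessel random-walk branches grown
#'   from the disc (default 7).
#' @param exudate_blobs `NULL`, or a data frame / matrix with columns
#'   `row`, `col`, `radius`, `intensity` (green-channel peak level,
#'   must exceed the background).
#' @param noise_density Salt-and-pepper corruption fraction inside the
#'   field of view, in \[0, 1\] (default 0.02).
#' @param illumination_gradient Peak-to-peak grey-level span of the
#'   smooth horizontal illumination ramp (default 20).
#' @param seed Integer seed; the same spec renders bit-identically.
#' @return Class `"synthetic_fundus_spec"` (a list of the above).
#' @export
synthetic_fundus_spec <- function(height = 240L, width = 360L,
                                  od_radius = NULL,
                                  od_intensity = 200,
                                  background_intensity = 95,
                                  macula_depth = 45,
                                  macula_angle_deg = 0,
                                  macula_dist_dd = 2,
                                  n_vessel_branches = 7L,
                                  exudate_blobs = NULL,
                                  noise_density = 0.02,
                                  illumination_gradient = 20,
                                  seed = 1L) {
  if (is.null(od_radius)) od_radius <- round(0.055 * width)
  if (od_radius <= 0) stop("`od_radius` must be positive", call. = FALSE)
  if (macula_depth <= 0) stop("`macula_depth` must be positive", call. = FALSE)
  if (abs(macula_angle_deg) > 37)
    stop("`macula_angle_deg` outside [-37, 37]", call. = FALSE)
  if (noise_density < 0 || noise_density > 1)
    stop("`noise_density` outside [0, 1]", call. = FALSE)
  if (!is.null(exudate_blobs)) {
    exudate_blobs <- as.data.frame(exudate_blobs)
    stopifnot(all(c("row", "col", "radius", "intensity") %in%
                    names(exudate_blobs)))
    if (any(exudate_blobs$intensity <= background_intensity))
      stop("exudate intensities must exceed the background", call. = FALSE)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 od_radius = od_radius, od_intensity = od_intensity,
                 background_intensity = background_intensity,
                 macula_depth = macula_depth,
                 macula_angle_deg = macula_angle_deg,
                 macula_dist_dd = macula_dist_dd,
                 n_vessel_branches = as.integer(n_vessel_branches),
                 exudate_blobs = exudate_blobs,
                 noise_density = noise_density,
                 illumination_gradient = illumination_gradient,
                 seed = as.integer(seed)),
            class = "synthetic_fundus_spec")
}

#' Render a synthetic fundus image with full ground truth
#'
#' Deterministic by `spec$seed`. The optic disc is placed on the
#' temporal side so that the fovea, `macula_dist_dd` disc diameters
#' away along `macula_angle_deg`, lands at the image centre; the
#' geometry therefore satisfies the same assumptions the detectors
#' make. Exudate blobs default to a soft (Gaussian-profile) edge so the
#' behaviour of the global threshold near its cut-off is exercised.
#'
#' @param spec A [synthetic_fundus_spec()].
#' @param blob_profile `"soft"` (default) or `"hard"` blob edges.
#' @return List with `image` (h x w x 3 RGB array, 0--255) and `truth`,
#'   a list with `od` (`"optic_disc"`), `macula` (`"macula_region"`),
#'   `vessels` and `exudates` (logical masks) and `maculopathy_label`
#'   (`TRUE` iff a planted exudate pixel falls inside the macula
#'   circle).
#' @export
generate_fundus <- function(spec, blob_profile = c("soft", "hard")) {
  stopifnot(inherits(spec, "synthetic_fundus_spec"))
  blob_profile <- match.arg(blob_profile)
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    rows <- matrix(0:(h - 1), h, w)
    cols <- matrix(0:(w - 1), h, w, byrow = TRUE)

    fov_c <- c((h - 1) / 2, (w - 1) / 2)
    fov_r <- 0.47 * min(h, w) + 0.25 * max(0, w - h)
    fov <- (rows - fov_c[1])^2 + (cols - fov_c[2])^2 <= fov_r^2

    dd <- 2 * spec$od_radius
    ang <- spec$macula_angle_deg * base::pi / 180
    fovea <- fov_c
    od_row <- fovea[1] - spec$macula_dist_dd * dd * sin(ang) * (-1)
    od_col <- fovea[2] + spec$macula_dist_dd * dd * cos(ang)
    od_c <- c(od_row, od_col)
    if (sqrt(sum((od_c - fov_c)^2)) + spec$od_radius > fov_r)
      stop("optic disc falls outside the field of view", call. = FALSE)

    ## background + smooth illumination ramp + choroidal texture
    ## (a smoothed random field; real retinal background is mottled,
    ## not flat, and the histogram-based enhancement expects a
    ## continuous intensity distribution)
    g <- matrix(spec$background_intensity, h, w)
    g <- g + spec$illumination_gradient * (cols / (w - 1) - 0.5)
    tex <- matrix(rnorm(h * w), h, w)
    tex <- gaussian_blur(clip255(tex * 20 + 128), 5) - 128
    g <- g + tex * (5 / max(sd(tex), 1e-6))

    ## macula: broad dark region covering 0.65 DD plus a sharper dip at
    ## the fovea itself (the foveal avascular zone is distinctly darker
    ## than the surrounding macula in real photographs)
    mac_r <- 0.65 * dd
    dmac <- sqrt((rows - fovea[1])^2 + (cols - fovea[2])^2)
    g <- g - spec$macula_depth * exp(-0.5 * (dmac / (0.8 * mac_r))^2)
    g <- g - 0.5 * spec$macula_depth * exp(-0.5 * (dmac / (0.15 * dd))^2)

    ## optic disc: bright plateau with a ~2 px soft rim
    dod <- sqrt((rows - od_c[1])^2 + (cols - od_c[2])^2)
    od_w <- pmin(pmax((spec$od_radius - dod) / 2, 0), 1)
    g <- g * (1 - od_w) + spec$od_intensity * od_w

    ## vessel tree: random walks leaving the disc centre
    vessels <- matrix(FALSE, h, w)
    for (b in seq_len(spec$n_vessel_branches)) {
      theta <- runif(1, 0, 2 * base::pi)
      pos <- od_c
      thick <- sample(1:2, 1)
      nstep <- round(runif(1, 0.45, 0.9) * min(h, w))
      for (s in seq_len(nstep)) {
        theta <- theta + rnorm(1, 0, 0.18)
        pos <- pos + 1.5 * c(-sin(theta), cos(theta))
        if (sqrt(sum((pos - fov_c)^2)) > fov_r - 2) break
        ri <- round(pos[1]) + 1; ci <- round(pos[2]) + 1
        if (ri < 1 || ri > h || ci < 1 || ci > w) break
        rr <- max(1, ri - thick):min(h, ri + thick)
        cc <- max(1, ci - thick):min(w, ci + thick)
        vessels[rr, cc] <- TRUE
      }
    }
    ## the fovea is avascular: no vessels within half the macula radius
    vessels <- vessels & fov & !(dod <= spec$od_radius) &
      !(dmac <= 0.5 * mac_r)
    g[vessels] <- pmax(g[vessels] - 60, 30)

    ## exudate blobs (ground-truth mask: nominal extent, d <= radius)
    ex_truth <- matrix(FALSE, h, w)
    blobs <- spec$exudate_blobs
    if (!is.null(blobs) && nrow(blobs) > 0) {
      for (k in seq_len(nrow(blobs))) {
        db <- sqrt((rows - blobs$row[k])^2 + (cols - blobs$col[k])^2)
        if (blob_profile == "soft") {
          p <- exp(-0.5 * (db / (blobs$radius[k] / 2))^2)
        } else {
          p <- as.numeric(db <= blobs$radius[k])
        }
        g <- g + (blobs$intensity[k] - spec$background_intensity) * p
        ex_truth <- ex_truth | (db <= blobs$radius[k])
      }
      ex_truth <- ex_truth & fov
    }

    g[!fov] <- 0
    g <- clip255(g)

    ## salt-and-pepper noise inside the field of view
    if (spec$noise_density > 0) {
      idx <- which(fov)
      n_noise <- round(spec$noise_density * length(idx))
      if (n_noise > 0) {
        hit <- sample(idx, n_noise)
        g[hit] <- ifelse(runif(n_noise) < 0.5, 0, 255)
      }
    }
    g <- round_half_up(g)

    img <- array(0, dim = c(h, w, 3L))
    img[, , 1] <- clip255(g * 1.3 + 15 * fov)
    img[, , 2] <- g
    img[, , 3] <- clip255(g * 0.35)

    macula <- macula_region(circle(fovea[1], fovea[2], mac_r),
                            angle_deg = spec$macula_angle_deg)
    truth <- list(od = optic_disc(circle(od_c[1], od_c[2], spec$od_radius)),
                  macula = macula,
                  vessels = vessels,
                  exudates = ex_truth,
                  maculopathy_label =
                    any(ex_truth & circle_mask(h, w, macula$circle)))
    list(image = img, truth = truth)
  })
}

#' Sample exudate blob positions for a given label
#'
#' Positives receive 1--3 blobs well inside the macula circle
#' (optionally plus distractors elsewhere); negatives receive either no
#' exudates or 1--3 blobs well outside the macula region.
#'
#' @keywords internal
sample_blobs <- function(spec, positive) {
  h <- spec$height; w <- spec$width
  dd <- 2 * spec$od_radius
  fovea <- c((h - 1) / 2, (w - 1) / 2)
  mac_r <- 0.65 * dd
  blob_r <- function() runif(1, 0.18 * dd, 0.3 * dd)
  blobs <- NULL
  if (positive) {
    n <- sample(1:3, 1)
    for (k in seq_len(n)) {
      a <- runif(1, 0, 2 * base::pi)
      d <- runif(1, 0, 0.4 * mac_r)
      blobs <- rbind(blobs, data.frame(
        row = fovea[1] + d * sin(a), col = fovea[2] + d * cos(a),
        radius = blob_r(), intensity = runif(1, 225, 245)))
    }
  } else if (runif(1) < 0.5) {
    n <- sample(1:3, 1)
    for (k in seq_len(n)) {
      a <- runif(1, base::pi / 3, 2 * base::pi / 3) * sample(c(-1, 1), 1)
      d <- runif(1, mac_r + 0.75 * dd, mac_r + 1.4 * dd)
      r <- fovea[1] + d * sin(a); c <- fovea[2] + d * cos(a)
      r <- min(max(r, 4), h - 5); c <- min(max(c, 4), w - 5)
      blobs <- rbind(blobs, data.frame(
        row = r, col = c, radius = blob_r(),
        intensity = runif(1, 225, 245)))
    }
  }
  blobs
}

#' Generate a labelled cohort of synthetic fundus images
#'
#' Renders `n` images of which `round(n * pos_fraction)` carry planted
#' exudates inside the macula region (maculopathy positive); per-image
#' seeds are derived deterministically from the master seed, and
#' per-image geometry (disc radius, fovea angle, background level) is
#' jittered within realistic bounds.
#'
#' @param n Number of images (>= 2).
#' @param pos_fraction Fraction of maculopathy-positive images, in
#'   (0, 1).
#' @param seed Master integer seed.
#' @param ... Overrides forwarded to [synthetic_fundus_spec()].
#' @return List with `images` (list of RGB arrays) and `truths` (list
#'   of ground-truth lists, as in [generate_fundus()]).
#' @export
generate_cohort <- function(n, pos_fraction, seed = 1L, ...) {
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (!(pos_fraction > 0 && pos_fraction < 1))
    stop("`pos_fraction` must be in (0, 1)", call. = FALSE)
  n_pos <- round(n * pos_fraction)
  if (n_pos < 1L || n_pos > n - 1L)
    stop("`pos_fraction` leaves an empty class", call. = FALSE)
  labels <- with_seed(seed, sample(rep(c(TRUE, FALSE), c(n_pos, n - n_pos))))
  images <- vector("list", n); truths <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- (as.integer(seed) * 7919L + i * 104729L) %% 2147483629L
    pars <- with_seed(sub_seed, list(
      od_radius = round(runif(1, 0.05, 0.062) * 360),
      macula_angle_deg = runif(1, -12, 12),
      background_intensity = runif(1, 88, 102),
      illumination_gradient = runif(1, 10, 22)))
    spec <- synthetic_fundus_spec(
      od_radius = pars$od_radius,
      macula_angle_deg = pars$macula_angle_deg,
      background_intensity = pars$background_intensity,
      illumination_gradient = pars$illumination_gradient,
      seed = sub_seed, ...)
    spec$exudate_blobs <- with_seed(sub_seed + 1L,
                                    sample_blobs(spec, labels[i]))
    if (!is.null(spec$exudate_blobs) &&
        any(spec$exudate_blobs$intensity <= spec$background_intensity))
      stop("internal: blob below background")   # unreachable by construction
    out <- generate_fundus(spec)
    images[[i]] <- out$image
    truths[[i]] <- out$truth
  }
  list(images = images, truths = truths)
}
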