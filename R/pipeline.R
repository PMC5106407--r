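#' Screen a colour fundus image for exudative maculopathy
#'
#' Runs the whole chain: preprocessing (green channel, complement,
#' fuzzy switching median filter, fuzzy histogram equalisation), optic
#' disc localisation on the filtered green channel, vessel segmentation
#' on the enhanced complement (vessels are bright there), macula
#' localisation from the disc geometry on the green channel, exudate
#' segmentation by global threshold on the re-complemented enhanced
#' image (bright-lesion polarity) with disc and vessel masking, and
#' maculopathy identification inside the macula circle, ending with the
#' six on-pixel features.
#'
#' @param img h x w x 3 RGB array, 0--255.
#' @param threshold Global exudate threshold (default 135).
#' @param min_lesion Minimum exudate connected-component area kept, in
#'   pixels (default 10); isolated supra-threshold specks from noise or
#'   enhancement artefacts are not plausible lesions.
#' @param macula_method `"geometric"` (default), `"centre"` or
#'   `"morphological"`.
#' @param side Temporal-side rule passed to
#'   [locate_macula_geometric()].
#' @param fsm,bpdfhe_args,od_args,vessel_args Named argument lists
#'   forwarded to the respective stages.
#' @return Class `"fundus_screen"`: list with `preprocessed` (the
#'   intermediate images), `od`, `vessels`, `macula`, `lesions`
#'   (a `"lesion_maps"`), `features` and `maculopathy_present`.
#' @export
screen_fundus <- function(img, threshold = 135, min_lesion = 10L,
                          macula_method = c("geometric", "centre",
                                            "morphological"),
                          side = "auto",
                          fsm = list(), bpdfhe_args = list(),
                          od_args = list(), vessel_args = list()) {
  macula_method <- match.arg(macula_method)
  assert_rgb(img)
  green <- extract_green_channel(img)
  filtered_green <- do.call(fsm_filter, c(list(green), fsm))

  pre <- preprocess_fundus(img, apply_complement = TRUE,
                           fsm = fsm, bpdfhe_args = bpdfhe_args)
  enhanced_inv <- pre$equalised           # bright vessels, dark lesions
  lesion_img <- complement(enhanced_inv)  # bright lesions for thresholding

  od <- do.call(detect_optic_disc, c(list(filtered_green), od_args))
  vessels <- do.call(segment_vessels, c(list(enhanced_inv), vessel_args))

  exudates <- detect_exudates(lesion_img, od = od, vessels = vessels,
                              t = threshold)
  exudates <- remove_small_objects(exudates, min_lesion)

  ## fovea scoring image: the segmented vessels and detected bright
  ## lesions (dilated a little to cover their soft rims) are filled in
  ## from their clean surroundings by normalised convolution, so that
  ## neither a vessel bundle nor an exudate inside the macula can
  ## misdirect the dark-window search, while the dark macular basin
  ## keeps its curvature everywhere else
  ## black top-hat catches thin dark structures the vessel mask missed
  occl <- vessels |
    (disc_close(filtered_green, max(4L, round(0.12 * od$dd))) -
       filtered_green) > 20
  if (any(exudates)) {
    occl <- occl | (from_ebimage(EBImage::dilate(
      as_ebimage(exudates * 255),
      EBImage::makeBrush(2L * max(2L, round(0.1 * od$dd)) + 1L,
                         "disc"))) > 0)
  }
  macula_img <- inpaint_masked(filtered_green, occl,
                               sigma = max(3, 0.25 * od$dd))
  macula <- switch(macula_method,
    geometric = locate_macula_geometric(macula_img, od, side = side),
    centre = locate_macula_image_centre(filtered_green,
                                        radius = 0.65 * od$dd),
    morphological = {
      mask <- locate_macula_morphological(macula_img)
      ctr <- which(mask, arr.ind = TRUE)
      macula_region(circle(mean(ctr[, 1]) - 1, mean(ctr[, 2]) - 1,
                           max(1, sqrt(sum(mask) / base::pi))))
    })

  lesions <- detect_maculopathy(exudates, macula)
  feats <- extract_features(lesions)

  structure(list(preprocessed = pre, od = od, vessels = vessels,
                 macula = macula, lesions = lesions, features = feats,
                 maculopathy_present = lesions$maculopathy_present,
                 threshold = threshold),
            class = "fundus_screen")
}

#' @export
print.fundus_screen <- function(x, ...) {
  cat("fundus screening result\n")
  print(x$od)
  print(x$macula)
  print(x$lesions)
  invisible(x)
}

#' @export
summary.fundus_screen <- function(object, ...) {
  cat("fundus screening summary\n")
  print(object$od)
  print(object$macula)
  cat(sprintf("vessel pixels: %d\n", sum(object$vessels)))
  print(object$lesions)
  cat("features:\n")
  print(object$features)
  invisible(object)
}

#' Screen a synthetic cohort and assemble the feature table
#'
#' Runs [screen_fundus()] on every image of a cohort and returns the
#' feature matrix together with the predicted and planted maculopathy
#' labels.
#'
#' @param cohort Output of [generate_cohort()].
#' @param ... Forwarded to [screen_fundus()].
#' @return List with `features` (n x 6 matrix), `predicted` and `truth`
#'   (logical vectors).
#' @export
screen_cohort <- function(cohort, ...) {
  n <- length(cohort$images)
  feats <- matrix(0, n, 6, dimnames = list(NULL, feature_names()))
  predicted <- logical(n)
  for (i in seq_len(n)) {
    res <- screen_fundus(cohort$images[[i]], ...)
    feats[i, ] <- as.numeric(res$features)
    predicted[i] <- res$maculopathy_present
  }
  list(features = feats, predicted = predicted,
       truth = vapply(cohort$truths, `[[`, logical(1), "maculopathy_label"))
}
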