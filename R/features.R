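#' Extract the six on-pixel features from the lesion maps
#'
#' Three statistics are taken from the exudate mask and the same three
#' from the maculopathy mask: the total on-pixel area, and the mean and
#' sample standard deviation of the 8-connected component areas. An
#' empty mask yields `(0, 0, 0)`; the standard deviation is 0 when a
#' mask has fewer than two components. Because the maculopathy mask is
#' a subset of the exudate mask, `mac_area <= ex_area` always.
#'
#' @param maps A `"lesion_maps"` object (or any list with logical
#'   `exudates` and `maculopathy` matrices).
#' @return Class `"fundus_features"`: named numeric vector with elements
#'   `ex_area`, `ex_mean`, `ex_sd`, `mac_area`, `mac_mean`, `mac_sd`.
#' @export
extract_features <- function(maps) {
  triple <- function(mask) {
    lab <- label_components(mask)
    if (max(lab) == 0L) return(c(0, 0, 0))
    areas <- tabulate(lab[lab > 0L])
    c(sum(areas), mean(areas), if (length(areas) < 2L) 0 else sd(areas))
  }
  out <- c(triple(maps$exudates), triple(maps$maculopathy))
  names(out) <- feature_names()
  class(out) <- "fundus_features"
  out
}

feature_names <- function() {
  c("ex_area", "ex_mean", "ex_sd", "mac_area", "mac_mean", "mac_sd")
}

#' @export
print.fundus_features <- function(x, ...) {
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Write a feature table to CSV
#'
#' One row per image: `image_id`, the six features, and the binary
#' maculopathy label.
#'
#' @param features List of `"fundus_features"` (or a numeric matrix with
#'   the six feature columns).
#' @param image_ids Character vector of image identifiers.
#' @param labels Logical maculopathy labels.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_feature_table <- function(features, image_ids, labels, path) {
  m <- if (is.list(features)) do.call(rbind, lapply(features, as.numeric))
       else as.matrix(features)
  colnames(m) <- feature_names()
  df <- data.frame(image_id = image_ids, m,
                   label = as.logical(labels))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", feature_names(), "label")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("feature table misses columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$label <- as.logical(df$label)
  df
}
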