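## Two-channel colocalization: normalized intensities and the pixelwise
## product ("yellow") map.

#' Normalize a raw channel image to [0, 1]
#'
#' @param raw Numeric matrix of non-negative intensities.
#' @param method Reference value: `"percentile"` (99.9th percentile, robust
#'   to hot pixels; the default) or `"max"`.
#' @param label Channel label, `"red"` or `"green"`.
#' @param offset Optional flat background subtracted before normalization.
#' @return A `channel_image`: matrix in [0, 1] with label attribute.
#' @export
normalize_channel <- function(raw, method = c("percentile", "max"),
                              label = "red", offset = 0) {
  method <- match.arg(method)
  raw <- as.matrix(raw)
  if (length(raw) == 0) stop("empty image")
  if (any(raw < 0)) stop("negative intensities")
  raw <- pmax(raw - offset, 0)
  ref <- switch(method,
                max = max(raw),
                percentile = stats::quantile(raw, 0.999, names = FALSE))
  if (ref <= 0) stop("all-zero image cannot be normalized")
  img <- pmin(raw / ref, 1)
  structure(img, label = label, class = c("channel_image", class(img)))
}

#' Read a grayscale image file as a channel
#'
#' PNG and TIFF files are supported (via the png/tiff packages); multi-band
#' images are averaged to grayscale before normalization.
#'
#' @param path Image file path.
#' @inheritParams normalize_channel
#' @export
read_channel <- function(path, method = "percentile", label = "red") {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = { requireNamespace("png"); png::readPNG(path) },
    tif = , tiff = { requireNamespace("tiff"); tiff::readTIFF(path) },
    stop("unsupported image format: ", ext))
  if (length(dim(raw)) == 3) raw <- apply(raw, c(1, 2), mean)
  normalize_channel(raw, method = method, label = label)
}

#' Pixelwise product ("yellow") colocalization map
#'
#' `I_y(i, j) = I_r(i, j) * I_g(i, j)`; a large product marks pixels where
#' both channels are intense, i.e. interpenetrated regions. In batch mode
#' (lists of image pairs) the mean yellow intensity is averaged over images
#' and the spread is the s.d. across images.
#'
#' @param red,green `channel_image`s (or matrices already in [0, 1]), same
#'   shape; or lists of them for batch mode.
#' @return List: `map` (last image pair's product), `mean_iy`, `sd_iy`, and
#'   in batch mode `per_image` means.
#' @export
yellow_map <- function(red, green) {
  if (is.list(red) && !is.matrix(red)) {
    stopifnot(is.list(green), length(red) == length(green))
    per <- mapply(function(r, g) yellow_map(r, g)$mean_iy, red, green)
    last <- yellow_map(red[[length(red)]], green[[length(green)]])
    return(list(map = last$map, mean_iy = mean(per), sd_iy = stats::sd(per),
                per_image = per))
  }
  red <- as.matrix(red); green <- as.matrix(green)
  if (!all(dim(red) == dim(green))) stop("channel shapes differ")
  iy <- red * green
  list(map = iy, mean_iy = mean(iy), sd_iy = stats::sd(as.numeric(iy)))
}
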