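## Wing-image contrast scoring: background removal, greyscale conversion,
## and RMS contrast of the masked wing region.

#' Construct an RGB(A) image object
#'
#' Images are stored as height x width x channels arrays with intensities on
#' the 0--255 scale (real-valued; never re-quantized). Three channels are
#' interpreted as RGB, four as RGBA with the alpha plane on 0--255 as well.
#'
#' @param arr numeric array, `height x width x 3` or `height x width x 4`,
#'   all values in `[0, 255]`.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(arr) {
  if (!is.array(arr) || length(dim(arr)) != 3L || !(dim(arr)[3] %in% c(3L, 4L)))
    stop("image must be a height x width x 3 (RGB) or x 4 (RGBA) array")
  if (dim(arr)[1] < 1L || dim(arr)[2] < 1L)
    stop("image must have width >= 1 and height >= 1")
  if (anyNA(arr) || min(arr) < 0 || max(arr) > 255)
    stop("intensities must lie in [0, 255]")
  structure(list(data = arr), class = "rgb_image")
}

#' Read a PNG file as an `rgb_image`
#'
#' Greyscale PNGs are expanded to three identical channels; intensities are
#' rescaled from the decoder's `[0, 1]` to the package's `[0, 255]` scale.
#'
#' @param path file path to an 8-bit PNG.
#' @return an `rgb_image`.
#' @export
read_wing_image <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  rgb_image(raw * 255)
}

#' Write an `rgb_image` to a PNG file
#'
#' @param image an `rgb_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wing_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  png::writePNG(image$data / 255, path)
  invisible(path)
}

#' Separate the wing from its background
#'
#' Museum wing images are photographed on a near-uniform background. The
#' wing mask is either taken from the alpha channel (preferred when present:
#' any pixel with alpha > 0 is wing) or obtained by chroma keying: a pixel is
#' background when its Euclidean RGB distance to the key colour is at most
#' `tolerance`.
#'
#' @param image an `rgb_image`.
#' @param background either the string `"alpha"` or a length-3 numeric key
#'   colour on the 0--255 scale (e.g. `c(255, 0, 255)`).
#' @param tolerance nonnegative chroma-key tolerance in RGB distance units;
#'   ignored for `"alpha"`. Default 10, suited to near-uniform backgrounds.
#' @return logical matrix, `TRUE` where the pixel belongs to the wing.
#' @export
remove_background <- function(image, background = "alpha", tolerance = 10) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- image$data
  if (identical(background, "alpha")) {
    if (dim(arr)[3] != 4L)
      stop("alpha mask requested but the image has no alpha channel")
    mask <- arr[, , 4L] > 0
  } else {
    key <- as.numeric(background)
    if (length(key) != 3L || anyNA(key))
      stop("background must be \"alpha\" or a length-3 RGB key colour")
    if (tolerance < 0) stop("tolerance must be >= 0")
    d2 <- (arr[, , 1L] - key[1])^2 + (arr[, , 2L] - key[2])^2 +
      (arr[, , 3L] - key[3])^2
    mask <- d2 > tolerance^2
  }
  if (!any(mask))
    stop("empty mask: every pixel matches the background")
  mask
}

#' Convert an image to greyscale
#'
#' Uses ITU-R BT.601 luma weights by default (0.299 R + 0.587 G + 0.114 B),
#' the common default in imaging toolkits. Grey values are carried as reals
#' on the 0--255 scale, without rounding, so downstream contrast statistics
#' are not degraded by re-quantization.
#'
#' @param image an `rgb_image`.
#' @param weights length-3 channel weights summing to 1.
#' @return numeric matrix of grey values.
#' @export
to_grayscale <- function(image, weights = c(0.299, 0.587, 0.114)) {
  stopifnot(inherits(image, "rgb_image"))
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be three values summing to 1")
  arr <- image$data
  g <- arr[, , 1L] * weights[1] + arr[, , 2L] * weights[2] +
    arr[, , 3L] * weights[3]
  matrix(g, dim(arr)[1], dim(arr)[2])   # keep matrix shape for 1-pixel edges
}

#' RMS contrast of a masked grey image
#'
#' The RMS contrast of a wing is the sample standard deviation of the grey
#' values of its pixels,
#' \deqn{RMS = \left[\frac{1}{n-1}\sum_{i=1}^{n}(x_i - \bar x)^2\right]^{1/2},}
#' computed only over pixels inside the wing mask. A perfectly uniform wing
#' has RMS 0; such wings receive `log_rms = log(rms + 1e-6)` (with a warning)
#' rather than `-Inf`, so they remain usable in downstream log-scale models.
#'
#' @param gray numeric matrix of grey values on the 0--255 scale.
#' @param mask logical matrix of the same shape; `TRUE` marks wing pixels.
#'   Defaults to all pixels.
#' @return a list with `rms`, `log_rms` (natural log) and `n_pixels`.
#' @export
rms_contrast <- function(gray, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  if (!identical(dim(gray), dim(mask)))
    stop("mask shape must equal image shape")
  x <- gray[mask]
  if (length(x) < 2L)
    stop("insufficient pixels: RMS contrast needs at least 2 masked pixels")
  rms <- stats::sd(x)
  if (rms == 0) {
    warning("uniform wing (rms = 0); log_rms computed as log(rms + 1e-6)")
    log_rms <- log(rms + 1e-6)
  } else {
    log_rms <- log(rms)
  }
  list(rms = rms, log_rms = log_rms, n_pixels = length(x))
}

#' Score a manifest of wing images
#'
#' Batch front end: reads each image, removes its background, converts to
#' greyscale and computes RMS contrast. Species-level summaries average the
#' per-image RMS before the log transform, mirroring how manual scores are
#' averaged across a species' images.
#'
#' @param manifest data frame with columns `species_id`, `image_id`, `path`
#'   (and optionally `source`), or the path of a CSV with those columns.
#' @param background as in [remove_background()]; one setting for the batch.
#' @param tolerance chroma-key tolerance, see [remove_background()].
#' @return list with `images` (per-image `species_id`, `image_id`, `n_pixels`,
#'   `rms`, `log_rms`) and `species` (per-species mean `rms` and its log).
#' @export
score_images <- function(manifest, background = "alpha", tolerance = 10) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  needed <- c("species_id", "image_id", "path")
  if (!all(needed %in% names(manifest)))
    stop("manifest must have columns species_id, image_id, path")
  per_image <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_wing_image(manifest$path[i])
    mask <- remove_background(img, background, tolerance)
    res <- rms_contrast(to_grayscale(img), mask)
    data.frame(species_id = manifest$species_id[i],
               image_id = manifest$image_id[i],
               n_pixels = res$n_pixels, rms = res$rms, log_rms = res$log_rms)
  })
  images <- do.call(rbind, per_image)
  mean_rms <- tapply(images$rms, images$species_id, mean)
  species <- data.frame(species_id = names(mean_rms),
                        n_images = as.integer(table(images$species_id)[names(mean_rms)]),
                        rms = as.numeric(mean_rms),
                        log_rms = log(pmax(as.numeric(mean_rms), 1e-6)),
                        stringsAsFactors = FALSE)
  rownames(species) <- NULL
  list(images = images, species = species)
}
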