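#' Input-gradient saliency map
#'
#' Gradient of the target class's pre-softmax score with respect to the
#' input pixels, aggregated over channels by the maximum absolute value —
#' the vanilla gradient saliency method. The model must carry an
#' `input_shape` (set at construction) or the image's own dimensions must
#' match the model's input size.
#'
#' @param model a trained `cascade_model` over raster inputs.
#' @param image numeric matrix or array (height x width or height x width
#'   x channels), flattened in R's column-major order for the model.
#' @param target_class integer class index whose score is differentiated.
#' @return a `saliency_map`: non-negative numeric matrix (height x width).
#' @export
saliency_map <- function(model, image, target_class) {
  stopifnot(inherits(model, "cascade_model"))
  shape <- model$input_shape %||% dim(image)
  if (is.null(shape) || length(shape) < 2L)
    stop("model has no raster input shape; saliency needs image inputs")
  if (prod(shape) != model$input_dim)
    stop("image shape does not match the model's input size")
  x <- matrix(as.numeric(image), nrow = 1L)
  head <- model$heads[[length(model$heads)]]
  if (target_class < 1L || target_class > head$k)
    stop("target class outside 1..", head$k)
  fwd <- forward_cascade(model, x)
  dlogits <- matrix(0, 1L, head$k)
  dlogits[1L, target_class] <- 1
  grads <- backward_cascade(model, x, fwd, dlogits, want_input_grad = TRUE)
  g <- array(abs(as.numeric(grads$input)), dim = shape)
  grid <- if (length(shape) == 3L) apply(g, c(1L, 2L), max) else g
  structure(grid, class = c("saliency_map", class(grid)))
}

#' Threshold a saliency map into a binary mask
#'
#' Keeps the top `threshold_fraction` of pixels by salience: pixels at or
#' above the `(1 - threshold_fraction)` quantile of the map's values are
#' set true (ties at the threshold are included). A constant map yields an
#' all-true mask with a warning.
#'
#' @param map a saliency map (non-negative numeric matrix).
#' @param threshold_fraction fraction of pixels to keep, in (0, 1);
#'   default 0.15.
#' @return logical matrix of the same shape.
#' @export
mask_from_saliency <- function(map, threshold_fraction = 0.15) {
  map <- unclass(map)
  stopifnot(is.matrix(map), is.numeric(map))
  if (!all(is.finite(map)) || any(map < 0))
    stop("saliency map must be finite and non-negative")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie strictly in (0, 1)")
  if (max(map) == min(map)) {
    warning("constant saliency map: mask is all-true")
    return(matrix(TRUE, nrow(map), ncol(map)))
  }
  thr <- stats::quantile(map, probs = 1 - threshold_fraction, names = FALSE)
  map >= thr
}

check_mask_pair <- function(a, b) {
  if (!is.logical(a)) storage.mode(a) <- "logical"
  if (!is.logical(b)) storage.mode(b) <- "logical"
  if (!all(dim(a) == dim(b))) stop("mask shapes do not match")
  list(a = a, b = b)
}

#' Intersection over union of two binary masks
#'
#' Defined as 0 when both masks are empty.
#'
#' @param a,b logical matrices of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
iou <- function(a, b) {
  m <- check_mask_pair(a, b)
  uni <- sum(m$a | m$b)
  if (uni == 0) return(0)
  sum(m$a & m$b) / uni
}

#' Coverage accuracy: intersection over the annotation area
#'
#' How much of the annotated region the mask covers.
#'
#' @param mask logical matrix (thresholded saliency).
#' @param annotation logical matrix (expert annotation), non-empty.
#' @return scalar in `[0, 1]`.
#' @export
coverage_accuracy <- function(mask, annotation) {
  m <- check_mask_pair(mask, annotation)
  denom <- sum(m$b)
  if (denom == 0) stop("annotation mask is empty")
  sum(m$a & m$b) / denom
}

#' Coverage precision: intersection over the mask area
#'
#' How much of the mask falls inside the annotated region.
#'
#' @inheritParams coverage_accuracy
#' @return scalar in `[0, 1]`.
#' @export
coverage_precision <- function(mask, annotation) {
  m <- check_mask_pair(mask, annotation)
  denom <- sum(m$a)
  if (denom == 0) stop("saliency mask is empty")
  sum(m$a & m$b) / denom
}

#' Read a binary mask from a single-channel PNG
#'
#' Convention: 0 = background, anything above half intensity = foreground.
#'
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

#' Write a binary mask as a single-channel PNG (0 / 255)
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}
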