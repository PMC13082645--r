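# Per-frame segmentation with a pluggable backend. The built-in backend is
# a classical threshold + distance-transform watershed pipeline; an
# "oracle" backend returns (optionally perturbed) ground-truth masks, and
# an adapter seam is provided for external learned segmenters.

#' Segment one pre-processed frame (built-in backend)
#'
#' Pipeline: Gaussian smoothing, global threshold (Otsu by default), hole
#' filling, then a watershed on the sum of the distance transform and the
#' (weighted) smoothed intensity, so that both shape necks and the dim
#' seams between touching cells deepen the saddles; components below
#' `min_area_px` are discarded. Deterministic given the image and
#' parameters.
#'
#' @param image matrix in `[0, 1]` (see [preprocess_frame()]).
#' @param sigma Gaussian smoothing sd in pixels.
#' @param threshold `"otsu"` or a fixed numeric threshold in `(0, 1)`.
#' @param tolerance watershed tolerance (minimum saddle-to-peak depth
#'   separating two objects); larger values merge more.
#' @param min_area_px discard components smaller than this.
#' @param intensity_weight weight of the smoothed intensity added to the
#'   distance transform before the watershed (0 gives a pure
#'   distance-transform watershed).
#' @return integer label matrix (0 = background).
#' @export
segment_frame <- function(image, sigma = 1, threshold = "otsu",
                          tolerance = 0.5, min_area_px = 30,
                          intensity_weight = 4) {
  stopifnot(is.matrix(image))
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(image),
                                          sigma = sigma))
  thr <- if (identical(threshold, "otsu")) {
    rg <- range(sm)
    if (diff(rg) < 1e-12) Inf else EBImage::otsu(EBImage::Image(sm), range = rg)
  } else threshold
  bw <- sm > thr
  if (!any(bw)) return(matrix(0L, nrow(image), ncol(image)))
  bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1)))
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(bw)))
  relief <- dm + intensity_weight * sm * bw
  lab <- EBImage::imageData(EBImage::watershed(EBImage::Image(relief),
                                               tolerance = tolerance))
  drop_small_labels(matrix(as.integer(lab), nrow(image)), min_area_px)
}

drop_small_labels <- function(lab, min_area_px) {
  if (!any(lab > 0)) return(lab)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area_px)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment a whole movie
#'
#' @param movie a `movie`.
#' @param backend `"builtin"` (see [segment_frame()]); `"oracle"` returns
#'   ground-truth masks, perturbed at `params$noise_level` if nonzero;
#'   `"external"` calls `params$segment_fun(image, ...)` if supplied, and
#'   raises "backend unavailable" otherwise (the adapter seam for learned
#'   segmenters, which this package does not bundle).
#' @param params list of backend parameters. For `"builtin"`,
#'   `preprocess = TRUE` runs [preprocess_frame()] first, and the
#'   [segment_frame()] arguments may be overridden. For `"oracle"`, supply
#'   `truth` (a `ground_truth`), optional `noise_level` and `seed`.
#' @return list of label matrices, one per frame.
#' @export
segment_movie <- function(movie, backend = c("builtin", "oracle", "external"),
                          params = list()) {
  backend <- match.arg(backend)
  if (backend == "oracle") {
    truth <- params$truth
    if (is.null(truth)) stop2("oracle backend requires params$truth")
    nl <- params$noise_level %||% 0
    if (nl == 0) return(truth$masks)
    return(perturb_masks(truth, nl, seed = params$seed))
  }
  if (backend == "external") {
    fun <- params$segment_fun
    if (is.null(fun)) stop2("backend unavailable: no external segmenter configured")
    return(lapply(movie$frames, fun))
  }
  pp <- params$preprocess %||% TRUE
  seg_args <- params[intersect(names(params),
                               c("sigma", "threshold", "tolerance",
                                 "min_area_px", "intensity_weight"))]
  lapply(movie$frames, function(f) {
    if (pp) f <- preprocess_frame(f)
    do.call(segment_frame, c(list(f), seg_args))
  })
}
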