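# Readers/writers for all on-disk formats (TIFF stacks, label masks, the
# single-cell table, lineage trees) and the image pre-processing step.

#' Movie container
#'
#' A movie is an ordered list of 2-D intensity matrices plus calibration:
#' frame interval `dt_h` (hours) and physical field side `field_um`
#' (micrometres). Pixel size is `field_um / px_per_side` um/px. Frame 0 is
#' the first acquisition; internal coordinates are 0-based (row, col).
#'
#' @param frames list of numeric matrices with identical shape (or `NULL`).
#' @param dt_h frame interval (h).
#' @param field_um field-of-view side (um).
#' @param px_per_side image side in pixels; defaults to the frame width.
#' @param validate check frame shapes.
#' @return object of class `movie`.
#' @export
new_movie <- function(frames, dt_h = 0.5, field_um = 1330,
                      px_per_side = NULL, validate = TRUE) {
  if (validate) {
    if (!length(frames)) stop2("empty stack")
    shp <- dim(frames[[1]])
    ok <- vapply(frames, function(f) identical(dim(f), shp), logical(1))
    if (!all(ok)) stop2("inconsistent frame shapes")
    if (is.null(px_per_side)) px_per_side <- shp[2]
  }
  if (dt_h <= 0) stop2("dt_h must be positive")
  if (is.null(px_per_side)) stop2("px_per_side required when frames are NULL")
  structure(list(frames = frames, dt_h = dt_h, field_um = field_um,
                 px_per_side = as.integer(px_per_side)),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  cat(sprintf("movie: %d frames, %d px (%.1f um), dt = %g h\n",
              length(x$frames), x$px_per_side, x$field_um, x$dt_h))
  invisible(x)
}

#' Micrometres per pixel of a movie
#' @param movie a `movie`.
#' @export
um_per_px <- function(movie) movie$field_um / movie$px_per_side

tiff_to_matrix <- function(x) {
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' Read an image stack
#'
#' Accepts either a multi-page TIFF or a directory of single-frame TIFFs
#' ordered by filename; both yield the same movie.
#'
#' @param path file or directory.
#' @param dt_h,field_um calibration to attach.
#' @return a [new_movie()].
#' @export
read_stack <- function(path, dt_h = 0.5, field_um = 1330) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop2("empty stack: no TIFF files in ", path)
    frames <- lapply(files, function(f) tiff_to_matrix(tiff::readTIFF(f)))
  } else {
    if (!file.exists(path)) stop2("unreadable file: ", path)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop2("unreadable file: ", path))
    if (!is.list(pages)) pages <- list(pages)
    if (!length(pages)) stop2("empty stack: ", path)
    frames <- lapply(pages, tiff_to_matrix)
  }
  new_movie(frames, dt_h = dt_h, field_um = field_um)
}

#' Write a movie as a multi-page TIFF
#'
#' Frames are stored as 16-bit; values are clipped to `[0, 65535]`.
#'
#' @param movie a `movie`.
#' @param path output file.
#' @export
write_stack <- function(movie, path) {
  frames <- lapply(movie$frames, function(f)
    matrix(pmin(1, pmax(0, f / 65535)), nrow(f), ncol(f)))
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' Read / write label masks
#'
#' Label masks are 16-bit single-channel TIFFs (one file per frame in a
#' directory, or one multi-page file); label 0 is background. The
#' round-trip is lossless for labels up to 65535.
#'
#' @param masks list of integer matrices.
#' @param path multi-page TIFF file path.
#' @return `read_masks`: list of integer label matrices.
#' @export
write_masks <- function(masks, path) {
  mx <- max(0, vapply(masks, max, numeric(1)))
  if (mx > 65535) stop2("labels exceed 16-bit range")
  tiff::writeTIFF(lapply(masks, function(m) m / 65535), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    p <- tiff_to_matrix(p)
    matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
  })
}

#' Pre-process a raw frame
#'
#' Background is estimated by a morphological rolling-ball opening (disc of
#' `radius_px`, computed on a downsampled copy for speed) and subtracted;
#' the result is rescaled so that its (`p_lo`, `p_hi`) percentiles map to
#' (0, 1), then clipped. A constant image returns all zeros.
#'
#' @param image 2-D numeric matrix with finite values.
#' @param radius_px rolling-ball radius in pixels (should exceed the largest
#'   cell radius).
#' @param p_lo,p_hi rescaling percentiles in `[0, 1]`.
#' @param downsample integer factor for the background estimate.
#' @return matrix in `[0, 1]`.
#' @export
preprocess_frame <- function(image, radius_px = 40, p_lo = 0.05, p_hi = 0.999,
                             downsample = 4) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  bg <- rolling_background(image, radius_px, downsample)
  x <- image - bg
  qs <- stats::quantile(x, c(p_lo, p_hi), names = FALSE)
  if (qs[2] - qs[1] < .Machine$double.eps * max(1, abs(qs[2])))
    return(matrix(0, nrow(image), ncol(image)))
  matrix(pmin(1, pmax(0, (x - qs[1]) / (qs[2] - qs[1]))),
         nrow(image), ncol(image))
}

# Rolling-ball background: grey opening with a disc, on a downsampled grid.
rolling_background <- function(image, radius_px, downsample) {
  n <- nrow(image); m <- ncol(image)
  f <- max(1L, as.integer(downsample))
  ri <- seq(1, n, by = f); ci <- seq(1, m, by = f)
  small <- image[ri, ci, drop = FALSE]
  r_small <- max(1, round(radius_px / f))
  brush <- EBImage::makeBrush(2 * r_small + 1, shape = "disc")
  op <- EBImage::opening(EBImage::Image(small), brush)
  op <- EBImage::imageData(op)
  # bilinear upsample back to full resolution
  interp_rows <- stats::approx(ri, seq_along(ri), xout = seq_len(n),
                               rule = 2)$y
  interp_cols <- stats::approx(ci, seq_along(ci), xout = seq_len(m),
                               rule = 2)$y
  bilinear_sample(op, interp_rows, interp_cols)
}

bilinear_sample <- function(img, rows, cols) {
  r0 <- pmin(floor(rows), nrow(img) - 1); r0 <- pmax(r0, 1)
  c0 <- pmin(floor(cols), ncol(img) - 1); c0 <- pmax(c0, 1)
  fr <- rows - r0; fc <- cols - c0
  a <- img[r0, c0, drop = FALSE]; b <- img[r0 + 1, c0, drop = FALSE]
  c_ <- img[r0, c0 + 1, drop = FALSE]; d <- img[r0 + 1, c0 + 1, drop = FALSE]
  fr_m <- matrix(fr, length(rows), length(cols))
  fc_m <- matrix(fc, length(rows), length(cols), byrow = TRUE)
  a * (1 - fr_m) * (1 - fc_m) + b * fr_m * (1 - fc_m) +
    c_ * (1 - fr_m) * fc_m + d * fr_m * fc_m
}

#' Export the single-cell table
#'
#' One row per (cell, frame) with position, surface area, intensity, and
#' origin/fate/lineage metadata. Columns (stable order): `cell_id`,
#' `frame`, `time_h`, `x_um`, `y_um`, `area_um2`, `mean_intensity`,
#' `origin`, `fate`, `mother_id`, `tree_id`, `category`.
#'
#' @param tracks a `track_set` (see [track_movie()] / [link_tracks()]).
#' @param path CSV output path.
#' @export
write_cell_table <- function(tracks, path) {
  tab <- cell_table(tracks)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @return `cell_table`: the table as a data frame.
#' @export
cell_table <- function(tracks) {
  obs <- tracks$obs
  cells <- tracks$cells
  if (!nrow(obs)) {
    return(data.frame(cell_id = integer(0), frame = integer(0),
                      time_h = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0), origin = character(0),
                      fate = character(0), mother_id = integer(0),
                      tree_id = integer(0), category = character(0)))
  }
  i <- match(obs$cell_id, cells$cell_id)
  data.frame(cell_id = obs$cell_id,
             frame = obs$frame,
             time_h = obs$frame * tracks$dt_h,
             x_um = obs$x_um,
             y_um = obs$y_um,
             area_um2 = obs$area_um2,
             mean_intensity = obs$mean_intensity %||% rep(NA_real_, nrow(obs)),
             origin = cells$origin[i],
             fate = cells$fate[i],
             mother_id = cells$mother_id[i],
             tree_id = (cells$tree_id %||% rep(NA_integer_, nrow(cells)))[i],
             category = (cells$category %||% rep(NA_character_, nrow(cells)))[i])
}

#' Read a single-cell table back into a track set
#'
#' Inverse of [write_cell_table()] up to numeric round-trip.
#'
#' @param path CSV path.
#' @param dt_h frame interval; if `NULL`, inferred from `time_h`.
#' @param um_per_px pixel size to attach (optional).
#' @return a `track_set`.
#' @export
read_cell_table <- function(path, dt_h = NULL, um_per_px = NA_real_) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(dt_h)) {
    dt_h <- if (nrow(tab) && any(tab$frame > 0))
      tab$time_h[which(tab$frame > 0)[1]] / tab$frame[which(tab$frame > 0)[1]]
    else 0.5
  }
  cells <- unique(tab[, c("cell_id", "origin", "fate", "mother_id",
                          "tree_id", "category")])
  agg <- split(tab$frame, tab$cell_id)
  cells$birth_frame <- vapply(agg[as.character(cells$cell_id)], min, numeric(1))
  cells$end_frame <- vapply(agg[as.character(cells$cell_id)], max, numeric(1))
  # daughters from mother_id
  cells$daughter1 <- NA_integer_; cells$daughter2 <- NA_integer_
  kids <- split(cells$cell_id, cells$mother_id)
  for (m in names(kids)) {
    i <- match(as.integer(m), cells$cell_id)
    if (is.na(i)) next
    d <- sort(kids[[m]])
    cells$daughter1[i] <- d[1]
    if (length(d) > 1) cells$daughter2[i] <- d[2]
  }
  rownames(cells) <- NULL
  new_track_set(cells = cells,
                obs = tab[, c("cell_id", "frame", "x_um", "y_um",
                              "area_um2", "mean_intensity")],
                dt_h = dt_h, um_per_px = um_per_px,
                n_frames = max(tab$frame) + 1L)
}

#' Export lineage trees as nested JSON
#'
#' Each tree is a nested object `{"id": ..., "children": [...]}`.
#'
#' @param trees result of [build_trees()].
#' @param tracks the `track_set` the trees were built from.
#' @param path JSON output path.
#' @export
write_trees_json <- function(trees, tracks, path) {
  cells <- tracks$cells
  nest <- function(id) {
    i <- match(id, cells$cell_id)
    kids <- c(cells$daughter1[i], cells$daughter2[i])
    kids <- kids[!is.na(kids)]
    list(id = id,
         children = lapply(kids, nest))
  }
  out <- lapply(trees$roots, nest)
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

#' Export lineage trees in Newick format
#'
#' Branch lengths are cell lifetimes in hours; tip/node labels are cell
#' ids. One tree per line; single-cell trees become single-leaf trees.
#'
#' @inheritParams write_trees_json
#' @export
write_trees_newick <- function(trees, tracks, path) {
  cells <- tracks$cells
  life_h <- (cells$end_frame - cells$birth_frame + 1) * tracks$dt_h
  rec <- function(id) {
    i <- match(id, cells$cell_id)
    kids <- c(cells$daughter1[i], cells$daughter2[i])
    kids <- kids[!is.na(kids)]
    lab <- sprintf("c%d:%g", id, life_h[i])
    if (!length(kids)) lab
    else sprintf("(%s)%s", paste(vapply(kids, rec, character(1)),
                                 collapse = ","), lab)
  }
  lines <- vapply(trees$roots, function(r) paste0("(", rec(r), ");"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value configuration; unknown keys are kept so downstream
#' modules can pick up their own parameters.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop2("missing config file: ", path)
  yaml::read_yaml(path)
}
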