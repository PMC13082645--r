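# Quantitative single-cell and population parameters: exponential growth
# and doubling time, MSD-based effective diffusion, surface areas,
# probability-to-exceed curves and bootstrap errors on their medians.

#' Fit exponential population growth
#'
#' Log-linear least squares of `log(counts)` against time for the model
#' N(t) = N0 * exp(r t); the doubling time is Td = ln(2) / r. A negative
#' rate yields a negative doubling time, flagged as decay; a zero rate an
#' infinite one.
#'
#' @param times_h time points (hours), at least 3.
#' @param counts cell counts, all at least 1.
#' @return list of class `growth_fit`: `N0`, `r` (1/h), `Td` (h),
#'   `residual` (residual sum of squares on the log scale), `decay`.
#' @export
fit_growth <- function(times_h, counts) {
  if (length(times_h) != length(counts)) stop2("length mismatch")
  if (length(times_h) < 3) stop2("need at least 3 time points")
  if (any(counts < 1)) stop2("counts below 1: log-linear fit undefined")
  fit <- stats::lm(log(counts) ~ times_h)
  r <- unname(stats::coef(fit)[2])
  structure(list(N0 = unname(exp(stats::coef(fit)[1])),
                 r = r,
                 Td = log(2) / r,
                 residual = sum(stats::residuals(fit)^2),
                 decay = r < 0),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("exponential growth: N0 = %.2f, r = %.4g /h, Td = %.1f h%s\n",
              x$N0, x$r, x$Td, if (x$decay) " (decay)" else ""))
  invisible(x)
}

#' Effective diffusion coefficient of a trajectory
#'
#' Per-step instantaneous estimates d_i = (dx_i^2 + dy_i^2) / dt are
#' summarized by their median over the whole trajectory, which suppresses
#' abrupt displacements during mitosis and rare tracking errors. Note that
#' for an ideal 2-D Brownian walk with true coefficient D the per-step
#' mean is 4 D, so the median of the exponential-like step distribution
#' converges to 4 ln(2) D; the estimator is used as a robust comparative
#' motility index, as is.
#'
#' @param xy_um two-column matrix of positions (um), one row per frame.
#' @param dt_h frame interval (h).
#' @return list of class `diffusion_estimate`: `D` (um^2/h), `n_steps`.
#' @export
diffusion_coefficient <- function(xy_um, dt_h) {
  xy_um <- as.matrix(xy_um)
  if (nrow(xy_um) < 2) stop2("trajectory too short")
  d <- diff(xy_um)
  per_step <- (d[, 1]^2 + d[, 2]^2) / dt_h
  structure(list(D = stats::median(per_step), n_steps = length(per_step)),
            class = "diffusion_estimate")
}

#' Per-cell diffusion coefficients of a track set
#'
#' @param tracks a `track_set`.
#' @param min_steps minimum number of displacements required.
#' @return data frame `cell_id`, `D_um2_h`, `n_steps`.
#' @export
cell_diffusion <- function(tracks, min_steps = 2) {
  obs <- tracks$obs[order(tracks$obs$cell_id, tracks$obs$frame), ]
  rows <- lapply(split(obs, obs$cell_id), function(o) {
    if (nrow(o) < min_steps + 1) return(NULL)
    est <- diffusion_coefficient(cbind(o$x_um, o$y_um), tracks$dt_h)
    data.frame(cell_id = o$cell_id[1], D_um2_h = est$D, n_steps = est$n_steps)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cell_id = integer(0),
                                      D_um2_h = numeric(0),
                                      n_steps = integer(0))
  rownames(out) <- NULL
  out
}

#' Surface area of a segmented cell
#'
#' Pixel count scaled by the squared pixel size.
#'
#' @param mask binary object mask.
#' @param um_per_px pixel side in micrometres.
#' @return area in um^2.
#' @export
cell_area_um2 <- function(mask, um_per_px) {
  stopifnot(um_per_px > 0)
  n <- sum(mask > 0)
  if (n == 0) stop2("empty mask")
  n * um_per_px^2
}

#' Probability-to-exceed (complementary CDF) curve
#'
#' PTE(x) = P(X >= x) over the sample: 1 at the sample minimum, decreasing
#' to 1/n at the maximum. The median is read off where the curve crosses
#' 0.5, using mid-point (Hazen) plotting positions so that for odd n it
#' equals the sample middle value.
#'
#' @param values finite numeric sample (at least one value).
#' @return list of class `pte_curve`: `support` (sorted values), `pte`,
#'   `median`, `n`.
#' @export
pte <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop2("empty input")
  x <- sort(values)
  n <- length(x)
  # PTE at a value is the fraction of the sample >= it; ties share rank
  ux <- unique(x)
  upte <- vapply(ux, function(v) mean(x >= v), numeric(1))
  hazen <- (n - seq_len(n) + 0.5) / n    # decreasing in i
  med <- if (n == 1) x else stats::approx(rev(hazen), rev(x), xout = 0.5,
                                          rule = 2, ties = "ordered")$y
  structure(list(support = ux, pte = upte, median = med, n = n,
                 values = x, positions = hazen),
            class = "pte_curve")
}

#' @export
print.pte_curve <- function(x, ...) {
  cat(sprintf("PTE curve: n = %d, median = %.4g\n", x$n, x$median))
  invisible(x)
}

#' Evaluate a PTE curve at arbitrary points
#' @param curve a `pte_curve`.
#' @param x points.
#' @return P(X >= x) for each point.
#' @export
pte_at <- function(curve, x) {
  vapply(x, function(v) mean(curve$values >= v), numeric(1))
}

#' Bootstrap error of a sample median
#'
#' Two-stage Monte-Carlo resampling: a pool of `n_pool` values is drawn
#' with replacement from the empirical distribution, then `n_resamples`
#' subsamples of `resample_size` are drawn from the pool and the standard
#' deviation of their medians is reported. Note the error reflects
#' `resample_size`, not the original sample size; this convention is kept
#' as a fixed part of the analysis so errors are comparable across
#' conditions.
#'
#' @param values observed sample.
#' @param n_pool pool size (default 1e5).
#' @param n_resamples number of subsamples (default 1e3).
#' @param resample_size subsample size (default 100).
#' @param seed optional seed for reproducibility.
#' @return standard deviation of the resampled medians.
#' @export
bootstrap_median_err <- function(values, n_pool = 1e5, n_resamples = 1e3,
                                 resample_size = 100, seed = NULL) {
  values <- values[is.finite(values)]
  if (!length(values)) stop2("empty input")
  run <- function() {
    pool <- sample(values, n_pool, replace = TRUE)
    meds <- vapply(seq_len(n_resamples), function(i)
      stats::median(sample(pool, resample_size, replace = TRUE)),
      numeric(1))
    stats::sd(meds)
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

#' Mean surface area over time for one category
#'
#' Per frame, mean and standard deviation of the areas of alive cells of
#' the category; frames with no such cells are omitted.
#'
#' @param tracks classified `track_set`.
#' @param category cell category (`"PROLIFERATIVE"`, `"ITA"`, `"RPTA"`,
#'   `"LTA"`), or `NULL` for all cells.
#' @return data frame `frame`, `time_h`, `mean_area_um2`, `sd_area_um2`,
#'   `n`.
#' @export
mean_area_over_time <- function(tracks, category = NULL) {
  obs <- tracks$obs
  if (!is.null(category)) {
    ids <- tracks$cells$cell_id[!is.na(tracks$cells$category) &
                                  tracks$cells$category == category]
    obs <- obs[obs$cell_id %in% ids, , drop = FALSE]
  }
  if (!nrow(obs)) {
    return(data.frame(frame = integer(0), time_h = numeric(0),
                      mean_area_um2 = numeric(0), sd_area_um2 = numeric(0),
                      n = integer(0)))
  }
  sp <- split(obs$area_um2, obs$frame)
  frames <- as.integer(names(sp))
  data.frame(frame = frames,
             time_h = frames * tracks$dt_h,
             mean_area_um2 = vapply(sp, mean, numeric(1)),
             sd_area_um2 = vapply(sp, function(v)
               if (length(v) > 1) stats::sd(v) else 0, numeric(1)),
             n = lengths(sp),
             row.names = NULL)
}
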