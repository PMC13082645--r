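# Synthetic time-lapse movie generator with exact ground truth.
#
# Cells are ellipses with smoothly varying orientation/aspect moving by
# reflected 2-D Brownian steps; divisions split the mother along its minor
# axis into two half-area daughters placed adjacently. Fate categories
# (proliferative / transiently arrested / long-term arrested) control cycle
# durations, motility and area dynamics, emulating the structure of
# irradiated epithelial-cell movies.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_movie()]. Defaults
#' describe a 4-day acquisition at 30-minute intervals over a
#' 1330 um x 1330 um field of view, with cell-cycle durations drawn from a
#' truncated Gaussian centred at 23 h (sd 9 h) on the normal-cycle window
#' 10-40 h.
#'
#' @param image_size_px square frame side in pixels.
#' @param field_um physical side length of the field of view (um).
#' @param dt_h frame interval in hours.
#' @param duration_h total simulated time in hours; the movie has
#'   `floor(duration_h / dt_h) + 1` frames.
#' @param n_initial_cells number of founder cells at frame 0.
#' @param dose_Gy nominal dose; only used to derive `category_probs` when
#'   they are not given explicitly (see [dose_category_probs()]).
#' @param category_probs named probabilities over tree categories
#'   `PROLIFERATIVE_TREE`, `TA_TREE`, `LTA`; must sum to 1.
#' @param cycle_mean_h,cycle_sd_h Gaussian cell-cycle parameters (hours).
#' @param cycle_min_h,cycle_max_h truncation window for normal cycles.
#' @param ita_delay_range_h interval (hours) for the arrested first cycle of
#'   transiently arrested founders; lower bound must exceed `cycle_max_h`.
#' @param diffusion_by_category true Brownian coefficients D (um^2/h) per
#'   cell category.
#' @param area_dynamics list of area-model parameters: `base_um2` (typical
#'   proliferative area), `prolif_swell` (fractional pre-division swell),
#'   `relax_h` (post-division recovery time), `ita_peak_factor` and
#'   `ita_rise_h` (swell-then-plateau of arrested founders),
#'   `lta_growth_per_h` (fractional linear growth of long-term arrested
#'   cells).
#' @param noise rendering parameters: `bg_level`, `grad_amp`, `grad_dir_deg`,
#'   `cell_level`, `cell_level_cv`, `read_sd`, `shot_scale`, all in 16-bit
#'   digital numbers.
#' @param allow_exit if `TRUE`, borders are absorbing instead of reflecting
#'   and cells may leave the field.
#' @param entry_rate_per_h expected number of cells entering from the
#'   boundary per hour (only when `allow_exit` is `TRUE`).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(image_size_px = 256,
                       field_um = 1330,
                       dt_h = 0.5,
                       duration_h = 96,
                       n_initial_cells = 8,
                       dose_Gy = 0,
                       category_probs = NULL,
                       cycle_mean_h = 23,
                       cycle_sd_h = 9,
                       cycle_min_h = 10,
                       cycle_max_h = 40,
                       ita_delay_range_h = c(45, 85),
                       diffusion_by_category = c(PROLIFERATIVE = 0.15,
                                                 ITA = 0.02,
                                                 RPTA = 0.20,
                                                 LTA = 0.01),
                       area_dynamics = list(),
                       noise = list(),
                       allow_exit = FALSE,
                       entry_rate_per_h = 0,
                       seed = 1L) {
  if (is.null(category_probs)) category_probs <- dose_category_probs(dose_Gy)
  area_defaults <- list(base_um2 = 4500, prolif_swell = 0.10, relax_h = 5,
                        ita_peak_factor = 3, ita_rise_h = 40,
                        lta_growth_per_h = 0.10)
  noise_defaults <- list(bg_level = 300, grad_amp = 80, grad_dir_deg = 30,
                         cell_level = 2000, cell_level_cv = 0.15,
                         read_sd = 40, shot_scale = 1,
                         edge_shade_px = 3, edge_shade_floor = 0.35)
  cfg <- list(image_size_px = as.integer(image_size_px), field_um = field_um,
              dt_h = dt_h, duration_h = duration_h,
              n_initial_cells = as.integer(n_initial_cells),
              dose_Gy = dose_Gy, category_probs = category_probs,
              cycle_mean_h = cycle_mean_h, cycle_sd_h = cycle_sd_h,
              cycle_min_h = cycle_min_h, cycle_max_h = cycle_max_h,
              ita_delay_range_h = ita_delay_range_h,
              diffusion_by_category = diffusion_by_category,
              area_dynamics = utils::modifyList(area_defaults, area_dynamics),
              noise = utils::modifyList(noise_defaults, noise),
              allow_exit = isTRUE(allow_exit),
              entry_rate_per_h = entry_rate_per_h,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$category_probs
  if (!all(TREE_CATEGORIES %in% names(p)))
    stop2("category_probs must be named over ",
          paste(TREE_CATEGORIES, collapse = ", "))
  if (abs(sum(p) - 1) > 1e-9) stop2("category_probs must sum to 1")
  if (any(p < 0)) stop2("category_probs must be nonnegative")
  if (cfg$dt_h <= 0) stop2("dt_h must be positive")
  if (cfg$duration_h < cfg$dt_h) stop2("duration_h must be at least dt_h")
  if (cfg$n_initial_cells < 1) stop2("n_initial_cells must be at least 1")
  if (cfg$ita_delay_range_h[1] <= cfg$cycle_max_h)
    stop2("ita_delay_range_h lower bound must exceed cycle_max_h")
  if (cfg$cycle_min_h >= cfg$cycle_max_h)
    stop2("cycle_min_h must be below cycle_max_h")
  if (!all(CELL_CATEGORIES %in% names(cfg$diffusion_by_category)))
    stop2("diffusion_by_category must be named over ",
          paste(CELL_CATEGORIES, collapse = ", "))
  invisible(cfg)
}

#' Dose-dependent tree-category mixture
#'
#' Returns the probabilities of the three tree categories as a function of
#' dose, interpolated between anchor mixtures that follow the published
#' per-dose founder counts: proliferation dominates at 0 Gy while arrested
#' categories dominate at 4-5 Gy.
#'
#' @param dose_Gy nonnegative dose in Gy; values above 5 use the 5 Gy mixture.
#' @return named numeric vector over `PROLIFERATIVE_TREE`, `TA_TREE`, `LTA`.
#' @export
dose_category_probs <- function(dose_Gy) {
  stopifnot(is.numeric(dose_Gy), length(dose_Gy) == 1, dose_Gy >= 0)
  anchors <- rbind(
    `0` = c(0.739, 0.071, 0.190),
    `1` = c(0.770, 0.055, 0.175),
    `2` = c(0.493, 0.107, 0.399),
    `3` = c(0.244, 0.173, 0.584),
    `4` = c(0.204, 0.185, 0.611),
    `5` = c(0.209, 0.146, 0.645))
  d <- min(dose_Gy, 5)
  lo <- floor(d); hi <- ceiling(d); w <- d - lo
  p <- (1 - w) * anchors[lo + 1, ] + w * anchors[hi + 1, ]
  p <- p / sum(p)
  stats::setNames(p, TREE_CATEGORIES)
}

#' Sample a cell-cycle duration
#'
#' Proliferative and re-proliferating (RPTA) cells draw from a Gaussian
#' truncated to the normal-cycle window; transiently arrested founders (ITA)
#' draw their delayed first cycle uniformly from `ita_delay_range_h`.
#' Long-term arrested cells do not divide.
#'
#' Uses the current R random-number stream; seed it (or call from
#' [simulate_movie()]) for reproducibility.
#'
#' @param category one of `"PROLIFERATIVE"`, `"RPTA"`, `"ITA"`.
#' @param config a [sim_config()].
#' @param n number of draws.
#' @return durations in hours.
#' @export
sample_cycle_duration <- function(category, config, n = 1) {
  category <- match.arg(category, CELL_CATEGORIES)
  if (category == "LTA") stop2("non-dividing category")
  if (category == "ITA")
    return(stats::runif(n, config$ita_delay_range_h[1],
                        config$ita_delay_range_h[2]))
  rtrunc_norm(n, config$cycle_mean_h, config$cycle_sd_h,
              config$cycle_min_h, config$cycle_max_h)
}

# Truncated-normal draws by rejection; exact for sd -> 0 (returns the mean,
# which must lie inside the window).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) {
    if (mean < lo || mean > hi) stop2("degenerate mean outside window")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Evaluate and restore the caller's RNG state around seeded code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Target area (um^2) of a cell at time t_h after its birth.
target_area <- function(category, birth_area, t_h, cycle_h, ad) {
  if (category == "LTA")
    return(birth_area * (1 + ad$lta_growth_per_h * t_h))
  if (category == "ITA")
    return(birth_area * (1 + (ad$ita_peak_factor - 1) *
                           min(1, t_h / ad$ita_rise_h)))
  # proliferative / RPTA: relax to base, then swell before division
  a <- ad$base_um2 + (birth_area - ad$base_um2) * max(0, 1 - t_h / ad$relax_h)
  if (is.finite(cycle_h)) {
    sw <- max(0, (t_h - 0.8 * cycle_h) / (0.2 * cycle_h))
    a <- a * (1 + ad$prolif_swell * min(1, sw))
  }
  a
}

# Expected field coverage at the end of the movie; used to refuse
# configurations that would grow confluent.
expected_end_coverage <- function(cfg) {
  ad <- cfg$area_dynamics
  p <- cfg$category_probs
  dur <- cfg$duration_h
  n_gen <- dur / cfg$cycle_mean_h
  area_prolif <- ad$base_um2 * 2^n_gen               # population doubles per cycle
  mean_delay <- mean(cfg$ita_delay_range_h)
  n_gen_ta <- max(0, (dur - mean_delay)) / cfg$cycle_mean_h
  area_ta <- ad$base_um2 * max(ad$ita_peak_factor / 2, 2^n_gen_ta) * 2
  area_lta <- ad$base_um2 * (1 + ad$lta_growth_per_h * dur)
  total <- cfg$n_initial_cells *
    (p["PROLIFERATIVE_TREE"] * area_prolif +
       p["TA_TREE"] * area_ta + p["LTA"] * area_lta)
  unname(total / cfg$field_um^2)
}

#' Simulate a fluorescence movie with ground truth
#'
#' Generates a synthetic single-channel movie together with exact per-frame
#' label masks, the true cell table (positions, areas, mother/daughter
#' links) and the true lineage-tree partition.
#'
#' @param config a [sim_config()].
#' @param render if `FALSE`, skip intensity rendering (masks and truth only;
#'   the movie's frames are all-zero placeholders are not created, `frames`
#'   is `NULL`).
#' @return list with elements `movie` (a [new_movie()] or `NULL` frames) and
#'   `truth` (class `ground_truth`: `masks`, `cells`, `obs`, `trees`).
#' @export
simulate_movie <- function(config, render = TRUE) {
  validate_sim_config(config)
  cov <- expected_end_coverage(config)
  if (cov > 0.9)
    stop2("over-confluent configuration: expected end coverage ",
          sprintf("%.0f%%", 100 * cov))
  with_seed(config$seed, simulate_movie_impl(config, render))
}

simulate_movie_impl <- function(cfg, render) {
  n_frames <- floor(cfg$duration_h / cfg$dt_h) + 1
  size <- cfg$image_size_px
  upp <- cfg$field_um / size
  ad <- cfg$area_dynamics
  L <- cfg$field_um

  # cell registry (grows as cells divide); positions in um
  reg <- list()
  new_cell <- function(id, cat, tree_cat, birth_frame, mother, x, y,
                       birth_area, theta, aspect) {
    cycle <- if (cat == "LTA") Inf else
      sample_cycle_duration(cat, cfg, 1)
    div_frame <- if (is.finite(cycle))
      birth_frame + max(1L, as.integer(round(cycle / cfg$dt_h))) else NA_integer_
    if (!is.na(div_frame) && div_frame > n_frames - 1) div_frame <- NA_integer_
    list(id = id, cat = cat, tree_cat = tree_cat,
         birth_frame = birth_frame, end_frame = NA_integer_,
         mother = mother, daughters = integer(0),
         x = x, y = y, birth_area = birth_area,
         cycle_h = cycle, div_frame = div_frame,
         theta = theta, aspect = aspect,
         D = unname(cfg$diffusion_by_category[[cat]]),
         fate = NA_character_,
         origin = if (is.na(mother)) "INITIAL" else "DAUGHTER")
  }

  # initial placement with pairwise separation
  r0 <- sqrt(ad$base_um2 / pi)
  pos <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(pos) < cfg$n_initial_cells) {
    cand <- stats::runif(2, 2.5 * r0, L - 2.5 * r0)
    ok <- nrow(pos) == 0 ||
      all(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2) > 2.4 * r0)
    if (ok) pos <- rbind(pos, cand)
    tries <- tries + 1
    if (tries > 400 * cfg$n_initial_cells)
      stop2("over-confluent configuration: cannot place initial cells")
  }
  tree_cat0 <- sample(TREE_CATEGORIES, cfg$n_initial_cells, replace = TRUE,
                      prob = cfg$category_probs[TREE_CATEGORIES])
  root_cell_cat <- c(PROLIFERATIVE_TREE = "PROLIFERATIVE",
                     TA_TREE = "ITA", LTA = "LTA")
  for (i in seq_len(cfg$n_initial_cells)) {
    reg[[i]] <- new_cell(i, root_cell_cat[[tree_cat0[i]]], tree_cat0[i],
                         0L, NA_integer_, pos[i, 1], pos[i, 2],
                         ad$base_um2,
                         theta = stats::runif(1, 0, pi),
                         aspect = stats::runif(1, 0.8, 1.2))
  }
  next_id <- cfg$n_initial_cells + 1L
  alive <- seq_len(cfg$n_initial_cells)

  masks <- vector("list", n_frames)
  frames <- if (render) vector("list", n_frames) else NULL
  obs <- vector("list", n_frames)

  for (f in seq_len(n_frames) - 1L) {
    if (f > 0) {
      # divisions scheduled for this frame
      dividing <- alive[vapply(reg[alive], function(cl)
        !is.na(cl$div_frame) && cl$div_frame == f, logical(1))]
      for (id in sort(dividing)) {
        m <- reg[[id]]
        a_div <- target_area(m$cat, m$birth_area, (f - m$birth_frame) * cfg$dt_h,
                             m$cycle_h, ad)
        d_area <- a_div / 2
        d_cat <- if (m$cat %in% c("ITA", "RPTA")) "RPTA" else "PROLIFERATIVE"
        # split along the minor axis; offsets of half the mother's
        # semi-minor axis keep both daughters inside her former footprint
        a_sem <- sqrt(d_area / (pi * m$aspect)); b_sem <- a_sem * m$aspect
        u <- c(-sin(m$theta), cos(m$theta))  # minor-axis direction
        off <- b_sem / sqrt(2)               # = half the mother's semi-minor
        for (s in c(-1, 1)) {
          d <- new_cell(next_id, d_cat, m$tree_cat, f, id,
                        m$x + s * off * u[1], m$y + s * off * u[2],
                        d_area, m$theta, m$aspect)
          reg[[next_id]] <- d
          reg[[id]]$daughters <- c(reg[[id]]$daughters, next_id)
          alive <- c(alive, next_id)
          next_id <- next_id + 1L
        }
        reg[[id]]$end_frame <- f - 1L
        reg[[id]]$fate <- "DIVIDED"
        alive <- setdiff(alive, id)
      }
      # boundary entries
      if (cfg$allow_exit && cfg$entry_rate_per_h > 0) {
        n_new <- stats::rpois(1, cfg$entry_rate_per_h * cfg$dt_h)
        for (k in seq_len(n_new)) {
          edge <- sample(4, 1)
          t_pos <- stats::runif(1, 0.1 * L, 0.9 * L)
          pad <- 0.8 * r0
          xy <- switch(edge, c(pad, t_pos), c(L - pad, t_pos),
                       c(t_pos, pad), c(t_pos, L - pad))
          tc <- sample(TREE_CATEGORIES, 1, prob = cfg$category_probs)
          cl <- new_cell(next_id, root_cell_cat[[tc]], tc, f, NA_integer_,
                         xy[1], xy[2], ad$base_um2,
                         stats::runif(1, 0, pi), stats::runif(1, 0.8, 1.2))
          cl$origin <- "ENTERED_BOUNDARY"
          reg[[next_id]] <- cl
          alive <- c(alive, next_id)
          next_id <- next_id + 1L
        }
      }
      # Brownian steps + shape drift, in id order for determinism
      for (id in sort(alive)) {
        cl <- reg[[id]]
        sdd <- sqrt(2 * cl$D * cfg$dt_h)
        cl$x <- cl$x + stats::rnorm(1, 0, sdd)
        cl$y <- cl$y + stats::rnorm(1, 0, sdd)
        cl$theta <- (cl$theta + stats::rnorm(1, 0, 0.08)) %% pi
        cl$aspect <- reflect_into(cl$aspect + stats::rnorm(1, 0, 0.02),
                                  0.7, 1.3)
        reg[[id]] <- cl
      }
    }
    # current geometry of live cells
    st <- live_geometry(reg, alive, f, cfg, ad)
    # keep cells inside (reflective borders) and resolve contacts
    if (!cfg$allow_exit) {
      for (k in seq_len(nrow(st))) {
        id <- st$id[k]
        pad <- st$a_um[k] + upp
        reg[[id]]$x <- reflect_into(reg[[id]]$x, min(pad, L / 2 - upp),
                                    max(L - pad, L / 2 + upp))
        reg[[id]]$y <- reflect_into(reg[[id]]$y, min(pad, L / 2 - upp),
                                    max(L - pad, L / 2 + upp))
      }
      st <- live_geometry(reg, alive, f, cfg, ad)
    }
    st <- resolve_contacts(st, reg, upp, L, cfg$allow_exit)
    for (k in seq_len(nrow(st))) {
      reg[[st$id[k]]]$x <- st$x[k]; reg[[st$id[k]]]$y <- st$y[k]
    }

    ras <- rasterize_cells(st, size, upp)
    # cells that left the field entirely
    gone <- st$id[!(st$id %in% ras$present)]
    for (id in gone) {
      reg[[id]]$end_frame <- f - 1L
      reg[[id]]$fate <- "LEFT_FIELD"
      alive <- setdiff(alive, id)
    }
    keep <- st$id %in% ras$present
    masks[[f + 1]] <- ras$labels
    obs[[f + 1]] <- data.frame(cell_id = st$id[keep], frame = f,
                               x_um = st$x[keep], y_um = st$y[keep],
                               area_um2 = ras$area_px[as.character(st$id[keep])] * upp^2)
    if (render) frames[[f + 1]] <- render_frame(ras$labels, cfg)
  }

  for (id in alive) {
    reg[[id]]$end_frame <- n_frames - 1L
    reg[[id]]$fate <- "PRESENT_AT_END"
  }

  cells <- do.call(rbind, lapply(reg, function(cl) data.frame(
    cell_id = cl$id, birth_frame = cl$birth_frame, end_frame = cl$end_frame,
    mother_id = cl$mother,
    daughter1 = if (length(cl$daughters) >= 1) cl$daughters[1] else NA_integer_,
    daughter2 = if (length(cl$daughters) >= 2) cl$daughters[2] else NA_integer_,
    category = cl$cat, tree_category = cl$tree_cat,
    origin = cl$origin, fate = cl$fate)))
  rownames(cells) <- NULL
  obs <- do.call(rbind, obs)
  trees <- truth_trees(cells)

  movie <- new_movie(frames, dt_h = cfg$dt_h, field_um = cfg$field_um,
                     px_per_side = size, validate = render)
  truth <- structure(list(masks = masks, cells = cells, obs = obs,
                          trees = trees, config = cfg),
                     class = "ground_truth")
  list(movie = movie, truth = truth)
}

reflect_into <- function(x, lo, hi) {
  if (hi <= lo) return((lo + hi) / 2)
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  lo + y
}

# Geometry table for live cells at frame f.
live_geometry <- function(reg, alive, f, cfg, ad) {
  alive <- sort(alive)
  rows <- lapply(reg[alive], function(cl) {
    t_h <- (f - cl$birth_frame) * cfg$dt_h
    area <- target_area(cl$cat, cl$birth_area, t_h, cl$cycle_h, ad)
    a_sem <- sqrt(area / (pi * cl$aspect))
    data.frame(id = cl$id, x = cl$x, y = cl$y, theta = cl$theta,
               a_um = a_sem, b_um = a_sem * cl$aspect, area_um2 = area)
  })
  do.call(rbind, rows)
}

# Soft pairwise repulsion: cells relax toward just-touching along the
# line of centres (directional ellipse support radii plus a 1 px gap).
ellipse_radius_towards <- function(a, b, theta, ux, uy) {
  ca <- ux * cos(theta) + uy * sin(theta)   # component along major axis
  sa <- -ux * sin(theta) + uy * cos(theta)
  sqrt((a * ca)^2 + (b * sa)^2)
}

resolve_contacts <- function(st, reg, upp, L, allow_exit) {
  n <- nrow(st)
  if (n < 2) return(st)
  for (iter in 1:3) {
    moved <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dx <- st$x[j] - st$x[i]; dy <- st$y[j] - st$y[i]
      d <- sqrt(dx^2 + dy^2)
      if (d < 1e-6) { dx <- 1; dy <- 0; d <- 1 }
      ux <- dx / d; uy <- dy / d
      ri <- ellipse_radius_towards(st$a_um[i], st$b_um[i], st$theta[i], ux, uy)
      rj <- ellipse_radius_towards(st$a_um[j], st$b_um[j], st$theta[j], ux, uy)
      min_d <- ri + rj + upp
      if (d < min_d) {
        # capped push: overlapping cells (e.g. newborn sisters) separate
        # over several frames rather than teleporting apart
        push <- min((min_d - d) / 2, 0.05 * min_d)
        st$x[i] <- st$x[i] - push * dx / d; st$y[i] <- st$y[i] - push * dy / d
        st$x[j] <- st$x[j] + push * dx / d; st$y[j] <- st$y[j] + push * dy / d
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  if (!allow_exit) {
    for (k in seq_len(n)) {
      pad <- st$a_um[k] + upp
      st$x[k] <- reflect_into(st$x[k], min(pad, L / 2 - upp),
                              max(L - pad, L / 2 + upp))
      st$y[k] <- reflect_into(st$y[k], min(pad, L / 2 - upp),
                              max(L - pad, L / 2 + upp))
    }
  }
  st
}

# Paint ellipses into a label image; contested pixels go to the cell with
# the smaller normalized elliptical distance (deterministic).
rasterize_cells <- function(st, size, upp) {
  lab <- matrix(0L, size, size)
  nd <- matrix(Inf, size, size)
  for (k in seq_len(nrow(st))) {
    cx <- st$x[k] / upp; cy <- st$y[k] / upp       # 0-based pixel coords
    a <- st$a_um[k] / upp; b <- st$b_um[k] / upp
    r <- max(a, b)
    rows <- max(1, floor(cy - r + 1)):min(size, ceiling(cy + r + 1))
    cols <- max(1, floor(cx - r + 1)):min(size, ceiling(cx + r + 1))
    if (!length(rows) || !length(cols)) next
    dy <- (rows - 1) - cy; dx <- (cols - 1) - cx
    ct <- cos(st$theta[k]); sn <- sin(st$theta[k])
    # outer over the crop: u along major axis, v along minor
    u <- outer(dy * sn, dx * ct, "+")   # rows x cols: dx*ct + dy*sn
    v <- outer(dy * ct, -dx * sn, "+")  # dy*ct - dx*sn
    nd2 <- (u / a)^2 + (v / b)^2
    inside <- nd2 <= 1 & nd2 < nd[rows, cols]
    if (any(inside)) {
      sub_l <- lab[rows, cols]; sub_n <- nd[rows, cols]
      sub_l[inside] <- st$id[k]; sub_n[inside] <- nd2[inside]
      lab[rows, cols] <- sub_l; nd[rows, cols] <- sub_n
    }
  }
  area <- table(lab[lab > 0])
  present <- as.integer(names(area))
  area_px <- as.numeric(area); names(area_px) <- names(area)
  list(labels = lab, present = present, area_px = area_px)
}

#' Render a fluorescence frame from a label mask
#'
#' Adds a flat background, a linear illumination gradient, per-cell signal
#' with multiplicative brightness variation and a radial edge shading
#' (cytoplasm is optically thinner near the membrane, so touching cells
#' show a dim seam), and Gaussian read + signal-dependent shot noise.
#' Output is a matrix of 16-bit digital numbers (0..65535). Uses the
#' current RNG stream.
#'
#' @param labels integer label matrix (0 = background).
#' @param config a [sim_config()]; only its `noise` entry is used.
#' @return numeric matrix, same shape as `labels`.
#' @export
render_frame <- function(labels, config) {
  nz <- config$noise
  n <- nrow(labels); m <- ncol(labels)
  ang <- nz$grad_dir_deg * pi / 180
  grad <- nz$grad_amp * (outer((seq_len(n) - 1) / max(1, n - 1) * cos(ang),
                               (seq_len(m) - 1) / max(1, m - 1) * sin(ang),
                               "+"))
  img <- nz$bg_level + grad
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids)) {
    shade_px <- nz$edge_shade_px %||% 0
    shade <- if (shade_px > 0) {
      dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(labels > 0)))
      fl <- nz$edge_shade_floor %||% 0.35
      fl + (1 - fl) * pmin(1, dm / shade_px)
    } else 1
    bright <- nz$cell_level *
      pmax(0.2, 1 + stats::rnorm(length(ids), 0, nz$cell_level_cv))
    idx <- match(labels, ids)
    img <- img + ifelse(is.na(idx), 0, bright[idx]) * shade
  }
  if (nz$read_sd > 0 || nz$shot_scale > 0) {
    sdpx <- sqrt(nz$read_sd^2 + nz$shot_scale^2 * pmax(img, 0))
    img <- img + stats::rnorm(length(img), 0, 1) * sdpx
  }
  matrix(pmin(65535, pmax(0, round(img))), n, m)
}

#' Ground truth as a track set
#'
#' Converts a simulation's ground truth into the same `track_set` container
#' the tracker produces, so classification and bioparameter analyses can be
#' run on exact lineages (bypassing tracking).
#'
#' @param truth a `ground_truth` from [simulate_movie()].
#' @return a `track_set`.
#' @export
truth_tracks <- function(truth) {
  cfg <- truth$config
  cells <- truth$cells
  cells$border_start <- FALSE
  cells$border_end <- cells$fate == "LEFT_FIELD"
  obs <- truth$obs
  obs$label <- obs$cell_id
  obs$mean_intensity <- NA_real_
  new_track_set(cells = cells,
                obs = obs[, c("cell_id", "frame", "label", "x_um", "y_um",
                              "area_um2", "mean_intensity")],
                dt_h = cfg$dt_h,
                um_per_px = cfg$field_um / cfg$image_size_px,
                n_frames = floor(cfg$duration_h / cfg$dt_h) + 1)
}

# Lineage-tree partition from a true cell table.
truth_trees <- function(cells) {
  root <- cells$cell_id
  mum <- cells$mother_id
  idx <- match(mum, cells$cell_id)
  # pointer jumping to the root
  repeat {
    has_m <- !is.na(mum)
    if (!any(has_m)) break
    root[has_m] <- root[idx[has_m]]
    mum <- cells$mother_id[match(root, cells$cell_id)]
    idx <- match(mum, cells$cell_id)
  }
  tree_id <- as.integer(factor(root, levels = sort(unique(root))))
  data.frame(cell_id = cells$cell_id, tree_id = tree_id, root_id = root)
}

#' Perturb ground-truth masks
#'
#' Degrades exact label masks to emulate segmentation error, independently
#' of any segmentation backend: per object and frame, a random integer
#' centroid shift, a one-pixel boundary dilation or erosion, and a small
#' dropout probability, all scaling with `noise_level`. Labels are
#' preserved (a subset of the input labels per frame); `noise_level = 0`
#' returns the masks unchanged.
#'
#' @param masks list of label matrices, or a `ground_truth` object.
#' @param noise_level in `[0, 1]`.
#' @param seed optional integer seed.
#' @param params overrides: `jitter_sd_px` (default 2; the shift sd is
#'   `jitter_sd_px * noise_level`), `morph_prob` (probability of a boundary
#'   operation, default `noise_level`), `dropout_prob` (default
#'   `0.01 * noise_level` per object and frame).
#' @return list of perturbed label matrices.
#' @export
perturb_masks <- function(masks, noise_level, seed = NULL, params = list()) {
  if (inherits(masks, "ground_truth")) masks <- masks$masks
  stopifnot(noise_level >= 0, noise_level <= 1)
  if (noise_level == 0 && is.null(params$dropout_prob)) return(masks)
  p <- utils::modifyList(list(jitter_sd_px = 2,
                              morph_prob = noise_level,
                              dropout_prob = 0.01 * noise_level), params)
  run <- function() lapply(masks, perturb_frame, noise_level = noise_level, p = p)
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

perturb_frame <- function(lab, noise_level, p) {
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  n <- nrow(lab); m <- ncol(lab)
  for (id in ids) {
    if (stats::runif(1) < p$dropout_prob) next
    w <- which(lab == id)
    rr <- ((w - 1) %% n) + 1
    cc <- ((w - 1) %/% n) + 1
    bin <- cbind(rr, cc)
    if (stats::runif(1) < p$morph_prob) {
      bin <- if (stats::runif(1) < 0.5) shift_dilate(bin, n, m)
             else shift_erode(bin, n, m)
      if (!nrow(bin)) bin <- cbind(rr[1], cc[1])
    }
    sh <- round(stats::rnorm(2, 0, p$jitter_sd_px * noise_level))
    r2 <- bin[, 1] + sh[1]; c2 <- bin[, 2] + sh[2]
    ok <- r2 >= 1 & r2 <= n & c2 >= 1 & c2 <= m
    if (!any(ok)) next
    idx <- (c2[ok] - 1) * n + r2[ok]
    idx <- idx[out[idx] == 0]          # earlier labels keep contested pixels
    out[idx] <- id
  }
  out
}

# 4-neighbour binary dilation/erosion on a pixel list (rows, cols).
shift_dilate <- function(px, n, m) {
  r <- px[, 1]; c <- px[, 2]
  all_r <- c(r, r + 1, r - 1, r, r)
  all_c <- c(c, c, c, c + 1, c - 1)
  ok <- all_r >= 1 & all_r <= n & all_c >= 1 & all_c <= m
  u <- unique((all_c[ok] - 1) * n + all_r[ok])
  cbind(((u - 1) %% n) + 1, ((u - 1) %/% n) + 1)
}

shift_erode <- function(px, n, m) {
  set <- (px[, 2] - 1) * n + px[, 1]
  inset <- function(r, c) ((c - 1) * n + r) %in% set & r >= 1 & r <= n &
    c >= 1 & c <= m
  r <- px[, 1]; c <- px[, 2]
  keep <- inset(r + 1, c) & inset(r - 1, c) & inset(r, c + 1) & inset(r, c - 1)
  px[keep, , drop = FALSE]
}
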