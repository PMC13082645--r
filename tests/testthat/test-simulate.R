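# Synthetic-movie generator: determinism, fate contracts, geometry and
# motion statistics.

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(category_probs = c(PROLIFERATIVE_TREE = 0.5,
                                             TA_TREE = 0.5, LTA = 0.1)),
               "sum to 1")
  expect_error(sim_config(ita_delay_range_h = c(30, 50)), "exceed")
  expect_error(sim_config(dt_h = 0), "dt_h")
  expect_error(sim_config(n_initial_cells = 0), "n_initial_cells")
})

test_that("over-confluent configurations are refused", {
  cfg <- sim_config(n_initial_cells = 400,
                    category_probs = c(PROLIFERATIVE_TREE = 0, TA_TREE = 0,
                                       LTA = 1))
  expect_error(simulate_movie(cfg), "over-confluent")
})

test_that("pure LTA populations never divide and grow monotonically", {
  cfg <- sim_config(image_size_px = 128, duration_h = 24,
                    n_initial_cells = 3,
                    category_probs = c(PROLIFERATIVE_TREE = 0, TA_TREE = 0,
                                       LTA = 1), seed = 9)
  sim <- simulate_movie(cfg, render = FALSE)
  cl <- sim$truth$cells
  expect_equal(nrow(cl), 3)
  expect_true(all(is.na(cl$daughter1)))
  expect_equal(length(unique(sim$truth$trees$tree_id)), 3)
  # monotone area growth per cell (target model is linear in time)
  for (id in cl$cell_id) {
    a <- sim$truth$obs$area_um2[sim$truth$obs$cell_id == id]
    expect_true(all(diff(a) > -0.05 * a[-length(a)]))  # rasterization jitter
    expect_gt(a[length(a)], a[1])
  }
})

test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(image_size_px = 96, duration_h = 12, n_initial_cells = 4,
                    seed = 11)
  a <- simulate_movie(cfg, render = TRUE)
  b <- simulate_movie(cfg, render = TRUE)
  expect_identical(a$truth$masks, b$truth$masks)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$movie$frames, b$movie$frames)
})

test_that("ground truth satisfies its structural invariants", {
  sim <- small_sim()$sim
  cl <- sim$truth$cells
  n_frames <- length(sim$truth$masks)
  expect_equal(n_frames, floor(48 / 0.5) + 1)
  # every division has exactly 2 daughters born the frame after mother ends
  div <- cl[!is.na(cl$fate) & cl$fate == "DIVIDED", ]
  expect_true(all(!is.na(div$daughter1) & !is.na(div$daughter2)))
  for (i in seq_len(nrow(div))) {
    for (d in c(div$daughter1[i], div$daughter2[i])) {
      expect_equal(cl$birth_frame[match(d, cl$cell_id)],
                   div$end_frame[i] + 1)
      expect_equal(cl$mother_id[match(d, cl$cell_id)], div$cell_id[i])
    }
  }
  # non-divided cells have no daughters
  expect_true(all(is.na(cl$daughter1[cl$fate != "DIVIDED"])))
  # tree partition is exact
  expect_setequal(sim$truth$trees$cell_id, cl$cell_id)
  expect_equal(sum(table(sim$truth$trees$tree_id)), nrow(cl))
  # labels in masks match alive cells in the truth table
  for (f in seq(1, n_frames, by = 16)) {
    labs <- sort(unique(sim$truth$masks[[f]][sim$truth$masks[[f]] > 0]))
    alive <- cl$cell_id[cl$birth_frame <= f - 1 & cl$end_frame >= f - 1]
    expect_setequal(labs, alive)
  }
})

test_that("division conserves area within 20%", {
  sim <- long_sim()$sim
  cl <- sim$truth$cells
  obs <- sim$truth$obs
  div <- cl[!is.na(cl$fate) & cl$fate == "DIVIDED", ]
  expect_gt(nrow(div), 3)
  for (i in seq_len(nrow(div))) {
    a_m <- obs$area_um2[obs$cell_id == div$cell_id[i] &
                          obs$frame == div$end_frame[i]]
    a_d <- sum(obs$area_um2[obs$cell_id %in% c(div$daughter1[i],
                                               div$daughter2[i]) &
                              obs$frame == div$end_frame[i] + 1])
    expect_lt(abs(a_d - a_m) / a_m, 0.2)
  }
})

test_that("cycle-duration sampling respects the category windows", {
  cfg <- sim_config()
  with_seed <- lineagetrack:::with_seed
  d <- with_seed(1, sample_cycle_duration("PROLIFERATIVE", cfg, 1e4))
  expect_true(all(d >= 10 & d <= 40))
  # distribution is the truncated Gaussian, not uniform: mode near the mean
  expect_gt(mean(d > 15 & d < 31), 0.6)
  d_ita <- with_seed(2, sample_cycle_duration("ITA", cfg, 1e3))
  expect_true(all(d_ita > 40))
  cfg0 <- sim_config(cycle_sd_h = 0)
  expect_equal(unique(sample_cycle_duration("PROLIFERATIVE", cfg0, 100)), 23)
  expect_error(sample_cycle_duration("LTA", cfg), "non-dividing")
})

test_that("Brownian step statistics match the configured coefficient", {
  # sparse non-dividing population: steps are pure reflected Brownian
  d_true <- 0.05
  cfg <- sim_config(image_size_px = 256, duration_h = 24,
                    n_initial_cells = 60,
                    category_probs = c(PROLIFERATIVE_TREE = 0, TA_TREE = 0,
                                       LTA = 1),
                    diffusion_by_category = c(PROLIFERATIVE = 0.1, ITA = 0.02,
                                              RPTA = 0.1, LTA = d_true),
                    area_dynamics = list(base_um2 = 800, lta_growth_per_h = 0),
                    seed = 21)
  sim <- simulate_movie(cfg, render = FALSE)
  obs <- sim$truth$obs[order(sim$truth$obs$cell_id, sim$truth$obs$frame), ]
  steps <- unlist(lapply(split(obs, obs$cell_id), function(o)
    (diff(o$x_um)^2 + diff(o$y_um)^2) / cfg$dt_h))
  expect_gt(length(steps), 2000)
  se <- stats::sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - 4 * d_true), 3 * se)
})

test_that("rendered frames put signal inside cells, noise controls apply", {
  cfg <- sim_config(image_size_px = 96, duration_h = 2, n_initial_cells = 3,
                    seed = 5)
  sim <- simulate_movie(cfg, render = TRUE)
  # zero cells: pure background
  empty <- matrix(0L, 96, 96)
  img0 <- lineagetrack:::with_seed(1, render_frame(empty, cfg))
  expect_lt(abs(mean(img0) - (cfg$noise$bg_level + cfg$noise$grad_amp / 2)),
            3 * cfg$noise$read_sd)
  # noise off: piecewise-deterministic given the mask
  cfg_q <- sim_config(image_size_px = 96,
                      noise = list(read_sd = 0, shot_scale = 0,
                                   cell_level_cv = 0))
  m <- disc_mask(96, 40, 40, 10)
  img_q <- render_frame(m, cfg_q)
  expect_equal(length(unique(img_q[m > 0])), 1 + length(unique(
    round(img_q[m > 0] - cfg_q$noise$cell_level))) - 1) # constant offset inside
  # default noise: inside > outside over seeded frames
  ins <- numeric(20); outs <- numeric(20)
  for (k in 1:20) {
    f <- sim$truth$masks[[k %% length(sim$truth$masks) + 1]]
    img <- lineagetrack:::with_seed(k, render_frame(f, cfg))
    ins[k] <- mean(img[f > 0]); outs[k] <- mean(img[f == 0])
  }
  expect_true(all(ins > outs))
})

test_that("mask perturbation: identity at 0, dropout limit, calibrated IoU", {
  sim <- small_sim()$sim
  masks <- sim$truth$masks[1:20]
  expect_identical(perturb_masks(masks, 0), masks)
  gone <- perturb_masks(masks, 1, seed = 1,
                        params = list(dropout_prob = 1))
  expect_true(all(vapply(gone, function(m) all(m == 0), logical(1))))
  # moderate noise keeps objects recognizable but not exact
  pm <- perturb_masks(masks, 0.2, seed = 3)
  ious <- c()
  for (f in seq_along(masks)) {
    for (id in unique(masks[[f]][masks[[f]] > 0])) {
      a <- masks[[f]] == id; b <- pm[[f]] == id
      if (!any(b)) next
      ious <- c(ious, sum(a & b) / sum(a | b))
    }
  }
  expect_gt(length(ious), 50)
  expect_gt(mean(ious), 0.5)
  expect_lt(mean(ious), 1)
  # labels stay unique per frame (subset of truth labels)
  for (f in seq_along(pm)) {
    labs <- pm[[f]][pm[[f]] > 0]
    expect_true(all(labs %in% masks[[f]]))
  }
})

test_that("dose presets interpolate and normalize", {
  p0 <- dose_category_probs(0)
  p5 <- dose_category_probs(5)
  expect_equal(sum(p0), 1)
  expect_gt(p0[["PROLIFERATIVE_TREE"]], p5[["PROLIFERATIVE_TREE"]])
  expect_gt(p5[["LTA"]], p0[["LTA"]])
  p25 <- dose_category_probs(2.5)
  expect_true(all(p25 >= pmin(dose_category_probs(2), dose_category_probs(3)) -
                    1e-12))
})
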