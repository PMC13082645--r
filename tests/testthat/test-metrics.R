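# Tracking-quality metrics.

test_that("detection matching: trivial and ambiguous cases", {
  gt <- list(disc_mask(64, 20, 20, 6) + disc_mask(64, 45, 40, 7, 2L))
  m <- match_detections(gt, gt, 0.5)
  expect_equal(m$tp, 2); expect_equal(m$fp, 0); expect_equal(m$fn, 0)
  expect_equal(det_a(m), 1)
  m0 <- match_detections(gt, list(matrix(0L, 64, 64)), 0.5)
  expect_equal(m0$fn, 2)
  expect_equal(det_a(m0), 0)
  expect_error(match_detections(gt, rep(gt, 2)), "frame-count mismatch")
  # empty vs empty is defined as perfect
  e <- list(matrix(0L, 8, 8))
  expect_equal(det_a(match_detections(e, e, 0.5)), 1)
})

test_that("one prediction over two ground-truth objects yields 1 TP + 1 FN", {
  # GT: two adjacent rectangles; one prediction straddles both
  # (IoU 0.57 with the first, 0.22 with the second, threshold 0.5)
  gt <- rect_mask(40, 5, 14, 5, 14) + rect_mask(40, 5, 14, 15, 24, 2L)
  pred <- rect_mask(40, 5, 14, 7, 18)
  m <- match_detections(list(gt), list(pred), 0.5)
  expect_equal(m$tp, 1)
  expect_equal(m$fn, 1)
  expect_equal(m$fp, 0)
  expect_equal(m$pairs$gt_label, 1)
  # 8 TP, 1 FP, 1 FN arithmetic
  expect_equal(8 / (8 + 1 + 1), 0.8)
  # adding an FP never increases DetA
  expect_lt(m$tp / (m$tp + m$fn + m$fp + 1), det_a(m))
})

# tiny fabricated truth/pred pair: one static GT object over 10 frames.
static_truth <- function(n_frames = 10) {
  m <- disc_mask(32, 16, 16, 5)
  obs <- data.frame(cell_id = 1L, frame = 0:(n_frames - 1))
  structure(list(masks = rep(list(m), n_frames),
                 cells = data.frame(cell_id = 1L, birth_frame = 0L,
                                    end_frame = n_frames - 1L,
                                    mother_id = NA_integer_,
                                    daughter1 = NA_integer_,
                                    daughter2 = NA_integer_,
                                    origin = "INITIAL",
                                    fate = "PRESENT_AT_END"),
                 obs = obs,
                 trees = data.frame(cell_id = 1L, tree_id = 1L,
                                    root_id = 1L)),
            class = "ground_truth")
}

test_that("a track split in half scores association 0.5 everywhere", {
  truth <- static_truth(10)
  pred <- lineagetrack:::new_track_set(
    cells = data.frame(cell_id = 1:2, birth_frame = c(0L, 5L),
                       end_frame = c(4L, 9L),
                       origin = c("INITIAL", "SPONTANEOUS"),
                       fate = c("LOST", "PRESENT_AT_END"),
                       mother_id = NA_integer_, daughter1 = NA_integer_,
                       daughter2 = NA_integer_),
    obs = data.frame(cell_id = rep(1:2, each = 5), frame = 0:9, label = 1L,
                     x_um = 0, y_um = 0, area_um2 = 80,
                     mean_intensity = NA_real_),
    dt_h = 0.5, um_per_px = 1, n_frames = 10L)
  m <- match_detections(truth$masks, truth$masks, 0.5)
  a <- ass_a(truth, pred, m)
  expect_equal(as.numeric(a), 0.5)
  # identical tracking scores 1
  perfect <- pred
  perfect$cells <- data.frame(cell_id = 1L, birth_frame = 0L, end_frame = 9L,
                              origin = "INITIAL", fate = "PRESENT_AT_END",
                              mother_id = NA_integer_,
                              daughter1 = NA_integer_,
                              daughter2 = NA_integer_)
  perfect$obs$cell_id <- 1L
  expect_equal(as.numeric(ass_a(truth, perfect, m)), 1)
})

test_that("id swaps lower AssA below 1", {
  sim <- small_sim()$sim
  cfg <- small_sim()$config
  tr <- run_tracking(sim$truth$masks,
                     um_per_px = cfg$field_um / cfg$image_size_px)
  m <- match_detections(sim$truth$masks, sim$truth$masks, 0.5)
  base <- as.numeric(ass_a(sim$truth, tr, m))
  swapped <- tr
  two <- head(swapped$cells$cell_id[swapped$cells$birth_frame == 0], 2)
  mid <- 40
  i1 <- swapped$obs$cell_id == two[1] & swapped$obs$frame >= mid
  i2 <- swapped$obs$cell_id == two[2] & swapped$obs$frame >= mid
  swapped$obs$cell_id[i1] <- two[2]
  swapped$obs$cell_id[i2] <- two[1]
  expect_lt(as.numeric(ass_a(sim$truth, swapped, m)), base)
})

test_that("metrics are invariant under relabeling of ids", {
  sim <- small_sim()$sim
  cfg <- small_sim()$config
  masks <- perturb_masks(sim$truth, 0.1, seed = 4)
  tr <- run_tracking(masks, um_per_px = cfg$field_um / cfg$image_size_px)
  r1 <- evaluate_tracking(sim$truth, tr, masks)
  # relabel predicted masks per frame (reverse label order) and re-track
  relab <- lapply(masks, function(m) {
    u <- sort(unique(m[m > 0]))
    if (!length(u)) return(m)
    new <- stats::setNames(rev(seq_along(u) + 100L), u)
    out <- m
    out[m > 0] <- new[as.character(m[m > 0])]
    out
  })
  tr2 <- run_tracking(relab, um_per_px = cfg$field_um / cfg$image_size_px)
  r2 <- evaluate_tracking(sim$truth, tr2, relab)
  expect_equal(r1$det_a, r2$det_a)
  expect_equal(as.numeric(r1$ass_a), as.numeric(r2$ass_a), tolerance = 1e-9)
  expect_equal(as.numeric(r1$lineage_assignment_accuracy),
               as.numeric(r2$lineage_assignment_accuracy), tolerance = 1e-9)
})

test_that("division scores respect the frame tolerance", {
  sim <- long_sim()$sim
  cfg <- long_sim()$config
  tr <- run_tracking(sim$truth$masks,
                     um_per_px = cfg$field_um / cfg$image_size_px)
  m <- match_detections(sim$truth$masks, sim$truth$masks, 0.5)
  ds0 <- division_scores(sim$truth, tr, m, frame_tolerance = 0)
  expect_equal(ds0$precision, 1)
  expect_equal(ds0$recall, 1)
  # shift every predicted division 1 frame late
  shifted <- tr
  div <- !is.na(shifted$cells$fate) & shifted$cells$fate == "DIVIDED"
  shifted$cells$end_frame[div] <- shifted$cells$end_frame[div] + 1L
  kids <- shifted$cells$origin == "DAUGHTER"
  shifted$cells$birth_frame[kids] <- shifted$cells$birth_frame[kids] + 1L
  ds1 <- division_scores(sim$truth, shifted, m, frame_tolerance = 2)
  expect_equal(ds1$recall, 1)
  ds_strict <- division_scores(sim$truth, shifted, m, frame_tolerance = 0)
  expect_lt(ds_strict$recall, 1)
})

test_that("lifetime agreement honours its tolerance", {
  sim <- long_sim()$sim
  cfg <- long_sim()$config
  tr <- run_tracking(sim$truth$masks,
                     um_per_px = cfg$field_um / cfg$image_size_px)
  m <- match_detections(sim$truth$masks, sim$truth$masks, 0.5)
  expect_equal(as.numeric(lifetime_agreement(sim$truth, tr, m)), 100)
  # off by 5 frames everywhere, tolerance 2: zero agreement
  off <- tr
  done <- off$cells$origin == "DAUGHTER" & !is.na(off$cells$fate) &
    off$cells$fate == "DIVIDED"
  off$cells$end_frame[done] <- off$cells$end_frame[done] + 5L
  expect_equal(as.numeric(lifetime_agreement(sim$truth, off, m, 2)), 0)
  # off by 1 frame, tolerance 2: full agreement
  off1 <- tr
  off1$cells$end_frame[done] <- off1$cells$end_frame[done] + 1L
  expect_equal(as.numeric(lifetime_agreement(sim$truth, off1, m, 2)), 100)
})

test_that("all metrics are perfect when prediction equals ground truth", {
  for (s in c(3, 19)) {
    cfg <- sim_config(image_size_px = 192, duration_h = 60,
                      n_initial_cells = 5, dose_Gy = 1, seed = s)
    sim <- simulate_movie(cfg, render = FALSE)
    tr <- run_tracking(sim$truth$masks,
                       um_per_px = cfg$field_um / cfg$image_size_px)
    rep <- evaluate_tracking(sim$truth, tr, sim$truth$masks)
    expect_equal(rep$det_a, 1)
    expect_equal(as.numeric(rep$ass_a), 1)
    expect_equal(as.numeric(rep$lineage_assignment_accuracy), 100)
    expect_equal(rep$division_precision, 1)
    expect_equal(rep$division_recall, 1)
    expect_equal(as.numeric(rep$lifetime_agreement), 100)
  }
})
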