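# Tree/cell categories, filtering and population summaries.

# Minimal hand-built linked track set:
#   1 INITIAL root dividing at 23 h -> proliferative tree {1,2,3}
#   4 INITIAL root dividing at 50 h -> TA tree {4,5,6}
#   7 INITIAL root alive throughout  -> LTA
#   8 INITIAL root lost at 30 h without division -> UNCLASSIFIED
#   9 SPONTANEOUS mid-movie track
toy_tracks <- function(n_frames = 193L, dt_h = 0.5) {
  cl <- data.frame(
    cell_id = 1:9,
    birth_frame = c(0L, 46L, 46L, 0L, 100L, 100L, 0L, 0L, 50L),
    end_frame = c(45L, 192L, 192L, 99L, 192L, 192L, 192L, 60L, 80L),
    origin = c("INITIAL", "DAUGHTER", "DAUGHTER", "INITIAL", "DAUGHTER",
               "DAUGHTER", "INITIAL", "INITIAL", "SPONTANEOUS"),
    fate = c("DIVIDED", "PRESENT_AT_END", "PRESENT_AT_END", "DIVIDED",
             "PRESENT_AT_END", "PRESENT_AT_END", "PRESENT_AT_END", "LOST",
             "LOST"),
    mother_id = c(NA, 1L, 1L, NA, 4L, 4L, NA, NA, NA),
    daughter1 = c(2L, NA, NA, 5L, NA, NA, NA, NA, NA),
    daughter2 = c(3L, NA, NA, 6L, NA, NA, NA, NA, NA))
  obs <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    fr <- cl$birth_frame[i]:cl$end_frame[i]
    data.frame(cell_id = cl$cell_id[i], frame = fr, label = cl$cell_id[i],
               x_um = 10 * i + 0.01 * fr, y_um = 10 * i,
               area_um2 = 4000 + 10 * i, mean_intensity = NA_real_)
  }))
  lineagetrack:::new_track_set(cl, obs, dt_h = dt_h, um_per_px = 5,
                               n_frames = n_frames)
}

test_that("tree classification follows the 40 h rule and the 4-day window", {
  tr <- classify_cells(toy_tracks())
  cl <- tr$cells
  expect_equal(cl$tree_category[cl$cell_id == 1], "PROLIFERATIVE_TREE")
  expect_equal(cl$category[cl$cell_id %in% 1:3],
               rep("PROLIFERATIVE", 3))
  expect_equal(cl$tree_category[cl$cell_id == 4], "TA_TREE")
  expect_equal(cl$category[cl$cell_id == 4], "ITA")
  expect_equal(cl$category[cl$cell_id %in% 5:6], rep("RPTA", 2))
  expect_equal(cl$category[cl$cell_id == 7], "LTA")
  expect_equal(cl$category[cl$cell_id == 8], "UNCLASSIFIED")
  expect_true(is.na(cl$category[cl$cell_id == 9]))  # excluded from trees
})

test_that("boundary cases of the first-division time", {
  # dividing exactly at 40 h is still proliferative; 40.5 h is arrested
  mk <- function(end_frame) {
    cl <- data.frame(cell_id = 1:3, birth_frame = c(0L, end_frame + 1L,
                                                    end_frame + 1L),
                     end_frame = c(end_frame, 192L, 192L),
                     origin = c("INITIAL", "DAUGHTER", "DAUGHTER"),
                     fate = c("DIVIDED", "PRESENT_AT_END", "PRESENT_AT_END"),
                     mother_id = c(NA, 1L, 1L),
                     daughter1 = c(2L, NA, NA), daughter2 = c(3L, NA, NA))
    lineagetrack:::new_track_set(cl, data.frame(), dt_h = 0.5, um_per_px = 5,
                                 n_frames = 193L)
  }
  expect_equal(classify_tree(1, mk(79L)), "PROLIFERATIVE_TREE")  # 40.0 h
  expect_equal(classify_tree(1, mk(80L)), "TA_TREE")             # 40.5 h
})

test_that("filtering removes spontaneous, debris and short cycles with reasons", {
  tr <- classify_cells(toy_tracks())
  # make cell 2 a debris-sized track and give cell 4 an 8 h cycle subtree
  tr$obs$area_um2[tr$obs$cell_id == 2] <- 50
  tr2 <- tr
  tr2$cells$birth_frame[tr2$cells$cell_id == 5] <- 116L
  tr2$cells$end_frame[tr2$cells$cell_id == 5] <- 131L   # 8 h complete cycle
  tr2$cells$fate[tr2$cells$cell_id == 5] <- "DIVIDED"
  tr2$cells$origin[tr2$cells$cell_id == 6] <- "DAUGHTER"
  tr2$cells$mother_id[tr2$cells$cell_id == 6] <- 5L
  tr2$cells$daughter1[tr2$cells$cell_id == 5] <- 6L
  tr2$cells$daughter2[tr2$cells$cell_id == 5] <- NA_integer_
  fl <- filter_cells(tr2, debris_min_um2 = 300)
  expect_setequal(fl$rejections$reason[fl$rejections$cell_id == 9],
                  "spontaneous")
  expect_setequal(fl$rejections$reason[fl$rejections$cell_id == 2], "debris")
  expect_true(all(c(5, 6) %in%
                    fl$rejections$cell_id[fl$rejections$reason ==
                                            "short-cycle"]))
  expect_false(any(fl$tracks$cells$cell_id %in% fl$rejections$cell_id))
  expect_equal(nrow(fl$rejections),
               nrow(tr2$cells) - nrow(fl$tracks$cells))
})

test_that("counts over time conserve the alive population", {
  tr <- classify_cells(toy_tracks())
  cot <- counts_over_time(tr)
  expect_equal(nrow(cot), 193)
  # 3 LTA-like constant? category LTA: only cell 7, alive throughout
  expect_true(all(cot$LTA == 1))
  # proliferative count steps 1 -> 2 at the division frame
  expect_equal(cot$PROLIFERATIVE[cot$frame == 45], 1)
  expect_equal(cot$PROLIFERATIVE[cot$frame == 46], 2)
  # conservation at every frame
  alive <- vapply(cot$frame, function(f)
    sum(tr$cells$birth_frame <= f & tr$cells$end_frame >= f &
          !is.na(tr$cells$category)), numeric(1))
  expect_equal(cot$total, alive)
})

test_that("population summary normalizes to the control condition", {
  tr <- classify_cells(toy_tracks())
  runs <- list(control = tr, treated = tr)
  # make the treated run smaller: drop one initial cell
  runs$treated$cells <- tr$cells[tr$cells$cell_id != 8, ]
  out <- population_summary(runs, control = "control")
  expect_equal(out$plating_efficiency_pct[out$condition == "control"], 100)
  expect_equal(out$plating_efficiency_pct[out$condition == "treated"],
               3 / 4 * 100)
  # cumulative counts are unique cells ever labelled with the category
  expect_equal(out$PROLIFERATIVE[1], 3)
  expect_equal(out$ITA[1], 1)
  expect_equal(out$RPTA[1], 2)
  expect_equal(out$LTA[1], 1)
  expect_error(population_summary(runs, control = "absent"),
               "control condition missing")
})

test_that("classification on simulator ground truth recovers every category", {
  sim <- long_sim()$sim
  tr <- truth_tracks(sim$truth)
  tr <- classify_cells(tr)
  cl <- tr$cells
  truth_cat <- sim$truth$cells$category[match(cl$cell_id,
                                              sim$truth$cells$cell_id)]
  expect_equal(cl$category, truth_cat)
  # ITA count equals the number of TA trees
  n_ta_trees <- length(unique(cl$tree_id[!is.na(cl$tree_category) &
                                           cl$tree_category == "TA_TREE"]))
  expect_equal(sum(cl$category == "ITA"), n_ta_trees)
  # retained cells are partitioned by the four categories
  expect_true(all(cl$category %in% c("PROLIFERATIVE", "ITA", "RPTA", "LTA")))
})
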