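# Fate classification: lineage trees are categorized by the behaviour of
# their founder cell (normal first cycle / delayed first cycle / no
# division), cells inherit per-cell categories (PROLIFERATIVE, ITA, RPTA,
# LTA), and filtering removes debris, short-cycle artifacts and
# spontaneous appearances before any population statistics.

#' Classify one lineage tree by its founder's behaviour
#'
#' A founder dividing with (possibly censored) first-division time at or
#' below `t_norm_max_h` makes a proliferative tree; dividing later makes a
#' transiently arrested tree; never dividing while observed to the end of
#' the window makes a long-term arrested cell. A founder that disappears
#' before the movie ends without dividing cannot be decided and is
#' `UNCLASSIFIED` (excluded downstream).
#'
#' @param root_id founder cell id.
#' @param tracks linked `track_set`.
#' @param t_norm_max_h maximum duration of a normal cycle (default 40 h).
#' @param observation_h observation window; defaults to the movie length.
#' @return one of `"PROLIFERATIVE_TREE"`, `"TA_TREE"`, `"LTA"`,
#'   `"UNCLASSIFIED"`.
#' @export
classify_tree <- function(root_id, tracks, t_norm_max_h = 40,
                          observation_h = NULL) {
  cl <- tracks$cells
  i <- match(root_id, cl$cell_id)
  if (is.na(i)) stop2("unknown root cell ", root_id)
  observation_h <- observation_h %||% ((tracks$n_frames - 1) * tracks$dt_h)
  if (!is.na(cl$fate[i]) && cl$fate[i] == "DIVIDED") {
    first_div_h <- (cl$end_frame[i] - cl$birth_frame[i] + 1) * tracks$dt_h
    return(if (first_div_h <= t_norm_max_h) "PROLIFERATIVE_TREE" else "TA_TREE")
  }
  end_h <- cl$end_frame[i] * tracks$dt_h
  if (cl$fate[i] == "PRESENT_AT_END" && end_h >= min(observation_h,
                                                     (tracks$n_frames - 1) * tracks$dt_h))
    return("LTA")
  "UNCLASSIFIED"
}

#' Classify all trees and label every cell
#'
#' Applies [classify_tree()] to each tree and assigns per-cell categories:
#' members of proliferative trees are `PROLIFERATIVE`; the founder of a
#' transiently arrested tree is `ITA` and its progeny `RPTA`; long-term
#' arrested founders are `LTA`. Cells of undecidable trees are
#' `UNCLASSIFIED`.
#'
#' @param tracks linked `track_set`.
#' @param trees result of [build_trees()] (recomputed when `NULL`).
#' @inheritParams classify_tree
#' @return the `track_set` with columns `tree_id`, `tree_category` and
#'   `category` filled in.
#' @export
classify_cells <- function(tracks, trees = NULL, t_norm_max_h = 40,
                           observation_h = NULL) {
  if (is.null(trees)) trees <- build_trees(tracks)
  tracks <- trees$tracks
  cl <- tracks$cells
  tree_cat <- vapply(trees$roots, classify_tree, character(1),
                     tracks = tracks, t_norm_max_h = t_norm_max_h,
                     observation_h = observation_h)
  mem <- trees$membership
  mem$tree_category <- tree_cat[mem$tree_id]
  mem$is_root <- mem$cell_id == mem$root_id
  mem$category <- ifelse(mem$tree_category == "PROLIFERATIVE_TREE",
                         "PROLIFERATIVE",
                  ifelse(mem$tree_category == "TA_TREE",
                         ifelse(mem$is_root, "ITA", "RPTA"),
                  ifelse(mem$tree_category == "LTA", "LTA",
                         "UNCLASSIFIED")))
  j <- match(cl$cell_id, mem$cell_id)
  cl$tree_category <- mem$tree_category[j]
  cl$category <- mem$category[j]
  tracks$cells <- cl
  tracks
}

#' Filter cells before biological analysis
#'
#' Removes (with one logged reason per removal): spontaneous-appearance
#' tracks; debris, i.e. tracks whose median area is below
#' `debris_min_um2`; and cells with a complete cycle shorter than
#' `min_cycle_h` together with their whole subtree (such short cycles
#' correspond to reconstruction artifacts, not real divisions).
#'
#' @param tracks linked (and optionally classified) `track_set`.
#' @param min_cycle_h shortest credible complete cycle (default 10 h).
#' @param debris_min_um2 minimum median area of a real cell (default
#'   300 um^2).
#' @return list: `tracks` (retained cells only, observations subset
#'   accordingly) and `rejections` (data frame `cell_id`, `reason`).
#' @export
filter_cells <- function(tracks, min_cycle_h = 10, debris_min_um2 = 300) {
  cl <- tracks$cells
  reasons <- character(0); ids <- integer(0)
  reject <- function(id, why) {
    new <- setdiff(id, ids)
    ids <<- c(ids, new); reasons <<- c(reasons, rep(why, length(new)))
  }
  reject(cl$cell_id[cl$origin == "SPONTANEOUS"], "spontaneous")

  med_area <- vapply(split(tracks$obs$area_um2, tracks$obs$cell_id),
                     stats::median, numeric(1))
  small <- as.integer(names(med_area))[med_area < debris_min_um2]
  reject(small, "debris")

  cyc <- cycle_durations(tracks)
  short <- cyc$cell_id[cyc$complete & !is.na(cyc$duration_h) &
                         cyc$duration_h < min_cycle_h]
  if (length(short)) {
    sub <- unlist(lapply(short, subtree_ids, cells = cl))
    reject(unique(sub), "short-cycle")
  }

  keep <- !(cl$cell_id %in% ids)
  tracks$cells <- cl[keep, , drop = FALSE]
  tracks$obs <- tracks$obs[tracks$obs$cell_id %in% cl$cell_id[keep], ,
                           drop = FALSE]
  rownames(tracks$cells) <- NULL
  list(tracks = tracks,
       rejections = data.frame(cell_id = ids, reason = reasons))
}

subtree_ids <- function(id, cells) {
  out <- id
  frontier <- id
  while (length(frontier)) {
    i <- match(frontier, cells$cell_id)
    kids <- c(cells$daughter1[i], cells$daughter2[i])
    kids <- kids[!is.na(kids)]
    frontier <- setdiff(kids, out)
    out <- c(out, frontier)
  }
  out
}

#' Per-frame cell counts by category
#'
#' Number of alive cells of each category at every frame; the per-frame sum
#' over categories equals the number of alive retained cells.
#'
#' @param tracks classified (and typically filtered) `track_set`.
#' @return data frame `frame`, `time_h`, one column per category, `total`.
#' @export
counts_over_time <- function(tracks) {
  cl <- tracks$cells
  cats <- c(CELL_CATEGORIES, "UNCLASSIFIED")
  frames <- 0:(tracks$n_frames - 1)
  out <- data.frame(frame = frames, time_h = frames * tracks$dt_h)
  for (cc in cats) out[[cc]] <- 0L
  for (i in seq_len(nrow(cl))) {
    cc <- if (is.null(cl$category)) NA_character_ else cl$category[i]
    if (is.na(cc)) next    # outside the tree partition (e.g. spontaneous)
    f <- (cl$birth_frame[i]:cl$end_frame[i]) + 1L
    out[[cc]][f] <- out[[cc]][f] + 1L
  }
  out$total <- rowSums(out[, cats, drop = FALSE])
  out
}

#' Population summary across conditions
#'
#' For each run: founders at frame 0, cumulative unique cells ever labelled
#' with each category, and plating efficiency (founders relative to the
#' control condition, as a percent).
#'
#' @param runs named list of classified `track_set`s; names are condition
#'   labels.
#' @param control name of the control condition (plating efficiency 100%).
#' @return data frame, one row per condition.
#' @export
population_summary <- function(runs, control = names(runs)[1]) {
  if (!control %in% names(runs)) stop2("control condition missing: ", control)
  rows <- lapply(names(runs), function(nm) {
    cl <- runs[[nm]]$cells
    init <- sum(cl$birth_frame == 0)
    cnt <- vapply(c(CELL_CATEGORIES, "UNCLASSIFIED"),
                  function(cc) sum(!is.na(cl$category) & cl$category == cc),
                  numeric(1))
    data.frame(condition = nm, initial_cells = init,
               PROLIFERATIVE = cnt[["PROLIFERATIVE"]], ITA = cnt[["ITA"]],
               RPTA = cnt[["RPTA"]], LTA = cnt[["LTA"]],
               UNCLASSIFIED = cnt[["UNCLASSIFIED"]])
  })
  out <- do.call(rbind, rows)
  ctrl_init <- out$initial_cells[out$condition == control]
  out$plating_efficiency_pct <- out$initial_cells / ctrl_init * 100
  out
}
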