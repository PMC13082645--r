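# Linking: resolve each mid-movie appearance into a division (with its
# mother), a boundary entry, or a spontaneous appearance, then build
# lineage trees. Divisions are strictly binary.

#' Classify one appearance against the previous frame
#'
#' The candidate mother is the previous-frame object maximizing the
#' overlap fraction `|new - intersect - prev| / |new|`. At the 30-minute
#' frame interval daughters still occupy their mother's footprint, so a
#' fraction of at least `tau_div` is read as a division; otherwise an
#' appearance near the frame edge is a boundary entry and anything else is
#' spontaneous.
#'
#' @param new_px pixel indices of the appeared object (in frame `t`).
#' @param masks_prev label matrix of frame `t - 1`.
#' @param at_border does the new object's bounding box lie within the
#'   border margin?
#' @param tau_div overlap-fraction threshold (default 0.5).
#' @return list with `type` (`"DIVISION"`, `"ENTERED_BOUNDARY"`,
#'   `"SPONTANEOUS"`), `mother_label`, `fraction`.
#' @export
assign_mother <- function(new_px, masks_prev, at_border, tau_div = 0.5) {
  prev <- masks_prev[new_px]
  prev <- prev[prev > 0]
  if (length(prev)) {
    cnt <- tabulate(prev)
    best <- which.max(cnt)
    frac <- cnt[best] / length(new_px)
    if (frac >= tau_div)
      return(list(type = "DIVISION", mother_label = best, fraction = frac))
  }
  if (isTRUE(at_border))
    return(list(type = "ENTERED_BOUNDARY", mother_label = NA_integer_,
                fraction = 0))
  list(type = "SPONTANEOUS", mother_label = NA_integer_, fraction = 0)
}

#' Resolve origins and fates of tracked cells
#'
#' Applies [assign_mother()] to every mid-movie appearance and performs the
#' division bookkeeping: the mother's track is truncated to end the frame
#' before the division with fate `DIVIDED`; if the mother's identity was
#' carried on by frame matching, that continuation is split off as a new
#' track with origin `DAUGHTER`; exactly two daughters are recorded. When
#' more than two new objects claim the same mother at the same frame, the
#' two with the highest overlap fractions are kept and the rest are marked
#' `SPONTANEOUS` (with a warning). Tracks that end mid-movie without
#' dividing get fate `LEFT_FIELD` if they ended at the border, else `LOST`.
#'
#' @param tracks a `track_set` from [track_movie()].
#' @param masks the label masks the tracks were computed from.
#' @param tau_div overlap-fraction threshold for calling a division.
#' @return the `track_set` with all origins, fates and mother/daughter
#'   links resolved.
#' @export
link_tracks <- function(tracks, masks, tau_div = 0.5) {
  cells <- tracks$cells
  obs <- tracks$obs
  next_id <- max(cells$cell_id) + 1L

  owner_at <- function(frame, label) {
    i <- which(obs$frame == frame & obs$label == label)
    if (!length(i)) NA_integer_ else obs$cell_id[i[1]]
  }

  # collect appearance claims
  pend <- cells[is.na(cells$origin), , drop = FALSE]
  pend <- pend[order(pend$birth_frame, pend$cell_id), , drop = FALSE]
  claims <- list()
  for (k in seq_len(nrow(pend))) {
    id <- pend$cell_id[k]; t <- pend$birth_frame[k]
    row <- which(obs$cell_id == id & obs$frame == t)
    lab <- obs$label[row[1]]
    npx <- which(masks[[t + 1]] == lab)
    am <- assign_mother(npx, masks[[t]], pend$border_start[k], tau_div)
    claims[[k]] <- data.frame(cell_id = id, frame = t, type = am$type,
                              mother_label = am$mother_label,
                              fraction = am$fraction)
  }
  claims <- if (length(claims)) do.call(rbind, claims) else
    data.frame(cell_id = integer(0), frame = integer(0),
               type = character(0), mother_label = integer(0),
               fraction = numeric(0))

  set_cell <- function(id, field, value) {
    cells[match(id, cells$cell_id), field] <<- value
  }
  get_cell <- function(id, field) cells[match(id, cells$cell_id), field]

  for (id in claims$cell_id[claims$type == "ENTERED_BOUNDARY"])
    set_cell(id, "origin", "ENTERED_BOUNDARY")
  for (id in claims$cell_id[claims$type == "SPONTANEOUS"])
    set_cell(id, "origin", "SPONTANEOUS")

  div <- claims[claims$type == "DIVISION", , drop = FALSE]
  div <- div[order(div$frame, -div$fraction, div$cell_id), , drop = FALSE]
  # process frame by frame: splits rewrite ownership of later frames
  for (t_cur in unique(div$frame)) {
    at_t <- div[div$frame == t_cur, , drop = FALSE]
    at_t$mother_id <- vapply(at_t$mother_label,
                             function(l) owner_at(t_cur - 1L, l), integer(1))
    orphan <- is.na(at_t$mother_id)   # mother object unowned: demote
    for (id in at_t$cell_id[orphan]) set_cell(id, "origin", "SPONTANEOUS")
    at_t <- at_t[!orphan, , drop = FALSE]
    for (grp in split(at_t, at_t$mother_id)) {
      m_id <- grp$mother_id[1]; t <- grp$frame[1]
      # continuation: mother's own track still alive at t
      has_cont <- get_cell(m_id, "end_frame") >= t &&
        get_cell(m_id, "birth_frame") < t
      n_slots <- 2L - as.integer(has_cont)
      keep <- head(grp$cell_id, n_slots)
      extra <- setdiff(grp$cell_id, keep)
      if (length(extra) || nrow(grp) > n_slots)
        warning("more than two daughters claim mother ", m_id,
                " at frame ", t, "; extras marked SPONTANEOUS",
                call. = FALSE)
      for (id in extra) set_cell(id, "origin", "SPONTANEOUS")
      if (!has_cont && length(keep) < 2L) {
        # binary division impossible: single orphan over a vanished mother
        for (id in keep) set_cell(id, "origin", "SPONTANEOUS")
        next
      }
      daughters <- keep
      if (has_cont) {
        # split the continuation of the mother's identity at frame t
        cont_id <- next_id; next_id <- next_id + 1L
        sel <- obs$cell_id == m_id & obs$frame >= t
        obs$cell_id[sel] <- cont_id
        cont <- cells[match(m_id, cells$cell_id), ]
        cont$cell_id <- cont_id
        cont$birth_frame <- t
        cont$origin <- "DAUGHTER"
        cont$mother_id <- m_id
        cont$border_start <- FALSE
        cells <- rbind(cells, cont)
        daughters <- c(daughters, cont_id)
      }
      set_cell(m_id, "end_frame", t - 1L)
      set_cell(m_id, "fate", "DIVIDED")
      daughters <- sort(daughters)
      set_cell(m_id, "daughter1", daughters[1])
      set_cell(m_id, "daughter2", daughters[2])
      for (id in daughters) {
        set_cell(id, "origin", "DAUGHTER")
        set_cell(id, "mother_id", m_id)
      }
    }
  }

  # remaining provisional fates
  open <- is.na(cells$fate)
  cells$fate[open] <- ifelse(cells$border_end[open], "LEFT_FIELD", "LOST")
  rownames(cells) <- NULL
  tracks$cells <- cells
  tracks$obs <- obs
  tracks
}

#' Build lineage trees from linked tracks
#'
#' Trees are the weakly connected components of the mother-daughter graph;
#' roots are `INITIAL` or `ENTERED_BOUNDARY` cells. `SPONTANEOUS` tracks
#' are excluded (a tracking-artifact class kept out of biological
#' analyses). Tree ids are also written into `tracks$cells$tree_id`.
#'
#' @param tracks a linked `track_set`.
#' @return list with `membership` (data frame `cell_id`, `tree_id`,
#'   `root_id`), `roots` (root cell id per tree) and the updated `tracks`.
#' @export
build_trees <- function(tracks) {
  cells <- tracks$cells
  root <- cells$cell_id
  mum <- cells$mother_id
  for (iter in seq_len(nrow(cells) + 1)) {
    has_m <- !is.na(mum)
    if (!any(has_m)) break
    if (iter > nrow(cells)) stop2("corrupt lineage: cycle in mother relation")
    root[has_m] <- root[match(mum[has_m], cells$cell_id)]
    mum <- cells$mother_id[match(root, cells$cell_id)]
  }
  if (anyNA(root)) stop2("corrupt lineage: mother outside track set")
  # drop components rooted in a spontaneous appearance (tracking artifacts)
  root_origin <- cells$origin[match(root, cells$cell_id)]
  keep <- root_origin != "SPONTANEOUS"
  sub_root <- root[keep]
  uroot <- sort(unique(sub_root))
  tree_id <- match(sub_root, uroot)
  membership <- data.frame(cell_id = cells$cell_id[keep], tree_id = tree_id,
                           root_id = sub_root)
  tracks$cells$tree_id <- membership$tree_id[match(tracks$cells$cell_id,
                                                   membership$cell_id)]
  list(membership = membership, roots = uroot, tracks = tracks)
}

#' Cell-cycle durations of tracked cells
#'
#' A complete cycle is defined only for cells whose birth (a division) and
#' own division were both observed: duration = (division frame - birth
#' frame) * dt. Roots present at frame 0 (or entering from the boundary)
#' that divide give a censored lower bound; everything else is undefined.
#'
#' @param tracks a linked `track_set`.
#' @return data frame `cell_id`, `duration_h`, `complete` (both endpoints
#'   observed), `censored` (division observed but birth unknown).
#' @export
cycle_durations <- function(tracks) {
  cl <- tracks$cells
  divided <- !is.na(cl$fate) & cl$fate == "DIVIDED"
  dur <- (cl$end_frame - cl$birth_frame + 1) * tracks$dt_h
  data.frame(cell_id = cl$cell_id,
             duration_h = ifelse(divided, dur, NA_real_),
             complete = divided & cl$origin == "DAUGHTER",
             censored = divided & cl$origin %in% c("INITIAL",
                                                   "ENTERED_BOUNDARY"))
}

#' @rdname cycle_durations
#' @param cell_id single cell id.
#' @return `cycle_duration`: list `duration_h`, `complete`, `censored`
#'   (duration `NA` when undefined).
#' @export
cycle_duration <- function(tracks, cell_id) {
  d <- cycle_durations(tracks)
  i <- match(cell_id, d$cell_id)
  list(duration_h = d$duration_h[i], complete = d$complete[i],
       censored = d$censored[i])
}
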