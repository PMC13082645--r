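# Frame-to-frame tracking: identities are propagated by minimizing contour
# variation, scored as 1 - IoU between label supports, with an optimal
# (maximum-cardinality, minimum-cost) bipartite assignment per frame pair.

#' Contour-variation cost between two object masks
#'
#' `1 - IoU` of the two binary supports: 0 for identical supports, 1 for
#' disjoint ones. If either mask is empty the cost is 1.
#'
#' @param mask_a,mask_b binary (or logical) matrices on the same grid.
#' @return cost in `[0, 1]`.
#' @export
contour_cost <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  a <- mask_a > 0; b <- mask_b > 0
  uni <- sum(a | b)
  if (uni == 0) return(1)
  1 - sum(a & b) / uni
}

# Pairwise overlap table between two label images.
# Returns data.frame(label_a, label_b, inter, area_a, area_b, iou).
label_overlaps <- function(lab_a, lab_b) {
  area_a <- tabulate(lab_a[lab_a > 0])
  area_b <- tabulate(lab_b[lab_b > 0])
  sel <- lab_a > 0 & lab_b > 0
  if (!any(sel)) {
    return(data.frame(label_a = integer(0), label_b = integer(0),
                      inter = integer(0), area_a = integer(0),
                      area_b = integer(0), iou = numeric(0)))
  }
  la <- lab_a[sel]; lb <- lab_b[sel]
  nb <- max(lb)
  key <- (la - 1) * nb + lb
  cnt <- tabulate(key)
  nz <- which(cnt > 0)
  a_id <- (nz - 1) %/% nb + 1
  b_id <- (nz - 1) %% nb + 1
  inter <- cnt[nz]
  data.frame(label_a = a_id, label_b = b_id, inter = inter,
             area_a = area_a[a_id], area_b = area_b[b_id],
             iou = inter / (area_a[a_id] + area_b[b_id] - inter))
}

# Optimal one-to-one assignment over candidate pairs, maximizing the number
# of matches first and total weight second; deterministic tie-break toward
# smaller (label_a, label_b).
assign_pairs <- function(pairs, weight) {
  if (!nrow(pairs)) {
    return(data.frame(label_a = integer(0), label_b = integer(0)))
  }
  ua <- sort(unique(pairs$label_a)); ub <- sort(unique(pairs$label_b))
  na <- length(ua); nb <- length(ub)
  ia <- match(pairs$label_a, ua); ib <- match(pairs$label_b, ub)
  w <- 1e4 + weight - 1e-7 * (ia + ib / (nb + 1))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)),
                                    rbind(ia, na + ib), directed = FALSE)
  res <- igraph::max_bipartite_match(g, weights = w)
  m <- res$matching[seq_len(na)]
  ok <- !is.na(m)
  data.frame(label_a = ua[ok], label_b = ub[m[ok] - na])
}

#' Match objects between two consecutive frames
#'
#' Computes the contour-variation cost (`1 - IoU`) for every overlapping
#' pair and solves the optimal one-to-one assignment restricted to pairs
#' with cost below `gate`. Unmatched objects at `t` are reported as
#' disappeared, at `t + 1` as appeared.
#'
#' @param masks_t,masks_t1 label matrices of frames `t` and `t + 1`.
#' @param gate maximum admissible cost in `(0, 1]`; the default 0.9 links
#'   any pair with IoU above 0.1.
#' @return list with `matches` (data frame `label_t`, `label_t1`, `cost`),
#'   `disappeared`, `appeared`.
#' @export
match_frames <- function(masks_t, masks_t1, gate = 0.9) {
  ov <- label_overlaps(masks_t, masks_t1)
  ov <- ov[1 - ov$iou < gate, , drop = FALSE]
  asg <- assign_pairs(data.frame(label_a = ov$label_a, label_b = ov$label_b),
                      weight = ov$iou)
  key <- paste(asg$label_a, asg$label_b)
  ov_key <- paste(ov$label_a, ov$label_b)
  cost <- 1 - ov$iou[match(key, ov_key)]
  labs_t <- sort(unique(masks_t[masks_t > 0]))
  labs_t1 <- sort(unique(masks_t1[masks_t1 > 0]))
  list(matches = data.frame(label_t = asg$label_a, label_t1 = asg$label_b,
                            cost = cost),
       disappeared = setdiff(labs_t, asg$label_a),
       appeared = setdiff(labs_t1, asg$label_b))
}

# Per-label properties of one frame.
mask_props <- function(lab, upp, img = NULL, border_margin_px = 2) {
  w <- which(lab > 0)
  if (!length(w)) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      mean_intensity = numeric(0), at_border = logical(0)))
  }
  n <- nrow(lab)
  l <- lab[w]
  r0 <- (w - 1) %% n          # 0-based row
  c0 <- (w - 1) %/% n         # 0-based col
  area <- tabulate(l)
  ids <- which(area > 0)
  sum_r <- rowsum(r0, l); sum_c <- rowsum(c0, l)
  # extremes per label, on pixels sorted by label
  ord <- order(l)
  ls <- l[ord]; rs <- r0[ord]; cs <- c0[ord]
  bnd <- c(which(diff(ls) != 0), length(ls))
  st <- c(1, head(bnd, -1) + 1)
  minr <- vapply(seq_along(bnd), function(k) min(rs[st[k]:bnd[k]]), numeric(1))
  maxr <- vapply(seq_along(bnd), function(k) max(rs[st[k]:bnd[k]]), numeric(1))
  minc <- vapply(seq_along(bnd), function(k) min(cs[st[k]:bnd[k]]), numeric(1))
  maxc <- vapply(seq_along(bnd), function(k) max(cs[st[k]:bnd[k]]), numeric(1))
  m <- border_margin_px
  at_border <- minr < m | minc < m | maxr >= n - m | maxc >= ncol(lab) - m
  mi <- if (!is.null(img)) as.numeric(rowsum(img[w], l)[, 1] / area[ids])
        else rep(NA_real_, length(ids))
  data.frame(label = ids,
             area_px = area[ids],
             x_um = as.numeric(sum_c[, 1] / area[ids]) * upp,
             y_um = as.numeric(sum_r[, 1] / area[ids]) * upp,
             mean_intensity = mi,
             at_border = at_border)
}

new_track_set <- function(cells, obs, dt_h, um_per_px, n_frames) {
  structure(list(cells = cells, obs = obs, dt_h = dt_h,
                 um_per_px = um_per_px, n_frames = as.integer(n_frames)),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks over %d frames (dt = %g h)\n",
              nrow(x$cells), x$n_frames, x$dt_h))
  invisible(x)
}

#' Track objects across a mask sequence
#'
#' Propagates identities frame to frame with [match_frames()]. Every
#' (frame, label) object belongs to exactly one track. Objects present at
#' frame 0 get origin `INITIAL`; all other appearances and all early track
#' ends are left provisional (`NA`) and resolved by [link_tracks()], which
#' turns them into divisions, boundary events, or spontaneous
#' appearances / losses.
#'
#' @param masks list of label matrices.
#' @param gate assignment gate, see [match_frames()].
#' @param border_margin_px bounding boxes within this many pixels of the
#'   frame edge make a track eligible for `LEFT_FIELD` / `ENTERED_BOUNDARY`.
#' @param movie optional `movie` supplying intensities and calibration.
#' @param um_per_px pixel size when no movie is given.
#' @param dt_h frame interval when no movie is given.
#' @return a `track_set` (pre-linking: provisional origins/fates are `NA`).
#' @export
track_movie <- function(masks, gate = 0.9, border_margin_px = 2,
                        movie = NULL, um_per_px = NULL, dt_h = NULL) {
  if (!length(masks)) stop2("empty mask sequence")
  if (!is.null(movie)) {
    um_per_px <- um_per_px %||% (movie$field_um / movie$px_per_side)
    dt_h <- dt_h %||% movie$dt_h
  }
  um_per_px <- um_per_px %||% 1
  dt_h <- dt_h %||% 0.5
  n_frames <- length(masks)

  props <- mask_props(masks[[1]], um_per_px,
                      img = if (!is.null(movie)) movie$frames[[1]],
                      border_margin_px = border_margin_px)
  next_id <- 1L
  active <- integer(0)               # active[label as character] -> track id
  cells <- list(); obs <- vector("list", n_frames)
  start_track <- function(label, frame, p) {
    id <- next_id; next_id <<- next_id + 1L
    cells[[id]] <<- list(cell_id = id, birth_frame = frame,
                         end_frame = NA_integer_,
                         origin = NA_character_, fate = NA_character_,
                         border_start = p$at_border[p$label == label],
                         border_end = NA)
    id
  }
  end_track <- function(id, frame, at_border) {
    cells[[id]]$end_frame <<- frame
    cells[[id]]$border_end <<- at_border
  }
  rec_obs <- function(frame, p, id_of_label) {
    obs[[frame + 1]] <<- data.frame(
      cell_id = unname(id_of_label[as.character(p$label)]),
      frame = rep(frame, nrow(p)), label = p$label,
      x_um = p$x_um, y_um = p$y_um,
      area_um2 = p$area_px * um_per_px^2,
      mean_intensity = p$mean_intensity)
  }

  id_of <- integer(0)
  for (lb in props$label) {
    id <- start_track(lb, 0L, props)
    cells[[id]]$origin <- "INITIAL"
    id_of[as.character(lb)] <- id
  }
  rec_obs(0L, props, id_of)
  prev_props <- props

  for (f in seq_len(n_frames - 1)) {
    cur <- mask_props(masks[[f + 1]], um_per_px,
                      img = if (!is.null(movie)) movie$frames[[f + 1]],
                      border_margin_px = border_margin_px)
    mm <- match_frames(masks[[f]], masks[[f + 1]], gate = gate)
    new_id_of <- integer(0)
    for (k in seq_len(nrow(mm$matches))) {
      lt <- mm$matches$label_t[k]; lt1 <- mm$matches$label_t1[k]
      new_id_of[as.character(lt1)] <- id_of[[as.character(lt)]]
    }
    for (lb in mm$disappeared) {
      id <- id_of[[as.character(lb)]]
      end_track(id, f - 1L,
                prev_props$at_border[prev_props$label == lb])
    }
    for (lb in mm$appeared) {
      new_id_of[as.character(lb)] <- start_track(lb, f, cur)
    }
    rec_obs(f, cur, new_id_of)
    id_of <- new_id_of
    prev_props <- cur
  }
  for (lb in names(id_of)) {
    id <- id_of[[lb]]
    end_track(id, n_frames - 1L,
              prev_props$at_border[prev_props$label == as.integer(lb)])
    cells[[id]]$fate <- "PRESENT_AT_END"
  }

  cells_df <- do.call(rbind, lapply(cells, function(cl) data.frame(
    cell_id = cl$cell_id, birth_frame = cl$birth_frame,
    end_frame = cl$end_frame, origin = cl$origin, fate = cl$fate,
    mother_id = NA_integer_, daughter1 = NA_integer_,
    daughter2 = NA_integer_,
    border_start = isTRUE(cl$border_start),
    border_end = isTRUE(cl$border_end))))
  rownames(cells_df) <- NULL
  obs_df <- do.call(rbind, obs)
  new_track_set(cells_df, obs_df, dt_h, um_per_px, n_frames)
}
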