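# Tracking-quality metrics against ground truth: HOTA-style detection and
# association accuracy, lineage-tree assignment accuracy, division
# detection and cell-lifetime agreement.

#' Match detections between ground-truth and predicted masks
#'
#' Per frame, the optimal one-to-one matching (maximum matches, then
#' maximum total IoU) between ground-truth and predicted objects among
#' pairs with IoU at or above `iou_threshold`.
#'
#' @param gt_masks,pred_masks lists of label matrices with equal length.
#' @param iou_threshold minimum IoU of an admissible pair, in `(0, 1)`.
#' @return list of class `det_matching`: `pairs` (data frame `frame`,
#'   `gt_label`, `pred_label`, `iou`), `n_gt`, `n_pred`, `tp`, `fp`, `fn`.
#' @export
match_detections <- function(gt_masks, pred_masks, iou_threshold = 0.5) {
  if (length(gt_masks) != length(pred_masks))
    stop2("frame-count mismatch: ", length(gt_masks), " vs ",
          length(pred_masks))
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  pairs <- vector("list", length(gt_masks))
  n_gt <- 0L; n_pred <- 0L
  for (f in seq_along(gt_masks)) {
    a <- gt_masks[[f]]; b <- pred_masks[[f]]
    n_gt <- n_gt + length(unique(a[a > 0]))
    n_pred <- n_pred + length(unique(b[b > 0]))
    ov <- label_overlaps(a, b)
    ov <- ov[ov$iou >= iou_threshold, , drop = FALSE]
    asg <- assign_pairs(data.frame(label_a = ov$label_a,
                                   label_b = ov$label_b),
                        weight = ov$iou)
    if (nrow(asg)) {
      iou <- ov$iou[match(paste(asg$label_a, asg$label_b),
                          paste(ov$label_a, ov$label_b))]
      pairs[[f]] <- data.frame(frame = f - 1L, gt_label = asg$label_a,
                               pred_label = asg$label_b, iou = iou)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs))
    pairs <- data.frame(frame = integer(0), gt_label = integer(0),
                        pred_label = integer(0), iou = numeric(0))
  tp <- nrow(pairs)
  structure(list(pairs = pairs, n_gt = n_gt, n_pred = n_pred,
                 tp = tp, fp = n_pred - tp, fn = n_gt - tp,
                 iou_threshold = iou_threshold),
            class = "det_matching")
}

#' Detection accuracy
#'
#' Pooled over frames: `TP / (TP + FN + FP)`. Defined as 1 when there are
#' neither ground-truth nor predicted objects.
#'
#' @param matching a `det_matching` from [match_detections()].
#' @return fraction in `[0, 1]`.
#' @export
det_a <- function(matching) {
  denom <- matching$tp + matching$fn + matching$fp
  if (denom == 0) return(1)
  matching$tp / denom
}

# Detection-level table with track identities on both sides.
# gt identities: in ground-truth masks the label IS the cell id.
det_track_pairs <- function(matching, pred_tracks) {
  p <- matching$pairs
  if (!nrow(p)) {
    p$gt_track <- integer(0); p$pred_track <- integer(0)
    return(p)
  }
  obs <- pred_tracks$obs
  key_obs <- paste(obs$frame, obs$label)
  p$gt_track <- p$gt_label
  p$pred_track <- obs$cell_id[match(paste(p$frame, p$pred_label), key_obs)]
  p
}

#' Association accuracy (HOTA-style)
#'
#' For every matched detection pair (g, p), the association score is
#' `|TPA| / (|TPA| + |FNA| + |FPA|)`, where TPA are the matched detection
#' pairs shared by g's ground-truth track and p's predicted track, FNA the
#' remaining detections of the ground-truth track and FPA those of the
#' predicted track. AssA is the mean over all matched detection pairs.
#'
#' @param truth a `ground_truth`.
#' @param pred_tracks a linked `track_set` on the predicted masks.
#' @param matching a `det_matching` between `truth$masks` and the
#'   predicted masks.
#' @return fraction in `[0, 1]` (0 when there are no matches).
#' @export
ass_a <- function(truth, pred_tracks, matching) {
  p <- det_track_pairs(matching, pred_tracks)
  p <- p[!is.na(p$pred_track), , drop = FALSE]
  if (!nrow(p)) return(0)
  gt_sizes <- table(truth$obs$cell_id)
  pred_sizes <- table(pred_tracks$obs$cell_id)
  key <- paste(p$gt_track, p$pred_track)
  c_tab <- table(key)
  cpair <- as.numeric(c_tab[key])
  g_sz <- as.numeric(gt_sizes[as.character(p$gt_track)])
  p_sz <- as.numeric(pred_sizes[as.character(p$pred_track)])
  scores <- cpair / (g_sz + p_sz - cpair)
  structure(mean(scores), n = length(scores))
}

# Majority-vote track correspondence from detection pairs.
# Returns named integer vector: from-track id -> to-track id.
majority_map <- function(pairs, from, to) {
  if (!nrow(pairs)) return(integer(0))
  cnt <- stats::aggregate(list(n = pairs$frame),
                          by = list(from = pairs[[from]], to = pairs[[to]]),
                          FUN = length)
  cnt <- cnt[order(cnt$from, -cnt$n, cnt$to), ]
  first <- !duplicated(cnt$from)
  stats::setNames(cnt$to[first], cnt$from[first])
}

#' Lineage-tree assignment accuracy
#'
#' Each retained predicted track is corresponded to the ground-truth track
#' it shares the most matched detections with; each predicted tree is
#' mapped to the ground-truth tree with which it shares the most
#' corresponded cells. The accuracy is the percentage of corresponded
#' cells whose predicted tree maps to their true tree. Spontaneous
#' predicted tracks are excluded before scoring.
#'
#' @inheritParams ass_a
#' @return percent in `[0, 100]` (`NaN` if nothing corresponds).
#' @export
lineage_assignment_accuracy <- function(truth, pred_tracks, matching) {
  p <- det_track_pairs(matching, pred_tracks)
  p <- p[!is.na(p$pred_track), , drop = FALSE]
  cl <- pred_tracks$cells
  retained <- cl$cell_id[cl$origin != "SPONTANEOUS"]
  p <- p[p$pred_track %in% retained, , drop = FALSE]
  corr <- majority_map(p, "pred_track", "gt_track")
  if (!length(corr)) return(NaN)
  pred_tree <- cl$tree_id[match(as.integer(names(corr)), cl$cell_id)]
  gt_tree <- truth$trees$tree_id[match(unname(corr), truth$trees$cell_id)]
  ok <- !is.na(pred_tree) & !is.na(gt_tree)
  pred_tree <- pred_tree[ok]; gt_tree <- gt_tree[ok]
  if (!length(pred_tree)) return(NaN)
  # map each predicted tree to the gt tree with most corresponded cells
  cnt <- stats::aggregate(list(n = gt_tree),
                          by = list(pt = pred_tree, gt = gt_tree),
                          FUN = length)
  cnt <- cnt[order(cnt$pt, -cnt$n, cnt$gt), ]
  tree_map <- stats::setNames(cnt$gt[!duplicated(cnt$pt)], cnt$pt)
  correct <- tree_map[as.character(pred_tree)] == gt_tree
  structure(100 * mean(correct), n = length(correct))
}

#' Division detection precision and recall
#'
#' A predicted division matches a ground-truth division when the mother
#' tracks correspond (majority vote over matched detections) and the
#' division frames differ by at most `frame_tolerance`.
#'
#' @inheritParams ass_a
#' @param frame_tolerance allowed frame offset (default 2).
#' @return list `precision`, `recall`, `n_gt`, `n_pred`.
#' @export
division_scores <- function(truth, pred_tracks, matching,
                            frame_tolerance = 2) {
  p <- det_track_pairs(matching, pred_tracks)
  p <- p[!is.na(p$pred_track), , drop = FALSE]
  corr <- majority_map(p, "pred_track", "gt_track")
  gt_div <- truth$cells[!is.na(truth$cells$fate) &
                          truth$cells$fate == "DIVIDED", , drop = FALSE]
  pr_div <- pred_tracks$cells[!is.na(pred_tracks$cells$fate) &
                                pred_tracks$cells$fate == "DIVIDED", ,
                              drop = FALSE]
  n_gt <- nrow(gt_div); n_pred <- nrow(pr_div)
  if (n_pred == 0 || n_gt == 0) {
    return(list(precision = if (n_pred == 0) NaN else 0,
                recall = if (n_gt == 0) NaN else 0,
                n_gt = n_gt, n_pred = n_pred))
  }
  pr_div$gt_mother <- unname(corr[as.character(pr_div$cell_id)])
  pr_div$div_frame <- pr_div$end_frame + 1L
  gt_div$div_frame <- gt_div$end_frame + 1L
  used <- rep(FALSE, n_gt)
  matched <- 0L
  for (i in order(pr_div$div_frame)) {
    gm <- pr_div$gt_mother[i]
    if (is.na(gm)) next
    j <- which(!used & gt_div$cell_id == gm &
                 abs(gt_div$div_frame - pr_div$div_frame[i]) <=
                   frame_tolerance)
    if (length(j)) { used[j[1]] <- TRUE; matched <- matched + 1L }
  }
  list(precision = matched / n_pred, recall = matched / n_gt,
       n_gt = n_gt, n_pred = n_pred)
}

#' Cell-lifetime (cycle-duration) agreement
#'
#' Over ground-truth complete cycles whose cell corresponds to a predicted
#' cell that also has a complete cycle, the percentage whose durations
#' differ by at most `tolerance_frames`.
#'
#' @inheritParams ass_a
#' @param tolerance_frames allowed duration difference in frames
#'   (default 2, i.e. 1 h at 30-minute intervals).
#' @return percent, or `NaN` (flagged undefined) when no ground-truth
#'   complete cycle has a corresponding predicted complete cycle.
#' @export
lifetime_agreement <- function(truth, pred_tracks, matching,
                               tolerance_frames = 2) {
  p <- det_track_pairs(matching, pred_tracks)
  p <- p[!is.na(p$pred_track), , drop = FALSE]
  g2p <- majority_map(p, "gt_track", "pred_track")
  gt <- truth$cells
  gt_complete <- gt[gt$origin == "DAUGHTER" & !is.na(gt$fate) &
                      gt$fate == "DIVIDED", , drop = FALSE]
  if (!nrow(gt_complete)) return(NaN)
  pc <- pred_tracks$cells
  pred_complete <- pc$origin == "DAUGHTER" & !is.na(pc$fate) &
    pc$fate == "DIVIDED"
  agree <- c(); n_used <- 0L
  for (i in seq_len(nrow(gt_complete))) {
    pid <- g2p[as.character(gt_complete$cell_id[i])]
    if (is.na(pid)) next
    j <- match(pid, pc$cell_id)
    if (!pred_complete[j]) next
    d_gt <- gt_complete$end_frame[i] - gt_complete$birth_frame[i]
    d_pr <- pc$end_frame[j] - pc$birth_frame[j]
    agree <- c(agree, abs(d_gt - d_pr) <= tolerance_frames)
    n_used <- n_used + 1L
  }
  if (!n_used) return(NaN)
  structure(100 * mean(agree), n = n_used)
}

#' Full tracking-quality report
#'
#' Runs all metrics of the module against a simulation's ground truth.
#'
#' @param truth a `ground_truth`.
#' @param pred_tracks linked `track_set` (with trees built, so `tree_id`
#'   is available; see [build_trees()]).
#' @param pred_masks the label masks the tracks were computed on.
#' @param iou_threshold detection IoU threshold (default 0.5).
#' @param division_tolerance,lifetime_tolerance frame tolerances.
#' @return list of class `metrics_report`.
#' @export
evaluate_tracking <- function(truth, pred_tracks, pred_masks,
                              iou_threshold = 0.5,
                              division_tolerance = 2,
                              lifetime_tolerance = 2) {
  m <- match_detections(truth$masks, pred_masks, iou_threshold)
  ds <- division_scores(truth, pred_tracks, m, division_tolerance)
  structure(list(
    det_a = det_a(m),
    ass_a = ass_a(truth, pred_tracks, m),
    lineage_assignment_accuracy =
      lineage_assignment_accuracy(truth, pred_tracks, m),
    division_precision = ds$precision,
    division_recall = ds$recall,
    lifetime_agreement = lifetime_agreement(truth, pred_tracks, m,
                                            lifetime_tolerance),
    iou_threshold = iou_threshold,
    lifetime_tolerance_frames = lifetime_tolerance,
    n_detections = m$n_gt,
    counts = list(tp = m$tp, fp = m$fp, fn = m$fn)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0(
    "tracking metrics (IoU >= %.2f):\n",
    "  DetA                %.3f\n",
    "  AssA                %.3f\n",
    "  lineage assignment  %.1f%%\n",
    "  division P / R      %.3f / %.3f\n",
    "  lifetime agreement  %.1f%%\n"),
    x$iou_threshold, x$det_a, x$ass_a, x$lineage_assignment_accuracy,
    x$division_precision, x$division_recall, x$lifetime_agreement))
  invisible(x)
}
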