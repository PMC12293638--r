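# Rotated-box detection scoring: greedy confidence-descending matching,
# precision/recall, average precision with monotone-envelope interpolation,
# and the mAP50 / mAP95 summary over IOU thresholds 0.50-0.95.

#' Scored detection
#'
#' @param box A [rotated_box()] in pixel coordinates.
#' @param confidence Score in `[0, 1]`.
#' @param image_id Identifier of the image the detection belongs to.
#' @return An object of class `detection`.
#' @export
detection <- function(box, confidence, image_id = "img") {
  stopifnot(is_rotated_box(box), is.numeric(confidence), length(confidence) == 1L)
  if (!is.finite(confidence) || confidence < 0 || confidence > 1) {
    stop("'confidence' must lie in [0, 1]")
  }
  structure(list(box = box, confidence = as.numeric(confidence),
                 image_id = as.character(image_id)),
            class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection> conf %.3f on '%s': %s\n",
              x$confidence, x$image_id, format(x$box)))
  invisible(x)
}

as_detection_list <- function(dets) {
  if (inherits(dets, "detection")) return(list(dets))
  stopifnot(is.list(dets), all(vapply(dets, inherits, logical(1), "detection")))
  dets
}

as_box_list <- function(truths) {
  if (is_rotated_box(truths)) return(list(truths))
  stopifnot(is.list(truths), all(vapply(truths, is_rotated_box, logical(1))))
  truths
}

#' Greedy matching of detections to ground-truth boxes
#'
#' Detections on one image are processed in descending confidence; each claims
#' the not-yet-claimed truth with the highest skew IOU, provided that IOU
#' reaches `iou_threshold` (ties broken by the lowest truth index). Each truth
#' and each detection participates in at most one pair.
#'
#' @param dets List of [detection()]s sharing one image.
#' @param truths List of ground-truth [rotated_box()]es for that image.
#' @param iou_threshold Minimum IOU for a valid match, in `(0, 1]`.
#' @return A list of class `match_result` with `pairs` (data.frame of
#'   detection index, truth index, iou), `unmatched_detections`,
#'   `unmatched_truths` (integer index vectors) and the counts `tp`, `fp`,
#'   `fn`.
#' @export
match_detections <- function(dets, truths, iou_threshold = 0.5) {
  dets <- as_detection_list(dets)
  truths <- as_box_list(truths)
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  nd <- length(dets); nt <- length(truths)
  ord <- if (nd) order(-vapply(dets, `[[`, numeric(1), "confidence")) else integer(0)
  claimed <- rep(FALSE, nt)
  pairs <- list()
  matched_det <- rep(FALSE, nd)
  for (di in ord) {
    best_iou <- -1; best_t <- 0L
    for (ti in seq_len(nt)) {
      if (claimed[ti]) next
      iou <- skew_iou(dets[[di]]$box, truths[[ti]])
      if (iou > best_iou + 1e-15) { # strictly higher wins; ties keep lower index
        best_iou <- iou; best_t <- ti
      }
    }
    if (best_t > 0L && best_iou >= iou_threshold) {
      claimed[best_t] <- TRUE
      matched_det[di] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        detection = di, truth = best_t, iou = best_iou)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(detection = integer(0), truth = integer(0), iou = numeric(0))
  structure(
    list(pairs = pairs,
         unmatched_detections = which(!matched_det),
         unmatched_truths = which(!claimed),
         tp = nrow(pairs),
         fp = sum(!matched_det),
         fn = sum(!claimed)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision and recall from a match result
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. Degenerate
#' conventions: with no detections and no truths both are 1 (nothing to find,
#' nothing wrongly found); with no detections but truths present precision is
#' 0; with detections but no truths recall is 1.
#'
#' @param match A `match_result` from [match_detections()].
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(match) {
  stopifnot(inherits(match, "match_result"))
  precision <- if (match$tp + match$fp == 0) {
    if (match$fn == 0) 1 else 0
  } else match$tp / (match$tp + match$fp)
  recall <- if (match$tp + match$fn == 0) 1 else match$tp / (match$tp + match$fn)
  c(precision = precision, recall = recall)
}

# Internal: TP/FP flags for the globally confidence-ranked detection list.
# Truths are claimed greedily per image as the ranking is swept, which is the
# standard protocol behind mAP50/mAP95.
rank_detections <- function(dets, truths, iou_threshold) {
  dets <- as_detection_list(dets)
  # truths: either a plain list of boxes (single image) or a named list of
  # box lists keyed by image_id
  single <- length(truths) == 0L || is_rotated_box(truths) ||
    (is.list(truths) && length(truths) && is_rotated_box(truths[[1]]))
  truth_map <- if (single) list(.all = as_box_list(truths)) else truths
  n_truth <- sum(vapply(truth_map, length, integer(1)))
  ord <- order(-vapply(dets, `[[`, numeric(1), "confidence"))
  claimed <- lapply(truth_map, function(tt) rep(FALSE, length(tt)))
  tp <- logical(length(dets))
  for (k in seq_along(ord)) {
    d <- dets[[ord[k]]]
    key <- if (single) ".all" else d$image_id
    tt <- truth_map[[key]]
    if (is.null(tt) || !length(tt)) next
    best_iou <- -1; best_t <- 0L
    for (ti in seq_along(tt)) {
      if (claimed[[key]][ti]) next
      iou <- skew_iou(d$box, tt[[ti]])
      if (iou > best_iou + 1e-15) { best_iou <- iou; best_t <- ti }
    }
    if (best_t > 0L && best_iou >= iou_threshold) {
      claimed[[key]][best_t] <- TRUE
      tp[k] <- TRUE
    }
  }
  list(tp = tp, n_truth = n_truth)
}

#' Average precision at one IOU threshold
#'
#' Builds the precision-recall curve by sweeping the global confidence ranking
#' of the detections (pooled across images), applies the monotone envelope
#' (right-to-left running maximum) to precision, and integrates it over
#' recall. With no ground-truth boxes AP is undefined and `NA` is returned
#' (distinct from an AP of 0).
#'
#' @param dets List of [detection()]s.
#' @param truths Ground truth: a list of [rotated_box()]es (single image) or a
#'   named list of such lists keyed by `image_id`.
#' @param iou_threshold IOU threshold defining a true positive.
#' @return AP in `[0, 1]`, or `NA` when there are no truths.
#' @export
average_precision <- function(dets, truths, iou_threshold = 0.5) {
  rk <- rank_detections(dets, truths, iou_threshold)
  if (rk$n_truth == 0L) {
    warning("no ground-truth boxes: AP is undefined")
    return(NA_real_)
  }
  if (!length(rk$tp)) return(0)
  tp_cum <- cumsum(rk$tp)
  fp_cum <- cumsum(!rk$tp)
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / rk$n_truth
  # monotone envelope, then sum precision over recall increments
  prec_env <- rev(cummax(rev(prec)))
  d_rec <- diff(c(0, rec))
  sum(prec_env * d_rec)
}

#' Evaluation summary over the mAP50-mAP95 threshold range
#'
#' Computes AP at each IOU threshold in `thresholds` (default 0.50 to 0.95 in
#' steps of 0.05), reports `map50` (AP at 0.50) and `map95` (the mean over all
#' ten thresholds), plus precision and recall at `iou_threshold = 0.5` after
#' discarding detections below `confidence_cutoff`. The task is single-class,
#' so mAP coincides with AP.
#'
#' @inheritParams average_precision
#' @param thresholds IOU thresholds for the AP sweep.
#' @param confidence_cutoff Minimum confidence for the precision/recall
#'   operating point (default 0.5; the AP sweep itself uses all detections).
#' @return An object of class `eval_summary`.
#' @export
map_range <- function(dets, truths, thresholds = seq(0.5, 0.95, by = 0.05),
                      confidence_cutoff = 0.5) {
  dets <- as_detection_list(dets)
  ap <- vapply(thresholds, function(th) average_precision(dets, truths, th),
               numeric(1))
  names(ap) <- sprintf("%.2f", thresholds)
  kept <- Filter(function(d) d$confidence >= confidence_cutoff, dets)
  single <- length(truths) == 0L || is_rotated_box(truths) ||
    (is.list(truths) && length(truths) && is_rotated_box(truths[[1]]))
  if (single) {
    m <- match_detections(kept, truths, iou_threshold = 0.5)
    tp <- m$tp; fp <- m$fp; fn <- m$fn
  } else {
    tp <- fp <- fn <- 0L
    for (key in names(truths)) {
      m <- match_detections(Filter(function(d) d$image_id == key, kept),
                            truths[[key]], iou_threshold = 0.5)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    stray <- Filter(function(d) !(d$image_id %in% names(truths)), kept)
    fp <- fp + length(stray)
  }
  precision <- if (tp + fp == 0) { if (fn == 0) 1 else 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  structure(
    list(precision = precision, recall = recall,
         ap_by_threshold = ap,
         map50 = unname(ap[["0.50"]]),
         map95 = mean(ap),
         confidence_cutoff = confidence_cutoff),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, digits = 3, ...) {
  cat("<eval_summary>\n")
  cat(sprintf("  precision: %.*f   recall: %.*f  (confidence cutoff %.2f)\n",
              digits, x$precision, digits, x$recall, x$confidence_cutoff))
  cat(sprintf("  mAP50: %.*f   mAP95: %.*f\n", digits, x$map50, digits, x$map95))
  cat("  AP by IOU threshold:\n")
  for (nm in names(x$ap_by_threshold)) {
    cat(sprintf("    %s: %.*f\n", nm, digits, x$ap_by_threshold[[nm]]))
  }
  invisible(x)
}

#' Serialize an evaluation summary
#'
#' Writes the summary as flat `key: value` text or JSON.
#'
#' @param x An `eval_summary`.
#' @param path Output file path.
#' @param format `"text"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_eval_summary <- function(x, path, format = c("text", "json")) {
  stopifnot(inherits(x, "eval_summary"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(precision = x$precision, recall = x$recall, map50 = x$map50,
           map95 = x$map95, ap_by_threshold = as.list(x$ap_by_threshold),
           confidence_cutoff = x$confidence_cutoff),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- c(
      sprintf("precision: %.6f", x$precision),
      sprintf("recall: %.6f", x$recall),
      sprintf("map50: %.6f", x$map50),
      sprintf("map95: %.6f", x$map95),
      sprintf("confidence_cutoff: %.2f", x$confidence_cutoff),
      sprintf("ap@%s: %.6f", names(x$ap_by_threshold), x$ap_by_threshold)
    )
    writeLines(lines, path)
  }
  invisible(path)
}
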