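#' Confusion counts at a screening cutoff
#'
#' Thresholds index values with a strict inequality in the stated
#' direction (`below`: values strictly under the cutoff are called
#' positive; `above`: strictly over). Values exactly at the cutoff are
#' negative calls. `NA` values are excluded (their count is attached as
#' attribute `"n_excluded"`).
#'
#' @param values Numeric vector of index values.
#' @param labels Logical vector of ground truth (TRUE = the gait feature
#'   is present), same length as `values`.
#' @param cutoff Scalar cutoff.
#' @param direction `"below"` or `"above"`.
#' @return List of class `confusion` with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutoff <- function(values, labels, cutoff,
                                direction = c("below", "above")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(labels))
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    .gp_message("confusion_at_cutoff: excluded ", n_excluded, " undefined values")
  values <- values[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  call_pos <- if (direction == "below") values < cutoff else values > cutoff
  structure(list(tp = sum(call_pos & labels), fp = sum(call_pos & !labels),
                 tn = sum(!call_pos & !labels), fn = sum(!call_pos & labels)),
            class = "confusion", n_excluded = n_excluded)
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d FP=%d TN=%d FN=%d (sens %.3f, spec %.3f)\n",
              x$tp, x$fp, x$tn, x$fn,
              x$tp / (x$tp + x$fn), x$tn / (x$tn + x$fp)))
  invisible(x)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = (TP * TN) / (FN * FP)` with the Woolf logit interval
#' `exp(log OR +/- 1.96 * sqrt(1/TP + 1/FP + 1/FN + 1/TN))`. When any
#' cell is zero, the Haldane-Anscombe correction adds 0.5 to every cell
#' (flagged in the result).
#'
#' @param counts A [confusion_at_cutoff()] result, or a list/vector with
#'   elements `tp`, `fp`, `tn`, `fn`.
#' @return List with `or`, `lo`, `hi`, and logical `corrected`.
#' @export
odds_ratio <- function(counts) {
  cells <- c(tp = counts[["tp"]], fp = counts[["fp"]],
             tn = counts[["tn"]], fn = counts[["fn"]])
  stopifnot(all(cells >= 0))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[["tp"]] * cells[["tn"]]) / (cells[["fn"]] * cells[["fp"]])
  se <- sqrt(sum(1 / cells))
  list(or = or, lo = exp(log(or) - 1.96 * se), hi = exp(log(or) + 1.96 * se),
       corrected = corrected)
}

#' Odds ratio implied by sensitivity and specificity
#'
#' For any 2x2 screening table, `OR = [sens/(1-sens)] * [spec/(1-spec)]`
#' exactly. Useful for checking the internal consistency of published
#' screening tables.
#'
#' @param sens Sensitivity, strictly inside (0, 1).
#' @param spec Specificity, strictly inside (0, 1).
#' @return Scalar odds ratio. Boundary inputs (0 or 1) return 0 or `Inf`
#'   with a warning.
#' @export
or_from_sens_spec <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  if (sens %in% c(0, 1) || spec %in% c(0, 1)) {
    warning("sensitivity/specificity at the boundary: odds ratio is 0 or Inf")
    return((sens / (1 - sens)) * (spec / (1 - spec)))
  }
  (sens / (1 - sens)) * (spec / (1 - spec))
}

#' ROC AUC with DeLong 95% confidence interval
#'
#' Area under the ROC curve via the Mann-Whitney formulation
#' (tie-corrected), with a DeLong 95% CI, computed with \pkg{pROC}. The
#' `direction` states which tail is disease-positive: `"below"` means
#' smaller values indicate the gait feature.
#'
#' @inheritParams confusion_at_cutoff
#' @param direction `"below"` or `"above"`.
#' @return List with `auc`, `lo`, `hi`, and logical `degenerate` (all
#'   values tied; AUC fixed at 0.5 with an undefined CI).
#' @export
roc_auc <- function(values, labels, direction = c("below", "above")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(labels))
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels)) stop("both classes must be present")
  if (length(unique(values)) < 2L)
    return(list(auc = 0.5, lo = NA_real_, hi = NA_real_, degenerate = TRUE))
  r <- pROC::roc(response = labels, predictor = values,
                 levels = c(FALSE, TRUE),
                 direction = if (direction == "below") ">" else "<",
                 quiet = TRUE)
  ci <- as.numeric(withCallingHandlers(
    pROC::ci.auc(r, method = "delong"),
    # perfect separation gives a point CI; pROC warns, we flag via lo == hi
    warning = function(w) {
      if (grepl("always 1-1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  list(auc = as.numeric(pROC::auc(r)), lo = ci[1L], hi = ci[3L],
       degenerate = FALSE)
}

#' Default feature-to-index screening pairs
#'
#' The published screening layout: which index (with which cutoff and
#' direction) screens for which gait feature.
#'
#' @return Data frame with columns `feature`, `index`, `cutoff`,
#'   `direction`.
#' @export
default_index_pairs <- function() {
  data.frame(
    feature = c("shuffling", "shuffling", "shuffling", "short_stepped",
                "wide_based", "wide_based", "wide_based"),
    index = c("hip_angle_range", "knee_angle_range",
              "heel_vertical_amplitude", "knee_angle_range",
              "heel_outward_shift", "toe_outward_shift", "leg_outward_shift"),
    cutoff = c(30, 45, 0.1, 45, -0.08, 0.18, 0.1),
    direction = c("below", "below", "below", "below",
                  "above", "above", "above"),
    stringsAsFactors = FALSE)
}

#' Cohort-level screening report
#'
#' Analyzes every recording in a labeled cohort and evaluates each
#' (gait feature, index) pair: ROC AUC with 95% CI, sensitivity and
#' specificity at the cutoff, and odds ratio with 95% CI.
#'
#' @param manifest Data frame with columns `subject_id`,
#'   `label_shuffling`, `label_short_stepped`, `label_wide_based`, and
#'   either a `path` column of keypoint CSV paths or a `recording`
#'   list-column of [gait_recording()] objects (as produced by
#'   [simulate_cohort()]).
#' @param level Tolerance-ellipse level.
#' @param score_threshold Confidence threshold.
#' @param pairs Feature/index table as from [default_index_pairs()].
#' @param amplitude_mode Passed to [compute_gait_indices()].
#' @return Data frame with one row per pair: `feature`, `index`,
#'   `cutoff`, `auc`, `auc_lo`, `auc_hi`, `sens`, `spec`, `or`, `or_lo`,
#'   `or_hi`, `tp`, `fp`, `tn`, `fn`. Attribute `"skipped"` lists
#'   recordings that could not be analyzed; attribute `"index_values"`
#'   holds the per-recording index matrix.
#' @export
cohort_report <- function(manifest, level = 0.75, score_threshold = 0.7,
                          pairs = default_index_pairs(),
                          amplitude_mode = c("ellipse", "raw")) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("manifest is empty")
  idx_names <- c("hip_angle_range", "knee_angle_range",
                 "heel_vertical_amplitude", "foot_angle",
                 "heel_outward_shift", "toe_outward_shift",
                 "leg_outward_shift")
  vals <- matrix(NA_real_, nrow(manifest), length(idx_names),
                 dimnames = list(manifest$subject_id, idx_names))
  skipped <- character(0)
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      rec <- if (!is.null(manifest$recording))
        manifest$recording[[i]] else read_recording(manifest$path[i])
      tracks <- project_recording(rec, score_threshold)
      compute_gait_indices(tracks, level,
                           amplitude_mode = amplitude_mode)$indices
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, sprintf("%s: %s", manifest$subject_id[i],
                                    conditionMessage(res)))
    } else {
      vals[i, ] <- res[idx_names]
    }
  }
  # evaluate only pairs whose feature has both classes in the manifest
  single <- character(0)
  usable <- logical(nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    lab_col <- paste0("label_", pairs$feature[j])
    if (is.null(manifest[[lab_col]]))
      stop("manifest has no column '", lab_col, "'")
    labels <- as.logical(manifest[[lab_col]])
    usable[j] <- any(labels, na.rm = TRUE) && !all(labels, na.rm = TRUE)
    if (!usable[j]) single <- union(single, pairs$feature[j])
  }
  if (!any(usable))
    stop("labels for feature(s) ", paste(single, collapse = ", "),
         " contain a single class; nothing to evaluate")
  if (length(single))
    warning("skipping single-class feature(s): ", paste(single, collapse = ", "))
  pairs <- pairs[usable, , drop = FALSE]

  rows <- vector("list", nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    labels <- as.logical(manifest[[paste0("label_", pairs$feature[j])]])
    v <- vals[, pairs$index[j]]
    auc <- roc_auc(v, labels, pairs$direction[j])
    cm <- confusion_at_cutoff(v, labels, pairs$cutoff[j], pairs$direction[j])
    or <- odds_ratio(cm)
    rows[[j]] <- data.frame(
      feature = pairs$feature[j], index = pairs$index[j],
      cutoff = pairs$cutoff[j],
      auc = auc$auc, auc_lo = auc$lo, auc_hi = auc$hi,
      sens = cm$tp / (cm$tp + cm$fn), spec = cm$tn / (cm$tn + cm$fp),
      or = or$or, or_lo = or$lo, or_hi = or$hi,
      tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  attr(out, "index_values") <- vals
  out
}
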