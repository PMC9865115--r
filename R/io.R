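#' Keypoint CSV dialect
#'
#' Recordings are interchanged as UTF-8 CSV with a `'.'` decimal mark.
#' Leading comment lines starting with `#` carry metadata
#' (`# fps:`, `# direction:`, `# subject_id:`, `# channel:`), followed by a
#' header row `frame,time,<name>_x,<name>_y,<name>_z,<name>_score` for each
#' of the 24 canonical keypoints in [keypoint_names()] order, one data row
#' per frame. Coordinates are navel-relative: x = screen-right, y =
#' screen-up, z = toward the camera, with the origin at the subject's navel
#' in every frame. Empty cells denote absent samples (never zeros).
#'
#' @name keypoint-csv-dialect
#' @keywords internal
NULL

.dialect_columns <- function() {
  kp <- keypoint_names()
  c("frame", "time",
    as.vector(t(outer(kp, c("x", "y", "z", "score"),
                      function(a, b) paste(a, b, sep = "_")))))
}

#' Read a keypoint recording from CSV
#'
#' Parses the wide keypoint CSV dialect (see `keypoint-csv-dialect`). Every
#' canonical column must be present; empty cells become absent samples.
#'
#' @param path Path to a CSV file.
#' @return A [gait_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(fps = 30, direction = "unknown", subject_id = "subject",
               channel = "smoothed")
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([a-z_]+):\\s*(.+?)\\s*$", ml))[[1L]]
    if (length(m) == 3L && m[2L] %in% names(meta)) meta[[m[2L]]] <- m[3L]
  }
  meta$fps <- as.numeric(meta$fps)

  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("malformed file: no header row")
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  expected <- .dialect_columns()
  missing <- setdiff(expected, header)
  if (length(missing))
    stop("malformed header: missing column '", missing[1L], "'")
  extra <- setdiff(header, expected)
  if (length(extra))
    stop("malformed header: unexpected column '", extra[1L], "'")

  df <- read.csv(text = paste(body, collapse = "\n"),
                 colClasses = "numeric", check.names = FALSE)
  n <- nrow(df)
  kp <- keypoint_names()
  pos <- array(NA_real_, c(n, 24L, 3L),
               dimnames = list(NULL, kp, c("x", "y", "z")))
  score <- matrix(NA_real_, n, 24L, dimnames = list(NULL, kp))
  if (n > 0L) {
    for (k in kp) {
      pos[, k, "x"] <- df[[paste0(k, "_x")]]
      pos[, k, "y"] <- df[[paste0(k, "_y")]]
      pos[, k, "z"] <- df[[paste0(k, "_z")]]
      score[, k] <- df[[paste0(k, "_score")]]
    }
    # a sample is absent if any of its four cells is empty
    absent <- is.na(score) | apply(is.na(pos), c(1L, 2L), any)
    score[absent] <- NA_real_
    for (d in 1:3) { sl <- pos[, , d, drop = FALSE]; sl[absent] <- NA_real_; pos[, , d] <- sl }
  }
  tm <- if (n > 0L) df$time else numeric(0)
  if (n > 1L && any(diff(tm) <= 0))
    stop("invalid recording: time column is not strictly increasing")
  gait_recording(time = tm, pos = pos, score = score, fps = meta$fps,
                 direction = meta$direction, subject_id = meta$subject_id)
}

#' Write a keypoint recording to CSV
#'
#' Inverse of [read_recording()]: coordinates are written with 9 decimals
#' and scores with 6, so a read/write round trip reproduces coordinates to
#' 1e-9 and scores exactly at 6 decimals. Output is byte-stable for a given
#' recording.
#'
#' @param rec A [gait_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gait_recording"))
  n <- length(rec$time)
  kp <- keypoint_names()
  fmt <- function(x, digits) {
    out <- sprintf(paste0("%.", digits, "f"), x)
    out[is.na(x)] <- ""
    out
  }
  cols <- vector("list", 2L + 96L)
  cols[[1L]] <- as.character(seq_len(n))
  cols[[2L]] <- fmt(rec$time, 6L)
  i <- 3L
  for (k in kp) {
    cols[[i]]      <- fmt(rec$pos[, k, "x"], 9L)
    cols[[i + 1L]] <- fmt(rec$pos[, k, "y"], 9L)
    cols[[i + 2L]] <- fmt(rec$pos[, k, "z"], 9L)
    cols[[i + 3L]] <- fmt(rec$score[, k], 6L)
    i <- i + 4L
  }
  rows <- if (n > 0L) do.call(paste, c(cols, sep = ",")) else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "# gaitplanes keypoint recording v1",
    "# coordinates: navel-relative; x = screen-right, y = screen-up, z = toward camera",
    paste0("# fps: ", format(rec$fps)),
    paste0("# direction: ", rec$direction),
    paste0("# subject_id: ", rec$subject_id),
    paste(.dialect_columns(), collapse = ","),
    rows), con = con, sep = "\n")
  invisible(path)
}

#' Filter keypoint samples by confidence score
#'
#' Drops (sets to absent) every sample whose score is strictly below
#' `threshold`; frames are kept even when some of their samples are
#' dropped. The default threshold of 0.7 matches the capture app's
#' recommended confidence floor.
#'
#' @param rec A [gait_recording()].
#' @param threshold Confidence threshold in `[0, 1]`; samples with
#'   `score >= threshold` are retained.
#' @return The filtered [gait_recording()], with an attribute `"dropped"`
#'   giving per-keypoint dropped-sample counts.
#' @export
filter_by_score <- function(rec, threshold = 0.7) {
  stopifnot(inherits(rec, "gait_recording"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  drop <- !is.na(rec$score) & rec$score < threshold
  out <- rec
  out$score[drop] <- NA_real_
  for (d in 1:3) {
    sl <- out$pos[, , d, drop = FALSE]
    sl[drop] <- NA_real_
    out$pos[, , d] <- sl
  }
  dropped <- colSums(drop)
  if (any(dropped > 0))
    .gp_message("filter_by_score: dropped ", sum(dropped), " samples (",
                paste0(names(dropped)[dropped > 0], "=", dropped[dropped > 0],
                       collapse = ", "), ")")
  attr(out, "dropped") <- dropped
  out
}

#' Read a cohort manifest
#'
#' A manifest CSV has columns `subject_id,path,label_shuffling,
#' label_short_stepped,label_wide_based` with 0/1 labels; `path` points to
#' keypoint CSV files (relative paths are resolved against the manifest's
#' directory).
#'
#' @param path Manifest CSV path.
#' @return A data frame with logical label columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path",
            "label_shuffling", "label_short_stepped", "label_wide_based")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest is missing column '", missing[1L], "'")
  for (cl in grep("^label_", names(df), value = TRUE))
    df[[cl]] <- as.logical(df[[cl]])
  rel <- !is.na(df$path) & nzchar(df$path) & !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}
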