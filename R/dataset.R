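#' Pose class labels
#'
#' Frames are labeled 1 standing, 2 sitting, 3 lying down, 4 "dangerous
#' sitting" (seated, slumped forward or collapsed backward). Two auxiliary
#' markers exist: \code{LABEL_TRANSITION} (frame recorded while moving
#' between poses) and \code{LABEL_UNTRACKED} (tracking lost, sentinel frame);
#' both are removed before training or scoring.
#'
#' @export
POSE_CLASSES <- c(standing = 1L, sitting = 2L, lying = 3L,
                  dangerous_sitting = 4L)

#' @rdname POSE_CLASSES
#' @export
LABEL_TRANSITION <- 0L

#' @rdname POSE_CLASSES
#' @export
LABEL_UNTRACKED <- -1L

#' Build a classification dataset from labeled feature tables
#'
#' Joins per-frame features with labels, drops transition and untracked
#' frames, and returns the design matrix the classifier consumes.
#'
#' @param features feature table from \code{\link{assemble_features}} /
#'   \code{\link{select_features}} (metadata + feature columns).
#' @param labels integer vector aligned with \code{features} rows: 1-4, or
#'   \code{LABEL_TRANSITION} / \code{LABEL_UNTRACKED}.
#' @return list of class \code{pose_dataset}: \code{X} (numeric matrix),
#'   \code{y} (integer labels 1-4), \code{subject_id} (character). Emits a
#'   warning when nothing survives filtering.
#' @export
build_dataset <- function(features, labels) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop("labels length (", length(labels), ") != feature rows (",
         nrow(features), ")")
  ok_lab <- labels %in% c(POSE_CLASSES, LABEL_TRANSITION, LABEL_UNTRACKED)
  if (any(!ok_lab))
    stop("unknown label value(s): ",
         paste(unique(labels[!ok_lab]), collapse = ", "))
  meta <- intersect(frame_meta_columns(), names(features))
  fcols <- setdiff(names(features), meta)
  X <- as.matrix(features[, fcols, drop = FALSE])
  tracked <- if ("tracked" %in% meta) features$tracked else
    !apply(X == SENTINEL, 1L, all)
  keep <- labels %in% POSE_CLASSES & tracked
  n_trans <- sum(labels == LABEL_TRANSITION)
  n_untr <- sum(!keep) - n_trans
  message("dataset: kept ", sum(keep), " frames; removed ", n_trans,
          " transition and ", n_untr, " untracked frames")
  if (!any(keep)) warning("no frames left after removing transition/untracked frames")
  structure(list(
    X = X[keep, , drop = FALSE],
    y = labels[keep],
    subject_id = if ("subject_id" %in% meta)
      as.character(features$subject_id[keep]) else rep("S01", sum(keep))
  ), class = "pose_dataset")
}

#' @export
print.pose_dataset <- function(x, ...) {
  cat("pose_dataset:", nrow(x$X), "frames x", ncol(x$X), "features,",
      length(unique(x$subject_id)), "subject(s)\n")
  print(dataset_summary(x$y))
  invisible(x)
}

#' Per-class frame counts and proportions
#'
#' Tabulates pose labels 1-4 and reports counts, proportions and the total;
#' the reporting path used to audit dataset arithmetic after transition
#' removal and collation of the per-camera streams.
#'
#' @param y integer pose labels (values outside 1-4 are ignored).
#' @return data.frame with one row per class plus a \code{total} attribute.
#' @export
dataset_summary <- function(y) {
  y <- y[y %in% POSE_CLASSES]
  counts <- as.integer(table(factor(y, levels = POSE_CLASSES)))
  out <- data.frame(class = as.integer(POSE_CLASSES),
                    pose = names(POSE_CLASSES),
                    frames = counts,
                    proportion = if (sum(counts) > 0)
                      counts / sum(counts) else rep(0, 4L))
  attr(out, "total") <- sum(counts)
  out
}

#' Subject-wise train/test split
#'
#' Splits a dataset by whole subject: every frame of a subject lands on one
#' side only, mirroring a leave-subjects-out evaluation protocol.
#'
#' @param dataset a \code{pose_dataset}.
#' @param n_train number of training subjects (used when explicit lists are
#'   not given).
#' @param train_subjects,test_subjects optional explicit subject id vectors;
#'   they must not overlap and must cover only known subjects.
#' @param seed integer seed for the random subject draw.
#' @return list with \code{train} and \code{test}, each a
#'   \code{pose_dataset}, plus the subject assignment.
#' @export
split_by_subject <- function(dataset, n_train = 10L, train_subjects = NULL,
                             test_subjects = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "pose_dataset"))
  subjects <- unique(dataset$subject_id)
  if (!is.null(train_subjects) || !is.null(test_subjects)) {
    if (is.null(train_subjects)) train_subjects <- setdiff(subjects, test_subjects)
    if (is.null(test_subjects)) test_subjects <- setdiff(subjects, train_subjects)
    overlap <- intersect(train_subjects, test_subjects)
    if (length(overlap) > 0L)
      stop("subject(s) present in both split sides: ",
           paste(overlap, collapse = ", "))
  } else {
    if (n_train >= length(subjects))
      stop("n_train must be smaller than the number of subjects (",
           length(subjects), ")")
    set.seed(as.integer(seed))
    train_subjects <- sort(sample(subjects, n_train))
    test_subjects <- setdiff(subjects, train_subjects)
  }
  take <- function(ids) {
    sel <- dataset$subject_id %in% ids
    structure(list(X = dataset$X[sel, , drop = FALSE],
                   y = dataset$y[sel],
                   subject_id = dataset$subject_id[sel]),
              class = "pose_dataset")
  }
  list(train = take(train_subjects), test = take(test_subjects),
       train_subjects = train_subjects, test_subjects = test_subjects)
}
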