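#' Read and write skeleton frame files
#'
#' Comma-separated text with a header row and columns \code{timestamp},
#' \code{camera_id}, \code{subject_id}, \code{tracked}, then the 51
#' coordinate columns \code{j01_x .. j17_z} (meters). One file per camera
#' per session. Coordinates survive a round trip within 1e-9 m; the
#' sentinel 999 is preserved exactly.
#'
#' @param path file path.
#' @param frames frame table to write.
#' @return \code{read_frames} returns the validated frame table;
#'   \code{write_frames} returns \code{path} invisibly.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("frame file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  expected <- c(frame_meta_columns(), coord_columns())
  if (!identical(header, expected))
    stop("malformed frame file header in ", path,
         " (line 1): expected ", length(expected), " documented columns")
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  bad <- which(nf != length(expected))
  bad <- setdiff(bad, 1L)
  if (length(bad) > 0L)
    stop("malformed frame row in ", path, " at line ", bad[1], ": ",
         nf[bad[1]], " fields instead of ", length(expected))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "integer", "character",
                                       "logical",
                                       rep("numeric", 3L * N_JOINTS)))
  validate_frames(df)
}

#' @rdname read_frames
#' @export
write_frames <- function(frames, path) {
  validate_frames(frames)
  out <- frames[, c(frame_meta_columns(), coord_columns())]
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-frame label files
#'
#' Comma-separated text: \code{timestamp}, \code{camera_id},
#' \code{subject_id}, \code{label} (1-4, 0 transition, -1 untracked).
#'
#' @param path file path.
#' @param labels label table.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "integer", "character",
                                       "integer"))
  need <- c("timestamp", "camera_id", "subject_id", "label")
  if (!identical(names(df), need))
    stop("malformed label file header in ", path)
  df
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write feature files
#'
#' Comma-separated text: the metadata columns then the feature columns (37
#' canonical names, or a selected subset, in order).
#'
#' @param path file path.
#' @param features feature table from \code{\link{assemble_features}} or
#'   \code{\link{select_features}}.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- setdiff(names(df), frame_meta_columns())
  unknown <- setdiff(fcols, feature_names())
  if (length(unknown) > 0L)
    stop("malformed feature file ", path, ": unknown column(s) ",
         paste(unknown, collapse = ", "))
  df
}

#' @rdname read_features
#' @export
write_features <- function(features, path) {
  utils::write.csv(format(features, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write camera calibration files
#'
#' Structured key-value text, one block per camera:
#' \preformatted{
#' camera: 1
#' rotation: r11 r12 r13 r21 r22 r23 r31 r32 r33
#' translation: tx ty tz
#' }
#' Rotations are row-major camera-to-room matrices.
#'
#' @param path file path.
#' @param calibrations named or ordered list of
#'   \code{\link{rigid_transform}}s.
#' @return \code{read_calibration} returns a list of
#'   \code{rigid_transform}s indexed by camera id.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- list(); cur <- NULL; rot <- NULL; tra <- NULL
  flush_cam <- function() {
    if (is.null(cur)) return()
    if (is.null(rot) || is.null(tra))
      stop("calibration error: camera ", cur, " lacks rotation/translation")
    out[[as.character(cur)]] <<- rigid_transform(
      matrix(rot, 3, 3, byrow = TRUE), tra)
  }
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = ":"))
    if (key == "camera") {
      flush_cam()
      cur <- as.integer(val); rot <- NULL; tra <- NULL
    } else if (key == "rotation") {
      rot <- as.numeric(strsplit(val, "\\s+")[[1]])
      if (length(rot) != 9L) stop("calibration error: rotation needs 9 values")
    } else if (key == "translation") {
      tra <- as.numeric(strsplit(val, "\\s+")[[1]])
      if (length(tra) != 3L) stop("calibration error: translation needs 3 values")
    } else stop("calibration error: unknown key '", key, "' in ", path)
  }
  flush_cam()
  if (length(out) == 0L) stop("calibration error: no cameras in ", path)
  out
}

#' @rdname read_calibration
#' @export
write_calibration <- function(calibrations, path) {
  ids <- names(calibrations)
  if (is.null(ids)) ids <- as.character(seq_along(calibrations))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(calibrations)) {
    tf <- calibrations[[i]]
    stopifnot(inherits(tf, "rigid_transform"))
    writeLines(c(paste0("camera: ", ids[i]),
                 paste0("rotation: ",
                        paste(sprintf("%.15g", t(tf$rotation)), collapse = " ")),
                 paste0("translation: ",
                        paste(sprintf("%.15g", tf$translation), collapse = " "))),
               con)
  }
  invisible(path)
}

#' Write a trained MLP model to structured text
#'
#' @param model an \code{mlp_model}.
#' @param path file path.
#' @param feature_spec selected feature names the model expects.
#' @export
write_model <- function(model, path, feature_spec = DEFAULT_SELECTION) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("sizes: ", paste(model$sizes, collapse = " ")),
               paste0("features: ", paste(feature_spec, collapse = " ")),
               paste0("weights: ",
                      paste(sprintf("%.17g", pack_weights(model)),
                            collapse = " "))), con)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (length(ln) != 1L) stop("malformed model file: missing ", key)
    sub(paste0("^", key, ": "), "", ln)
  }
  sizes <- as.integer(strsplit(get("sizes"), " ")[[1]])
  feats <- strsplit(get("features"), " ")[[1]]
  w <- as.numeric(strsplit(get("weights"), " ")[[1]])
  model <- mlp_init(sizes[1], sizes[2:3], sizes[4], seed = 0L)
  model <- unpack_weights(model, w)
  attr(model, "feature_spec") <- feats
  model
}
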