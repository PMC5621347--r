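#' Construct a tremor recording
#'
#' Container for a six-channel IMU recording: tri-axial acceleration plus
#' tri-axial angular velocity sampled at a common rate. All downstream code
#' assumes SI units (m/s^2 and rad/s); [read_recording()] converts g and
#' deg/s at read time.
#'
#' @param accel numeric N x 3 matrix of acceleration (m/s^2), columns x, y, z.
#' @param gyro numeric N x 3 matrix of angular velocity (rad/s), columns x, y, z.
#' @param sample_rate sampling rate in Hz.
#' @param id optional recording identifier.
#' @param hand optional `"left"` or `"right"`.
#' @param label optional UPDRS rest-tremor score in `0:4`; `NA` for
#'   inference-only recordings.
#' @return An object of class `tremor_recording`: a list with elements
#'   `accel`, `gyro`, `sample_rate`, `meta`.
#' @export
tremor_recording <- function(accel, gyro, sample_rate = 125,
                             id = NA_character_, hand = NA_character_,
                             label = NA_integer_) {
  accel <- as_axis_matrix(accel, "accel")
  gyro <- as_axis_matrix(gyro, "gyro")
  if (nrow(accel) != nrow(gyro)) {
    stop("accel and gyro must have the same number of samples (",
         nrow(accel), " vs ", nrow(gyro), ")")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  if (!is.na(label)) {
    label <- as.integer(label)
    if (!label %in% 0:4) stop("label must be in 0:4, got ", label)
  }
  if (!is.na(hand) && !hand %in% c("left", "right")) {
    stop("hand must be 'left' or 'right'")
  }
  structure(
    list(accel = accel, gyro = gyro, sample_rate = as.numeric(sample_rate),
         meta = list(id = id, hand = hand, label = label)),
    class = "tremor_recording"
  )
}

as_axis_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(what, " must have 3 columns (x, y, z)")
  if (!is.numeric(x)) stop(what, " must be numeric")
  colnames(x) <- c("x", "y", "z")
  x
}

#' @export
print.tremor_recording <- function(x, ...) {
  n <- nrow(x$accel)
  cat(sprintf("<tremor_recording> %d samples at %g Hz (%.1f s)\n",
              n, x$sample_rate, n / x$sample_rate))
  cat(sprintf("  id: %s  hand: %s  label: %s\n",
              x$meta$id, x$meta$hand,
              ifelse(is.na(x$meta$label), "unlabelled", x$meta$label)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [tremor_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "tremor_recording"))
  nrow(rec$accel) / rec$sample_rate
}

#' Read an IMU recording from CSV
#'
#' Expects a comma-separated file with a header row and columns `ax, ay, az`
#' (acceleration) and `gx, gy, gz` (angular velocity); a `t` column is
#' accepted and ignored beyond ordering (sampling is taken to be uniform at
#' `sample_rate`). No resampling is performed. Channels are converted to SI
#' at read time: g to m/s^2 by 9.80665, deg/s to rad/s by pi/180.
#'
#' @param path path to the CSV file.
#' @param sample_rate sampling rate in Hz (default 125).
#' @param accel_unit `"ms2"` (already SI) or `"g"`.
#' @param gyro_unit `"rads"` (already SI) or `"dps"` (degrees per second).
#' @param id,hand,label recording metadata; see [tremor_recording()].
#' @return A [tremor_recording()].
#' @export
read_recording <- function(path, sample_rate = 125,
                           accel_unit = c("ms2", "g"),
                           gyro_unit = c("rads", "dps"),
                           id = basename(path), hand = NA_character_,
                           label = NA_integer_) {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- c("ax", "ay", "az", "gx", "gy", "gz")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("recording file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in needed) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop("non-numeric value in column '", col, "' at data row ", bad)
    }
  }
  accel <- as.matrix(df[needed[1:3]])
  gyro <- as.matrix(df[needed[4:6]])
  if (accel_unit == "g") accel <- accel * 9.80665
  if (gyro_unit == "dps") gyro <- gyro * pi / 180
  tremor_recording(accel, gyro, sample_rate = sample_rate,
                   id = id, hand = hand, label = label)
}

#' Write an IMU recording to CSV
#'
#' Writes columns `t, ax, ay, az, gx, gy, gz` in SI units, full precision.
#' `read_recording(write_recording(rec, path))` round-trips the channel
#' values exactly for finite inputs.
#'
#' @param rec a [tremor_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "tremor_recording"))
  n <- nrow(rec$accel)
  df <- data.frame(
    t = (seq_len(n) - 1) / rec$sample_rate,
    ax = rec$accel[, 1], ay = rec$accel[, 2], az = rec$accel[, 3],
    gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3]
  )
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' One row per recording, canonical feature columns first (see
#' [feature_names()]), `label` column last. A zero-row matrix yields a
#' header-only file.
#'
#' @param features a data frame of features with an optional `label` column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(is.data.frame(features))
  if ("label" %in% names(features)) {
    features <- features[c(setdiff(names(features), "label"), "label")]
  }
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path path to the CSV file.
#' @return data frame with feature columns and, if present, `label` last.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, check.names = FALSE)
}

#' Construct a 5 x 5 ordinal confusion matrix
#'
#' Rows are true UPDRS classes 0-4, columns predicted classes.
#'
#' @param counts 5 x 5 matrix of nonnegative integer counts.
#' @return An object of class `tremor_confusion` (an integer matrix with
#'   dimnames `0:4` x `0:4`).
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(5, 5))) stop("counts must be 5 x 5")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(true = 0:4, predicted = 0:4)
  class(counts) <- c("tremor_confusion", class(counts))
  counts
}

#' Read a confusion matrix from whitespace-delimited text
#' @param path path to a plain-text file holding a 5 x 5 integer table.
#' @return A [confusion_matrix()].
#' @export
read_confusion <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  confusion_matrix(m)
}

#' Published reference confusion matrix (131 recordings)
#'
#' The confusion matrix of a decision-tree UPDRS rest-tremor classifier
#' evaluated by leave-one-out cross-validation over 131 clinician-consensus
#' recordings, shipped with the package as a worked example and regression
#' fixture for the evaluation module. Row sums are (79, 22, 22, 6, 2) and
#' the diagonal is (75, 18, 15, 4, 0).
#'
#' @return A [confusion_matrix()].
#' @export
reference_confusion <- function() {
  path <- system.file("extdata", "reference_confusion.txt",
                      package = "tremorscore", mustWork = TRUE)
  read_confusion(path)
}
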