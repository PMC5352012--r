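#' Convert raw ROI time series to percent signal change
#'
#' Each column (one region of interest) is expressed as percent change from
#' its own time-series mean: `100 * (x - mean(x)) / mean(x)`. Columns of the
#' result have exactly zero mean, which is the convention assumed by all
#' model-fitting functions in this package (models have no intercept).
#'
#' @param raw_activity Numeric matrix, timepoints x ROIs, in raw scanner
#'   units. Every column must have a nonzero mean: percent change from a
#'   zero baseline is undefined, and a zero-mean column usually means the
#'   data were already converted.
#' @return Numeric matrix of the same dimension, in percent signal change.
#' @examples
#' to_percent_signal_change(cbind(a = c(100, 110, 90)))
#' @export
to_percent_signal_change <- function(raw_activity) {
  raw_activity <- as.matrix(raw_activity)
  if (!is.numeric(raw_activity)) {
    stop("activity matrix must be numeric")
  }
  mu <- colMeans(raw_activity)
  bad <- which(abs(mu) < .Machine$double.eps^0.5)
  if (length(bad) > 0L) {
    nm <- colnames(raw_activity)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("cannot convert to percent signal change: zero-mean column(s) ",
         paste(nm, collapse = ", "))
  }
  out <- 100 * sweep(sweep(raw_activity, 2L, mu, "-"), 2L, mu, "/")
  # remove the O(eps) residual mean so downstream zero-mean checks are exact
  sweep(out, 2L, colMeans(out), "-")
}

#' Split a time series into contiguous train/validation/test segments
#'
#' The series is split into the first half (training), third quarter
#' (validation) and last quarter (test). Boundaries use the floor rule:
#' training covers `[0, floor(T/2))` and validation ends at `floor(3T/4)`,
#' with half-open 0-based index ranges.
#'
#' @param n_timepoints Total series length `T`; must be at least 8 so all
#'   three segments are non-empty.
#' @return An object of class `"segment_split"`: a list with elements
#'   `train`, `validation`, `test`, each a length-2 integer vector
#'   `c(start, end)` holding a half-open 0-based range, plus `n_timepoints`.
#' @seealso [segment_rows()] to obtain 1-based row indices for a segment.
#' @examples
#' split_segments(660)
#' @export
split_segments <- function(n_timepoints) {
  n_timepoints <- as.integer(n_timepoints)
  if (length(n_timepoints) != 1L || is.na(n_timepoints) || n_timepoints < 8L) {
    stop("too few timepoints to segment (need T >= 8)")
  }
  h <- n_timepoints %/% 2L
  q3 <- (3L * n_timepoints) %/% 4L
  structure(
    list(train = c(0L, h),
         validation = c(h, q3),
         test = c(q3, n_timepoints),
         n_timepoints = n_timepoints),
    class = "segment_split"
  )
}

#' @export
print.segment_split <- function(x, ...) {
  cat("Segment split over", x$n_timepoints, "timepoints (0-based, half-open):\n")
  for (s in c("train", "validation", "test")) {
    cat(sprintf("  %-10s [%d, %d)  (%d rows)\n", s, x[[s]][1], x[[s]][2],
                x[[s]][2] - x[[s]][1]))
  }
  invisible(x)
}

#' Row indices of one segment
#'
#' @param split A [split_segments()] object.
#' @param segment One of `"train"`, `"validation"`, `"test"`, or `"all"`.
#' @return Integer vector of 1-based row indices into the activity matrix.
#' @export
segment_rows <- function(split, segment = c("train", "validation", "test", "all")) {
  segment <- match.arg(segment)
  if (segment == "all") return(seq_len(split$n_timepoints))
  rng <- split[[segment]]
  seq.int(rng[1] + 1L, rng[2])
}

#' Construct a per-subject ROI dataset
#'
#' Bundles one subject's timepoints x ROIs activity matrix (percent signal
#' change) with the parcel metadata and subject metadata, and validates the
#' pieces against each other.
#'
#' @param activity Numeric matrix, timepoints x ROIs, percent signal change
#'   (zero-mean columns). Use `convert = TRUE` for raw-unit input.
#' @param parcels Data frame with one row per ROI, columns `label`,
#'   `hemisphere` (`"left"`, `"right"` or `"none"`), `x_mm`, `y_mm`, `z_mm`,
#'   `voxel_count`. Row order must match the activity columns; ROI ids are
#'   assigned 0..R-1 in that order.
#' @param meta List or single-row data frame with `subject_id`, `age_years`
#'   (> 0) and `head_motion_mm` (>= 0, mean displacement between consecutive
#'   volumes).
#' @param tr Repetition time (sampling interval) in seconds.
#' @param convert If `TRUE`, `activity` is in raw units and is passed through
#'   [to_percent_signal_change()] first.
#' @return An object of class `"roi_dataset"`.
#' @export
roi_dataset <- function(activity, parcels, meta = NULL, tr = 1.94,
                        convert = FALSE) {
  activity <- as.matrix(activity)
  if (!is.numeric(activity)) stop("activity must be a numeric matrix")
  if (anyNA(activity)) {
    idx <- which(is.na(activity), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in activity at row %d, column %d",
                 idx[1], idx[2]))
  }
  if (nrow(activity) < 8L) stop("need at least 8 timepoints")
  parcels <- validate_parcels(parcels)
  if (nrow(parcels) != ncol(activity)) {
    stop(sprintf("parcel table has %d rows but activity has %d columns",
                 nrow(parcels), ncol(activity)))
  }
  if (convert) activity <- to_percent_signal_change(activity)
  mu <- colMeans(activity)
  if (any(abs(mu) > 1e-6)) {
    stop("activity columns are not zero-mean percent signal change; ",
         "pass convert = TRUE for raw-unit input")
  }
  colnames(activity) <- parcels$label_hemi
  meta <- validate_subject_meta(meta)
  structure(
    list(activity = activity, parcels = parcels, meta = meta, tr = tr),
    class = "roi_dataset"
  )
}

validate_parcels <- function(parcels) {
  parcels <- as.data.frame(parcels)
  need <- c("label", "hemisphere", "x_mm", "y_mm", "z_mm", "voxel_count")
  miss <- setdiff(need, names(parcels))
  if (length(miss) > 0L) {
    stop("parcel table is missing column(s): ", paste(miss, collapse = ", "))
  }
  parcels$hemisphere <- as.character(parcels$hemisphere)
  bad_hemi <- !parcels$hemisphere %in% c("left", "right", "none")
  if (any(bad_hemi)) {
    stop("hemisphere must be one of left/right/none; got: ",
         paste(unique(parcels$hemisphere[bad_hemi]), collapse = ", "))
  }
  key <- paste(parcels$label, parcels$hemisphere)
  if (anyDuplicated(key)) {
    stop("duplicate ROI label within a hemisphere: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (any(parcels$voxel_count <= 0)) stop("voxel_count must be positive")
  parcels$roi_id <- seq_len(nrow(parcels)) - 1L
  parcels$label_hemi <- ifelse(parcels$hemisphere == "none",
                               parcels$label,
                               paste(parcels$label, parcels$hemisphere,
                                     sep = "_"))
  rownames(parcels) <- NULL
  parcels
}

validate_subject_meta <- function(meta) {
  if (is.null(meta)) {
    return(list(subject_id = "unknown", age_years = NA_real_,
                head_motion_mm = NA_real_))
  }
  meta <- as.list(meta)
  need <- c("subject_id", "age_years", "head_motion_mm")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) {
    stop("subject metadata is missing field(s): ", paste(miss, collapse = ", "))
  }
  if (!is.na(meta$age_years) && meta$age_years <= 0) stop("age must be > 0")
  if (!is.na(meta$head_motion_mm) && meta$head_motion_mm < 0) {
    stop("head motion must be >= 0")
  }
  meta[need]
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("ROI dataset: %d timepoints x %d ROIs (TR = %g s)\n",
              nrow(x$activity), ncol(x$activity), x$tr))
  cat(sprintf("  subject: %s (age %s, head motion %s mm)\n",
              x$meta$subject_id, format(x$meta$age_years),
              format(x$meta$head_motion_mm)))
  hemi <- table(x$parcels$hemisphere)
  cat("  parcels:", paste(sprintf("%s=%d", names(hemi), hemi), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of ROIs / timepoints in a dataset
#' @param dataset An [roi_dataset()].
#' @return Integer.
#' @export
n_rois <- function(dataset) ncol(dataset$activity)

#' @rdname n_rois
#' @export
n_timepoints <- function(dataset) nrow(dataset$activity)

#' Resolve an ROI reference to a 0-based ROI id
#'
#' Accepts a 0-based integer id or a character label (either the bare label
#' with a unique hemisphere, or the `label_hemisphere` form).
#'
#' @param dataset An [roi_dataset()].
#' @param roi Integer id or character label.
#' @return A single 0-based integer ROI id.
#' @export
resolve_roi <- function(dataset, roi) {
  p <- dataset$parcels
  if (is.character(roi)) {
    hit <- which(p$label_hemi == roi)
    if (length(hit) == 0L) hit <- which(p$label == roi)
    if (length(hit) == 0L) stop("unknown ROI label: ", roi)
    if (length(hit) > 1L) {
      stop("ambiguous ROI label (specify hemisphere): ", roi)
    }
    return(p$roi_id[hit])
  }
  roi <- as.integer(roi)
  if (is.na(roi) || roi < 0L || roi >= nrow(p)) {
    stop("ROI id out of range: ", roi)
  }
  roi
}

roi_column <- function(dataset, roi_id) dataset$activity[, roi_id + 1L]

#' Homotopic partner of an ROI
#'
#' The partner is the parcel with the same label in the opposite hemisphere,
#' when one exists.
#'
#' @param parcels Validated parcel table (from an [roi_dataset()]).
#' @param roi_id 0-based ROI id.
#' @return The partner's 0-based id, or `NA` if the ROI is unpaired.
#' @export
homotopic_partner <- function(parcels, roi_id) {
  row <- parcels[parcels$roi_id == roi_id, ]
  if (nrow(row) != 1L || row$hemisphere == "none") return(NA_integer_)
  opp <- c(left = "right", right = "left")[[row$hemisphere]]
  hit <- parcels$roi_id[parcels$label == row$label & parcels$hemisphere == opp]
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

# ---- delimited-text I/O ----------------------------------------------------

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a per-subject ROI dataset from delimited-text files
#'
#' @param activity_path CSV/TSV with one header row of ROI labels and one
#'   time sample per row.
#' @param parcel_path CSV with columns `label`, `hemisphere`, `x_mm`, `y_mm`,
#'   `z_mm`, `voxel_count`, one row per activity column, in column order.
#' @param meta_path Optional CSV with columns `subject_id`, `age_years`,
#'   `head_motion_mm` (single row).
#' @param units `"raw"` (default) converts via [to_percent_signal_change()];
#'   `"percent"` declares the file is already percent signal change.
#' @param tr Repetition time in seconds.
#' @return An [roi_dataset()].
#' @export
read_roi_dataset <- function(activity_path, parcel_path, meta_path = NULL,
                             units = c("raw", "percent"), tr = 1.94) {
  units <- match.arg(units)
  act <- read_delim_auto(activity_path)
  num <- vapply(act, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric activity column(s): ",
         paste(names(act)[!num], collapse = ", "))
  }
  act <- as.matrix(act)
  if (anyNA(act)) {
    idx <- which(is.na(act), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-numeric cell in %s at row %d, column %s",
                 basename(activity_path), idx[1], colnames(act)[idx[2]]))
  }
  parcels <- read_delim_auto(parcel_path)
  meta <- if (!is.null(meta_path)) read_delim_auto(meta_path)[1L, ] else NULL
  roi_dataset(act, parcels, meta, tr = tr, convert = (units == "raw"))
}

#' Write an ROI dataset to delimited-text files
#'
#' Activity values are written with 6 significant digits; reading the files
#' back with [read_roi_dataset()] (with `units = "percent"`) reproduces the
#' matrix at that precision.
#'
#' @param dataset An [roi_dataset()].
#' @param activity_path,parcel_path,meta_path Output CSV paths (`meta_path`
#'   optional).
#' @return Invisibly, the activity path.
#' @export
write_roi_dataset <- function(dataset, activity_path, parcel_path,
                              meta_path = NULL) {
  act <- signif(dataset$activity, 6)
  utils::write.csv(as.data.frame(act), activity_path, row.names = FALSE)
  p <- dataset$parcels[, c("label", "hemisphere", "x_mm", "y_mm", "z_mm",
                           "voxel_count")]
  utils::write.csv(p, parcel_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.csv(as.data.frame(dataset$meta[c("subject_id", "age_years",
                                                  "head_motion_mm")]),
                     meta_path, row.names = FALSE)
  }
  invisible(activity_path)
}
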