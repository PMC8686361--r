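#' The 39-label full-body marker model
#'
#' Label set of the Plug-in-Gait-style full-body marker placement used
#' throughout the package: four head markers, trunk markers (C7, T10, CLAV,
#' STRN, RBAK), bilateral shoulder/arm/wrist/hand markers, four pelvis
#' markers (left/right anterior and posterior superior iliac spines) and
#' bilateral thigh, knee, shank, ankle, heel and toe markers.
#'
#' @return A list with elements `required_labels` (character, length 39) and
#'   `side_map`, a list with `left`, `right` and `midline` label vectors.
#' @export
#' @examples
#' length(marker_model()$required_labels)  # 39
marker_model <- function() {
  midline <- c("C7", "T10", "CLAV", "STRN", "RBAK")
  head <- c("LFHD", "RFHD", "LBHD", "RBHD")
  per_side <- c("SHO", "UPA", "ELB", "FRM", "WRA", "WRB", "FIN",
                "ASI", "PSI", "THI", "KNE", "TIB", "ANK", "HEE", "TOE")
  left <- c("LFHD", "LBHD", paste0("L", per_side))
  right <- c("RFHD", "RBHD", paste0("R", per_side))
  labels <- c(head, midline, paste0("L", per_side), paste0("R", per_side))
  stopifnot(length(labels) == 39L)
  list(
    required_labels = labels,
    side_map = list(left = left, right = right, midline = midline)
  )
}

#' Construct a marker trajectory set
#'
#' The core container of the pipeline: time-indexed 3-D positions for a named
#' marker set in a global frame with X to the subject's right at trial start,
#' Y anterior and Z up. Positions are stored in metres; files in millimetres
#' are converted at read time.
#'
#' @param markers Named list of `n_frames x 3` numeric matrices (columns
#'   x, y, z, metres). `NA` rows mark missing samples.
#' @param rate Sampling frequency in Hz (> 0; 100 Hz is the conventional
#'   optical-capture rate assumed by downstream defaults).
#' @return An object of class `marker_set` with elements `markers`, `rate`,
#'   `n_frames` and `missing_mask` (an `n_frames x n_markers` logical matrix).
#' @export
marker_set <- function(markers, rate) {
  stopifnot(is.list(markers), length(markers) > 0L, !is.null(names(markers)))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  nf <- vapply(markers, nrow, integer(1))
  if (length(unique(nf)) != 1L)
    stop("all markers must have the same number of frames")
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each marker matrix must have 3 columns (x, y, z)")
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y", "z")
    m
  })
  miss <- vapply(markers, function(m) rowSums(is.na(m)) > 0L,
                 logical(nf[[1]]))
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = nf[[1]],
                                         dimnames = list(NULL, names(markers)))
  bad <- vapply(seq_along(markers), function(j) {
    m <- markers[[j]]
    any(!is.finite(m[!miss[, j], , drop = FALSE]))
  }, logical(1))
  if (any(bad))
    stop("non-finite positions outside the missing mask in: ",
         paste(names(markers)[bad], collapse = ", "))
  structure(
    list(markers = markers, rate = rate, n_frames = as.integer(nf[[1]]),
         missing_mask = miss),
    class = "marker_set"
  )
}

#' @export
#' @method print marker_set
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers x %d frames @ %g Hz (%.2f s)\n",
              length(x$markers), x$n_frames, x$rate, x$n_frames / x$rate))
  gaps <- colMeans(x$missing_mask)
  if (any(gaps > 0))
    cat(sprintf("  missing data on %d marker(s), worst %.1f%%\n",
                sum(gaps > 0), 100 * max(gaps)))
  invisible(x)
}

# time vector of a marker_set (seconds, first frame at t = 0)
set_time <- function(set) (seq_len(set$n_frames) - 1L) / set$rate

validate_labels <- function(labels, model) {
  missing <- setdiff(model$required_labels, labels)
  if (length(missing) > 0L)
    stop("missing required marker label(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read marker trajectories from a wide CSV file
#'
#' The CSV dialect has a header `frame,<LABEL>_x,<LABEL>_y,<LABEL>_z,...`
#' with one row per frame and positions in metres (or millimetres with
#' `units = "mm"`). Missing samples are encoded as empty fields or `NA` and
#' are flagged in the missing mask, never silently zeroed.
#'
#' @param path File path.
#' @param rate Sampling rate in Hz of the recording.
#' @param model Marker model whose `required_labels` must all be present;
#'   `NULL` skips label validation.
#' @param units `"m"` (default) or `"mm"`; millimetre files are converted to
#'   metres on read.
#' @return A [marker_set()].
#' @export
read_markers <- function(path, rate = 100, model = marker_model(),
                         units = c("m", "mm")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("cannot read marker file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- setdiff(names(df), "frame")
  labels <- unique(sub("_[xyz]$", "", cols))
  if (!is.null(model)) validate_labels(labels, model)
  scale <- if (units == "mm") 1e-3 else 1
  markers <- lapply(labels, function(lb) {
    need <- paste0(lb, c("_x", "_y", "_z"))
    if (!all(need %in% names(df)))
      stop("incomplete coordinate triplet for label ", lb)
    as.matrix(df[, need]) * scale
  })
  names(markers) <- labels
  marker_set(markers, rate = rate)
}

#' Write marker trajectories to a wide CSV file
#'
#' Inverse of [read_markers()]: one column triplet per label in the order the
#' markers appear in the set (or in marker-model order when `model` is
#' given), one row per frame, missing samples written as empty fields.
#'
#' @param set A [marker_set()].
#' @param path Output path.
#' @param model Optional marker model fixing the column order.
#' @return `path`, invisibly.
#' @export
write_markers <- function(set, path, model = NULL) {
  stopifnot(inherits(set, "marker_set"))
  if (set$n_frames < 2L) stop("refusing to write a set with < 2 frames")
  labels <- names(set$markers)
  if (!is.null(model)) {
    validate_labels(labels, model)
    labels <- intersect(model$required_labels, labels)
  }
  cols <- lapply(labels, function(lb) set$markers[[lb]])
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(vapply(labels, function(lb)
    paste0(lb, c("_x", "_y", "_z")), character(3)))
  df <- data.frame(frame = seq_len(set$n_frames), out, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-trial metadata record
#'
#' @param subject_id Subject identifier.
#' @param group Group label, e.g. `"control"`, `"pd"`, `"freezer"`,
#'   `"nonfreezer"`.
#' @param inner_side `"left"` or `"right"`: the side performing the inner
#'   steps of the turn (by convention the more affected limb).
#' @param covariates Named list/vector with `age`, `sex`, `height`, `bmi`
#'   (required by the association stage, optional elsewhere).
#' @param clinical Named list of clinical scores (UPDRS total/III, PIGD,
#'   H&Y, NFOGQ, MMSE, disease duration, LED); missing values allowed.
#' @return A list of class `trial_metadata`.
#' @export
trial_metadata <- function(subject_id, group, inner_side,
                           covariates = NULL, clinical = NULL) {
  inner_side <- match.arg(inner_side, c("left", "right"))
  structure(list(subject_id = subject_id, group = group,
                 inner_side = inner_side,
                 covariates = covariates, clinical = clinical),
            class = "trial_metadata")
}

#' Report data-quality issues of a trial
#'
#' Report-only check: lists marker labels absent from the model, per-marker
#' gap fractions, and sampling-rate mismatch against the expected rate.
#'
#' @param set A [marker_set()].
#' @param metadata Optional [trial_metadata()].
#' @param model Marker model to check coverage against.
#' @param expected_rate Expected sampling rate (Hz).
#' @return A data frame with columns `issue`, `detail`, `value`; zero rows
#'   when the trial is clean.
#' @export
validate_trial <- function(set, metadata = NULL, model = marker_model(),
                           expected_rate = 100) {
  issues <- list()
  missing <- setdiff(model$required_labels, names(set$markers))
  for (lb in missing)
    issues[[length(issues) + 1L]] <-
      data.frame(issue = "missing_label", detail = lb, value = NA_real_)
  gaps <- colMeans(set$missing_mask)
  for (lb in names(gaps)[gaps > 0])
    issues[[length(issues) + 1L]] <-
      data.frame(issue = "gaps", detail = lb, value = unname(gaps[lb]))
  if (!isTRUE(all.equal(set$rate, expected_rate)))
    issues[[length(issues) + 1L]] <-
      data.frame(issue = "rate_mismatch",
                 detail = sprintf("%g Hz (expected %g)", set$rate,
                                  expected_rate),
                 value = set$rate)
  if (length(issues) == 0L)
    return(data.frame(issue = character(), detail = character(),
                      value = numeric()))
  do.call(rbind, issues)
}

#' Read / write a trial metadata table
#'
#' One row per trial with documented columns: `subject_id`, `trial`,
#' `group`, `inner_side`, covariates (`age`, `sex`, `height`, `bmi`) and any
#' clinical score columns. Stored as tab-separated text so fixtures are
#' diffable.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("cannot read metadata table: ", path)
  utils::read.delim(path, check.names = FALSE)
}

#' @rdname read_metadata
#' @param table Data frame to write.
#' @export
write_metadata <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
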