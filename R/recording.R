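#' Activity classes
#'
#' The classifier distinguishes three behaviour classes: `dynamic`
#' (walking, cycling, transfers), `standing` (static upright posture)
#' and `sedentary` (sitting or lying). This closed set is used as factor
#' levels throughout the package.
#'
#' @return Character vector of the three class names, in canonical order.
#' @export
activity_levels <- function() c("dynamic", "standing", "sedentary")

#' Coerce to activity labels
#'
#' @param x character vector (case-insensitive) of class names.
#' @return factor with levels [activity_levels()].
#' @export
as_activity_label <- function(x) {
  lv <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(lv), activity_levels())
  if (length(bad) > 0L) {
    stop("unknown activity label(s): ", paste(sQuote(bad), collapse = ", "),
         "; expected one of ", paste(activity_levels(), collapse = ", "),
         call. = FALSE)
  }
  factor(lv, levels = activity_levels())
}

#' Tri-axial accelerometer recording
#'
#' Container for a raw tri-axial acceleration time series in units of g.
#' The X axis is the thigh-longitudinal axis, positive toward the hip, so
#' that upright standing yields a gravity projection of about +1 g on X
#' and sitting/lying about 0 g.
#'
#' @param samples numeric matrix (or coercible) with 3 columns
#'   `ax, ay, az`, one row per sample, values in g within the +/- 8 g
#'   sensor range.
#' @param sampling_rate sampling frequency in Hz (> 0); 25 Hz is the
#'   device default.
#' @param subject_id opaque subject identifier.
#' @param start_offset start time of the first sample in seconds.
#' @return An object of class `acc_recording`.
#' @export
acc_recording <- function(samples, sampling_rate = 25, subject_id = "s1",
                          start_offset = 0) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) {
    stop("samples must have exactly 3 columns (ax, ay, az); got ",
         ncol(samples), call. = FALSE)
  }
  storage.mode(samples) <- "double"
  colnames(samples) <- c("ax", "ay", "az")
  if (nrow(samples) < 1L) stop("recording must contain at least one sample",
                               call. = FALSE)
  if (!all(is.finite(samples))) stop("all sample values must be finite",
                                     call. = FALSE)
  if (any(abs(samples) > 8)) {
    stop("sample values outside the +/- 8 g sensor range", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         subject_id = as.character(subject_id),
         start_offset = as.numeric(start_offset)),
    class = "acc_recording"
  )
}

#' @export
print.acc_recording <- function(x, ...) {
  cat(sprintf("<acc_recording> subject %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$samples), x$sampling_rate,
              recording_duration(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an [acc_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  stopifnot(inherits(recording, "acc_recording"))
  nrow(recording$samples) / recording$sampling_rate
}

#' Per-second gold-standard annotation series
#'
#' One activity label per second, 0-based: label `i` covers the interval
#' `[i, i + 1)` seconds, mirroring an observer's event sheet built from
#' video recordings.
#'
#' @param labels character or factor vector of activity labels, one per
#'   second.
#' @param observer_id opaque observer identifier.
#' @return An object of class `activity_annotation`.
#' @export
activity_annotation <- function(labels, observer_id = "obs1") {
  labels <- as_activity_label(labels)
  if (length(labels) < 1L) stop("annotation must contain at least one second",
                                call. = FALSE)
  structure(list(labels = labels, observer_id = as.character(observer_id)),
            class = "activity_annotation")
}

#' @export
print.activity_annotation <- function(x, ...) {
  cat(sprintf("<activity_annotation> observer %s: %d s\n",
              x$observer_id, length(x$labels)))
  print(annotation_totals(x))
  invisible(x)
}

#' Total annotated seconds per activity class
#'
#' @param annotation an [activity_annotation()].
#' @return named numeric vector of seconds, one entry per class; the
#'   entries always sum to the annotation length.
#' @export
annotation_totals <- function(annotation) {
  stopifnot(inherits(annotation, "activity_annotation"))
  tab <- table(annotation$labels)
  stats::setNames(as.numeric(tab), names(tab))
}

# full-precision number formatting for lossless CSV round-trips
.fmt_g <- function(x) formatC(x, digits = 17, format = "g")

#' Write a recording to CSV
#'
#' Writes a `# sampling_rate_hz=<rate>` metadata comment, an `ax,ay,az`
#' header and one row per sample at full float precision, so that
#' [read_recording_csv()] round-trips values to better than 1e-9 g.
#'
#' @param recording an [acc_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "acc_recording"))
  s <- recording$samples
  lines <- c(
    sprintf("# sampling_rate_hz=%s", .fmt_g(recording$sampling_rate)),
    "ax,ay,az",
    paste(.fmt_g(s[, 1]), .fmt_g(s[, 2]), .fmt_g(s[, 3]), sep = ",")
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Expects three axis columns named `ax,ay,az` or `x,y,z`
#' (case-insensitive) and an optional `# sampling_rate_hz=` comment. An
#' explicit `sampling_rate` argument always wins over the file comment.
#'
#' @param path input CSV path.
#' @param sampling_rate sampling rate in Hz; if `NULL`, taken from the
#'   file's metadata comment (error if absent there too).
#' @param subject_id subject identifier to attach.
#' @return an [acc_recording()].
#' @export
read_recording_csv <- function(path, sampling_rate = NULL, subject_id = "s1") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  comments <- grep("^\\s*#", raw, value = TRUE)
  rate_line <- grep("sampling_rate_hz\\s*=", comments, value = TRUE)
  if (is.null(sampling_rate)) {
    if (length(rate_line) == 0L) {
      stop("no sampling_rate argument and no '# sampling_rate_hz=' comment in ",
           path, call. = FALSE)
    }
    sampling_rate <- as.numeric(sub(".*sampling_rate_hz\\s*=\\s*", "",
                                    rate_line[1]))
  }
  body <- raw[!grepl("^\\s*#", raw)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)
  df <- utils::read.csv(text = body, colClasses = "character",
                        strip.white = TRUE)
  names(df) <- tolower(names(df))
  wanted <- c("ax", "ay", "az")
  for (i in 1:3) {  # accept x,y,z as axis aliases
    short <- c("x", "y", "z")[i]
    if (short %in% names(df) && !wanted[i] %in% names(df)) {
      names(df)[names(df) == short] <- wanted[i]
    }
  }
  missing <- setdiff(wanted, names(df))
  extra <- setdiff(names(df), wanted)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop("expected exactly axis columns ax,ay,az (or x,y,z); found: ",
         paste(names(df), collapse = ","),
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ",")) else "",
         call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = 3L,
                dimnames = list(NULL, wanted))
  for (col in wanted) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value %s in column '%s' at data row %d of %s",
                   sQuote(df[[col]][bad[1]]), col, bad[1], path),
           call. = FALSE)
    }
    out <- which(abs(v) > 8)
    if (length(out) > 0L) {
      stop(sprintf(
        "value %g in column '%s' at data row %d of %s outside +/- 8 g range",
        v[out[1]], col, out[1], path), call. = FALSE)
    }
    mat[, col] <- v
  }
  acc_recording(mat, sampling_rate = sampling_rate, subject_id = subject_id)
}

#' Write an annotation series to CSV
#'
#' Two columns `second,label`, seconds consecutive from 0.
#'
#' @param annotation an [activity_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(annotation, path) {
  stopifnot(inherits(annotation, "activity_annotation"))
  df <- data.frame(second = seq_along(annotation$labels) - 1L,
                   label = as.character(annotation$labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-second annotation series from CSV
#'
#' Expects columns `second,label` with `second` consecutive from 0 and
#' labels among the three activity classes (case-insensitive).
#'
#' @param path input CSV path.
#' @param observer_id observer identifier to attach.
#' @return an [activity_annotation()].
#' @export
read_annotation_csv <- function(path, observer_id = "obs1") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE,
                        comment.char = "#")
  names(df) <- tolower(names(df))
  if (!identical(sort(names(df)), c("label", "second"))) {
    stop("expected columns second,label; found: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  sec <- suppressWarnings(as.integer(df$second))
  expect <- seq_len(nrow(df)) - 1L
  bad <- which(is.na(sec) | sec != expect)
  if (length(bad) > 0L) {
    stop(sprintf(
      "'second' column must run consecutively from 0; first bad entry %s at row %d",
      sQuote(df$second[bad[1]]), bad[1]), call. = FALSE)
  }
  activity_annotation(df$label, observer_id = observer_id)
}
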