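#' Construct a vital-sign record for one subject
#'
#' A `vital_record` holds one subject's irregularly sampled multichannel
#' vital-sign series. Channels are the six canonical numerics: `hr`
#' (beats/min), `rr` (breaths/min), `spo2` (percent), and `abpsys`,
#' `abpdias`, `abpmean` (mmHg). Each channel is a data frame with strictly
#' increasing `time_s` (seconds from the record's own start) and finite
#' `value`. Channels may cover different stretches of time and have
#' different sample times.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param channels Named list; each element a data frame with columns
#'   `time_s` and `value`. Names must be among the six canonical channels.
#' @param nominal_period_s Expected sampling period in seconds (60 for
#'   minute-level numerics, 1 for 1 Hz trends).
#' @return An object of class `"vital_record"`.
#' @examples
#' rec <- vital_record("s1", list(hr = data.frame(time_s = 0:5 * 60,
#'                                                value = c(80, 82, 81, 85, 84, 83))))
#' rec
#' @export
vital_record <- function(subject_id, channels, nominal_period_s = 60) {
  subject_id <- as.character(subject_id)
  stopifnot(length(subject_id) == 1L, is.list(channels))
  bad <- setdiff(names(channels), CHANNELS)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  channels <- lapply(channels, function(ch) {
    ch <- as.data.frame(ch)[, c("time_s", "value")]
    ch <- ch[is.finite(ch$value) & is.finite(ch$time_s), , drop = FALSE]
    ch <- ch[order(ch$time_s), , drop = FALSE]
    if (anyDuplicated(ch$time_s)) {
      # collapse duplicate timestamps by median so times stay strictly increasing
      ch <- do.call(rbind, lapply(split(ch, ch$time_s), function(g)
        data.frame(time_s = g$time_s[1], value = stats::median(g$value))))
    }
    rownames(ch) <- NULL
    ch
  })
  x <- structure(list(subject_id = subject_id, channels = channels,
                      nominal_period_s = nominal_period_s),
                 class = "vital_record")
  validate_vital_record(x)
  x
}

validate_vital_record <- function(x) {
  stopifnot(inherits(x, "vital_record"))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    if (nrow(ch) > 1 && any(diff(ch$time_s) <= 0))
      stop("channel ", nm, ": times must be strictly increasing")
    if (any(!is.finite(ch$value)))
      stop("channel ", nm, ": non-finite values")
    if (nm == "spo2" && nrow(ch) && (min(ch$value) < 0 || max(ch$value) > 100))
      stop("spo2 values must lie in [0, 100]")
    if (nm %in% c("hr", "rr") && nrow(ch) && min(ch$value) < 0)
      stop(nm, " values must be nonnegative")
  }
  invisible(x)
}

#' @method print vital_record
#' @export
print.vital_record <- function(x, ...) {
  n <- vapply(x$channels, nrow, integer(1))
  span <- range(unlist(lapply(x$channels, `[[`, "time_s")), na.rm = TRUE)
  cat(sprintf("<vital_record> subject %s, %d channel(s), %.1f h span, period %gs\n",
              x$subject_id, length(x$channels), diff(span) / 3600,
              x$nominal_period_s))
  for (nm in names(x$channels))
    cat(sprintf("  %-8s %5d samples\n", nm, n[[nm]]))
  invisible(x)
}

#' Channel accessors
#'
#' `record_channel()` returns one channel's samples as a data frame
#' (`time_s`, `value`); `record_extent()` returns the first and last sample
#' time across all channels (or of one channel).
#'
#' @param record A [vital_record()].
#' @param channel Canonical channel name.
#' @return `record_channel()`: data frame; `record_extent()`: numeric
#'   length-2 vector `c(start_s, end_s)`.
#' @export
record_channel <- function(record, channel) {
  stopifnot(inherits(record, "vital_record"))
  record$channels[[channel]] %||% data.frame(time_s = numeric(0), value = numeric(0))
}

#' @rdname record_channel
#' @export
record_extent <- function(record, channel = NULL) {
  chs <- if (is.null(channel)) record$channels else record$channels[channel]
  tt <- unlist(lapply(chs, `[[`, "time_s"))
  if (!length(tt)) return(c(NA_real_, NA_real_))
  range(tt)
}

#' Decimate a 1 Hz record to the 1-min analysis grid
#'
#' The whole pipeline operates on a one-minute nominal grid. Records sampled
#' at 1 Hz are reduced to one sample per minute by taking the per-minute
#' median of each channel; the decimated sample is stamped at the start of
#' its minute. Records already at 60 s period are returned unchanged.
#'
#' @param record A [vital_record()].
#' @return A [vital_record()] with `nominal_period_s = 60`.
#' @export
decimate_record <- function(record) {
  stopifnot(inherits(record, "vital_record"))
  if (record$nominal_period_s >= 60) return(record)
  channels <- lapply(record$channels, function(ch) {
    if (!nrow(ch)) return(ch)
    minute <- floor(ch$time_s / 60)
    agg <- vapply(split(ch$value, minute), stats::median, numeric(1))
    data.frame(time_s = as.numeric(names(agg)) * 60, value = unname(agg))
  })
  vital_record(record$subject_id, channels, nominal_period_s = 60)
}
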