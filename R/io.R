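#' Read vital-sign records from CSV
#'
#' Long format (the canonical interchange format) has columns
#' `subject,time_s,channel,value`, one sample per row. Wide format has
#' columns `subject,time_s,hr,rr,spo2,abpsys,abpdias,abpmean` with empty
#' cells for missing samples. Channel names are normalized to lower case;
#' rows with unknown channels are skipped with a warning, and rows with
#' non-finite values are dropped (the count is reported via message and the
#' `"n_dropped"` attribute). Records with `nominal_period_s = 1` are
#' decimated to the one-minute grid by per-minute medians.
#'
#' @param path Path to a CSV file.
#' @param format `"long_csv"` or `"wide_csv"`.
#' @param nominal_period_s Expected sampling period of the file (60 or 1).
#' @return A named list of [vital_record()] objects, one per subject, in
#'   order of first appearance. Attribute `"n_dropped"` counts discarded
#'   non-finite samples.
#' @export
read_records <- function(path, format = c("long_csv", "wide_csv"),
                         nominal_period_s = 60) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("unparseable file ", path, ": ", conditionMessage(e))
  )
  if (format == "long_csv") {
    need <- c("subject", "time_s", "channel", "value")
    if (!all(need %in% names(df)))
      stop("long CSV must have columns ", paste(need, collapse = ","),
           "; first bad line is the header")
    df$channel <- tolower(trimws(df$channel))
    unknown <- setdiff(unique(df$channel), CHANNELS)
    if (length(unknown)) {
      warning("skipping unknown channel(s): ", paste(unknown, collapse = ", "))
      df <- df[df$channel %in% CHANNELS, , drop = FALSE]
    }
    df$time_s <- suppressWarnings(as.numeric(df$time_s))
    df$value <- suppressWarnings(as.numeric(df$value))
    ok <- is.finite(df$time_s) & is.finite(df$value)
    n_dropped <- sum(!ok)
    df <- df[ok, , drop = FALSE]
    long <- df
  } else {
    if (!all(c("subject", "time_s") %in% names(df)))
      stop("wide CSV must have columns subject,time_s,<channels>")
    chans <- intersect(tolower(names(df)), CHANNELS)
    names(df) <- tolower(names(df))
    pieces <- lapply(chans, function(ch)
      data.frame(subject = df$subject,
                 time_s = suppressWarnings(as.numeric(df$time_s)),
                 channel = ch,
                 value = suppressWarnings(as.numeric(df[[ch]]))))
    long <- do.call(rbind, pieces)
    # empty wide cells become NA: absent samples, not errors
    was_na <- is.na(long$value)
    ok <- is.finite(long$time_s) & is.finite(long$value)
    n_dropped <- sum(!ok & !was_na)
    long <- long[ok, , drop = FALSE]
  }
  if (n_dropped > 0)
    message("read_records: dropped ", n_dropped, " non-finite sample(s)")
  subjects <- unique(as.character(long$subject))
  recs <- lapply(subjects, function(s) {
    sub <- long[long$subject == s, , drop = FALSE]
    channels <- lapply(split(sub, sub$channel), function(g)
      data.frame(time_s = g$time_s, value = g$value))
    decimate_record(vital_record(s, channels,
                                 nominal_period_s = nominal_period_s))
  })
  names(recs) <- subjects
  attr(recs, "n_dropped") <- n_dropped
  recs
}

#' Write records to long CSV
#'
#' Inverse of [read_records()]: one row per sample, columns
#' `subject,time_s,channel,value`, channels in canonical order and times
#' sorted within each channel.
#'
#' @param records A list of [vital_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(intersect(CHANNELS, names(rec$channels)), function(nm) {
      ch <- rec$channels[[nm]]
      if (!nrow(ch)) return(NULL)
      data.frame(subject = rec$subject_id, time_s = ch$time_s,
                 channel = nm, value = ch$value)
    }))
  })
  write_table(do.call(rbind, rows), path)
}

#' Write / read pipeline product tables
#'
#' All pipeline products (episode tables, window tables, feature tables,
#' trajectories) are plain CSV with a header and a deterministic column
#' order; `read_table(write_table(x))` reproduces `x` with numeric values
#' kept to full double precision.
#'
#' @param rows A data frame with at least one column.
#' @param path Output (or input) path.
#' @return `write_table()` returns `path` invisibly; `read_table()` returns
#'   a data frame.
#' @export
write_table <- function(rows, path) {
  if (is.null(rows)) rows <- data.frame()
  stopifnot(is.data.frame(rows))
  if (ncol(rows) == 0) stop("refusing to write a table with no columns")
  ok <- tryCatch({
    utils::write.csv(format_table_(rows), path, row.names = FALSE, quote = TRUE,
                     na = "")
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

# full-precision text rendering of numeric columns
format_table_ <- function(rows) {
  for (j in seq_along(rows)) {
    if (is.numeric(rows[[j]])) {
      v <- sprintf("%.17g", rows[[j]])
      v[is.na(rows[[j]])] <- NA
      rows[[j]] <- v
    }
  }
  rows
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
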