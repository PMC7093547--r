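# Recording I/O.
#
# CSV dialect: one file per channel, first line "# fs=<Hz>" then one
# sample value per line (header "value"); recording metadata (id,
# reference AHI, total recording time, t0) in a JSON side-car. EDF input
# is supported read-only; channels are located by configurable label
# regexes because vendor labels vary.

#' Write a recording as per-channel CSV files plus JSON metadata
#'
#' Creates `<id>_spo2.csv`, `<id>_airflow.csv` and `<id>.json` inside
#' `dir`. Samples are written at full precision (15 significant digits).
#'
#' @param rec A [recording()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the JSON metadata file.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ch in c("spo2", "airflow")) {
    sig <- rec[[ch]]
    path <- file.path(dir, paste0(rec$id, "_", ch, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# fs=%.10g", sig$fs), con)
    writeLines("value", con)
    writeLines(formatC(sig$samples, digits = 15, format = "g"), con)
    close(con)
  }
  meta <- list(id = rec$id, reference_ahi = rec$reference_ahi,
               trt_seconds = rec$trt_seconds,
               t0 = list(spo2 = rec$spo2$t0, airflow = rec$airflow$t0))
  json_path <- file.path(dir, paste0(rec$id, ".json"))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(json_path)
}

read_signal_csv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^# fs=([0-9.eE+-]+)$", header))[[1]]
  if (length(m) != 2L) stop("malformed signal CSV (missing '# fs=' line): ",
                            path)
  fs <- as.numeric(m[2])
  dat <- utils::read.csv(path, skip = 1L)
  if (!identical(names(dat), "value")) {
    stop("malformed signal CSV (expected single 'value' column): ", path)
  }
  list(samples = dat$value, fs = fs)
}

#' Read a two-channel recording from CSV or EDF
#'
#' For `format = "csv"`, `path` is the JSON metadata file written by
#' [write_recording()] (the per-channel CSVs are located next to it).
#' For `format = "edf"`, `path` is a European Data Format file; the SpO2
#' and airflow channels are located by the label regexes in
#' `channel_patterns`.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`.
#' @param channel_patterns Named list of case-insensitive regexes used to
#'   identify EDF channels.
#' @return A [recording()]; `reference_ahi` is `NA` unless present in the
#'   metadata.
#' @export
read_recording <- function(path, format = c("csv", "edf"),
                           channel_patterns = list(
                             spo2 = "SpO2|SaO2",
                             airflow = "Flow|Pres|Cannula")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    dir <- dirname(path)
    sp <- read_signal_csv(file.path(dir, paste0(meta$id, "_spo2.csv")))
    af <- read_signal_csv(file.path(dir, paste0(meta$id, "_airflow.csv")))
    t0 <- meta$t0
    recording(meta$id,
              oximetry_signal(sp$samples, sp$fs,
                              t0 = if (!is.null(t0)) t0[["spo2"]] else 0),
              airflow_signal(af$samples, af$fs,
                             t0 = if (!is.null(t0)) t0[["airflow"]] else 0),
              reference_ahi = if (is.null(meta$reference_ahi)) NA_real_
                              else as.numeric(meta$reference_ahi),
              trt_seconds = meta$trt_seconds)
  } else {
    edf <- read_edf(path)
    pick <- function(patt, what) {
      hit <- grep(patt, edf$labels, ignore.case = TRUE)
      if (!length(hit)) stop("no EDF channel matching '", patt,
                             "' for ", what)
      hit[1]
    }
    i_sp <- pick(channel_patterns$spo2, "SpO2")
    i_af <- pick(channel_patterns$airflow, "airflow")
    id <- sub("\\.edf$", "", basename(path), ignore.case = TRUE)
    recording(id,
              oximetry_signal(edf$signals[[i_sp]], edf$fs[i_sp]),
              airflow_signal(edf$signals[[i_af]], edf$fs[i_af]))
  }
}

# Minimal EDF reader: fixed 256-byte ASCII header, 256 bytes per signal
# of per-channel metadata, then data records of 2-byte little-endian
# integers scaled to physical units. Continuous (EDF, not EDF+D) files
# only.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_field <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr_field(8)                      # version
  hdr_field(80); hdr_field(80)      # patient / recording id
  hdr_field(8); hdr_field(8)        # start date / time
  header_bytes <- as.integer(hdr_field(8))
  hdr_field(44)                     # reserved
  n_records <- as.integer(hdr_field(8))
  record_dur <- as.numeric(hdr_field(8))
  ns <- as.integer(hdr_field(4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header: ", path)
  fields <- function(width) {
    vapply(seq_len(ns), function(i) hdr_field(width), character(1))
  }
  labels <- fields(16)
  fields(80); fields(8)             # transducer, physical dimension
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)                        # prefiltering
  spr <- as.integer(fields(8))      # samples per record
  fields(32)                        # reserved
  seek(con, header_bytes)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  raw_sig <- lapply(seq_len(ns), function(i) numeric(n_records * spr[i]))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[i]) stop("truncated EDF data record: ", path)
      raw_sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }
  signals <- lapply(seq_len(ns), function(i) {
    phys_min[i] + gain[i] * (raw_sig[[i]] - dig_min[i])
  })
  list(labels = labels, signals = signals, fs = spr / record_dur,
       record_dur = record_dur, n_records = n_records)
}

#' Canonical feature-column names for one channel
#'
#' @param channel `"spo2"` or `"airflow"`.
#' @return Character vector of prefixed feature names (the default
#'   registry; see [feature_registry()]).
#' @export
feature_names <- function(channel = c("spo2", "airflow")) {
  channel <- match.arg(channel)
  prefix <- if (channel == "spo2") "spo2" else "af"
  paste0(prefix, "_", feature_registry()[[channel]])
}

#' Write / read a per-recording feature table
#'
#' The table has one row per recording: an `id` column, the named feature
#' columns, and a final `reference_ahi` column.
#'
#' @param table Data frame as produced by [extract_feature_table()].
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  if (anyDuplicated(names(table))) stop("duplicate column names")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param allowed Optional character vector of permitted feature columns;
#'   defaults to the canonical dual-channel registry. Unknown columns are
#'   rejected.
#' @export
read_feature_table <- function(path, allowed = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(tab))) stop("duplicate column names in ", path)
  if (is.null(allowed)) {
    allowed <- c(feature_names("spo2"), feature_names("airflow"))
  }
  extra <- setdiff(names(tab), c("id", allowed, "reference_ahi"))
  if (length(extra)) {
    stop("unknown feature columns: ", paste(extra, collapse = ", "))
  }
  tab
}

#' Write / read an event-annotation table
#'
#' Plain CSV with columns `kind`, `onset_s`, `duration_s`, `depth`.
#'
#' @param events An [event_set()].
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  dat <- utils::read.csv(path)
  event_set(dat$kind, dat$onset_s, dat$duration_s, dat$depth)
}
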