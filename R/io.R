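# Signal ingestion: plain CSV and PhysioNet WFDB (format 16) records,
# anti-aliased decimation, gap repair, beat annotations.
#
# Time convention throughout: seconds from record start, sample n at
# t = n * Ts, 0-based.

new_signal_record <- function(id, fs, samples, units = "mmHg",
                              channel = NA_character_, provenance = list()) {
  out <- list(id = id, fs = fs, samples = as.numeric(samples),
              units = units, channel = channel, provenance = provenance)
  class(out) <- "ppv_signal"
  out
}

#' @export
print.ppv_signal <- function(x, ...) {
  cat(sprintf("signal record '%s': %d samples at %g Hz (%.1f s), %s\n",
              x$id, length(x$samples), x$fs, length(x$samples) / x$fs,
              x$units))
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), unlist(lapply(
      x$provenance, format)), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a single-channel signal from CSV or a WFDB record
#'
#' CSV dialects: two columns `time_s,value` (any value column name; the
#' rate is inferred from the time spacing) or a single value column with
#' the rate given via `sample_rate`.  A path without a `.csv` extension is
#' treated as a WFDB record name (the `.hea` header next to it is read; see
#' [read_wfdb()]).
#'
#' Non-finite samples are repaired by linear interpolation and counted in
#' the provenance; records with more than `max_gap_frac` interpolated
#' samples are refused.
#'
#' @param path CSV file path or WFDB record name (with or without `.hea`).
#' @param channel channel selector for multi-channel WFDB records: an index
#'   or a label substring; default picks the ABP channel by label match.
#' @param sample_rate sampling rate for single-column CSV input.
#' @param max_gap_frac maximum tolerated fraction of interpolated samples.
#' @return A `"ppv_signal"` record: `id`, `fs`, `samples`, `units`,
#'   `channel`, `provenance`.
#' @export
read_signal <- function(path, channel = NULL, sample_rate = NULL,
                        max_gap_frac = 0.05) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rec <- read_signal_csv(path, sample_rate = sample_rate)
  } else {
    rec <- read_wfdb(path, channel = channel)
  }
  repair_gaps(rec, max_gap_frac)
}

read_signal_csv <- function(path, sample_rate = NULL) {
  if (!file.exists(path)) stop("cannot read signal file: ", path)
  df <- utils::read.csv(path)
  if ("time_s" %in% names(df)) {
    vcol <- setdiff(names(df), "time_s")[1L]
    if (is.na(vcol)) stop("CSV has a time_s column but no value column")
    dt <- diff(df$time_s)
    if (length(dt) < 1L || any(dt <= 0)) {
      stop("time_s column must be strictly increasing")
    }
    fs <- 1 / stats::median(dt)
    samples <- df[[vcol]]
  } else {
    if (is.null(sample_rate)) {
      stop("single-column CSV needs an explicit sample_rate")
    }
    fs <- sample_rate
    vcol <- names(df)[1L]
    samples <- df[[1L]]
  }
  new_signal_record(id = sub("\\.csv$", "", basename(path),
                             ignore.case = TRUE),
                    fs = fs, samples = samples, channel = vcol,
                    provenance = list(file = path, format = "csv"))
}

#' Write a signal record to CSV
#'
#' Columns `time_s,abp_mmhg`, full double precision (round trips are
#' bit-identical).
#'
#' @param rec a `"ppv_signal"` record or numeric vector.
#' @param path output path.
#' @param sample_rate rate when `rec` is a plain vector.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(rec, path, sample_rate = NULL) {
  if (!inherits(rec, "ppv_signal")) {
    stopifnot(!is.null(sample_rate))
    rec <- new_signal_record("signal", sample_rate, rec)
  }
  t <- (seq_along(rec$samples) - 1L) / rec$fs
  write_csv_full(data.frame(time_s = t, abp_mmhg = rec$samples), path)
  invisible(path)
}

#' Read a WFDB record (format 16)
#'
#' A minimal reader for the PhysioNet WFDB format: parses the `.hea` header
#' (record line `name nsig fs nsamples`, then one line per signal with
#' `file format gain(baseline)/units ...`) and decodes 16-bit little-endian
#' two's-complement samples, returning physical units
#' `(adc - baseline) / gain`.  Only format 16 is supported; multi-channel
#' files are assumed sample-interleaved, as written by the standard tools.
#'
#' @param record record path/name, with or without the `.hea` extension.
#' @param channel channel index (1-based) or label substring; `NULL` picks
#'   the first channel whose description matches "ABP"/"art", else errors
#'   listing the available labels (single-channel records are unambiguous).
#' @return A `"ppv_signal"` record.
#' @export
read_wfdb <- function(record, channel = NULL) {
  hea <- if (grepl("\\.hea$", record)) record else paste0(record, ".hea")
  if (!file.exists(hea)) stop("cannot read WFDB header: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rec_line <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  name <- rec_line[1L]
  nsig <- as.integer(rec_line[2L])
  fs <- if (length(rec_line) >= 3L) as.numeric(rec_line[3L]) else 250
  nsamp <- if (length(rec_line) >= 4L) as.numeric(rec_line[4L]) else NA
  if (length(lines) < 1L + nsig) stop("WFDB header truncated: ", hea)
  sig <- lapply(lines[1L + seq_len(nsig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1L]]
    fmt <- tok[2L]
    if (fmt != "16") stop("unsupported WFDB signal format '", fmt,
                          "' (only format 16 is supported)")
    gspec <- tok[3L]
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gspec)))
    if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default ADU/mV
    baseline <- if (grepl("\\(", gspec)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gspec))
    } else 0
    units <- if (grepl("/", gspec)) sub(".*/", "", gspec) else "adu"
    desc <- if (length(tok) >= 9L) {
      paste(tok[9:length(tok)], collapse = " ")
    } else paste0("sig", tok[2L])
    list(file = tok[1L], gain = gain, baseline = baseline, units = units,
         desc = desc)
  })
  labels <- vapply(sig, `[[`, character(1), "desc")
  ch <- if (is.null(channel)) {
    if (nsig == 1L) 1L else {
      hit <- grep("abp|arterial|art", labels, ignore.case = TRUE)
      if (!length(hit)) {
        stop("no ABP channel found; available channels: ",
             paste(sprintf("[%d] %s", seq_along(labels), labels),
                   collapse = ", "))
      }
      hit[1L]
    }
  } else if (is.numeric(channel)) {
    as.integer(channel)
  } else {
    hit <- grep(channel, labels, ignore.case = TRUE)
    if (!length(hit)) {
      stop("channel '", channel, "' not found; available channels: ",
           paste(sprintf("[%d] %s", seq_along(labels), labels),
                 collapse = ", "))
    }
    hit[1L]
  }
  if (ch < 1L || ch > nsig) stop("channel index out of range")
  dat <- file.path(dirname(hea), sig[[ch]]$file)
  if (!file.exists(dat)) stop("cannot read WFDB signal file: ", dat)
  raw_n <- file.size(dat) / 2L
  adc <- readBin(dat, "integer", n = raw_n, size = 2L, signed = TRUE,
                 endian = "little")
  # channels are interleaved sample by sample
  adc <- adc[seq.int(ch, length(adc), by = nsig)]
  if (is.finite(nsamp) && nsamp > 0) adc <- adc[seq_len(min(nsamp,
                                                            length(adc)))]
  samples <- (adc - sig[[ch]]$baseline) / sig[[ch]]$gain
  new_signal_record(id = name, fs = fs, samples = samples,
                    units = sig[[ch]]$units, channel = labels[ch],
                    provenance = list(file = dat, format = "wfdb16",
                                      channel_index = ch))
}

#' Write a signal as a WFDB record (format 16)
#'
#' Quantizes to 16-bit ADC units with the given gain (samples round to
#' `round(value * gain)`); a subsequent [read_wfdb()] returns the quantized
#' values exactly.
#'
#' @param rec a `"ppv_signal"` record or numeric vector.
#' @param record output record path/name (writes `<record>.hea` and
#'   `<record>.dat`).
#' @param sample_rate rate when `rec` is a plain vector.
#' @param gain ADC units per physical unit.
#' @param label channel description written to the header.
#' @return The record name, invisibly.
#' @export
write_wfdb <- function(rec, record, sample_rate = NULL, gain = 200,
                       label = "ABP") {
  if (!inherits(rec, "ppv_signal")) {
    stopifnot(!is.null(sample_rate))
    rec <- new_signal_record(basename(record), sample_rate, rec)
  }
  adc <- as.integer(round(rec$samples * gain))
  if (any(abs(adc) > 32767)) stop("signal exceeds 16-bit range at this gain")
  name <- basename(record)
  hea <- paste0(record, ".hea")
  dat_name <- paste0(name, ".dat")
  writeLines(c(
    sprintf("%s 1 %.10g %d", name, rec$fs, length(adc)),
    sprintf("%s 16 %g(0)/%s 16 0 %d 0 0 %s", dat_name, gain, rec$units,
            if (length(adc)) adc[1L] else 0L, label)),
    hea)
  writeBin(adc, file.path(dirname(record), dat_name), size = 2L,
           endian = "little")
  invisible(record)
}

repair_gaps <- function(rec, max_gap_frac = 0.05) {
  bad <- !is.finite(rec$samples)
  n_bad <- sum(bad)
  if (n_bad == 0L) {
    rec$provenance$interpolated <- 0L
    return(rec)
  }
  if (n_bad / length(rec$samples) > max_gap_frac) {
    stop(sprintf(
      "record refused: %.1f %% of samples are missing (limit %.1f %%)",
      100 * n_bad / length(rec$samples), 100 * max_gap_frac))
  }
  idx <- seq_along(rec$samples)
  rec$samples[bad] <- stats::approx(idx[!bad], rec$samples[!bad],
                                    xout = idx[bad], rule = 2)$y
  rec$provenance$interpolated <- n_bad
  rec
}

#' Preprocess a signal for tracking
#'
#' Decimates to the target rate behind a zero-phase anti-alias low-pass
#' (Butterworth order 4, cutoff at 0.8x the target Nyquist, applied
#' forward-backward), then mean-centers.  The removed mean is stored in the
#' provenance so envelopes can be re-offset for display.  The source rate
#' must be an integer multiple of the target rate (e.g. 360 Hz -> 40 Hz,
#' factor 9) unless `allow_resample` permits rational resampling.
#'
#' @param rec a `"ppv_signal"` record.
#' @param target_rate target sampling rate, Hz.
#' @param allow_resample permit non-integer decimation factors via
#'   polyphase resampling.
#' @return The preprocessed `"ppv_signal"` (mean-centered, at
#'   `target_rate`), with `provenance$removed_mean` and
#'   `provenance$decimation_factor`.
#' @export
preprocess_signal <- function(rec, target_rate = 40, allow_resample = FALSE) {
  stopifnot(inherits(rec, "ppv_signal"))
  x <- rec$samples
  factor <- rec$fs / target_rate
  if (abs(factor - round(factor)) < 1e-9) {
    factor <- round(factor)
    if (factor > 1L) {
      bf <- signal::butter(4, 0.8 * target_rate / rec$fs)  # 0.8x target Nyquist
      x <- signal::filtfilt(bf, x)
      x <- x[seq.int(1L, length(x), by = factor)]
    }
  } else if (allow_resample) {
    frac <- as.integer(c(1e6, round(1e6 * factor)))
    g <- gcd_int(frac[1L], frac[2L])
    bf <- signal::butter(4, 0.8 * target_rate / rec$fs)
    x <- signal::filtfilt(bf, x)
    x <- signal::resample(x, frac[1L] / g, frac[2L] / g)
  } else {
    stop(sprintf(
      "source rate %g Hz is not an integer multiple of target %g Hz; %s",
      rec$fs, target_rate, "pass allow_resample = TRUE to permit resampling"))
  }
  mu <- mean(x)
  rec$samples <- x - mu
  rec$fs <- target_rate
  rec$provenance$decimation_factor <- factor
  rec$provenance$removed_mean <- mu
  rec
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Read beat/cycle annotations
#'
#' CSV with columns `type` (`peak`, `trough` or `cycle`), `time_s`,
#' `value`.  Peak and trough times must each be strictly increasing and
#' must alternate beat by beat; violations are reported with the offending
#' line number.  `cycle` rows (respiratory cycle boundaries) are optional.
#'
#' @param path annotation CSV path.
#' @return An object of class `"ppv_annotations"`: list with `peaks`,
#'   `troughs` (data frames `time_s`, `value`) and `cycles` (numeric
#'   times, possibly empty).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("type", "time_s", "value")
  if (!all(need %in% names(df))) {
    stop("annotation file needs columns: ", paste(need, collapse = ", "))
  }
  df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  beats <- df[df$type %in% c("peak", "trough"), , drop = FALSE]
  if (nrow(beats)) {
    dt <- diff(beats$time_s)
    if (any(dt <= 0)) {
      bad <- beats$line[which(dt <= 0)[1L] + 1L]
      stop("annotation times not strictly increasing at line ", bad)
    }
    same <- beats$type[-1L] == beats$type[-nrow(beats)]
    if (any(same)) {
      bad <- beats$line[which(same)[1L] + 1L]
      stop("peaks and troughs must alternate; two consecutive '",
           beats$type[which(same)[1L]], "' entries at line ", bad)
    }
  }
  cyc <- df$time_s[df$type == "cycle"]
  if (length(cyc) && any(diff(cyc) <= 0)) {
    stop("cycle boundary times must be strictly increasing")
  }
  out <- list(
    peaks = beats[beats$type == "peak", c("time_s", "value"), drop = FALSE],
    troughs = beats[beats$type == "trough", c("time_s", "value"),
                    drop = FALSE],
    cycles = cyc)
  rownames(out$peaks) <- rownames(out$troughs) <- NULL
  class(out) <- "ppv_annotations"
  out
}

#' @export
print.ppv_annotations <- function(x, ...) {
  cat(sprintf("annotations: %d peaks, %d troughs, %d cycle boundaries\n",
              nrow(x$peaks), nrow(x$troughs), length(x$cycles)))
  invisible(x)
}

#' Local-extremum beat detector
#'
#' A deliberately simple comparator aid: finds systolic peaks and diastolic
#' troughs as local extrema separated by at least a refractory interval.
#' Manual annotations remain the gold standard input; this detector only
#' supports quick synthetic-data comparisons.
#'
#' @param rec a `"ppv_signal"` record (or numeric vector with
#'   `sample_rate`).
#' @param sample_rate rate when `rec` is a plain vector.
#' @param min_interval minimum spacing between consecutive peaks, seconds.
#' @return A `"ppv_annotations"` object with detected peaks and troughs.
#' @export
detect_beats <- function(rec, sample_rate = NULL, min_interval = 0.3) {
  if (!inherits(rec, "ppv_signal")) {
    stopifnot(!is.null(sample_rate))
    rec <- new_signal_record("signal", sample_rate, rec)
  }
  x <- rec$samples
  n <- length(x)
  t <- (seq_len(n) - 1L) / rec$fs
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
              FALSE)
  is_min <- c(FALSE, x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n],
              FALSE)
  keep_spaced <- function(idx, values, take_max) {
    if (!length(idx)) return(integer(0))
    kept <- idx[1L]
    for (i in idx[-1L]) {
      last <- kept[length(kept)]
      if (t[i] - t[last] >= min_interval) {
        kept <- c(kept, i)
      } else if ((take_max && values[i] > values[last]) ||
                 (!take_max && values[i] < values[last])) {
        kept[length(kept)] <- i
      }
    }
    kept
  }
  pk <- keep_spaced(which(is_max), x, TRUE)
  tr <- keep_spaced(which(is_min), x, FALSE)
  # enforce alternation: between consecutive peaks keep the lowest trough
  out <- list(peaks = data.frame(time_s = t[pk], value = x[pk]),
              troughs = data.frame(time_s = t[tr], value = x[tr]),
              cycles = numeric(0))
  class(out) <- "ppv_annotations"
  out
}
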