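#' Windowed PPV measurements
#'
#' Reproduces the measurement protocol used to assess the tracker: several
#' PPV measurements per record, spaced a fixed interval apart, each the
#' average over five consecutive complete respiratory cycles.  For a
#' continuous PPV trace the average is the time average over those cycles;
#' for a per-cycle table it is the mean of the five per-cycle PPV values.
#'
#' @param x either a [ppv_track()] fit, a [ppv_simulate()] result (its true
#'   PPV trace is measured), or a [ppv_per_cycle()] data frame.
#' @param n_windows number of measurement windows.
#' @param spacing window spacing in seconds (default 120 s = 2 min).
#' @param cycles_per_window respiratory cycles averaged per measurement.
#' @param anchor start time of the first window, seconds.
#' @param record record identifier carried into the output.
#' @param source `"automatic"` or `"manual"`, carried into the output.
#' @param cycles optional explicit cycle boundary times; defaults to the
#'   boundaries implied by the (tracked or true) respiratory angle.
#' @return Data frame of class `"ppv_measurements"` with columns `record`,
#'   `window`, `start_s`, `value` (mean PPV, percent), `source`, `valid`
#'   (`FALSE` when fewer than `cycles_per_window` complete cycles fit in
#'   the window, in which case `value` is `NA`).
#' @export
ppv_windows <- function(x, n_windows = 5L, spacing = 120,
                        cycles_per_window = 5L, anchor = 0,
                        record = "record", source = "automatic",
                        cycles = NULL) {
  starts <- anchor + spacing * (seq_len(n_windows) - 1L)
  if (is.data.frame(x)) {
    # per-cycle table from ppv_per_cycle()
    stopifnot(all(c("cycle_start_s", "ppv_pct", "valid") %in% names(x)))
    measure <- function(s) {
      cand <- x[x$cycle_start_s >= s & x$valid, , drop = FALSE]
      if (nrow(cand) < cycles_per_window) return(NA_real_)
      mean(cand$ppv_pct[seq_len(cycles_per_window)])
    }
  } else {
    if (inherits(x, "ppv_sim")) {
      time <- x$time
      trace <- x$truth$ppv
      if (is.null(cycles)) {
        cycles <- resp_cycle_boundaries(time, x$truth$theta_resp_unwrapped)
      }
    } else if (inherits(x, "ppv_track")) {
      if (is.null(x$ppv)) stop("track was run with envelopes = FALSE")
      time <- x$time
      trace <- x$ppv
      if (is.null(cycles)) {
        cycles <- resp_cycle_boundaries(time, x$theta_resp_unwrapped)
      }
    } else {
      stop("x must be a ppv_track, ppv_sim or per-cycle data frame")
    }
    measure <- function(s) {
      b <- cycles[cycles >= s]
      if (length(b) < cycles_per_window + 1L) return(NA_real_)
      lo <- b[1L]
      hi <- b[cycles_per_window + 1L]
      sel <- time >= lo & time < hi
      if (!any(sel)) return(NA_real_)
      mean(trace[sel])
    }
  }
  vals <- vapply(starts, measure, numeric(1))
  out <- data.frame(record = record, window = seq_len(n_windows),
                    start_s = starts, value = vals, source = source,
                    valid = !is.na(vals))
  class(out) <- c("ppv_measurements", class(out))
  out
}

#' Bland-Altman agreement between automatic and manual PPV measurements
#'
#' Pairs two measurement tables one-to-one by `(record, window)` and
#' computes the paired differences `auto - manual`, their mean (bias),
#' sample standard deviation, limits of agreement (bias +/- 1.96 sd), the
#' maximum absolute difference, and a per-record mean +/- sd summary of
#' both sources.
#'
#' @param auto,manual measurement tables as returned by [ppv_windows()]
#'   (any data frame with `record`, `window`, `value` works).  Invalid
#'   (`NA`) measurements must pair as invalid in both tables or an error is
#'   raised.
#' @return An object of class `"ppv_agreement"`: list with `pairs` (data
#'   frame of paired values and differences), `bias`, `sd`, `loa`
#'   (lower/upper limits of agreement), `max_abs_diff`, `n`, and
#'   `per_record` (per-record mean +/- sd table of each source).
#' @export
bland_altman <- function(auto, manual) {
  need <- c("record", "window", "value")
  stopifnot(all(need %in% names(auto)), all(need %in% names(manual)))
  key_a <- paste(auto$record, auto$window, sep = "#")
  key_m <- paste(manual$record, manual$window, sep = "#")
  missing_m <- setdiff(key_a, key_m)
  missing_a <- setdiff(key_m, key_a)
  if (length(missing_m) || length(missing_a)) {
    stop("unpaired measurements: ",
         paste(c(missing_m, missing_a), collapse = ", "))
  }
  m <- merge(auto[, need], manual[, need], by = c("record", "window"),
             suffixes = c("_auto", "_manual"))
  ok <- stats::complete.cases(m[, c("value_auto", "value_manual")])
  both_na <- is.na(m$value_auto) & is.na(m$value_manual)
  if (any(!ok & !both_na)) {
    stop("measurements valid in one source but not the other: ",
         paste(paste(m$record[!ok & !both_na], m$window[!ok & !both_na],
                     sep = "#"), collapse = ", "))
  }
  m <- m[ok, , drop = FALSE]
  m$diff <- m$value_auto - m$value_manual
  m$mean <- (m$value_auto + m$value_manual) / 2
  bias <- mean(m$diff)
  sdd <- stats::sd(m$diff)
  per_record <- do.call(rbind, lapply(split(m, m$record), function(g) {
    data.frame(record = g$record[1L], n = nrow(g),
               manual_mean = mean(g$value_manual),
               manual_sd = stats::sd(g$value_manual),
               auto_mean = mean(g$value_auto),
               auto_sd = stats::sd(g$value_auto))
  }))
  rownames(per_record) <- NULL
  out <- list(pairs = m, bias = bias, sd = sdd,
              loa = c(lower = bias - 1.96 * sdd, upper = bias + 1.96 * sdd),
              max_abs_diff = max(abs(m$diff)), n = nrow(m),
              per_record = per_record)
  class(out) <- "ppv_agreement"
  out
}

#' @export
print.ppv_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement, %d paired PPV measurements\n", x$n))
  cat(sprintf("  bias %.2f %%, sd %.2f %%, limits of agreement [%.2f, %.2f] %%\n",
              x$bias, x$sd, x$loa[["lower"]], x$loa[["upper"]]))
  cat(sprintf("  max |difference| %.2f %%\n", x$max_abs_diff))
  cat("per-record summary (mean +/- sd):\n")
  pr <- x$per_record
  for (i in seq_len(nrow(pr))) {
    cat(sprintf("  %-10s manual %5.1f +/- %4.1f   auto %5.1f +/- %4.1f\n",
                pr$record[i], pr$manual_mean[i], pr$manual_sd[i],
                pr$auto_mean[i], pr$auto_sd[i]))
  }
  invisible(x)
}

#' @export
plot.ppv_agreement <- function(x, ...) {
  graphics::plot(x$pairs$value_manual, x$pairs$diff,
                 xlab = "manual PPV (%)",
                 ylab = "automatic - manual PPV (%)",
                 main = "Bland-Altman", pch = 19, ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2), col = "grey40")
  invisible(x)
}

#' Table-shaped per-record agreement summary
#'
#' @param x a [bland_altman()] result.
#' @param path optional CSV output path.
#' @return The per-record summary data frame (invisibly if written).
#' @export
agreement_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "ppv_agreement"))
  tab <- x$per_record
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
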