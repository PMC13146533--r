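#' Split a multi-cycle trace into heating/cooling pairs
#'
#' Cycle boundaries come from the protocol's known on/off times, not
#' from the signal: each laser-on segment paired with the following
#' laser-off segment forms one cycle. The heating sub-trace holds the
#' samples within the on window (both boundaries included); the cooling
#' sub-trace holds the samples after shut-off up to the end of the off
#' window. An on segment with no following off segment yields a cycle
#' whose cooling member is `NULL`, with a warning.
#'
#' @param trace A [temperature_trace()] spanning the protocol.
#' @param protocol A [laser_protocol()] alternating on (power > 0) and
#'   off (power 0) segments.
#' @return A list of cycles; each element is a list with members
#'   `heating` and `cooling` ([temperature_trace()]s with original,
#'   un-rezeroed times).
#' @export
segment_cycles <- function(trace, protocol) {
  stopifnot(inherits(trace, "temperature_trace"),
            inherits(protocol, "laser_protocol"))
  segs <- protocol$segments
  on_idx <- which(segs$power_W > 0)
  if (length(on_idx) == 0)
    stop("protocol has no laser-on segment", call. = FALSE)
  sub <- function(lo, hi, closed_left, what) {
    keep <- if (closed_left) trace$times >= lo & trace$times <= hi
            else trace$times > lo & trace$times <= hi
    if (sum(keep) < 2)
      stop(sprintf("insufficient data: trace does not cover the %s window %g..%g s",
                   what, lo, hi), call. = FALSE)
    temperature_trace(trace$times[keep], trace$temps[keep],
                      label = trace$label)
  }
  lapply(seq_along(on_idx), function(k) {
    i <- on_idx[k]
    heating <- sub(segs$start_s[i], segs$end_s[i], TRUE, "heating")
    cooling <- NULL
    if (i < nrow(segs) && segs$power_W[i + 1] == 0) {
      cooling <- sub(segs$end_s[i], segs$end_s[i + 1], FALSE, "cooling")
    } else {
      warning(sprintf("cycle %d has no laser-off segment; cooling empty", k),
              call. = FALSE)
    }
    list(heating = heating, cooling = cooling)
  })
}

#' Per-cycle peak and trough summary
#'
#' The peak is the maximum sample within the heating window (the
#' highest temperature of the cycle); the trough is the minimum of the
#' cooling window, or `NA` for a cycle without cooling data.
#'
#' @param cycles Output of [segment_cycles()].
#' @return A data frame with one row per cycle: `index`, `peak_temp`,
#'   `peak_time_s`, `trough_temp`.
#' @export
summarize_cycles <- function(cycles) {
  if (!is.list(cycles) || length(cycles) == 0)
    stop("`cycles` must be a non-empty list from segment_cycles()",
         call. = FALSE)
  out <- do.call(rbind, lapply(seq_along(cycles), function(k) {
    h <- cycles[[k]]$heating
    cool <- cycles[[k]]$cooling
    i_max <- which.max(h$temps)
    data.frame(index = k,
               peak_temp = h$temps[i_max],
               peak_time_s = h$times[i_max],
               trough_temp = if (is.null(cool)) NA_real_
                             else min(cool$temps))
  }))
  rownames(out) <- NULL
  out
}

#' Peak temperature decay across cycles
#'
#' Photostability metric: the first-cycle peak minus the last-cycle
#' peak, in K. Positive values indicate degradation (e.g.
#' photobleaching of the dye).
#'
#' @param cycle_summary Data frame from [summarize_cycles()], >= 2
#'   rows.
#' @return Peak decay in K.
#' @export
peak_decay <- function(cycle_summary) {
  if (!is.data.frame(cycle_summary) ||
      !all(c("index", "peak_temp") %in% names(cycle_summary)))
    stop("`cycle_summary` must come from summarize_cycles()",
         call. = FALSE)
  if (nrow(cycle_summary) < 2)
    stop("insufficient data: need at least 2 cycles", call. = FALSE)
  ord <- order(cycle_summary$index)
  first <- cycle_summary$peak_temp[ord[1]]
  last <- cycle_summary$peak_temp[ord[length(ord)]]
  first - last
}

#' Photostability report for a multi-cycle trace
#'
#' Convenience wrapper: segments the trace, summarizes each cycle and
#' computes the peak decay.
#'
#' @inheritParams segment_cycles
#' @return An object of class `stability_report`: list with `cycles`
#'   (the [summarize_cycles()] table), `peak_decay_K` and `n_cycles`.
#' @export
stability_report <- function(trace, protocol) {
  cycles <- summarize_cycles(segment_cycles(trace, protocol))
  structure(list(cycles = cycles,
                 peak_decay_K = if (nrow(cycles) >= 2) peak_decay(cycles)
                                else NA_real_,
                 n_cycles = nrow(cycles)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Photostability over %d cycle%s\n", x$n_cycles,
              if (x$n_cycles == 1) "" else "s"))
  print(x$cycles, row.names = FALSE)
  if (!is.na(x$peak_decay_K))
    cat(sprintf("Peak decay (first - last cycle): %.2f K\n",
                x$peak_decay_K))
  invisible(x)
}

#' Plateau temperature rise across a laser power series
#'
#' For each trace, the plateau temperature rise above ambient (mean of
#' the last `plateau_k` samples, the same plateau rule the efficiency
#' estimate uses). The table is sorted by power density; rises that are
#' not strictly increasing are flagged with a warning, since the
#' steady-state rise must grow with power for a fixed system.
#'
#' @param traces A list; each element a list with members
#'   `power_density` (W/cm^2) and `trace` (a [temperature_trace()]).
#'   At least 2 distinct powers.
#' @param ambient Ambient temperature in deg C.
#' @param plateau_k Trailing samples averaged for the plateau.
#' @return A data frame with columns `power_density`, `dT_max` plus an
#'   attribute `monotone` (logical).
#' @export
power_series_summary <- function(traces, ambient, plateau_k = 3) {
  if (!is.list(traces) || length(traces) < 2)
    stop("insufficient data: need traces at >= 2 power densities",
         call. = FALSE)
  powers <- vapply(traces, function(x) x$power_density, numeric(1))
  if (anyDuplicated(powers))
    stop("duplicate power density values", call. = FALSE)
  dT <- vapply(traces, function(x) {
    tr <- x$trace
    stopifnot(inherits(tr, "temperature_trace"))
    k <- min(plateau_k, length(tr$temps))
    mean(utils::tail(tr$temps, k)) - ambient
  }, numeric(1))
  ord <- order(powers)
  out <- data.frame(power_density = powers[ord], dT_max = dT[ord])
  monotone <- all(diff(out$dT_max) > 0)
  if (!monotone)
    warning("plateau rise not monotone in laser power", call. = FALSE)
  attr(out, "monotone") <- monotone
  out
}
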