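# FUCCI cell-cycle phase calling from two-channel degron-reporter traces.

#' Construct a FUCCI trace
#'
#' Holds one cell's E2f1-GFP (degraded at S onset, so high in G1/G2) and
#' CycB-RFP (degraded from mid-mitosis through G1, so high in S/G2) time
#' series. Both channels drop during mitosis (nuclear-envelope breakdown).
#'
#' @param cell_id identifier.
#' @param times_min minutes from trace start.
#' @param e2f_green,cycb_red per-frame intensities (a.u., >= 0).
#' @param phases optional per-frame phases ({G1, S, G2, M, unknown}).
#' @return object of class \code{"fucci_trace"}.
#' @export
fucci_trace <- function(cell_id, times_min, e2f_green, cycb_red,
                        phases = NULL) {
  n <- length(times_min)
  if (length(e2f_green) != n || length(cycb_red) != n)
    stop("series lengths differ")
  if (!is.null(phases) && length(phases) != n)
    stop("phases length differs from series length")
  if (any(e2f_green < 0) || any(cycb_red < 0))
    stop("intensities must be >= 0")
  structure(list(cell_id = as.character(cell_id)[1],
                 times_min = as.numeric(times_min),
                 e2f_green = as.numeric(e2f_green),
                 cycb_red = as.numeric(cycb_red),
                 phases = phases),
            class = "fucci_trace")
}

#' @export
print.fucci_trace <- function(x, ...) {
  cat("<fucci_trace> cell", x$cell_id, "-", length(x$times_min), "frames\n")
  invisible(x)
}

# merge runs shorter than min_run into their longer neighbour until stable
.merge_short_runs <- function(states, min_run) {
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1) return(states)
    short <- which(r$lengths < min_run)
    if (!length(short)) return(states)
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1) r$lengths[i - 1] else -1
    right <- if (i < length(r$lengths)) r$lengths[i + 1] else -1
    r$values[i] <- if (left >= right) r$values[i - 1] else r$values[i + 1]
    states <- inverse.rle(r)
  }
}

#' Call cell-cycle phases from a FUCCI trace
#'
#' A channel is "present" in a frame when its intensity is at least
#' \code{presence_fraction} of that channel's per-trace maximum (relative
#' thresholds, so calls are invariant to per-cell intensity scaling).
#' Green-only frames are G1, red-only S, both-present G2. Neither-present
#' runs are M when flanked by a G2 run before and a G1 run after (the
#' G2 -> M -> G1 transition, both reporters lost at nuclear-envelope
#' breakdown), otherwise unknown. Runs shorter than \code{min_run_frames}
#' are merged into their longer neighbour first.
#'
#' @param trace a \code{\link{fucci_trace}}.
#' @param presence_fraction relative presence threshold (default 0.2).
#' @param min_run_frames minimum run length in frames (default 4, i.e.
#'   1 min at 15 s frames).
#' @return character vector of per-frame phases.
#' @export
call_phase <- function(trace, presence_fraction = 0.2, min_run_frames = 4) {
  n <- length(trace$times_min)
  if (n < min_run_frames)
    stop("trace shorter than min_run_frames (", n, " < ", min_run_frames, ")")
  gmax <- max(trace$e2f_green); rmax <- max(trace$cycb_red)
  if (gmax == 0 && rmax == 0) {
    warning("all-zero trace '", trace$cell_id, "': phases unknown")
    return(rep("unknown", n))
  }
  gp <- gmax > 0 & trace$e2f_green >= presence_fraction * gmax
  rp <- rmax > 0 & trace$cycb_red >= presence_fraction * rmax
  states <- ifelse(gp & rp, "G2", ifelse(gp, "G1", ifelse(rp, "S", "N")))
  states <- .merge_short_runs(states, min_run_frames)
  r <- rle(states)
  for (i in seq_along(r$values)) {
    if (r$values[i] == "N") {
      before_g2 <- i > 1 && r$values[i - 1] == "G2"
      after_g1 <- i < length(r$values) && r$values[i + 1] == "G1"
      r$values[i] <- if (before_g2 && after_g1) "M" else "unknown"
    }
  }
  inverse.rle(r)
}

#' Population phase proportions at a time point
#'
#' For each trace whose time range covers \code{at_time}, the phase of the
#' nearest frame is taken; fractions are reported over called (non-unknown)
#' cells and sum to 1.
#'
#' @param population list of \code{fucci_trace} with non-NULL \code{phases}
#'   (e.g. after \code{\link{call_phase}}).
#' @param at_time minutes.
#' @return named numeric fractions over G1, S, G2, M.
#' @export
phase_proportions <- function(population, at_time) {
  calls <- vapply(population, function(tr) {
    if (is.null(tr$phases) || !length(tr$times_min)) return(NA_character_)
    if (at_time < min(tr$times_min) || at_time > max(tr$times_min))
      return(NA_character_)
    tr$phases[which.min(abs(tr$times_min - at_time))]
  }, character(1))
  calls <- calls[!is.na(calls) & calls != "unknown"]
  if (!length(calls))
    stop("undefined proportions: no called cells at t = ", at_time)
  vapply(c(G1 = "G1", S = "S", G2 = "G2", M = "M"),
         function(p) mean(calls == p), numeric(1))
}
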