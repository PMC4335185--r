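#' Specify an fMRI acquisition design
#'
#' Holds the acquisition timing (repetition time, slices per volume, number
#' of volumes) and the stimulus train of every experimental input.  The
#' neuronal ODE is integrated on the microtime grid with step
#' `ts = tr / n_slices`; BOLD observations are sampled once per TR.
#' Stimuli are unit-height boxcars over half-open intervals
#' `[onset, onset + duration)`; "stick" events are boxcars one microtime
#' bin long.
#'
#' @param tr repetition time in seconds (> 0).
#' @param n_slices slices acquired per volume (>= 1); sets the microtime
#'   step `ts = tr / n_slices`.
#' @param n_volumes number of volumes acquired (>= 2); session length is
#'   `tr * n_volumes` seconds.
#' @param stimuli named list, one element per input, each a data frame (or
#'   list) with numeric `onset`, `duration` and optional `amplitude`
#'   (default 1) columns, in seconds.  An input with no stimuli is an empty
#'   data frame.
#' @param sample_offset microtime bin (0-based) within each TR period at
#'   which the BOLD observation is taken; default 0, the first bin.
#' @return An object of class `dcm_design` with derived fields
#'   `microtime_step` and `session`.
#' @export
design_spec <- function(tr, n_slices, n_volumes, stimuli = list(),
                        sample_offset = 0L) {
  if (!is.numeric(tr) || tr <= 0) stop("tr must be > 0")
  if (n_slices < 1) stop("n_slices must be >= 1")
  if (n_volumes < 2) stop("n_volumes must be >= 2")
  n_slices <- as.integer(n_slices); n_volumes <- as.integer(n_volumes)
  sample_offset <- as.integer(sample_offset)
  if (sample_offset < 0L || sample_offset >= n_slices)
    stop("sample_offset must lie in [0, n_slices)")
  session <- tr * n_volumes
  stimuli <- lapply(stimuli, .as_stimulus_frame)
  for (nm in names(stimuli)) {
    st <- stimuli[[nm]]
    if (nrow(st) && (any(st$onset < 0) || any(st$onset + st$duration > session + 1e-9)))
      stop(sprintf("input '%s': stimuli must lie within [0, %g] s", nm, session))
  }
  structure(list(tr = tr, n_slices = n_slices, n_volumes = n_volumes,
                 stimuli = stimuli, sample_offset = sample_offset,
                 microtime_step = tr / n_slices, session = session),
            class = "dcm_design")
}

.as_stimulus_frame <- function(st) {
  if (is.null(st) || (is.data.frame(st) && nrow(st) == 0) || length(st) == 0)
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      amplitude = numeric(0)))
  st <- as.data.frame(st)
  if (is.null(st$amplitude)) st$amplitude <- 1
  if (any(st$duration <= 0)) stop("stimulus durations must be > 0")
  st[order(st$onset), c("onset", "duration", "amplitude"), drop = FALSE]
}

#' @export
print.dcm_design <- function(x, ...) {
  cat(sprintf(
    "fMRI design: TR %g s, %d slices (ts = %g s), %d volumes, session %g s (%g min)\n",
    x$tr, x$n_slices, x$microtime_step, x$n_volumes, x$session, x$session / 60))
  for (nm in names(x$stimuli))
    cat(sprintf("  input '%s': %d stimulus epoch(s)\n", nm, nrow(x$stimuli[[nm]])))
  invisible(x)
}

#' Input values at given times
#' @param design a [design_spec()].
#' @param t numeric vector of times in seconds.
#' @return Matrix `length(t) x n_inputs` of boxcar input values
#'   (half-open intervals).
#' @export
input_values <- function(design, t) {
  ns <- .to_ns(t)
  out <- matrix(0, length(t), length(design$stimuli),
                dimnames = list(NULL, names(design$stimuli)))
  for (i in seq_along(design$stimuli)) {
    st <- design$stimuli[[i]]
    for (k in seq_len(nrow(st))) {
      on <- .to_ns(st$onset[k]); off <- .to_ns(st$onset[k] + st$duration[k])
      hit <- ns >= on & ns < off
      out[hit, i] <- out[hit, i] + st$amplitude[k]
    }
  }
  out
}

# Times are bookkept in integer nanoseconds so that microtime grid points and
# stimulus change points that should coincide do coincide exactly.
.to_ns <- function(t) as.numeric(round(t * 1e9))

# Precompute everything about a design that does not depend on parameter
# values: the microtime grid, the piecewise-constant-input segment list and
# the unique input rows.  Segment s runs between consecutive break points;
# `rec` is the 1-based microtime grid column recorded at the segment's end
# (0 if the end is an interior stimulus change point).
design_segments <- function(design, n_inputs) {
  ts <- design$microtime_step
  n_grid <- design$n_slices * design$n_volumes
  ts_ns <- .to_ns(ts)
  grid_ns <- (seq_len(n_grid) - 1) * ts_ns
  cp <- unlist(lapply(design$stimuli, function(st)
    c(st$onset, st$onset + st$duration)), use.names = FALSE)
  cp_ns <- if (length(cp)) .to_ns(cp) else numeric(0)
  last <- grid_ns[n_grid]
  cp_ns <- cp_ns[cp_ns > 0 & cp_ns < last]
  breaks <- sort(unique(c(grid_ns, cp_ns)))
  n_seg <- length(breaks) - 1L
  seg_dt <- diff(breaks) / 1e9
  rec <- match(breaks[-1L], grid_ns)
  rec[is.na(rec)] <- 0L

  u <- input_values(design, breaks[-length(breaks)] / 1e9)
  if (n_inputs != ncol(u)) {
    if (ncol(u) == 0) u <- matrix(0, nrow(u), n_inputs)
    else stop("design has a different number of inputs than the model")
  }
  key <- if (n_inputs) apply(u, 1, paste, collapse = "\r") else rep("", n_seg)
  # unique (input pattern, dt) pairs index the precomputed propagators
  dt_ns <- diff(breaks)
  pair_key <- paste(key, dt_ns)
  uniq <- !duplicated(pair_key)
  prop_u <- u[uniq, , drop = FALSE]
  prop_dt <- seg_dt[uniq]
  seg_prop <- match(pair_key, pair_key[uniq]) - 1L  # 0-based for the core

  list(n_grid = n_grid, times = (seq_len(n_grid) - 1) * ts,
       prop_u = prop_u, prop_dt = prop_dt, seg_prop = seg_prop,
       seg_dt = seg_dt, seg_rec = rec)
}
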