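#' Design variants: repetition time
#'
#' Replaces the TR while holding the session length (not the volume
#' count) fixed: the volume count is rescaled to `session / new_tr`,
#' rounded down so sampling never runs past the stimulus-covered period.
#' Slices per volume and the absolute stimulus timing are preserved.
#'
#' @param design a [design_spec()].
#' @param new_tr new repetition time in seconds (> 0).
#' @param hold_volumes keep `n_volumes` instead of the session length.
#' @return The new design.
#' @export
vary_tr <- function(design, new_tr, hold_volumes = FALSE) {
  if (new_tr <= 0) stop("new_tr must be > 0")
  n_vol <- if (hold_volumes) design$n_volumes
  else as.integer(floor(design$session / new_tr + 1e-9))
  design_spec(new_tr, design$n_slices, n_vol,
              .clip_stimuli(design$stimuli, new_tr * n_vol),
              design$sample_offset)
}

#' Design variants: session duration
#'
#' Replaces the volume count.  Stimuli beyond the new session end are
#' dropped (durations truncated at the boundary); for an extension the
#' base stimulus pattern of each input repeats with its original onset
#' spacing.
#'
#' @param design a [design_spec()].
#' @param n_volumes new volume count (>= 2).
#' @return The new design.
#' @export
vary_session <- function(design, n_volumes) {
  if (n_volumes < 2) stop("n_volumes must be >= 2")
  new_session <- design$tr * n_volumes
  stimuli <- design$stimuli
  if (new_session > design$session + 1e-9) {
    stimuli <- lapply(stimuli, function(st) {
      if (nrow(st) == 0) return(st)
      spacing <- if (nrow(st) >= 2) st$onset[2] - st$onset[1]
      else design$session
      base <- st  # durations/amplitudes recycled from the base pattern
      k <- nrow(base)
      onset <- tail(base$onset, 1) + spacing
      while (onset < new_session - 1e-9) {
        k <- k + 1L
        pat <- base[((k - 1L) %% nrow(base)) + 1L, , drop = FALSE]
        pat$onset <- onset
        st <- rbind(st, pat)
        onset <- onset + spacing
      }
      st
    })
  }
  design_spec(design$tr, design$n_slices, n_volumes,
              .clip_stimuli(stimuli, new_session), design$sample_offset)
}

#' Design variants: epoch duration
#'
#' Every stimulus keeps its onset and amplitude; its duration becomes
#' `epoch_s`, so the stimulus count is unchanged and only the epoch
#' length varies.  Epochs longer than the minimum onset spacing would
#' overlap and raise an error.
#'
#' @param design a [design_spec()].
#' @param epoch_s new epoch duration in seconds (> 0).
#' @return The new design.
#' @export
vary_epoch <- function(design, epoch_s) {
  if (epoch_s <= 0) stop("epoch_s must be > 0")
  spacings <- unlist(lapply(design$stimuli, function(st)
    if (nrow(st) >= 2) diff(st$onset) else numeric(0)))
  if (length(spacings) && epoch_s > min(spacings) + 1e-9)
    stop(sprintf("epoch_s = %g s exceeds the minimum onset spacing (%g s); epochs would overlap",
                 epoch_s, min(spacings)))
  stimuli <- lapply(design$stimuli, function(st) {
    st$duration <- rep(epoch_s, nrow(st)); st
  })
  design_spec(design$tr, design$n_slices, design$n_volumes,
              .clip_stimuli(stimuli, design$session), design$sample_offset)
}

.clip_stimuli <- function(stimuli, session) {
  lapply(stimuli, function(st) {
    st <- st[st$onset < session - 1e-9, , drop = FALSE]
    over <- st$onset + st$duration > session
    st$duration[over] <- session - st$onset[over]
    st
  })
}

#' Specify a design sweep
#'
#' One-at-a-time variation of TR, session duration (volume count), epoch
#' duration and SNR around a base design, the grid evaluated by
#' [run_sweep()].
#'
#' @param base_design a [design_spec()].
#' @param tr_values,n_volume_values,epoch_durations,snr_values numeric
#'   vectors of variant values (any may be NULL).
#' @param replicates replicate noise realizations per variant (default 1).
#' @param base_snr SNR used for variants of the timing axes (default 10).
#' @return List of class `dcm_sweep`.
#' @export
sweep_spec <- function(base_design, tr_values = NULL, n_volume_values = NULL,
                       epoch_durations = NULL, snr_values = NULL,
                       replicates = 1L, base_snr = 10) {
  stopifnot(replicates >= 1)
  structure(list(base_design = base_design, tr_values = tr_values,
                 n_volume_values = n_volume_values,
                 epoch_durations = epoch_durations, snr_values = snr_values,
                 replicates = as.integer(replicates), base_snr = base_snr),
            class = "dcm_sweep")
}

#' Run an identifiability sweep over design variants
#'
#' Evaluates [assess_model()] for every design variant and replicate and
#' tabulates the outcome: mean-CI criterion, number of identifiable
#' parameters, per-parameter statuses.  Each variant x replicate uses a
#' distinct, logged seed (`base_seed + 1000 * variant + replicate`) so
#' every row is a different noise realization.  Individual variant
#' failures are recorded per row; the sweep continues.
#'
#' @param model a [dcm_model()] with generating parameter values.
#' @param sweep a [sweep_spec()].
#' @param base_seed integer seed root.
#' @param settings a [profile_settings()] list.
#' @param keep_reports also return the full reports (attribute
#'   `reports`).
#' @return A tidy data frame: axis, value, replicate, seed, mci,
#'   n_identifiable, n_params, statuses, error.
#' @export
run_sweep <- function(model, sweep, base_seed = 1L,
                      settings = profile_settings(), keep_reports = FALSE) {
  variants <- list(list(axis = "base", value = NA_real_,
                        design = sweep$base_design, snr = sweep$base_snr))
  add <- function(axis, values, make) {
    for (v in values)
      variants[[length(variants) + 1L]] <<- list(
        axis = axis, value = v, design = make(v),
        snr = if (axis == "snr") v else sweep$base_snr)
  }
  if (!is.null(sweep$tr_values))
    add("tr", sweep$tr_values, function(v) vary_tr(sweep$base_design, v))
  if (!is.null(sweep$n_volume_values))
    add("n_volumes", sweep$n_volume_values,
        function(v) vary_session(sweep$base_design, v))
  if (!is.null(sweep$epoch_durations))
    add("epoch", sweep$epoch_durations,
        function(v) vary_epoch(sweep$base_design, v))
  if (!is.null(sweep$snr_values))
    add("snr", sweep$snr_values, function(v) sweep$base_design)
  if (length(variants) > 1L) variants <- variants[-1L]  # base only if no axes

  rows <- list(); reports <- list()
  for (vi in seq_along(variants)) {
    vr <- variants[[vi]]
    for (r in seq_len(sweep$replicates)) {
      seed <- as.integer(base_seed + 1000L * vi + r)
      rep_out <- tryCatch(
        assess_model(model, vr$design, vr$snr, seed, settings = settings),
        error = function(e) e)
      if (inherits(rep_out, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          axis = vr$axis, value = vr$value, replicate = r, seed = seed,
          mci = NA_real_, n_identifiable = NA_integer_,
          n_params = n_params(model), statuses = NA_character_,
          error = conditionMessage(rep_out), stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        axis = vr$axis, value = vr$value, replicate = r, seed = seed,
        mci = rep_out$mci,
        n_identifiable = sum(rep_out$cis$status == "identifiable"),
        n_params = nrow(rep_out$cis),
        statuses = paste(rep_out$cis$status, collapse = ";"),
        error = NA_character_, stringsAsFactors = FALSE)
      if (keep_reports) reports[[length(rows)]] <- rep_out
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_reports) attr(out, "reports") <- reports
  out
}
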