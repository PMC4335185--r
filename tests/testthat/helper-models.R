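# Small models and designs shared across tests.  Everything is built in
# code; no stored fixtures beyond the package's bundled network configs.

# One region, one driving input, two free parameters (a11, c11).
one_region_model <- function(a = -0.5, c = 0.8) {
  dcm_model(a_mask = matrix(1), a_values = matrix(a),
            c_mask = matrix(1), c_values = matrix(c),
            region_names = "R1", input_names = "drive")
}

# One region, two driving inputs (a11, c11, c12 free).
two_input_model <- function(a = -0.5, c1 = 0.8, c2 = 0.4) {
  dcm_model(a_mask = matrix(1), a_values = matrix(a),
            c_mask = matrix(c(1, 1), 1), c_values = matrix(c(c1, c2), 1),
            region_names = "R1", input_names = c("in1", "in2"))
}

# Two regions in a feed-forward chain; 4 free parameters
# (a11, a21, a22, c11).  Triangular A keeps the eigenvalues on the
# diagonal, so fits rarely wander into diverging regimes.
chain_model <- function(a11 = -0.6, a21 = 0.4, a22 = -0.6, c1 = 0.8) {
  dcm_model(a_mask = rbind(c(1, 0), c(1, 1)),
            a_values = rbind(c(a11, 0), c(a21, a22)),
            c_mask = rbind(1, 0), c_values = rbind(c1, 0),
            region_names = c("R1", "R2"), input_names = "drive")
}

# Blocked design: 20 s epochs every 40 s.
block_design <- function(tr = 2, n_slices = 2, n_volumes = 180,
                         n_inputs = 1, epoch = 20, spacing = 40) {
  session <- tr * n_volumes
  onsets <- seq(0, session - epoch, by = spacing)
  st <- data.frame(onset = onsets, duration = epoch)
  stimuli <- rep(list(st), n_inputs)
  names(stimuli) <- if (n_inputs == 1) "drive" else sprintf("in%d", seq_len(n_inputs))
  design_spec(tr, n_slices, n_volumes, stimuli)
}

# Reduced-budget profiling settings for test-sized problems.
test_settings <- function(max_points = 30, ...) {
  profile_settings(max_points = max_points,
                   control = fit_control(maxiter = 60, restarts = 0), ...)
}
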