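# Model + design configuration schema

A configuration is a YAML (`.yaml`/`.yml`) or JSON (`.json`) file read by
`read_dcm_config()` and written by `write_dcm_config()`.

Required keys:

- `regions`: list of region labels (length `m`).
- `inputs`: list of input objects, in input order. Each has
  - `name`: input label,
  - `onsets`: stimulus onsets in seconds (may be empty),
  - `durations`: epoch durations in seconds (same length as `onsets`),
  - `amplitudes` (optional, default 1): boxcar heights.
  Stimuli are unit-height boxcars over half-open intervals
  `[onset, onset + duration)`; all must lie inside the session
  `[0, tr * n_volumes]`.
- `A`: object with `mask` and `values`, each an `m x m` matrix given as a
  list of rows. Rows index target regions, columns source regions; entries
  are rates of change in Hz. The mask is binary, its diagonal is always
  treated as 1 (self-connections), and values must be zero wherever the
  mask is zero.
- `C`: object with `mask` and `values`, `m x n_inputs` (driving inputs).
- `tr`: repetition time in seconds.
- `n_slices`: slices per volume; the integration microtime step is
  `ts = tr / n_slices`.
- `n_volumes`: volumes acquired; session length is `tr * n_volumes`.

Optional keys:

- `B`: object mapping an *input name* to `{mask, values}` (`m x m`) for the
  modulation that input exerts on connections. Inputs without an entry do
  not modulate.
- `snr`: signal-to-noise ratio (SD of clean signal / SD of noise, per
  region) used when simulating data from the config.
- `seed`: integer RNG seed for the noise realization.
- `name`: free-form label.

Example (three regions, one driving and one modulatory input):

```yaml
regions: [R1, R2, R3]
inputs:
- name: drive
  onsets: [0, 40]
  durations: [20, 20]
- name: mod
  onsets: [40]
  durations: [20]
A:
  mask:   [[1, 0, 0], [1, 1, 0], [0, 1, 1]]
  values: [[-0.5, 0, 0], [0.3, -0.5, 0], [0, 0.3, -0.5]]
C:
  mask:   [[1, 0], [0, 0], [0, 0]]
  values: [[0.8, 0], [0, 0], [0, 0]]
B:
  mod:
    mask:   [[0, 0, 0], [1, 0, 0], [0, 0, 0]]
    values: [[0, 0, 0], [0.4, 0, 0], [0, 0, 0]]
tr: 2.0
n_slices: 8
n_volumes: 180
snr: 10
seed: 1
```
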