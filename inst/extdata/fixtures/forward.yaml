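name: forward
regions:
- V1
- V5
- SPC
inputs:
- name: Photic
  onsets:
  - 0.0
  - 64.4
  - 128.8
  - 193.2
  - 257.6
  - 322.0
  - 386.4
  - 450.8
  - 515.2
  - 579.6
  - 644.0
  - 708.4
  - 772.8
  - 837.2
  - 901.6
  - 966.0
  - 1030.4
  - 1094.8
  durations:
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  amplitudes:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
- name: Motion
  onsets:
  - 0.0
  - 128.8
  - 257.6
  - 386.4
  - 515.2
  - 644.0
  - 772.8
  - 901.6
  - 1030.4
  durations:
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  amplitudes:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
- name: Attention
  onsets:
  - 64.4
  - 193.2
  - 322.0
  - 450.8
  - 579.6
  - 708.4
  - 837.2
  - 966.0
  - 1094.8
  durations:
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  - 32.2
  amplitudes:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
A:
  mask:
  - - 1.0
    - 1.0
    - 0.0
  - - 1.0
    - 1.0
    - 1.0
  - - 0.0
    - 1.0
    - 1.0
  values:
  - - -0.5
    - 0.3
    - 0.0
  - - 0.3
    - -0.5
    - 0.3
  - - 0.0
    - 0.3
    - -0.5
C:
  mask:
  - - 1.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
  values:
  - - 0.8
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
  - - 0.0
    - 0.0
    - 0.0
B:
  Motion:
    mask:
    - - 0.0
      - 0.0
      - 0.0
    - - 1.0
      - 0.0
      - 0.0
    - - 0.0
      - 0.0
      - 0.0
    values:
    - - 0.0
      - 0.0
      - 0.0
    - - 0.4
      - 0.0
      - 0.0
    - - 0.0
      - 0.0
      - 0.0
  Attention:
    mask:
    - - 0.0
      - 0.0
      - 0.0
    - - 1.0
      - 0.0
      - 0.0
    - - 0.0
      - 0.0
      - 0.0
    values:
    - - 0.0
      - 0.0
      - 0.0
    - - 0.4
      - 0.0
      - 0.0
    - - 0.0
      - 0.0
      - 0.0
tr: 3.22
n_slices: 32.0
n_volumes: 360.0
snr: 10.0
seed: 1.0
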