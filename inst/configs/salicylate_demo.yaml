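# Two-condition salicylate-analogue demonstration: the "salicylate"
# condition raises each unit's rate gain and phase-locking concentration
# and lowers the behavioral psychometric threshold, so temporal, rate,
# decoder and behavioral AM thresholds all come out lower than baseline.
seed: 1
stages: [simulate, amcode, popdecode, behavior]
n_units: 8
n_trials: 15
fmod: 16
depths: [0, 0.06, 0.125, 0.25, 0.5, 1]
um_duration: 1
am_duration: 1
conditions:
  baseline: {gain: 1, lock: 1}
  salicylate: {gain: 1.6, lock: 2}
behavior:
  baseline: {threshold_db: -10}
  salicylate: {threshold_db: -16}
  n_per_cell: 30
  n_catch: 60
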