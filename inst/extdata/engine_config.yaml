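# Engine configuration: timers, drug doses, defibrillation energies.
# All clinical constants live here, never in code, so that guideline
# revisions require only a config change.
timers:
  rhythm_check:
    period_s: 120          # rhythm re-check reminder
    priority_rank: 2
    repeating: true
  medication:
    period_s: 180          # epinephrine repeat interval; allowed 180-300
    priority_rank: 1       # medication alerts outrank rhythm-check alerts
    repeating: true
    start: first_epi       # one of: first_epi, case_start
doses:
  epinephrine:
    per_kg: 0.01           # mg/kg IV/IO
    max_total: 1.0         # mg per dose
    concentration: 0.1     # mg/mL (1:10,000 dilution)
    dilution: "1:10000"
    round_to: 3
energy:
  first_j_per_kg: 2
  second_j_per_kg: 4
  subsequent_j_per_kg: 4
  cap_j_per_kg: 10
  absolute_cap_j: 360
metronome:
  min_bpm: 100
  max_bpm: 120
limits:
  max_weight_kg: 100
buttons:
  recognition: recognize_arrest
  epinephrine_administration: administer_epinephrine
  shock_delivery: deliver_shock
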