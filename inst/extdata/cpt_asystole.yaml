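# Clinical-performance tasks for the asystole section, maximum total 13.
# Each task scores 0 when its anchor event is absent, full points when
# present with all timing/payload criteria met, and full-minus-one
# (partial / late / incorrect) otherwise. Task wording and windows are
# reconstructions, flagged as such.
instrument: cpt_asystole
max_total: 13
tasks:
  - id: recognition_and_help
    max_points: 2
    reconstructed: true
    rule: {event: TAP, button: recognize_arrest, window: {from: case_start, max_s: 60}}
  - id: cpr_initiation
    max_points: 2
    reconstructed: true
    rule: {event: TAP, button: start_cpr, window: {from: recognition, max_s: 60}}
  - id: rhythm_identification
    max_points: 2
    reconstructed: true
    rule: {event: RHYTHM_SELECTED, window: {from: case_start, max_s: 90}}
  - id: epinephrine_administration
    max_points: 2
    reconstructed: true
    rule: {event: TAP, button: administer_epinephrine, window: {from: recognition, max_s: 300}}
  - id: reversible_causes
    max_points: 2
    reconstructed: true
    rule: {event: TAP, button: assess_hypovolemia, window: {from: case_start, max_s: 420}}
  - id: airway_ventilation
    max_points: 2
    reconstructed: true
    rule: {event: TAP, button: ventilate_effectively, window: {from: case_start, max_s: 240}}
  - id: rhythm_reassessment
    max_points: 1
    reconstructed: true
    rule: {event: RHYTHM_SELECTED, min_count: 2}
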