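# Default 16-item deviation checklist for a nonshockable pediatric
# cardiac-arrest scenario. Each item names one correct critical action;
# an item scores 0 when its rule holds in the event log and 1 (one
# deviation) otherwise. Every item is anchored on a distinct log event so
# that single faults map to single items. The published instrument is not
# reproduced verbatim; all items here are reconstructions from standard
# resuscitation criteria and are flagged as such.
instrument: cdevplus
max_items: 16
items:
  - id: timely_recognition
    description_key: item.timely_recognition
    reconstructed: true
    rule: {event: TAP, button: recognize_arrest, window: {from: case_start, max_s: 60}}
  - id: help_called
    description_key: item.help_called
    reconstructed: true
    rule: {event: TAP, button: call_for_help}
  - id: early_cpr
    description_key: item.early_cpr
    reconstructed: true
    rule: {event: TAP, button: start_cpr, window: {from: recognition, max_s: 30}}
  - id: correct_compression_ratio
    description_key: item.correct_compression_ratio
    reconstructed: true
    rule: {event: TAP, button: resume_cpr, payload: {key: ratio, equals: "15:2"}}
  - id: monitor_attached
    description_key: item.monitor_attached
    reconstructed: true
    rule: {event: TAP, button: attach_monitor}
  - id: airway_opened
    description_key: item.airway_opened
    reconstructed: true
    rule: {event: TAP, button: open_airway}
  - id: vascular_access
    description_key: item.vascular_access
    reconstructed: true
    rule: {event: TAP, button: obtain_vascular_access}
  - id: epinephrine_prepared
    description_key: item.epinephrine_prepared
    reconstructed: true
    rule: {event: TAP, button: prepare_epinephrine}
  - id: correct_epinephrine_dose
    description_key: item.correct_epinephrine_dose
    reconstructed: true
    rule: {event: DOSE_COMPUTED, payload: {key: mass_mg, equals_key: recommended_mg}}
  - id: correct_dilution
    description_key: item.correct_dilution
    reconstructed: true
    rule: {event: TAP, button: verify_dilution, payload: {key: dilution, equals: "1:10000"}}
  - id: timely_epinephrine
    description_key: item.timely_epinephrine
    reconstructed: true
    rule: {event: TAP, button: administer_epinephrine, window: {from: recognition, max_s: 300}}
  - id: line_flushed
    description_key: item.line_flushed
    reconstructed: true
    rule: {event: TAP, button: flush_line}
  - id: reversible_causes_search
    description_key: item.reversible_causes_search
    reconstructed: true
    rule: {event: TAP, button: assess_hypovolemia}
  - id: hypovolemia_treated
    description_key: item.hypovolemia_treated
    reconstructed: true
    rule: {event: TAP, button: give_fluid_bolus}
  - id: effective_ventilation
    description_key: item.effective_ventilation
    reconstructed: true
    rule: {event: TAP, button: ventilate_effectively}
  - id: rhythm_reassessed
    description_key: item.rhythm_reassessed
    reconstructed: true
    rule: {event: RHYTHM_SELECTED, min_count: 2}
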