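# Default study scenario: nonshockable (asystole) arrest in a 10 kg
# infant; the rhythm becomes organized with a pulse once two epinephrine
# doses have been given and at least six minutes have elapsed. The case
# is capped at ten minutes.
initial_rhythm: ASYSTOLE
weight_kg: 10
max_duration_s: 600
transition_rules:
  - when: {min_epi_doses: 2, min_elapsed_s: 360}
    rhythm: ORGANIZED_WITH_PULSE
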