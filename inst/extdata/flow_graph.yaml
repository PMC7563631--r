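# Default guidance flow graph: shared entry, a rhythm-choice screen, and
# nonshockable / shockable pathways that re-join on the shared medication,
# reversible-causes and airway screens before looping back to the rhythm
# check. An organized rhythm with a pulse exits to post-resuscitation care.
start_node: start
pathway_tags:
  start: shared
  rhythm_check: shared
  nonshock_cpr: nonshockable
  shock_delivery: shockable
  shock_cpr: shockable
  epi_preparation: shared
  epi_administration: shared
  reversible_causes: shared
  airway_management: shared
  rosc_care: shared
nodes:
  - id: start
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: rhythm_check
    buttons:
      - {id: recognize_arrest, label_key: btn.recognize_arrest, layout: SEQUENTIAL, kind: ACTION}
      - {id: call_for_help, label_key: btn.call_for_help, layout: SEQUENTIAL, kind: ACTION}
      - {id: start_cpr, label_key: btn.start_cpr, layout: SEQUENTIAL, kind: ACTION}
      - {id: attach_monitor, label_key: btn.attach_monitor, layout: SEQUENTIAL, kind: ACTION}
  - id: rhythm_check
    advance_rule: ONE_CHOICE_SELECTED
    rhythm_choice: true
    on_advance:
      nonshockable: nonshock_cpr
      shockable: shock_delivery
      rosc: rosc_care
    buttons:
      - {id: nonshockable, label_key: btn.rhythm_nonshockable, layout: ALTERNATIVE, kind: CHOICE}
      - {id: shockable, label_key: btn.rhythm_shockable, layout: ALTERNATIVE, kind: CHOICE}
      - {id: rosc, label_key: btn.rhythm_organized_pulse, layout: ALTERNATIVE, kind: CHOICE}
  - id: nonshock_cpr
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: epi_preparation
    buttons:
      - {id: resume_cpr, label_key: btn.resume_cpr, layout: SEQUENTIAL, kind: ACTION}
      - {id: obtain_vascular_access, label_key: btn.obtain_vascular_access, layout: SEQUENTIAL, kind: ACTION}
  - id: shock_delivery
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: shock_cpr
    buttons:
      - {id: charge_defibrillator, label_key: btn.charge_defibrillator, layout: SEQUENTIAL, kind: ACTION}
      - {id: clear_team, label_key: btn.clear_team, layout: SEQUENTIAL, kind: ACTION}
      - {id: deliver_shock, label_key: btn.deliver_shock, layout: SEQUENTIAL, kind: ACTION}
  - id: shock_cpr
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: epi_preparation
    buttons:
      - {id: resume_cpr, label_key: btn.resume_cpr, layout: SEQUENTIAL, kind: ACTION}
      - {id: obtain_vascular_access, label_key: btn.obtain_vascular_access, layout: SEQUENTIAL, kind: ACTION}
  - id: epi_preparation
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: epi_administration
    buttons:
      - {id: prepare_epinephrine, label_key: btn.prepare_epinephrine, layout: SEQUENTIAL, kind: ACTION}
      - {id: verify_dilution, label_key: btn.verify_dilution, layout: SEQUENTIAL, kind: ACTION}
  - id: epi_administration
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: reversible_causes
    buttons:
      - {id: administer_epinephrine, label_key: btn.administer_epinephrine, layout: SEQUENTIAL, kind: ACTION}
      - {id: flush_line, label_key: btn.flush_line, layout: SEQUENTIAL, kind: ACTION}
  - id: reversible_causes
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: airway_management
    buttons:
      - {id: assess_hypovolemia, label_key: btn.assess_hypovolemia, layout: SEQUENTIAL, kind: ACTION}
      - {id: give_fluid_bolus, label_key: btn.give_fluid_bolus, layout: SEQUENTIAL, kind: ACTION}
      - {id: assess_hypoxia, label_key: btn.assess_hypoxia, layout: SEQUENTIAL, kind: ACTION}
      - {id: assess_metabolic, label_key: btn.assess_metabolic, layout: SEQUENTIAL, kind: ACTION}
      - {id: assess_obstructive, label_key: btn.assess_obstructive, layout: SEQUENTIAL, kind: ACTION}
  - id: airway_management
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: rhythm_check
    buttons:
      - {id: open_airway, label_key: btn.open_airway, layout: SEQUENTIAL, kind: ACTION}
      - {id: ventilate_effectively, label_key: btn.ventilate_effectively, layout: SEQUENTIAL, kind: ACTION}
      - {id: consider_advanced_airway, label_key: btn.consider_advanced_airway, layout: SEQUENTIAL, kind: ACTION}
  - id: rosc_care
    advance_rule: ALL_SEQUENTIAL_TAPPED
    on_advance: ~
    buttons:
      - {id: assess_abcde, label_key: btn.assess_abcde, layout: SEQUENTIAL, kind: ACTION}
      - {id: support_ventilation, label_key: btn.support_ventilation, layout: SEQUENTIAL, kind: ACTION}
      - {id: maintain_perfusion, label_key: btn.maintain_perfusion, layout: SEQUENTIAL, kind: ACTION}
      - {id: arrange_intensive_care, label_key: btn.arrange_intensive_care, layout: SEQUENTIAL, kind: ACTION}
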