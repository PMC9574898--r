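# AOI label -> group mapping for the five-phase induction scenario.
# Entries without a "phases" list apply to all phases 1-5.
groups:
  patient:
    - aoi: patients_head
    - aoi: patients_thorax
    - aoi: iv_access
    - aoi: face_mask
      phases: [3, 4, 5]
    - aoi: patients_mouth
    - aoi: laryngoscope_monitor
      phases: [5]
    - aoi: patients_arm
  monitoring_equipment:
    - aoi: anesthesia_machine
    - aoi: patient_monitor
    - aoi: settings_patient_monitor
    - aoi: settings_anesthesia_machine
    - aoi: clock
  documentation:
    - aoi: patient_record
    - aoi: anesthesia_chart
  medication_general_equipment:
    - aoi: nurses_hands
    - aoi: infusion
    - aoi: face_mask
      phases: [1, 2]
    - aoi: respiratory_tube
    - aoi: drug_application
    - aoi: anesthesia_trolley
    - aoi: laryngoscope_monitor
      phases: [1, 2, 3, 4]
    - aoi: monitoring_cable
  excluded:
    - aoi: nurses_head
    - aoi: movement_in_room
    - aoi: floor
    - aoi: walls
    - aoi: front_pocket_content
    - aoi: iv_pumps_not_in_use
    - aoi: desk
    - aoi: entrance_door
    - aoi: not_classified
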