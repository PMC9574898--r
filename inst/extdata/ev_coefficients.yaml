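# SYNTHETIC RECONSTRUCTION of an expectancy-value parametrization for the
# five induction phases. The expectancy (EX) and value (V) entries are
# lowest-ordinal integer ranks assigned from the phase task structure
# (phase 1 chart review, phase 2 equipment precheck, phase 3 preoxygenation
# and drug induction, phase 4 mask ventilation and muscle relaxation,
# phase 5 laryngoscopy) against the two clinical main goals (inducing
# anesthesia; maintaining hemodynamic stability and ventilation).
# This table is NON-AUTHORITATIVE: it is a documented stand-in for the
# original study's expert parametrization, which is not publicly deposited.
# Salience (S) and effort (EF) are zero throughout (EV model).
model: EV
phases:
  - phase: 1
    label: case_history
    groups:
      patient: {EX: 1, V: 2}
      monitoring_equipment: {EX: 0, V: 1}
      documentation: {EX: 2, V: 3}
      medication_general_equipment: {EX: 1, V: 1}
  - phase: 2
    label: precheck
    groups:
      patient: {EX: 1, V: 1}
      monitoring_equipment: {EX: 2, V: 2}
      documentation: {EX: 0, V: 1}
      medication_general_equipment: {EX: 3, V: 3}
  - phase: 3
    label: preoxygenation_induction
    groups:
      patient: {EX: 3, V: 3}
      monitoring_equipment: {EX: 2, V: 2}
      documentation: {EX: 0, V: 1}
      medication_general_equipment: {EX: 2, V: 2}
  - phase: 4
    label: mask_ventilation_relaxation
    groups:
      patient: {EX: 3, V: 3}
      monitoring_equipment: {EX: 3, V: 2}
      documentation: {EX: 0, V: 1}
      medication_general_equipment: {EX: 1, V: 1}
  - phase: 5
    label: laryngoscopy
    groups:
      patient: {EX: 3, V: 3}
      monitoring_equipment: {EX: 1, V: 1}
      documentation: {EX: 0, V: 0}
      medication_general_equipment: {EX: 1, V: 1}
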