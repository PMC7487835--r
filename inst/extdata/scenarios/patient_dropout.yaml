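name: patient_dropout
description: >
  Five patients are enrolled and one drops out: the dropout event is
  broadcast, the participating count falls to four, and the dropped
  patient's roster slot is zeroed while pre-drop data is retained.
min_patients: 5
cohort: 5
steps:
  - {op: request_ind, expect: ok}
  - {op: set_ind_approval, approved: true, expect: ok, events: [INDStageStatus]}
  - {op: request_ct_initiation, expect: ok}
  - {op: set_ct_initiation_decision, approved: true, expect: ok, events: [CTInitiationStageStatus]}
  - {op: enroll_patient, patient: 1, expect: ok, events: [NewPatientEnrolled]}
  - {op: enroll_patient, patient: 2, expect: ok, events: [NewPatientEnrolled]}
  - {op: enroll_patient, patient: 3, expect: ok, events: [NewPatientEnrolled]}
  - {op: enroll_patient, patient: 4, expect: ok, events: [NewPatientEnrolled]}
  - {op: enroll_patient, patient: 5, expect: ok, events: [NewPatientEnrolled]}
  - {op: complete_enrollment, expect: ok, events: [EnrollmentStageStatus], stage: MONITORING}
  - {op: record_visit, patient: 1, expect: ok}
  - {op: drop_patient, patient: 1, expect: ok, events: [PatientDroppedOut], count: 4}
  - {op: drop_patient, patient: 1, expect: already_dropped, count: 4}
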