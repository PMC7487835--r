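name: patient_enrollment
description: >
  Enrolling a patient broadcasts an event carrying the new pseudonymous
  address; enrolling the same address twice is refused.
min_patients: 5
cohort: 5
steps:
  - {op: request_ind, expect: ok}
  - {op: set_ind_approval, approved: true, expect: ok, events: [INDStageStatus]}
  - {op: request_ct_initiation, expect: ok}
  - {op: set_ct_initiation_decision, approved: true, expect: ok, events: [CTInitiationStageStatus]}
  - {op: enroll_patient, patient: 1, expect: ok, events: [NewPatientEnrolled], count: 1}
  - {op: enroll_patient, patient: 1, expect: duplicate_patient, count: 1}
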