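name: enrollment_shortfall
description: >
  The minimum is five patients. After four enrollments the completion
  attempt broadcasts an incomplete-stage event and enrollment stays open;
  after the fifth, the stage completes and monitoring begins.
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
  - {op: complete_enrollment, expect: ok, events: [EnrollmentStageStatus], stage: ENROLLMENT}
  - {op: enroll_patient, patient: 5, expect: ok, events: [NewPatientEnrolled]}
  - {op: complete_enrollment, expect: ok, events: [EnrollmentStageStatus], stage: MONITORING}
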