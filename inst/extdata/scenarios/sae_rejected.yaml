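name: sae_rejected
description: >
  A serious adverse event is reported during monitoring; the ethics board
  rejects continuation and the trial is halted to protect the patients.
min_patients: 2
cohort: 2
steps:
  - {op: request_ind, expect: ok}
  - {op: set_ind_approval, approved: true, expect: ok, events: [INDStageStatus]}
  - {op: request_ct_initiation, expect: ok}
  - {op: set_ct_initiation_decision, approved: true, expect: ok, events: [CTInitiationStageStatus]}
  - {op: enroll_patient, patient: 1, expect: ok, events: [NewPatientEnrolled]}
  - {op: enroll_patient, patient: 2, expect: ok, events: [NewPatientEnrolled]}
  - {op: complete_enrollment, expect: ok, events: [EnrollmentStageStatus], stage: MONITORING}
  - {op: report_sae, expect: ok, stage: SAE_PENDING}
  - {op: record_visit, patient: 1, expect: order_violation}
  - {op: set_sae_decision, approved: false, expect: ok, events: [SAEStatus], stage: HALTED}
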