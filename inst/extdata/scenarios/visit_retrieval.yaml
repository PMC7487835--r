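name: visit_retrieval
description: >
  During monitoring the physician records two visits for one patient; the
  second visit's documents are retrievable by (patient, visit number), and
  an out-of-range visit number is not found.
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
  - {op: record_visit, patient: 2, expect: ok}
  - {op: record_visit, patient: 2, expect: ok}
  - {op: get_visit, patient: 2, visit: 2, expect: ok}
  - {op: get_visit, patient: 2, visit: 3, expect: not_found}
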