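name: postdrop_violation
description: >
  Monitoring a dropped patient is against the protocol: the attempt stores
  nothing, broadcasts a monitoring-violation alert, and the caller is told
  the patient is inactive.
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
  - {op: drop_patient, patient: 1, expect: ok, events: [PatientDroppedOut], count: 1}
  - {op: record_visit, patient: 1, expect: patient_inactive, events: [MonitoringViolation]}
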