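name: final_approval
description: >
  Monitoring completes after the trial period, the sponsor submits the
  closure report, and the FDA's approval is publicly disclosed.
min_patients: 2
cohort: 2
steps:
  - {op: request_ind, expect: ok}
  - {op: set_ind_approval, approved: true, expect: ok, events: [INDStageStatus]}
  - {op: request_ct_initiation, completion: 100, expect: ok}
  - {op: set_ct_initiation_decision, approved: true, expect: ok, events: [CTInitiationStageStatus]}
  - {op: enroll_patient, patient: 1, expect: ok, events: [NewPatientEnrolled]}
  - {op: enroll_patient, patient: 2, expect: ok, events: [NewPatientEnrolled]}
  - {op: complete_enrollment, expect: ok, events: [EnrollmentStageStatus], stage: MONITORING}
  - {op: record_visit, patient: 1, expect: ok}
  - {op: set_ct_decision, approved: true, expect: order_violation}
  - {op: advance_clock, days: 120}
  - {op: complete_monitoring, expect: ok, stage: ANALYSIS}
  - {op: submit_final_report, expect: ok}
  - {op: set_ct_decision, approved: true, expect: ok, events: [CTDecisionDisclosure], stage: CT_APPROVED}
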