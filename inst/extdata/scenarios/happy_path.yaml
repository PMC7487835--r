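name: happy_path
description: >
  The full workflow end to end: IND approval, initiation approval,
  enrollment of five patients against a minimum of five, monitoring visits,
  an SAE that the board allows the trial to survive, a protocol amendment,
  monitoring completion after the trial period, closure report and final
  approval.
min_patients: 5
cohort: 5
steps:
  - {op: request_ind, expect: ok}
  - {op: set_ind_approval, approved: true, expect: ok, events: [INDStageStatus]}
  - {op: request_ct_initiation, completion: 100, expect: ok}
  - {op: set_ct_initiation_decision, approved: true, expect: ok, events: [CTInitiationStageStatus], stage: ENROLLMENT}
  - {op: enroll_patient, patient: 1, expect: ok, events: [NewPatientEnrolled]}
  - {op: enroll_patient, patient: 2, expect: ok, events: [NewPatientEnrolled]}
  - {op: enroll_patient, patient: 3, expect: ok, events: [NewPatientEnrolled]}
  - {op: enroll_patient, patient: 4, expect: ok, events: [NewPatientEnrolled]}
  - {op: enroll_patient, patient: 5, expect: ok, events: [NewPatientEnrolled]}
  - {op: complete_enrollment, expect: ok, events: [EnrollmentStageStatus], stage: MONITORING}
  - {op: record_visit, patient: 1, expect: ok}
  - {op: record_visit, patient: 2, expect: ok}
  - {op: record_visit, patient: 2, expect: ok}
  - {op: report_sae, expect: ok, stage: SAE_PENDING}
  - {op: set_sae_decision, approved: true, expect: ok, events: [SAEStatus], stage: MONITORING}
  - {op: amend_protocol, expect: ok}
  - {op: record_visit, patient: 3, expect: ok}
  - {op: advance_clock, days: 120}
  - {op: complete_monitoring, expect: ok, stage: ANALYSIS}
  - {op: submit_final_report, expect: ok}
  - {op: set_ct_decision, approved: true, expect: ok, events: [CTDecisionDisclosure], stage: CT_APPROVED}
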