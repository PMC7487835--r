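name: premature_initiation
description: >
  Trial initiation cannot be requested before the IND application stage is
  completed and approved; once approved, the same request succeeds.
min_patients: 5
cohort: 5
steps:
  - {op: request_ind, expect: ok}
  - {op: request_ct_initiation, expect: order_violation}
  - {op: set_ind_approval, approved: true, expect: ok, events: [INDStageStatus]}
  - {op: request_ct_initiation, expect: ok, stage: CT_INIT_REQUESTED}
  - {op: set_ct_initiation_decision, approved: true, expect: ok, events: [CTInitiationStageStatus], stage: ENROLLMENT}
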