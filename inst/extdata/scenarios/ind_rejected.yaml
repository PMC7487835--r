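name: ind_rejected
description: >
  The FDA rejects the new drug application; the decision event is broadcast
  and the trial instance terminates.
min_patients: 5
cohort: 5
steps:
  - {op: request_ind, expect: ok}
  - {op: set_ind_approval, approved: false, expect: ok, events: [INDStageStatus], stage: IND_REJECTED}
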