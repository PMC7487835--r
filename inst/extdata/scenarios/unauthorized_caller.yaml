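name: unauthorized_caller
description: >
  A stakeholder without permission attempts a gated function: the sponsor
  tries to decide its own IND application, which only the FDA may do. The
  call is refused and leaves no trace on the ledger; the FDA then decides.
min_patients: 5
cohort: 5
steps:
  - {op: request_ind, expect: ok}
  - {op: set_ind_approval, by: SPONSOR, approved: true, expect: permission_denied}
  - {op: set_ind_approval, approved: true, expect: ok, events: [INDStageStatus], stage: IND_APPROVED}
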