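# trialchain

A desk-scale, fully self-contained simulation of smart-contract style
clinical-trial data management. It is aimed at clinical-trial informatics and
health-data-provenance researchers who want to study — without deploying any
blockchain infrastructure — how a role-gated workflow contract, a
tamper-evident audit ledger and content-addressed document storage interact
to enforce protocol compliance in a trial.

## What it models

A single-site trial with six single-entity stakeholders — trial sponsor,
FDA, IRB, principal investigator (PI), physician and medical lab scientist —
plus passive patients identified only by pseudonymous addresses. Three
mechanisms work together:

**The workflow state machine.** The trial is sliced into six sequential
stages: new drug application (IND), trial initiation, patient enrollment,
patient monitoring, serious-adverse-event (SAE) review, and analysis &
reporting. Every state-mutating operation carries a guard of the form

> caller's role ∈ permitted(op)  ∧  stage(state) ∈ legal(op)  ∧ payload valid

so no actor can act out of turn and no stage can begin before its
predecessor completes. Enrollment closes only when the number of active
patients *n* satisfies *n* ≥ *m*, the minimum fixed at initiation; a dropped
patient's roster slot is overwritten with the all-zeros address and their
data is retained exactly up to the dropout.

**The ledger.** Each successful operation becomes one signed transaction
(one block). With `Hᵢ = SHA-256(canonical(indexᵢ, tᵢ, callerᵢ, opᵢ,
payloadᵢ, Hᵢ₋₁))` and `H₋₁ = 0⁶⁴`, each transaction commits to its
predecessor, and each is Ed25519-signed by its caller over those same
bytes — any single-field mutation anywhere breaks verification. Because
signatures are deterministic, a fixed seed reproduces a ledger byte for
byte, and the full trial state is an event-sourced fold over the chain.

**The document store.** Trial documents (IND application, protocol, SOP,
consent, CRFs, lab results, SAE and closure reports) live off-ledger in a
content-addressed store: `cid = "sha256:" || SHA-256(bytes)`. Amending a
document yields a new CID; nothing is ever deleted, so the amendment history
is traceable end to end.

Randomized arm assignment covers placebo-controlled, noninferiority,
factorial and two-period crossover designs: a seeded shuffle and round-robin
deal gives a balanced (±1) partition of the active roster, recorded
on-ledger by address only.

## Worked example

```r
library(trialchain)

eng <- trial_engine()
bootstrap_roles(eng, seed = 42)

ind <- put_document(eng$store, charToRaw("IND application, compound TC-101"))
request_ind(eng, trial_phase = "I", trial_number = "CT-2020-001", ind_cid = ind)
set_ind_approval(eng, approved = TRUE)
request_ct_initiation(eng, start_date = 1, completion_date = 90, min_patients = 5,
  protocol_cid = put_document(eng$store, charToRaw("protocol v1")),
  sop_cid      = put_document(eng$store, charToRaw("SOP v1")),
  pi_cv_cid    = put_document(eng$store, charToRaw("PI curriculum vitae")))
set_ct_initiation_decision(eng, approved = TRUE)

cohort <- generate_cohort(5, seed = 42)
for (i in 1:4) enroll_patient(eng, cohort$address[i], cohort$age[i],
  consent_cid = put_document(eng$store, cohort$consent[[i]]),
  history_cid = put_document(eng$store, cohort$history[[i]]))

complete_enrollment(eng)
trial_state(eng)$stage
#> [1] "ENROLLMENT"
```

Four of the required five patients are enrolled, so the completion attempt
broadcasts an incomplete `EnrollmentStageStatus` event and the stage does
not advance. After the fifth enrollment it does:

```r
enroll_patient(eng, cohort$address[5], cohort$age[5],
  consent_cid = put_document(eng$store, cohort$consent[[5]]),
  history_cid = put_document(eng$store, cohort$history[[5]]))
complete_enrollment(eng)
trial_state(eng)$stage
#> [1] "MONITORING"

drop_patient(eng, cohort$address[1])
count_patients(eng)
#> [1] 4
get_patient_roster(eng)[1]
#> [1] "0x0000000000000000000000000000000000000000"

glance(eng)
#> # A tibble: 1 × 8
#>   stage      stage_group     n_tx n_events n_enrolled n_active clock chain_valid
#>   <chr>      <chr>          <int>    <int>      <int>    <int> <dbl> <lgl>
#> 1 MONITORING PATIENT_MONIT…    18       10          5        4    18 TRUE
```

After the dropout the participating count is 4, the dropped patient's
roster slot is zeroed, five patients remain on record, and the 18-transaction
chain still verifies. `ledger_tbl()`, `events_tbl()`, `roster_tbl()` and
`visits_tbl()` give tibble views of the audit trail; `autoplot(ledger(eng))`
draws the transaction timeline; `write_ledger()` / `read_ledger()` /
`replay_state()` round-trip the ledger through line-delimited JSON.

Eleven scripted compliance scenarios (unauthorized callers, premature stage
entry, enrollment shortfall, dropout, post-dropout monitoring violations,
SAE rejection, final approval, …) ship as YAML and run with
`run_scenario("patient_dropout", seed = 1)`; a thin CLI wraps the same
functions (`inst/cli/trialchain scenario list`).

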