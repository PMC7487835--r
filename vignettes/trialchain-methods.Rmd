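---
title: "Simulating protocol-compliant clinical-trial data management on a permissioned ledger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating protocol-compliant clinical-trial data management on a permissioned ledger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialchain)
```

## The problem

Clinical-trial data management has to demonstrate four properties at once:
that every action was taken by an actor who was allowed to take it, that the
trial moved through its stages in the protocol's order, that recorded data
was never silently altered, and that every stakeholder can see what
happened. Smart-contract systems obtain these properties from a combination
of role-gated contract functions, an append-only signed transaction log, and
content-addressed off-chain file storage. trialchain reproduces that
combination as an ordinary R package — a guarded state machine over a
hash-chained ledger — so the mechanism can be studied, tested and extended
at a desk, with no network, consensus layer or gas accounting involved.
Those network properties are assumed, not simulated: there is exactly one
ledger copy, and one transaction per block.

## The model

### Actors and identity

Six single-entity stakeholders interact with the engine: trial sponsor,
FDA, IRB, principal investigator, physician and medical lab scientist.
Each holds an Ed25519 key pair; the identifier (the "address") is
`"0x"` plus the lowercase hex of the last 20 bytes of the SHA-256 digest of
the 32-byte public key, mimicking the shape of an Ethereum address without
any Ethereum dependency. Patients are deliberately passive: they hold
addresses, not keys, and never call operations — the physician custodies
their identifiers and files everything on their behalf. The all-zeros
address is reserved; it can never be registered and marks the roster slot
of a patient who has dropped out.

Ed25519 was chosen over ECDSA because its signatures are deterministic
given key and message: a ledger built under a fixed seed is reproducible
byte for byte, which the test suite and scenario runner rely on. Seeded key
generation draws 32 bytes from R's RNG (leaving the caller's RNG state
untouched) and wraps them in a PKCS#8 envelope.

### The permission matrix

Every state-mutating operation names the set of roles allowed to invoke it
(sponsor files applications and reports, FDA decides them, the physician
enrolls, monitors and drops patients, the lab scientist co-records visits,
the PI reports serious adverse events, the IRB decides them). Read-only
queries — patient count, roster, per-patient record, per-visit record — are
open to every registered participant; unregistered addresses get nothing.
`authorize()` is total: any (caller, operation) pair outside the matrix is
simply `FALSE`, never an error.

### The six-stage workflow

The trial advances CREATED → IND application → trial initiation →
enrollment → monitoring (with an SAE detour) → analysis & reporting. The
engine internally tracks a finer state (each regulatory decision splits its
stage into requested/approved/rejected), and `stage_group()` projects the
fine states onto the six workflow stages that `trial_stages()` exposes.
Decisions that can end the trial are terminal for the trial instance:
rejection of the IND application or of initiation, an SAE the board refuses
to let the trial survive (HALTED), and the final disclosure. There is no
retry path; a new attempt is a new engine. We read the board's SAE
"rejection" as *halt the trial* — the wording could also mean "report
inadequate, re-investigate", but halting is the reading that protects
patients and it keeps the state graph acyclic apart from the
monitoring ↔ SAE loop.

Three guards deserve a note:

* **Enrollment threshold.** `complete_enrollment()` succeeds iff the count
  of *active* patients reaches the minimum fixed at initiation. Patients
  dropped during enrollment do not count. The attempt is legal either way;
  only the broadcast event differs (`complete = TRUE/FALSE`).
* **Monitoring end.** The source workflow says only that monitoring
  continues "until the trial period ends", with no mechanism. We close it
  with an explicit sponsor call guarded by the logical clock against the
  completion date set at initiation (`too_early` before that). Dates are
  day counts on the logical clock, not calendar strings, for determinism.
* **Protocol amendments.** The sponsor may attach a re-uploaded protocol
  during monitoring as an annotation transaction; the stage does not reset
  and no fresh regulatory approval is required. The old and new document
  versions both remain retrievable, so the amendment trail is complete.

### The ledger

Every successful mutating call appends one transaction holding index,
logical timestamp, caller address, operation, payload, the predecessor's
hash and its own hash, plus the caller's signature. Hashing and signing
operate on a canonical serialization: JSON with keys sorted bytewise,
UTF-8, no insignificant whitespace, scalars unboxed, integers rendered
without exponent. This rule is implemented in the package rather than
delegated, because no general-purpose JSON writer guarantees the bit-exact
ordering the hash chain needs.

Role registration is itself on-chain: six self-signed `register_role`
transactions carry each public key, so `verify_chain()` can check every
signature — and re-derive every address from its key — using nothing but
the chain. Verification walks the chain once and reports the first failing
index and reason.

Rejected calls are not recorded: a permission or sequencing violation
raises a classed R condition and leaves the chain untouched, mirroring how
a reverted contract call alters no state. Whether failed attempts should
themselves be auditable is a real design question; we keep them off-chain
and leave surfacing them to the caller. The single exception is monitoring
a dropped patient: the source workflow treats that as a protocol breach
worth broadcasting, so the attempt appends a `monitoring_violation`
transaction (storing no patient data), emits the `MonitoringViolation`
event, and then raises `patient_inactive` to the caller. This keeps two
invariants compatible: every event is caused by exactly one transaction,
and failures emit nothing — except this one sanctioned alert.

State is event-sourced. `replay_state()` folds the same reducer the live
engine uses over the verified chain, so replay equivalence — the replayed
state is byte-identical, under the canonical serialization, to the live
engine's — holds by construction and is asserted across every shipped
scenario in the tests.

### The document store

Documents are byte-sequences addressed by content:
`cid = "sha256:" || hex(SHA-256(bytes))`. Storage is idempotent, there is
no delete, and retrieval re-hashes the bytes so corruption surfaces as an
`integrity_error` instead of silently wrong content. A flat-directory
backend persists across sessions; the in-memory backend serves tests and
scenario runs. We use a plain SHA-256 prefix rather than a multihash/base58
encoding — the model only needs a unique cryptographic identifier, and this
keeps the format inspectable.

### Trial-design variants

Arm assignment deals the shuffled active roster round-robin into the
design's groups: two arms for placebo-controlled and noninferiority
(the latter's control being an existing effective therapy rather than a
placebo), one stream per intervention for factorial, and two sequence
groups for crossover, where group 1 receives the treatments in listed
order and group 2 in reverse, period by period. Round-robin after a seeded
shuffle guarantees balance within one patient and reproducibility; no
allocation algorithm was prescribed, so the simplest one with those two
properties was chosen. The realized assignment is stored in the
transaction payload — replay must not depend on RNG state — and references
patients only by address, so no personal field ever reaches the ledger's
assignment record. Period advancement in crossover is an explicit
physician call, not clock-driven, which keeps the visit sequence aligned
with the recorded periods. Assignments are stored openly on-ledger;
blinding workflows are out of scope.

## Synthetic data and scenarios

`generate_cohort(n, seed)` produces distinct pseudonymous patients with
adult ages (18–79, uniform) and seeded pseudo-random consent and
medical-history documents headed by a readable kind/tag line. The default
study conditions mirror the workflow's own worked cases: a minimum of five
patients with enrollment attempts at four and five, and a five-patient
cohort losing one participant for the dropout accounting. The generator
emulates only what the contract sees — addresses, ages, opaque document
bytes. It does not emulate inclusion/exclusion screening, visit outcomes,
treatment response or consent withdrawal dynamics, so passing tests say
nothing about clinical realism; they validate the compliance machinery.

Scenarios are YAML data, not code: each step names a role, an operation,
arguments, and the expected outcome (success or a specific failure kind),
plus optional event/stage/count assertions. Eleven shipped scripts cover
the workflow's test cases end to end. The runner re-derives everything from
the seed, so a scenario run is deterministic down to the ledger bytes.

## Numerical and engineering choices

* Problem sizes are small by design — cohorts of ≤ 8, ledgers of ~30
  transactions, 100 rosters per design for the allocation properties —
  because every property being checked is exact, not asymptotic.
* The tamper-detection check is exhaustive rather than sampled: every
  single-field mutation of every transaction in the fixture chain must
  break verification.
* Timestamps are a monotone logical counter ticking once per transaction,
  plus explicit `advance_clock()` jumps; equal timestamps are allowed
  (non-decreasing), which models several actions on one day.
* `verify_payload()` and `verify_chain()` return `FALSE` (with a reason)
  rather than raising: verification is a query, not an assertion.
* Degenerate inputs are first-class: empty documents hash and store
  normally; an empty chain replays to the initial CREATED state; a
  one-patient roster is a legal (trivially balanced) randomization input;
  an empty roster is a validation error.

## Known limitations

Single site, single trial phase, one address per role with no rotation or
multi-signature, no key encryption at rest, no networking or consensus, no
gas/cost model, and no statistical analysis of outcomes — the closure
report is an opaque document, as analysis is delegated to downstream
applications in the modelled system. The IRB has no decision function at
the IND stage (it is notified only), matching the modelled workflow.
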