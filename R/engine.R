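#' Create a trial engine
#'
#' The engine is the simulated smart contract: it holds the role registry,
#' the document store, the logical clock, the hash-chained ledger and the
#' current trial state, and exposes one function per contract operation.
#' Every successful state-mutating call appends exactly one signed
#' transaction; rejected calls (wrong role, wrong stage, bad payload) raise
#' a classed condition and leave the chain untouched — with the single
#' exception of a visit attempt on a dropped patient, which records a
#' `monitoring_violation` transaction so the protocol breach itself is
#' broadcast and auditable.
#'
#' Timestamps come from an injectable logical clock: a monotone counter that
#' ticks once per transaction and can be moved forward explicitly with
#' [advance_clock()] (dates are day counts, not calendar strings, so runs
#' are deterministic).
#'
#' @param store a [docstore()]; defaults to a fresh in-memory store
#' @param clock starting value of the logical clock (day 0 by default)
#' @return a `trial_engine`
#' @examples
#' eng <- trial_engine()
#' bootstrap_roles(eng, seed = 1)
#' cid <- put_document(eng$store, charToRaw("IND application"))
#' request_ind(eng, "I", "CT-001", cid)
#' trial_state(eng)$stage
#' @export
trial_engine <- function(store = docstore(), clock = 0) {
  eng <- new.env(parent = emptyenv())
  eng$store <- store
  eng$registry <- role_registry()
  eng$keys <- list()          # role -> keypair (custodied for the simulation)
  eng$chain <- new_chain()
  eng$events <- list()
  eng$clock <- as.numeric(clock)
  eng$state <- new_trial_state()
  class(eng) <- "trial_engine"
  eng
}

#' @export
print.trial_engine <- function(x, ...) {
  cat("<trial_engine>", x$state$stage, "|",
      length(x$chain), "tx |", length(x$events), "events | clock",
      x$clock, "\n")
  invisible(x)
}

#' Move the logical clock forward
#'
#' @param engine a [trial_engine()]
#' @param days positive number of days to advance
#' @return the new clock value, invisibly
#' @export
advance_clock <- function(engine, days) {
  stopifnot(is.numeric(days), days >= 0)
  engine$clock <- engine$clock + days
  invisible(engine$clock)
}

#' Register the six stakeholder roles
#'
#' Generates (or accepts) one identity per role and records each binding as a
#' self-signed `register_role` transaction, so the registry is part of the
#' auditable ledger. With `seed`, all six identities are deterministic.
#'
#' @param engine a [trial_engine()]
#' @param seed optional integer; derives one sub-seed per role
#' @param seeds optional named integer vector/list, role -> seed (overrides
#'   `seed`); roles absent from it get unseeded identities
#' @return the engine, invisibly
#' @export
bootstrap_roles <- function(engine, seed = NULL, seeds = NULL) {
  if (is.null(seeds) && !is.null(seed)) {
    sub <- local_seeded(seed, sample.int(.Machine$integer.max, length(ROLES)))
    seeds <- stats::setNames(as.list(sub), ROLES)
  }
  for (role in ROLES) {
    id <- generate_identity(seed = if (!is.null(seeds)) seeds[[role]] else NULL)
    register_identity(engine, role, id)
  }
  invisible(engine)
}

#' Register a single role with an explicit identity
#'
#' @param engine a [trial_engine()]
#' @param role one of [trial_roles()]
#' @param identity a list as returned by [generate_identity()]
#' @return the appended transaction, invisibly
#' @export
register_identity <- function(engine, role, identity) {
  kp <- identity$keypair
  addr <- identity$address
  tx <- append_transaction(
    engine, addr, "register_role",
    list(role = role, address = addr,
         pubkey = paste(format(kp$public), collapse = "")),
    kp)
  # the on-chain guard vetted role/address/key; mirror into the live registry
  register_role(engine$registry, addr, role, kp$public)
  engine$keys[[role]] <- kp
  invisible(tx)
}

#' Append a signed transaction (low-level)
#'
#' Checks, in order: the key pair actually owns `caller`; `caller`'s role is
#' permitted to invoke `operation`; the operation is legal in the current
#' stage with this payload. Only then is the transaction hashed, signed,
#' chained and applied.
#'
#' @param engine a [trial_engine()]
#' @param caller the caller's address
#' @param operation operation name
#' @param payload named list of scalar fields / CIDs
#' @param keypair the caller's `trialchain_keypair`
#' @return the appended `trialchain_tx`, invisibly
#' @export
append_transaction <- function(engine, caller, operation, payload, keypair) {
  if (!inherits(keypair, "trialchain_keypair") ||
      !identical(derive_address(keypair$public), caller))
    tc_abort("signature_invalid", "key pair does not own the caller address")
  if (!identical(operation, "register_role") &&
      !authorize(engine$registry, caller, operation))
    tc_abort("permission_denied",
             sprintf("%s may not be called by %s (role %s)",
                     operation, caller,
                     role_of(engine$registry, caller)))
  check_operation(engine$state, operation, payload,
                  store = engine$store, timestamp = engine$clock + 1)
  engine$clock <- engine$clock + 1
  tx <- build_transaction(
    index = length(engine$chain), timestamp = engine$clock,
    caller = caller, operation = operation, payload = payload,
    prev_hash = if (length(engine$chain) == 0) GENESIS_HASH
                else engine$chain[[length(engine$chain)]]$tx_hash,
    keypair = keypair)
  res <- apply_operation(engine$state, operation, payload, caller, tx$index)
  engine$state <- res$state
  engine$chain[[length(engine$chain) + 1]] <- tx
  for (ev in res$events) {
    engine$events[[length(engine$events) + 1]] <-
      list(name = ev$name, emitted_at_tx = tx$index, detail = ev$detail)
  }
  invisible(tx)
}

# Submit an operation as a role (the simulation custodies role keys).
# `by` lets a test or scenario deliberately call with the wrong stakeholder.
submit_as <- function(engine, role, operation, payload) {
  if (!role %in% names(engine$keys))
    tc_abort("validation_error", paste0("role not bootstrapped: ", role))
  addr <- engine$registry$role_to_addr[[role]]
  append_transaction(engine, addr, operation, payload, engine$keys[[role]])
}

# record_visit / record_arm_visit share the dropped-patient alert path:
# the violation itself is put on-chain and broadcast, then the caller is told.
submit_visit <- function(engine, role, operation, payload) {
  tryCatch(
    submit_as(engine, role, operation, payload),
    trialchain_error_patient_inactive = function(e) {
      submit_as(engine, role, "monitoring_violation",
                list(patient = e$patient, attempted = operation))
      stop(e)
    })
}

# ---- contract operations ----------------------------------------------------

#' File a new drug application request
#'
#' @param engine a [trial_engine()]
#' @param trial_phase trial phase label (the workflow models a single phase,
#'   e.g. `"I"`)
#' @param trial_number trial identifier string
#' @param ind_cid CID of the stored IND application document
#' @param by calling role (defaults to the permitted one; passing another
#'   role exercises the permission check)
#' @return the appended transaction, invisibly
#' @export
request_ind <- function(engine, trial_phase, trial_number, ind_cid,
                        by = "SPONSOR") {
  submit_as(engine, by, "request_ind",
            list(trial_phase = trial_phase, trial_number = trial_number,
                 ind_cid = ind_cid))
}

#' Approve or reject the new drug application
#' @inheritParams request_ind
#' @param approved logical decision
#' @return the appended transaction, invisibly
#' @export
set_ind_approval <- function(engine, approved, by = "FDA") {
  submit_as(engine, by, "set_ind_approval", list(approved = isTRUE(approved)))
}

#' Request clinical trial initiation
#'
#' @inheritParams request_ind
#' @param start_date,completion_date trial period bounds as day counts on the
#'   logical clock; `completion_date` must exceed `start_date`
#' @param min_patients minimum number of patients that must be enrolled
#'   before monitoring can begin
#' @param protocol_cid,sop_cid,pi_cv_cid CIDs of the stored trial protocol,
#'   SOP and principal investigator's CV
#' @return the appended transaction, invisibly
#' @export
request_ct_initiation <- function(engine, start_date, completion_date,
                                  min_patients, protocol_cid, sop_cid,
                                  pi_cv_cid, by = "SPONSOR") {
  submit_as(engine, by, "request_ct_initiation",
            list(start_date = as.numeric(start_date),
                 completion_date = as.numeric(completion_date),
                 min_patients = as.numeric(min_patients),
                 protocol_cid = protocol_cid, sop_cid = sop_cid,
                 pi_cv_cid = pi_cv_cid))
}

#' Approve or reject trial initiation
#'
#' Approval opens patient enrollment; rejection ends the trial instance.
#' @inheritParams set_ind_approval
#' @return the appended transaction, invisibly
#' @export
set_ct_initiation_decision <- function(engine, approved, by = "FDA") {
  submit_as(engine, by, "set_ct_initiation_decision",
            list(approved = isTRUE(approved)))
}

#' Enroll a patient
#'
#' Patients are passive: they hold addresses but never call operations, and
#' informed consent is mandatory — enrollment without a stored consent
#' document is refused.
#'
#' @inheritParams request_ind
#' @param patient the patient's address (their pseudonymous identifier)
#' @param age patient age in years
#' @param consent_cid,history_cid CIDs of the stored informed consent and
#'   medical history documents
#' @return the appended transaction, invisibly
#' @export
enroll_patient <- function(engine, patient, age, consent_cid, history_cid,
                           by = "PHYSICIAN") {
  submit_as(engine, by, "enroll_patient",
            list(patient = patient, age = as.numeric(age),
                 consent_cid = consent_cid, history_cid = history_cid))
}

#' Attempt to complete the enrollment stage
#'
#' Succeeds — moving the trial to monitoring — iff the number of active
#' patients meets or exceeds `min_patients`; otherwise the stage is
#' unchanged. Either way an `EnrollmentStageStatus` event is broadcast.
#'
#' @inheritParams request_ind
#' @return the appended transaction, invisibly
#' @export
complete_enrollment <- function(engine, by = "PHYSICIAN") {
  submit_as(engine, by, "complete_enrollment", list())
}

#' Record a monitoring visit
#'
#' A visit attempt on a dropped patient stores nothing but broadcasts a
#' `MonitoringViolation` event (recorded on-chain) and raises
#' `patient_inactive`.
#'
#' @inheritParams enroll_patient
#' @param crf_cid,lab_cid,followup_cid CIDs of the visit's case report form,
#'   lab results and follow-up documents
#' @return the appended transaction, invisibly
#' @export
record_visit <- function(engine, patient, crf_cid, lab_cid, followup_cid,
                         by = "PHYSICIAN") {
  submit_visit(engine, by, "record_visit",
               list(patient = patient, crf_cid = crf_cid, lab_cid = lab_cid,
                    followup_cid = followup_cid))
}

#' Drop a patient from the trial
#'
#' The roster slot is replaced by the all-zeros address, the patient count
#' decrements, and all data recorded up to the dropout is retained.
#'
#' @inheritParams enroll_patient
#' @return the appended transaction, invisibly
#' @export
drop_patient <- function(engine, patient, by = "PHYSICIAN") {
  submit_as(engine, by, "drop_patient", list(patient = patient))
}

#' Close the monitoring stage
#'
#' Allowed once the logical clock has reached the trial's completion date;
#' moves the trial to analysis and reporting.
#'
#' @inheritParams request_ind
#' @return the appended transaction, invisibly
#' @export
complete_monitoring <- function(engine, by = "SPONSOR") {
  submit_as(engine, by, "complete_monitoring", list())
}

#' Report a serious adverse event
#'
#' Suspends monitoring until the ethics board decides.
#' @inheritParams request_ind
#' @param sae_cid CID of the stored SAE report
#' @return the appended transaction, invisibly
#' @export
report_sae <- function(engine, sae_cid, by = "PI") {
  submit_as(engine, by, "report_sae", list(sae_cid = sae_cid))
}

#' Ethics-board decision on a reported SAE
#'
#' Approval lets monitoring resume; rejection halts the trial to protect the
#' participating patients.
#'
#' @inheritParams set_ind_approval
#' @return the appended transaction, invisibly
#' @export
set_sae_decision <- function(engine, approved, by = "IRB") {
  submit_as(engine, by, "set_sae_decision", list(approved = isTRUE(approved)))
}

#' Submit the trial closure report
#' @inheritParams request_ind
#' @param closure_cid CID of the stored closure report
#' @return the appended transaction, invisibly
#' @export
submit_final_report <- function(engine, closure_cid, by = "SPONSOR") {
  submit_as(engine, by, "submit_final_report",
            list(closure_cid = closure_cid))
}

#' Final regulatory decision on the trial
#'
#' Requires a submitted closure report; broadcasts `CTDecisionDisclosure`.
#' @inheritParams set_ind_approval
#' @return the appended transaction, invisibly
#' @export
set_ct_decision <- function(engine, approved, by = "FDA") {
  submit_as(engine, by, "set_ct_decision", list(approved = isTRUE(approved)))
}

#' Amend the trial protocol during monitoring
#'
#' The amended document gets a new CID; the full amendment history stays on
#' the ledger and in the store (nothing is ever deleted).
#'
#' @inheritParams request_ind
#' @param protocol_cid CID of the re-uploaded protocol document
#' @return the appended transaction, invisibly
#' @export
amend_protocol <- function(engine, protocol_cid, by = "SPONSOR") {
  submit_as(engine, by, "amend_protocol", list(protocol_cid = protocol_cid))
}

#' Randomize the active roster into the design's arms
#'
#' Computes a seeded, balanced assignment (see [assign_arms()]) of the active
#' patients and records it on-chain, so replay reproduces the allocation
#' without re-running any RNG.
#'
#' @inheritParams request_ind
#' @param design a [design_spec()]
#' @return the appended transaction, invisibly
#' @export
randomize_arms <- function(engine, design, by = "PHYSICIAN") {
  active <- names(engine$state$records)[
    vapply(engine$state$records, function(r) isTRUE(r$active), logical(1))]
  assignment <- assign_arms(design, active)
  submit_as(engine, by, "assign_arms",
            list(design = unclass(design), assignment = as.list(assignment)))
}

#' Record a monitoring visit under a named arm
#'
#' The visit must be filed under the arm the patient was randomized to (for
#' crossover designs, under the treatment their sequence group receives in
#' the current period); anything else is an `arm_mismatch`.
#'
#' @inheritParams record_visit
#' @param arm the arm (or crossover treatment) label the visit is filed under
#' @return the appended transaction, invisibly
#' @export
record_arm_visit <- function(engine, patient, arm, crf_cid, lab_cid,
                             followup_cid, by = "PHYSICIAN") {
  submit_visit(engine, by, "record_arm_visit",
               list(patient = patient, arm = arm, crf_cid = crf_cid,
                    lab_cid = lab_cid, followup_cid = followup_cid))
}

#' Advance a crossover trial to its next treatment period
#' @inheritParams request_ind
#' @return the appended transaction, invisibly
#' @export
advance_period <- function(engine, by = "PHYSICIAN") {
  submit_as(engine, by, "advance_period", list())
}

# ---- open queries (read-only, available to every network participant) ------

#' Number of patients currently participating
#'
#' Dropped patients are excluded.
#' @param engine a [trial_engine()]
#' @return integer count of active patients
#' @export
count_patients <- function(engine) {
  active_count(engine$state)
}

#' The patient roster in enrollment order
#'
#' Dropped patients keep their slot, shown as the all-zeros address.
#' @param engine a [trial_engine()]
#' @return character vector of addresses
#' @export
get_patient_roster <- function(engine) {
  unlist(engine$state$patients, use.names = FALSE) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enrollment record of one patient
#'
#' Data recorded before a dropout is retained; `active` and `dropped_at_tx`
#' say whether and when the patient left.
#'
#' @param engine a [trial_engine()]
#' @param patient a patient address
#' @return the patient record (list with `address`, `age`, `consent_cid`,
#'   `history_cid`, `active`, `dropped_at_tx`, `visits`)
#' @export
get_patient_record <- function(engine, patient) {
  rec <- engine$state$records[[patient]]
  if (is.null(rec)) tc_abort("not_found", paste0("unknown patient: ", patient))
  rec
}

#' One patient's visit by visit number
#'
#' @param engine a [trial_engine()]
#' @param patient a patient address
#' @param visit_number 1-based visit index
#' @return the visit record (list with CIDs, recorder, arm/period tags)
#' @export
get_visit <- function(engine, patient, visit_number) {
  rec <- get_patient_record(engine, patient)
  if (!is.numeric(visit_number) || length(visit_number) != 1 ||
      is.na(visit_number) || visit_number < 1 ||
      visit_number > length(rec$visits) || visit_number != trunc(visit_number))
    tc_abort("not_found",
             sprintf("no visit %s recorded for %s", visit_number, patient))
  rec$visits[[visit_number]]
}

#' Current trial state
#' @param engine a [trial_engine()]
#' @return a `trial_state` (a value copy; mutating it does not touch the
#'   engine)
#' @export
trial_state <- function(engine) engine$state

#' The engine's ledger
#' @param engine a [trial_engine()]
#' @return a `trialchain_chain`
#' @export
ledger <- function(engine) engine$chain
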