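#' Trial workflow stages
#'
#' The workflow is sliced into six sequential stages; one stage cannot begin
#' until its predecessor completed successfully. The engine tracks a finer
#' state (approval decisions split each regulatory stage into
#' requested/approved/rejected, and a serious adverse event suspends
#' monitoring), which [stage_group()] maps back onto the six stages.
#'
#' @return character vector of the six stage names, in workflow order
#' @export
trial_stages <- function() {
  c("NEW_DRUG_APPLICATION", "CT_INITIATION", "PATIENT_ENROLLMENT",
    "PATIENT_MONITORING", "SAE_OCCURRENCE", "ANALYSIS_AND_REPORTING")
}

# fine-grained engine states; *_REJECTED / HALTED / CT_* decisions are terminal
STATES <- c("CREATED",
            "IND_REQUESTED", "IND_APPROVED", "IND_REJECTED",
            "CT_INIT_REQUESTED", "CT_INIT_REJECTED",
            "ENROLLMENT", "MONITORING", "SAE_PENDING", "HALTED",
            "ANALYSIS", "CT_APPROVED", "CT_REJECTED")

TERMINAL_STATES <- c("IND_REJECTED", "CT_INIT_REJECTED", "HALTED",
                     "CT_APPROVED", "CT_REJECTED")

#' Map a fine-grained engine state to its workflow stage
#'
#' @param state a fine-grained state name such as `"IND_REQUESTED"` or
#'   `"MONITORING"`
#' @return one of [trial_stages()], or `NA` for the pre-workflow `"CREATED"`
#' @export
stage_group <- function(state) {
  map <- c(CREATED = NA_character_,
           IND_REQUESTED = "NEW_DRUG_APPLICATION",
           IND_APPROVED = "NEW_DRUG_APPLICATION",
           IND_REJECTED = "NEW_DRUG_APPLICATION",
           CT_INIT_REQUESTED = "CT_INITIATION",
           CT_INIT_REJECTED = "CT_INITIATION",
           ENROLLMENT = "PATIENT_ENROLLMENT",
           MONITORING = "PATIENT_MONITORING",
           SAE_PENDING = "SAE_OCCURRENCE",
           HALTED = "SAE_OCCURRENCE",
           ANALYSIS = "ANALYSIS_AND_REPORTING",
           CT_APPROVED = "ANALYSIS_AND_REPORTING",
           CT_REJECTED = "ANALYSIS_AND_REPORTING")
  unname(map[state])
}

new_trial_state <- function() {
  structure(list(
    stage = "CREATED",
    trial_phase = NA_character_,
    trial_number = NA_character_,
    ind_cid = NA_character_,
    start_date = NA_real_,
    completion_date = NA_real_,
    min_patients = NA_real_,
    protocol_cid = NA_character_,
    sop_cid = NA_character_,
    pi_cv_cid = NA_character_,
    amendments = list(),
    sae_cid = NA_character_,
    closure_cid = NA_character_,
    patients = list(),   # roster in enrollment order; zero-address = dropped
    records = list(),    # named by patient address
    roles = list(),      # role -> address, rebuilt on replay
    design = NULL,
    arms = list(),       # patient address -> arm (or sequence group)
    period = NA_real_    # current crossover period
  ), class = "trial_state")
}

#' @export
print.trial_state <- function(x, ...) {
  cat("<trial_state>", x$stage,
      sprintf("(%d enrolled, %d active)\n",
              length(x$records), active_count(x)))
  invisible(x)
}

active_count <- function(state) {
  sum(vapply(state$records, function(r) isTRUE(r$active), logical(1)))
}

#' Serialize a trial state to canonical bytes
#'
#' Two states are identical iff their serializations are byte-identical; the
#' replay-equivalence guarantee (rebuilding state from the ledger reproduces
#' the live engine's state exactly) is stated in these terms.
#'
#' @param state a `trial_state`
#' @return length-1 character string (canonical JSON)
#' @export
serialize_state <- function(state) {
  canonical_json(unclass(state))
}

# ---- guards -----------------------------------------------------------------

# Validate an operation against the current state (stage sequencing, payload
# sanity, document existence). Raises a classed condition on violation.
# `store` may be NULL (replay path: documents were checked at append time).
check_operation <- function(state, operation, payload, store = NULL,
                            timestamp = NULL) {
  need_stage <- function(...) {
    ok <- c(...)
    if (!state$stage %in% ok)
      tc_abort("order_violation",
               sprintf("%s requires stage %s but trial is in %s",
                       operation, paste(ok, collapse = "/"), state$stage))
  }
  need_cid <- function(cid, what, kind = "unknown_cid") {
    if (!is_cid(cid))
      tc_abort(kind, sprintf("%s: malformed or missing CID for %s",
                             operation, what))
    if (!is.null(store) && !has_document(store, cid))
      tc_abort(kind, sprintf("%s: no stored document for %s (%s)",
                             operation, what, cid))
  }
  switch(operation,
    register_role = {
      need_stage("CREATED")
      if (!payload$role %in% ROLES)
        tc_abort("validation_error", paste0("unknown role: ", payload$role))
      if (payload$role %in% names(state$roles))
        tc_abort("duplicate_role", paste0("role already bound: ", payload$role))
      if (!is_address(payload$address) ||
          identical(payload$address, zero_address()))
        tc_abort("invalid_address", "not a registrable address")
      if (payload$address %in% unlist(state$roles))
        tc_abort("invalid_address", "address already bound to a role")
    },
    request_ind = {
      need_stage("CREATED")
      need_cid(payload$ind_cid, "IND application")
    },
    set_ind_approval = need_stage("IND_REQUESTED"),
    request_ct_initiation = {
      need_stage("IND_APPROVED")
      mp <- payload$min_patients
      if (!is.numeric(mp) || length(mp) != 1 || is.na(mp) || mp < 1 ||
          mp != trunc(mp))
        tc_abort("validation_error", "min_patients must be a positive integer")
      if (!is.numeric(payload$start_date) || !is.numeric(payload$completion_date) ||
          !(payload$completion_date > payload$start_date))
        tc_abort("validation_error", "completion_date must be after start_date")
      need_cid(payload$protocol_cid, "trial protocol")
      need_cid(payload$sop_cid, "SOP")
      need_cid(payload$pi_cv_cid, "PI CV")
    },
    set_ct_initiation_decision = need_stage("CT_INIT_REQUESTED"),
    enroll_patient = {
      need_stage("ENROLLMENT")
      p <- payload$patient
      if (!is_address(p) || identical(p, zero_address()))
        tc_abort("invalid_address", "patient address malformed or reserved")
      if (p %in% names(state$records))
        tc_abort("duplicate_patient", paste0("already enrolled: ", p))
      if (!is.numeric(payload$age) || length(payload$age) != 1 ||
          is.na(payload$age) || payload$age <= 0)
        tc_abort("validation_error", "age must be a positive number")
      need_cid(payload$consent_cid, "informed consent", kind = "missing_consent")
      need_cid(payload$history_cid, "medical history")
    },
    complete_enrollment = need_stage("ENROLLMENT"),
    record_visit = {
      need_stage("MONITORING")
      check_patient_active(state, payload$patient)
      need_cid(payload$crf_cid, "CRF")
      need_cid(payload$lab_cid, "lab results")
      need_cid(payload$followup_cid, "follow-up")
    },
    monitoring_violation = need_stage("MONITORING"),
    drop_patient = {
      need_stage("ENROLLMENT", "MONITORING")
      p <- payload$patient
      if (!p %in% names(state$records))
        tc_abort("not_found", paste0("unknown patient: ", p))
      if (!isTRUE(state$records[[p]]$active))
        tc_abort("already_dropped", paste0("patient already dropped: ", p))
    },
    report_sae = {
      need_stage("MONITORING")
      need_cid(payload$sae_cid, "SAE report")
    },
    set_sae_decision = need_stage("SAE_PENDING"),
    complete_monitoring = {
      need_stage("MONITORING")
      if (!is.null(timestamp) && is.finite(state$completion_date) &&
          timestamp < state$completion_date)
        tc_abort("too_early",
                 sprintf("trial period ends at day %s (clock at %s)",
                         state$completion_date, timestamp))
    },
    submit_final_report = {
      need_stage("ANALYSIS")
      need_cid(payload$closure_cid, "closure report")
    },
    set_ct_decision = {
      need_stage("ANALYSIS")
      if (!is_cid(state$closure_cid))
        tc_abort("order_violation",
                 "final decision requires a submitted closure report")
    },
    amend_protocol = {
      need_stage("MONITORING")
      need_cid(payload$protocol_cid, "amended protocol")
    },
    assign_arms = {
      need_stage("MONITORING")
      if (length(state$arms) > 0)
        tc_abort("validation_error", "arms already assigned")
      validate_design(payload$design)
      check_assignment(payload$design, payload$assignment, state)
    },
    record_arm_visit = {
      need_stage("MONITORING")
      if (length(state$arms) == 0)
        tc_abort("validation_error", "no arm assignment recorded")
      check_patient_active(state, payload$patient)
      check_arm_membership(state, payload$patient, payload$arm)
      need_cid(payload$crf_cid, "CRF")
      need_cid(payload$lab_cid, "lab results")
      need_cid(payload$followup_cid, "follow-up")
    },
    advance_period = {
      need_stage("MONITORING")
      if (is.null(state$design) || state$design$design != "CROSSOVER")
        tc_abort("design_mismatch", "periods only apply to crossover designs")
      if (state$period >= state$design$n_periods)
        tc_abort("validation_error", "already in the final period")
    },
    tc_abort("validation_error", paste0("unknown operation: ", operation))
  )
  invisible(TRUE)
}

check_patient_active <- function(state, p) {
  if (!is.character(p) || !p %in% names(state$records))
    tc_abort("not_found", paste0("unknown patient: ", p))
  if (!isTRUE(state$records[[p]]$active))
    tc_abort("patient_inactive",
             paste0("patient dropped out, monitoring not permissible: ", p),
             patient = p)
}

# ---- reducer ----------------------------------------------------------------

# Apply a validated operation to the state. Pure: returns the new state plus
# the events the operation emits. Used identically by the live engine and by
# ledger replay, which is what makes replay equivalence hold by construction.
apply_operation <- function(state, operation, payload, caller, tx_index) {
  events <- list()
  emit <- function(name, ...) {
    events[[length(events) + 1]] <<- list(name = name, detail = list(...))
  }
  switch(operation,
    register_role = {
      state$roles[[payload$role]] <- payload$address
    },
    request_ind = {
      state$stage <- "IND_REQUESTED"
      state$trial_phase <- payload$trial_phase
      state$trial_number <- payload$trial_number
      state$ind_cid <- payload$ind_cid
    },
    set_ind_approval = {
      state$stage <- if (isTRUE(payload$approved)) "IND_APPROVED" else "IND_REJECTED"
      emit("INDStageStatus", approved = isTRUE(payload$approved))
    },
    request_ct_initiation = {
      state$stage <- "CT_INIT_REQUESTED"
      state$start_date <- as.numeric(payload$start_date)
      state$completion_date <- as.numeric(payload$completion_date)
      state$min_patients <- as.numeric(payload$min_patients)
      state$protocol_cid <- payload$protocol_cid
      state$sop_cid <- payload$sop_cid
      state$pi_cv_cid <- payload$pi_cv_cid
    },
    set_ct_initiation_decision = {
      ok <- isTRUE(payload$approved)
      state$stage <- if (ok) "ENROLLMENT" else "CT_INIT_REJECTED"
      emit("CTInitiationStageStatus", approved = ok)
    },
    enroll_patient = {
      p <- payload$patient
      state$patients[[length(state$patients) + 1]] <- p
      state$records[[p]] <- list(
        address = p, age = as.numeric(payload$age),
        consent_cid = payload$consent_cid,
        history_cid = payload$history_cid,
        active = TRUE, dropped_at_tx = NA_real_, visits = list())
      emit("NewPatientEnrolled", patient = p)
    },
    complete_enrollment = {
      done <- active_count(state) >= state$min_patients
      if (done) state$stage <- "MONITORING"
      emit("EnrollmentStageStatus", complete = done,
           enrolled = active_count(state), required = state$min_patients)
    },
    record_visit = {
      state <- add_visit(state, payload, caller)
    },
    monitoring_violation = {
      emit("MonitoringViolation", patient = payload$patient,
           attempted = payload$attempted)
    },
    drop_patient = {
      p <- payload$patient
      state$records[[p]]$active <- FALSE
      state$records[[p]]$dropped_at_tx <- as.numeric(tx_index)
      slot <- which(vapply(state$patients, identical, logical(1), p))
      state$patients[[slot[1]]] <- zero_address()
      emit("PatientDroppedOut", patient = p)
    },
    report_sae = {
      state$stage <- "SAE_PENDING"
      state$sae_cid <- payload$sae_cid
    },
    set_sae_decision = {
      ok <- isTRUE(payload$approved)
      state$stage <- if (ok) "MONITORING" else "HALTED"
      emit("SAEStatus", approved = ok)
    },
    complete_monitoring = {
      state$stage <- "ANALYSIS"
    },
    submit_final_report = {
      state$closure_cid <- payload$closure_cid
    },
    set_ct_decision = {
      ok <- isTRUE(payload$approved)
      state$stage <- if (ok) "CT_APPROVED" else "CT_REJECTED"
      emit("CTDecisionDisclosure", approved = ok)
    },
    amend_protocol = {
      state$amendments[[length(state$amendments) + 1]] <- payload$protocol_cid
      state$protocol_cid <- payload$protocol_cid
    },
    assign_arms = {
      state$design <- payload$design
      state$arms <- payload$assignment
      if (payload$design$design == "CROSSOVER") state$period <- 1
    },
    record_arm_visit = {
      state <- add_visit(state, payload, caller,
                         arm = payload$arm, period = state$period)
    },
    advance_period = {
      state$period <- state$period + 1
    },
    tc_abort("validation_error", paste0("unknown operation: ", operation))
  )
  list(state = state, events = events)
}

add_visit <- function(state, payload, caller, arm = NA_character_,
                      period = NA_real_) {
  p <- payload$patient
  visits <- state$records[[p]]$visits
  visits[[length(visits) + 1]] <- list(
    visit_number = length(visits) + 1L,
    crf_cid = payload$crf_cid, lab_cid = payload$lab_cid,
    followup_cid = payload$followup_cid,
    recorded_by = caller, arm = arm,
    period = if (is.null(period)) NA_real_ else as.numeric(period))
  state$records[[p]]$visits <- visits
  state
}
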