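#' Scenario runner
#'
#' Scenarios are data, not code: YAML scripts (shipped under
#' `inst/extdata/scenarios/`) listing, step by step, which role calls which
#' operation with which arguments, and what must happen — success, a named
#' failure kind, broadcast events, a resulting stage or patient count. The
#' shipped set walks every workflow test case: an unauthorized caller, IND
#' rejection, premature initiation, enrollment events, the enrollment
#' threshold, visit retrieval, dropout accounting, post-dropout monitoring
#' violations, SAE rejection, and the full path to final approval.
#'
#' A run bootstraps a fresh engine and cohort from the seed, interprets the
#' steps, and reports each step's observed vs expected outcome. Running the
#' same scenario twice with the same seed yields byte-identical ledgers
#' (deterministic keys, signatures, documents and clock).
#'
#' @name trialchain-scenarios
NULL

scenario_dir_default <- function() {
  system.file("extdata", "scenarios", package = "trialchain", mustWork = TRUE)
}

#' List the shipped scenarios
#'
#' @param dir directory of scenario YAML files
#' @return a tibble with columns `name` and `description`
#' @export
list_scenarios <- function(dir = scenario_dir_default()) {
  files <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  defs <- lapply(files, yaml::read_yaml)
  tibble::tibble(
    name = vapply(defs, `[[`, character(1), "name"),
    description = vapply(defs, `[[`, character(1), "description"))
}

load_scenario <- function(name, dir = scenario_dir_default()) {
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path))
    tc_abort("unknown_scenario", paste0("no scenario named ", name))
  yaml::read_yaml(path)
}

#' Run a named scenario
#'
#' @param name a scenario name from [list_scenarios()]
#' @param seed integer seed driving identities, cohort and documents
#' @param dir directory of scenario YAML files
#' @return a list of class `scenario_run`: `name`, `passed` (all steps met
#'   expectations and the ledger verifies), `report` (tibble: one row per
#'   step with observed vs expected outcome), `chain`, `engine`, `cohort`
#' @examples
#' run <- run_scenario("enrollment_shortfall", seed = 1)
#' run$passed
#' run$report
#' @export
run_scenario <- function(name, seed = 1L, dir = scenario_dir_default()) {
  sc <- load_scenario(name, dir)
  eng <- trial_engine()
  bootstrap_roles(eng, seed = seed)
  n_cohort <- sc$cohort %||% 5L
  cohort <- generate_cohort(n_cohort, seed = seed)
  minp <- sc$min_patients %||% n_cohort

  doc <- function(kind, tag = "") {
    put_document(eng$store, synth_document(kind, seed, tag))
  }
  rows <- list()
  note <- function(step_i, role, op, expected, observed, events_ok = TRUE,
                   assert_ok = TRUE) {
    rows[[length(rows) + 1]] <<- list(
      step = step_i, role = role, operation = op,
      expected = expected, observed = observed,
      pass = identical(expected, observed) && events_ok && assert_ok)
  }

  for (i in seq_along(sc$steps)) {
    st <- sc$steps[[i]]
    op <- st$op
    expected <- st$expect %||% "ok"
    n_events_before <- length(eng$events)
    pt <- function() cohort$address[[st$patient]]
    observed <- outcome_of(switch(op,
      request_ind = request_ind(eng, "I", sc$trial_number %||% "CT-001",
                                doc("ind-application"),
                                by = st$by %||% "SPONSOR"),
      set_ind_approval = set_ind_approval(eng, isTRUE(st$approved),
                                          by = st$by %||% "FDA"),
      request_ct_initiation = request_ct_initiation(
        eng, start_date = st$start %||% 1, completion_date = st$completion %||% 100,
        min_patients = minp, protocol_cid = doc("protocol"),
        sop_cid = doc("sop"), pi_cv_cid = doc("pi-cv"),
        by = st$by %||% "SPONSOR"),
      set_ct_initiation_decision = set_ct_initiation_decision(
        eng, isTRUE(st$approved), by = st$by %||% "FDA"),
      enroll_patient = enroll_patient(
        eng, pt(), cohort$age[[st$patient]],
        consent_cid = put_document(eng$store, cohort$consent[[st$patient]]),
        history_cid = put_document(eng$store, cohort$history[[st$patient]]),
        by = st$by %||% "PHYSICIAN"),
      complete_enrollment = complete_enrollment(eng, by = st$by %||% "PHYSICIAN"),
      record_visit = record_visit(
        eng, pt(), crf_cid = doc("crf", paste0(st$patient, "-", i)),
        lab_cid = doc("lab-results", paste0(st$patient, "-", i)),
        followup_cid = doc("follow-up", paste0(st$patient, "-", i)),
        by = st$by %||% "PHYSICIAN"),
      drop_patient = drop_patient(eng, pt(), by = st$by %||% "PHYSICIAN"),
      report_sae = report_sae(eng, doc("sae-report"), by = st$by %||% "PI"),
      set_sae_decision = set_sae_decision(eng, isTRUE(st$approved),
                                          by = st$by %||% "IRB"),
      advance_clock = advance_clock(eng, st$days),
      complete_monitoring = complete_monitoring(eng, by = st$by %||% "SPONSOR"),
      submit_final_report = submit_final_report(eng, doc("closure-report"),
                                                by = st$by %||% "SPONSOR"),
      set_ct_decision = set_ct_decision(eng, isTRUE(st$approved),
                                        by = st$by %||% "FDA"),
      amend_protocol = amend_protocol(eng, doc("protocol-amendment", i),
                                      by = st$by %||% "SPONSOR"),
      get_visit = get_visit(eng, pt(), st$visit),
      tc_abort("unknown_scenario", paste0("unknown scenario step op: ", op))
    ))
    new_events <- if (length(eng$events) > n_events_before)
      eng$events[(n_events_before + 1):length(eng$events)] else list()
    emitted <- vapply(new_events, `[[`, character(1), "name")
    events_ok <- if (!is.null(st$events))
      identical(emitted, unlist(st$events)) else TRUE
    assert_ok <- TRUE
    if (!is.null(st$stage))
      assert_ok <- assert_ok && identical(eng$state$stage, st$stage)
    if (!is.null(st$count))
      assert_ok <- assert_ok && identical(count_patients(eng),
                                          as.integer(st$count))
    note(i, st$by %||% "", op, expected, observed, events_ok, assert_ok)
  }

  report <- tibble::tibble(
    step = vapply(rows, function(r) as.integer(r$step), integer(1)),
    role = vapply(rows, `[[`, character(1), "role"),
    operation = vapply(rows, `[[`, character(1), "operation"),
    expected = vapply(rows, `[[`, character(1), "expected"),
    observed = vapply(rows, `[[`, character(1), "observed"),
    pass = vapply(rows, `[[`, logical(1), "pass"))
  passed <- all(report$pass) && isTRUE(verify_chain(eng$chain))
  structure(list(name = name, passed = passed, report = report,
                 chain = eng$chain, engine = eng, cohort = cohort),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat("<scenario_run>", x$name,
      if (x$passed) "PASSED" else "FAILED",
      sprintf("(%d/%d steps ok, %d tx)\n",
              sum(x$report$pass), nrow(x$report), length(x$chain)))
  invisible(x)
}
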