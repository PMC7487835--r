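# drive a fresh engine to a named fine-grained state
engine_at <- function(state, seed = 1) {
  eng <- boot_engine(seed)
  step <- function(f) f(eng)
  path <- list(
    CREATED = NULL,
    IND_REQUESTED = function(e) request_ind(e, "I", "CT-001", put_text(e, "ind")),
    IND_APPROVED = function(e) set_ind_approval(e, TRUE),
    CT_INIT_REQUESTED = function(e)
      request_ct_initiation(e, 1, 100, 2, put_text(e, "p"), put_text(e, "s"),
                            put_text(e, "c")),
    ENROLLMENT = function(e) set_ct_initiation_decision(e, TRUE),
    MONITORING = function(e) {
      co <- generate_cohort(2, seed = seed + 1000)
      attr(e, "cohort") <- co
      for (i in 1:2)
        enroll_patient(e, co$address[i], co$age[i],
                       put_document(e$store, co$consent[[i]]),
                       put_document(e$store, co$history[[i]]))
      complete_enrollment(e)
    },
    SAE_PENDING = function(e) report_sae(e, put_text(e, "sae")),
    ANALYSIS = function(e) { set_sae_decision(e, TRUE)
      advance_clock(e, 200); complete_monitoring(e) })
  for (nm in names(path)) {
    if (!is.null(path[[nm]])) path[[nm]](eng)
    if (identical(nm, state)) break
  }
  eng
}

test_that("the engine exposes six sequential workflow stages", {
  expect_identical(length(trial_stages()), 6L)
  expect_identical(trial_stages(),
                   c("NEW_DRUG_APPLICATION", "CT_INITIATION",
                     "PATIENT_ENROLLMENT", "PATIENT_MONITORING",
                     "SAE_OCCURRENCE", "ANALYSIS_AND_REPORTING"))
  # every reachable fine state maps into one of the six (or pre-workflow)
  fine <- c("IND_REQUESTED", "IND_APPROVED", "IND_REJECTED",
            "CT_INIT_REQUESTED", "CT_INIT_REJECTED", "ENROLLMENT",
            "MONITORING", "SAE_PENDING", "HALTED", "ANALYSIS",
            "CT_APPROVED", "CT_REJECTED")
  expect_true(all(stage_group(fine) %in% trial_stages()))
  expect_true(is.na(stage_group("CREATED")))
})

test_that("each stage's entry operation fails from every other state", {
  entry_ops <- list(
    request_ind = function(e) request_ind(e, "I", "N", put_text(e, "i")),
    set_ind_approval = function(e) set_ind_approval(e, TRUE),
    request_ct_initiation = function(e)
      request_ct_initiation(e, 1, 100, 2, put_text(e, "p"), put_text(e, "s"),
                            put_text(e, "c")),
    set_ct_initiation_decision = function(e) set_ct_initiation_decision(e, TRUE),
    complete_enrollment = function(e) complete_enrollment(e),
    report_sae = function(e) report_sae(e, put_text(e, "sae")),
    set_sae_decision = function(e) set_sae_decision(e, TRUE),
    complete_monitoring = function(e) { advance_clock(e, 500); complete_monitoring(e) },
    submit_final_report = function(e) submit_final_report(e, put_text(e, "z")))
  legal_in <- list(
    request_ind = "CREATED",
    set_ind_approval = "IND_REQUESTED",
    request_ct_initiation = "IND_APPROVED",
    set_ct_initiation_decision = "CT_INIT_REQUESTED",
    complete_enrollment = "ENROLLMENT",
    report_sae = "MONITORING",
    set_sae_decision = "SAE_PENDING",
    complete_monitoring = "MONITORING",
    submit_final_report = "ANALYSIS")
  states <- c("CREATED", "IND_REQUESTED", "IND_APPROVED", "CT_INIT_REQUESTED",
              "ENROLLMENT", "MONITORING", "SAE_PENDING", "ANALYSIS")
  for (st in states) {
    eng <- engine_at(st)
    for (op in names(entry_ops)) {
      if (identical(legal_in[[op]], st)) next
      expect_tc_error(entry_ops[[op]](eng), "order_violation")
      expect_identical(trial_state(eng)$stage, st)
    }
  }
})

test_that("initiation request validation rejects bad dates and thresholds", {
  eng <- engine_at("IND_APPROVED")
  p <- put_text(eng, "p"); s <- put_text(eng, "s"); cv <- put_text(eng, "c")
  expect_tc_error(request_ct_initiation(eng, 1, 100, 0, p, s, cv),
                  "validation_error")
  expect_tc_error(request_ct_initiation(eng, 100, 100, 5, p, s, cv),
                  "validation_error")
  bogus <- paste0("sha256:", strrep("0", 64))
  expect_tc_error(request_ct_initiation(eng, 1, 100, 5, bogus, s, cv),
                  "unknown_cid")
  request_ct_initiation(eng, 1, 100, 5, p, s, cv)
  expect_identical(trial_state(eng)$stage, "CT_INIT_REQUESTED")
})

test_that("rejection branches are terminal", {
  eng <- engine_at("IND_REQUESTED")
  set_ind_approval(eng, FALSE)
  expect_identical(trial_state(eng)$stage, "IND_REJECTED")
  expect_tc_error(request_ind(eng, "I", "N", put_text(eng, "i")),
                  "order_violation")

  eng2 <- engine_at("CT_INIT_REQUESTED")
  set_ct_initiation_decision(eng2, FALSE)
  expect_identical(trial_state(eng2)$stage, "CT_INIT_REJECTED")
})

test_that("enrollment requires consent and refuses duplicates", {
  eng <- engine_at_enrollment(min_patients = 3, seed = 7)
  co <- attr(eng, "cohort")
  hist <- put_document(eng$store, co$history[[1]])
  bogus <- paste0("sha256:", strrep("1", 64))
  expect_tc_error(
    enroll_patient(eng, co$address[1], co$age[1], bogus, hist),
    "missing_consent")
  enroll_n(eng, 1)
  expect_tc_error(
    enroll_patient(eng, co$address[1], co$age[1],
                   put_document(eng$store, co$consent[[1]]), hist),
    "duplicate_patient")
  expect_tc_error(
    enroll_patient(eng, zero_address(), 30,
                   put_document(eng$store, co$consent[[2]]), hist),
    "invalid_address")
  expect_identical(count_patients(eng), 1L)
})

test_that("enrollment completes iff active count reaches the minimum", {
  minp <- 3
  for (n in 0:(2 * minp)) {
    eng <- engine_at_enrollment(min_patients = minp, n_cohort = 2 * minp,
                                seed = 10 + n)
    enroll_n(eng, n)
    complete_enrollment(eng)
    ev <- events_tbl(eng, filter = "EnrollmentStageStatus")
    expect_identical(nrow(ev), 1L)
    expect_identical(ev$detail[[1]]$complete, n >= minp)
    expect_identical(trial_state(eng)$stage,
                     if (n >= minp) "MONITORING" else "ENROLLMENT")
  }
})

test_that("dropped patients do not count toward the enrollment threshold", {
  eng <- engine_at_enrollment(min_patients = 2, n_cohort = 3, seed = 30)
  enroll_n(eng, 2)
  drop_patient(eng, attr(eng, "cohort")$address[1])
  complete_enrollment(eng)
  expect_identical(trial_state(eng)$stage, "ENROLLMENT")
  enroll_n(eng, 1, from = 3)
  complete_enrollment(eng)
  expect_identical(trial_state(eng)$stage, "MONITORING")
})

test_that("dropout accounting: count, zeroed slot, retained data", {
  eng <- engine_at_monitoring(n = 5, seed = 8)
  co <- attr(eng, "cohort")
  d <- visit_docs(eng, 1)
  record_visit(eng, co$address[1], d$crf, d$lab, d$fu)
  expect_identical(count_patients(eng), 5L)

  drop_patient(eng, co$address[1])
  expect_identical(count_patients(eng), 4L)
  roster <- get_patient_roster(eng)
  expect_identical(roster[1], zero_address())
  expect_identical(roster[-1], co$address[2:5])
  # conservation: active + zeroed slots = total ever enrolled
  expect_identical(count_patients(eng) + sum(roster == zero_address()), 5L)

  rec <- get_patient_record(eng, co$address[1])
  expect_false(rec$active)
  expect_identical(length(rec$visits), 1L)
  expect_identical(rec$visits[[1]]$crf_cid, d$crf)
  expect_identical(rec$consent_cid,
                   put_document(eng$store, co$consent[[1]]))
  expect_tc_error(drop_patient(eng, co$address[1]), "already_dropped")
  expect_tc_error(drop_patient(eng, paste0("0x", strrep("9", 40))), "not_found")
})

test_that("no visit can ever be added after a dropout", {
  eng <- engine_at_monitoring(n = 3, seed = 9)
  co <- attr(eng, "cohort")
  drop_patient(eng, co$address[2])
  n_before <- length(get_patient_record(eng, co$address[2])$visits)
  for (rep in 1:3) {
    d <- visit_docs(eng, rep)
    expect_tc_error(record_visit(eng, co$address[2], d$crf, d$lab, d$fu),
                    "patient_inactive")
  }
  expect_identical(length(get_patient_record(eng, co$address[2])$visits),
                   n_before)
  viol <- events_tbl(eng, filter = "MonitoringViolation")
  expect_identical(nrow(viol), 3L)
})

test_that("visits store sequential numbers and are retrievable per visit", {
  eng <- engine_at_monitoring(n = 2, seed = 11)
  co <- attr(eng, "cohort")
  d1 <- visit_docs(eng, 1); d2 <- visit_docs(eng, 2)
  record_visit(eng, co$address[2], d1$crf, d1$lab, d1$fu)
  record_visit(eng, co$address[2], d2$crf, d2$lab, d2$fu, by = "LAB_SCIENTIST")

  v2 <- get_visit(eng, co$address[2], 2)
  expect_identical(v2$visit_number, 2L)
  expect_identical(v2$crf_cid, d2$crf)
  expect_identical(v2$lab_cid, d2$lab)
  expect_identical(v2$recorded_by,
                   eng$registry$role_to_addr[["LAB_SCIENTIST"]])
  expect_tc_error(get_visit(eng, co$address[2], 0), "not_found")
  expect_tc_error(get_visit(eng, co$address[2], 3), "not_found")
  expect_tc_error(get_visit(eng, zero_address(), 1), "not_found")
})

test_that("SAE review suspends monitoring and the board decides the outcome", {
  eng <- engine_at_monitoring(n = 2, seed = 12)
  co <- attr(eng, "cohort")
  report_sae(eng, put_text(eng, "sae report"))
  expect_identical(trial_state(eng)$stage, "SAE_PENDING")
  d <- visit_docs(eng)
  expect_tc_error(record_visit(eng, co$address[1], d$crf, d$lab, d$fu),
                  "order_violation")

  set_sae_decision(eng, TRUE)
  expect_identical(trial_state(eng)$stage, "MONITORING")
  ev <- events_tbl(eng, filter = "SAEStatus")
  expect_true(ev$detail[[1]]$approved)

  report_sae(eng, put_text(eng, "sae report 2"))
  set_sae_decision(eng, FALSE)
  expect_identical(trial_state(eng)$stage, "HALTED")
})

test_that("monitoring closes only after the trial period ends", {
  eng <- engine_at_monitoring(n = 2, seed = 13)     # completion day 100
  expect_tc_error(complete_monitoring(eng), "too_early")
  advance_clock(eng, 120)
  complete_monitoring(eng)
  expect_identical(trial_state(eng)$stage, "ANALYSIS")
})

test_that("final decision needs the closure report first", {
  eng <- engine_at("ANALYSIS", seed = 14)
  expect_tc_error(set_ct_decision(eng, TRUE), "order_violation")
  submit_final_report(eng, put_text(eng, "closure report"))
  set_ct_decision(eng, TRUE)
  expect_identical(trial_state(eng)$stage, "CT_APPROVED")
  ev <- events_tbl(eng, filter = "CTDecisionDisclosure")
  expect_true(ev$detail[[1]]$approved)
})

test_that("protocol amendments accumulate without resetting the stage", {
  eng <- engine_at_monitoring(n = 2, seed = 15)
  v1 <- trial_state(eng)$protocol_cid
  amend_protocol(eng, put_text(eng, "protocol v2"))
  amend_protocol(eng, put_text(eng, "protocol v3"))
  st <- trial_state(eng)
  expect_identical(st$stage, "MONITORING")
  expect_identical(length(st$amendments), 2L)
  expect_false(identical(st$protocol_cid, v1))
})

test_that("every mutating success emits exactly its contracted events", {
  expected_events <- list(
    request_ind = character(0),
    set_ind_approval = "INDStageStatus",
    request_ct_initiation = character(0),
    set_ct_initiation_decision = "CTInitiationStageStatus",
    enroll_patient = "NewPatientEnrolled",
    complete_enrollment = "EnrollmentStageStatus",
    record_visit = character(0),
    drop_patient = "PatientDroppedOut",
    report_sae = character(0),
    set_sae_decision = "SAEStatus",
    complete_monitoring = character(0),
    submit_final_report = character(0),
    set_ct_decision = "CTDecisionDisclosure")
  eng <- boot_engine(seed = 16)
  co <- generate_cohort(2, seed = 17)
  run <- list(
    request_ind = function() request_ind(eng, "I", "N", put_text(eng, "i")),
    set_ind_approval = function() set_ind_approval(eng, TRUE),
    request_ct_initiation = function()
      request_ct_initiation(eng, 1, 100, 2, put_text(eng, "p"),
                            put_text(eng, "s"), put_text(eng, "c")),
    set_ct_initiation_decision = function() set_ct_initiation_decision(eng, TRUE),
    enroll_patient = function() {
      for (i in 1:2)
        enroll_patient(eng, co$address[i], co$age[i],
                       put_document(eng$store, co$consent[[i]]),
                       put_document(eng$store, co$history[[i]]))
    },
    complete_enrollment = function() complete_enrollment(eng),
    record_visit = function() {
      d <- visit_docs(eng); record_visit(eng, co$address[1], d$crf, d$lab, d$fu)
    },
    drop_patient = function() drop_patient(eng, co$address[2]),
    report_sae = function() report_sae(eng, put_text(eng, "sae")),
    set_sae_decision = function() set_sae_decision(eng, TRUE),
    complete_monitoring = function() { advance_clock(eng, 150)
      complete_monitoring(eng) },
    submit_final_report = function() submit_final_report(eng, put_text(eng, "z")),
    set_ct_decision = function() set_ct_decision(eng, TRUE))
  for (op in names(run)) {
    before <- length(eng$events)
    run[[op]]()
    emitted <- vapply(eng$events[seq_len(length(eng$events) - before) + before],
                      `[[`, character(1), "name")
    exp <- expected_events[[op]]
    if (identical(op, "enroll_patient")) exp <- rep(exp, 2)
    expect_identical(emitted, exp, label = paste("events of", op))
  }
})

test_that("short random call sequences never leave the declared state graph", {
  legal <- c("CREATED", "IND_REQUESTED", "IND_APPROVED", "IND_REJECTED",
             "CT_INIT_REQUESTED", "CT_INIT_REJECTED", "ENROLLMENT",
             "MONITORING", "SAE_PENDING", "HALTED", "ANALYSIS",
             "CT_APPROVED", "CT_REJECTED")
  edges <- list(CREATED = "IND_REQUESTED",
                IND_REQUESTED = c("IND_APPROVED", "IND_REJECTED"),
                IND_APPROVED = "CT_INIT_REQUESTED",
                CT_INIT_REQUESTED = c("ENROLLMENT", "CT_INIT_REJECTED"),
                ENROLLMENT = c("ENROLLMENT", "MONITORING"),
                MONITORING = c("SAE_PENDING", "ANALYSIS", "MONITORING"),
                SAE_PENDING = c("MONITORING", "HALTED"),
                ANALYSIS = c("CT_APPROVED", "CT_REJECTED"))
  set.seed(99)
  for (trial in 1:15) {
    eng <- boot_engine(seed = 500 + trial)
    co <- generate_cohort(3, seed = 600 + trial)
    k <- 0
    calls <- list(
      function() request_ind(eng, "I", "N", put_text(eng, "i")),
      function() set_ind_approval(eng, sample(c(TRUE, FALSE), 1)),
      function() request_ct_initiation(eng, 1, 50, 2, put_text(eng, "p"),
                                       put_text(eng, "s"), put_text(eng, "c")),
      function() set_ct_initiation_decision(eng, sample(c(TRUE, FALSE), 1)),
      function() { k <<- k + 1; i <- ((k - 1) %% 3) + 1
        enroll_patient(eng, co$address[i], co$age[i],
                       put_document(eng$store, co$consent[[i]]),
                       put_document(eng$store, co$history[[i]])) },
      function() complete_enrollment(eng),
      function() { d <- visit_docs(eng, k); k <<- k + 1
        record_visit(eng, sample(co$address, 1), d$crf, d$lab, d$fu) },
      function() drop_patient(eng, sample(co$address, 1)),
      function() report_sae(eng, put_text(eng, "sae", k)),
      function() set_sae_decision(eng, sample(c(TRUE, FALSE), 1)),
      function() { advance_clock(eng, 30); NULL },
      function() complete_monitoring(eng),
      function() submit_final_report(eng, put_text(eng, "z")),
      function() set_ct_decision(eng, sample(c(TRUE, FALSE), 1)))
    prev <- trial_state(eng)$stage
    for (step in 1:25) {
      f <- calls[[sample(length(calls), 1)]]
      try(f(), silent = TRUE)
      cur <- trial_state(eng)$stage
      expect_true(cur %in% legal)
      if (!identical(cur, prev)) {
        expect_true(cur %in% edges[[prev]],
                    label = sprintf("transition %s -> %s", prev, cur))
      }
      prev <- cur
    }
    expect_true(isTRUE(verify_chain(ledger(eng))))
  }
})
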