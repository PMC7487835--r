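# shared fixtures, all built in code at test time

put_text <- function(eng, ...) put_document(eng$store, paste0(...))

boot_engine <- function(seed = 1) {
  eng <- trial_engine()
  bootstrap_roles(eng, seed = seed)
  eng
}

# engine advanced to the ENROLLMENT stage with a cohort attached
engine_at_enrollment <- function(min_patients = 5, n_cohort = min_patients,
                                 seed = 1, completion = 100) {
  eng <- boot_engine(seed)
  request_ind(eng, "I", "CT-001", put_text(eng, "ind"))
  set_ind_approval(eng, TRUE)
  request_ct_initiation(eng, 1, completion, min_patients,
                        put_text(eng, "protocol"), put_text(eng, "sop"),
                        put_text(eng, "cv"))
  set_ct_initiation_decision(eng, TRUE)
  attr(eng, "cohort") <- generate_cohort(n_cohort, seed = seed + 1000)
  eng
}

enroll_n <- function(eng, n, from = 1) {
  co <- attr(eng, "cohort")
  for (i in seq(from, length.out = n)) {
    enroll_patient(eng, co$address[i], co$age[i],
                   put_document(eng$store, co$consent[[i]]),
                   put_document(eng$store, co$history[[i]]))
  }
  invisible(eng)
}

# engine in MONITORING with n enrolled (min defaults to n)
engine_at_monitoring <- function(n = 5, min_patients = n, seed = 1) {
  eng <- engine_at_enrollment(min_patients, n_cohort = max(n, min_patients),
                              seed = seed)
  enroll_n(eng, n)
  complete_enrollment(eng)
  eng
}

visit_docs <- function(eng, tag = "v") {
  list(crf = put_text(eng, "crf-", tag), lab = put_text(eng, "lab-", tag),
       fu = put_text(eng, "followup-", tag))
}

expect_tc_error <- function(expr, kind) {
  err <- tryCatch({ expr; NULL }, trialchain_error = function(e) e)
  expect_false(is.null(err),
               label = sprintf("expected a '%s' failure, got success", kind))
  if (!is.null(err)) expect_identical(error_kind(err), kind)
  invisible(err)
}

# independent SHA-256 oracle (digest pkg), used to cross-check openssl-based
# hashing without sharing any code with the implementation
oracle_sha256 <- function(bytes) {
  digest::digest(bytes, algo = "sha256", serialize = FALSE)
}
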