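#' Trial-design variants and randomized arm assignment
#'
#' Beyond the single-arm default, four designs are supported, differing in how
#' active patients are allocated to monitoring streams:
#'
#' * **placebo-controlled** — two arms, active treatment vs placebo;
#' * **noninferiority** — two arms, active treatment vs an existing effective
#'   therapy (active control);
#' * **factorial** — one monitoring stream per intervention (≥ 2);
#' * **crossover** — two sequence groups over `n_periods` treatment periods;
#'   group 1 receives the treatments in order, group 2 in reverse, so every
#'   patient eventually receives every treatment.
#'
#' Allocation is a seeded shuffle of the roster followed by round-robin
#' dealing into the arms: the result is a partition of the active roster,
#' balanced within one patient across arms, and fully reproducible for a
#' fixed seed. Assignments reference patients only by address — no personal
#' field ever enters an assignment record.
#'
#' @name trialchain-designs
NULL

DESIGNS <- c("SINGLE_ARM", "PLACEBO_CONTROLLED", "CROSSOVER",
             "FACTORIAL", "NONINFERIORITY")

#' Construct and validate a design specification
#'
#' @param design one of `"SINGLE_ARM"`, `"PLACEBO_CONTROLLED"`,
#'   `"CROSSOVER"`, `"FACTORIAL"`, `"NONINFERIORITY"`
#' @param arm_names treatment labels; two-arm designs need exactly 2,
#'   factorial at least 2; for crossover these are the treatments
#'   administered across periods
#' @param n_periods number of treatment periods (crossover only, ≥ 2)
#' @param seed integer driving the randomization
#' @return a `design_spec` list
#' @examples
#' design_spec("PLACEBO_CONTROLLED", c("active", "placebo"), seed = 7)
#' @export
design_spec <- function(design, arm_names, n_periods = NULL, seed = 0L) {
  spec <- list(design = design, arm_names = as.list(arm_names),
               n_periods = if (is.null(n_periods)) NA_real_
                           else as.numeric(n_periods),
               seed = as.numeric(seed))
  validate_design(spec)
  structure(spec, class = "design_spec")
}

validate_design <- function(spec) {
  if (is.null(spec) || !spec$design %in% DESIGNS)
    tc_abort("design_mismatch", "unknown design")
  k <- length(spec$arm_names)
  if (spec$design %in% c("PLACEBO_CONTROLLED", "NONINFERIORITY") && k != 2)
    tc_abort("design_mismatch",
             paste0(spec$design, " needs exactly 2 arms, got ", k))
  if (spec$design == "FACTORIAL" && k < 2)
    tc_abort("design_mismatch", "FACTORIAL needs at least 2 arms")
  if (spec$design == "CROSSOVER") {
    if (k != 2)
      tc_abort("design_mismatch", "CROSSOVER compares exactly 2 treatments")
    if (!is.numeric(spec$n_periods) || is.na(spec$n_periods) ||
        spec$n_periods < 2)
      tc_abort("design_mismatch", "CROSSOVER needs n_periods >= 2")
  }
  if (spec$design == "SINGLE_ARM" && k != 1)
    tc_abort("design_mismatch", "SINGLE_ARM has one arm")
  invisible(TRUE)
}

# group labels patients are dealt into (crossover deals into sequence groups)
design_groups <- function(spec) {
  if (spec$design == "CROSSOVER") c("seq1", "seq2")
  else unlist(spec$arm_names)
}

#' Randomly assign a roster to arms
#'
#' Seeded shuffle, then round-robin into the design's groups: a balanced
#' (±1) partition, identical on every run with the same seed. The caller's
#' RNG state is left untouched.
#'
#' @param design a [design_spec()]
#' @param roster character vector of active patient addresses (non-empty)
#' @return named character vector: address -> arm name (crossover: sequence
#'   group `"seq1"`/`"seq2"`)
#' @examples
#' ids <- vapply(1:6, function(i) generate_identity(i)$address, "")
#' assign_arms(design_spec("PLACEBO_CONTROLLED", c("active", "placebo"),
#'                         seed = 7), ids)
#' @export
assign_arms <- function(design, roster) {
  validate_design(design)
  roster <- as.character(roster)
  roster <- roster[roster != zero_address()]
  if (length(roster) == 0)
    tc_abort("validation_error", "roster is empty")
  if (anyDuplicated(roster))
    tc_abort("validation_error", "roster contains duplicate addresses")
  groups <- design_groups(design)
  shuffled <- local_seeded(design$seed, sample(roster))
  assignment <- rep_len(groups, length(shuffled))
  names(assignment) <- shuffled
  assignment[roster]  # report in roster order
}

#' Treatment administered to a group in a given crossover period
#'
#' Group 1 takes the treatments in listed order, group 2 in reverse; periods
#' beyond the number of treatments cycle through the sequence again.
#'
#' @param design a crossover [design_spec()]
#' @param group `"seq1"` or `"seq2"`
#' @param period period number (1-based)
#' @return a treatment label from `design$arm_names`
#' @export
crossover_treatment <- function(design, group, period) {
  arms <- unlist(design$arm_names)
  seqs <- list(seq1 = arms, seq2 = rev(arms))
  if (!group %in% names(seqs))
    tc_abort("design_mismatch", paste0("unknown sequence group: ", group))
  s <- seqs[[group]]
  s[((period - 1) %% length(s)) + 1]
}

# assignment payload validation at append time: partition of active roster
check_assignment <- function(design, assignment, state) {
  active <- names(state$records)[vapply(state$records,
                                        function(r) isTRUE(r$active),
                                        logical(1))]
  got <- names(assignment)
  if (!setequal(got, active) || anyDuplicated(got))
    tc_abort("design_mismatch",
             "assignment is not a partition of the active roster")
  groups <- design_groups(design)
  if (!all(unlist(assignment) %in% groups))
    tc_abort("design_mismatch", "assignment uses labels outside the design")
  invisible(TRUE)
}

# does `arm` match what this patient should be monitored under right now?
check_arm_membership <- function(state, patient, arm) {
  if (!patient %in% names(state$arms))
    tc_abort("arm_mismatch", paste0("patient has no arm assignment: ", patient))
  assigned <- state$arms[[patient]]
  expected <- if (state$design$design == "CROSSOVER")
    crossover_treatment(state$design, assigned, state$period)
  else assigned
  if (!identical(arm, expected))
    tc_abort("arm_mismatch",
             sprintf("visit labelled %s but patient is under %s", arm, expected))
  invisible(TRUE)
}
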