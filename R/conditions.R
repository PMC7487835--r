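#' @title Error conditions
#' @description
#' All failures raised by trialchain are classed conditions so callers (and the
#' scenario runner) can match on the failure kind rather than on message text.
#' Every condition inherits from `trialchain_error`; the specific class is
#' `trialchain_error_<kind>` with kinds such as `permission_denied`,
#' `order_violation`, `validation_error`, `duplicate_patient`, `not_found`.
#' @name trialchain-conditions
#' @keywords internal
NULL

tc_abort <- function(kind, message, ...) {
  cond <- structure(
    class = c(paste0("trialchain_error_", kind), "trialchain_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), kind = kind, ...)
  )
  stop(cond)
}

#' Extract the failure kind from a trialchain condition
#'
#' @param cond a condition object caught from a trialchain call
#' @return a length-1 character such as `"permission_denied"`, or `NA` if the
#'   condition was not raised by trialchain
#' @export
error_kind <- function(cond) {
  if (inherits(cond, "trialchain_error")) cond$kind else NA_character_
}

# Run `expr`; on a trialchain error return its kind, otherwise "ok".
# Used by the scenario runner and tests.
outcome_of <- function(expr) {
  tryCatch({ force(expr); "ok" },
           trialchain_error = function(e) e$kind)
}
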