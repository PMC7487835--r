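#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ledger as a tibble
#'
#' One row per transaction; `payload` is a list-column.
#'
#' @param engine a [trial_engine()] or a `trialchain_chain`
#' @return a tibble with columns `index`, `timestamp`, `caller`, `role`,
#'   `operation`, `payload`, `prev_hash`, `tx_hash`
#' @export
ledger_tbl <- function(engine) {
  chain <- if (inherits(engine, "trial_engine")) engine$chain else engine
  txs <- unclass(chain)
  roles <- list()
  role_col <- vapply(txs, function(tx) {
    if (identical(tx$operation, "register_role"))
      roles[[tx$caller]] <<- tx$payload$role
    roles[[tx$caller]] %||% NA_character_
  }, character(1))
  tibble::tibble(
    index = vapply(txs, function(t) as.numeric(t$index), numeric(1)),
    timestamp = vapply(txs, function(t) as.numeric(t$timestamp), numeric(1)),
    caller = vapply(txs, `[[`, character(1), "caller"),
    role = role_col,
    operation = vapply(txs, `[[`, character(1), "operation"),
    payload = lapply(txs, `[[`, "payload"),
    prev_hash = vapply(txs, `[[`, character(1), "prev_hash"),
    tx_hash = vapply(txs, `[[`, character(1), "tx_hash"))
}

#' Events emitted so far, as a tibble
#'
#' @param engine a [trial_engine()]
#' @param filter optional event name
#' @return tibble with columns `event`, `emitted_at_tx`, `detail`
#' @export
events_tbl <- function(engine, filter = NULL) {
  evs <- engine$events
  out <- tibble::tibble(
    event = vapply(evs, `[[`, character(1), "name"),
    emitted_at_tx = vapply(evs, function(e) as.numeric(e$emitted_at_tx),
                           numeric(1)),
    detail = lapply(evs, `[[`, "detail"))
  if (!is.null(filter)) out <- out[out$event %in% filter, ]
  out
}

#' Patient roster as a tibble
#'
#' @param engine a [trial_engine()]
#' @return tibble with columns `slot`, `address`, `active`, `age`,
#'   `n_visits`, `arm` (dropped slots show the zero address and `NA` details)
#' @export
roster_tbl <- function(engine) {
  st <- engine$state
  roster <- get_patient_roster(engine)
  recs <- lapply(roster, function(a) st$records[[a]])
  tibble::tibble(
    slot = seq_along(roster),
    address = roster,
    active = vapply(recs, function(r) if (is.null(r)) FALSE else
      isTRUE(r$active), logical(1)),
    age = vapply(recs, function(r) if (is.null(r)) NA_real_ else r$age,
                 numeric(1)),
    n_visits = vapply(recs, function(r) if (is.null(r)) NA_real_ else
      length(r$visits), numeric(1)),
    arm = vapply(roster, function(a) {
      v <- st$arms[[a]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1), USE.NAMES = FALSE))
}

#' All recorded visits as a tibble
#'
#' @param engine a [trial_engine()]
#' @return tibble with one row per visit: `address`, `visit_number`, `arm`,
#'   `period`, `recorded_by`, `crf_cid`, `lab_cid`, `followup_cid`
#' @export
visits_tbl <- function(engine) {
  rows <- list()
  for (rec in engine$state$records) {
    for (v in rec$visits) {
      rows[[length(rows) + 1]] <- c(list(address = rec$address), v)
    }
  }
  grab <- function(f, type) vapply(rows, function(r) {
    x <- r[[f]]
    if (is.null(x)) x <- NA
    if (identical(type, "c")) as.character(x) else as.numeric(x)
  }, if (identical(type, "c")) character(1) else numeric(1))
  tibble::tibble(
    address = grab("address", "c"),
    visit_number = grab("visit_number", "n"),
    arm = grab("arm", "c"),
    period = grab("period", "n"),
    recorded_by = grab("recorded_by", "c"),
    crf_cid = grab("crf_cid", "c"),
    lab_cid = grab("lab_cid", "c"),
    followup_cid = grab("followup_cid", "c"))
}

#' @rdname ledger_tbl
#' @param x a `trialchain_chain`
#' @param ... unused
#' @method tidy trialchain_chain
#' @export
tidy.trialchain_chain <- function(x, ...) ledger_tbl(x)

#' One-row summary of an engine
#'
#' @param x a `trial_engine`
#' @param ... unused
#' @return tibble with `stage`, `stage_group`, `n_tx`, `n_events`,
#'   `n_enrolled`, `n_active`, `clock`, `chain_valid`
#' @method glance trial_engine
#' @export
glance.trial_engine <- function(x, ...) {
  tibble::tibble(
    stage = x$state$stage,
    stage_group = stage_group(x$state$stage),
    n_tx = length(x$chain),
    n_events = length(x$events),
    n_enrolled = length(x$state$records),
    n_active = count_patients(x),
    clock = x$clock,
    chain_valid = isTRUE(verify_chain(x$chain)))
}

#' Plot a ledger timeline
#'
#' Transactions along the logical clock, coloured by calling role and
#' labelled by operation — a quick audit view of who did what, when.
#'
#' @param object a `trialchain_chain`
#' @param ... unused
#' @return a ggplot
#' @method autoplot trialchain_chain
#' @export
autoplot.trialchain_chain <- function(object, ...) {
  d <- ledger_tbl(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timestamp,
                                  y = stats::reorder(.data$operation,
                                                     .data$index),
                                  colour = .data$role)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "logical clock (days)", y = NULL, colour = "role",
                  title = "Ledger timeline") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
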