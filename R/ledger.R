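#' Hash-chained signed transaction ledger
#'
#' Every successful state-mutating operation becomes one transaction — one
#' block, in effect — holding: a strictly sequential index, a logical
#' timestamp, the caller's address, the operation name, the payload, the
#' previous transaction's hash (`prev_hash`, 64 zeros for the first
#' transaction), its own hash, and the caller's Ed25519 signature.
#'
#' `tx_hash` is the SHA-256 digest of the canonical serialization of
#' `(index, timestamp, caller, operation, payload, prev_hash)`; the signature
#' is over those same bytes. Because each transaction commits to its
#' predecessor's hash, changing any recorded field anywhere breaks
#' verification from that point on — the ledger is tamper-evident.
#'
#' Role registration is itself on-chain (self-signed `register_role`
#' transactions carrying the public key), so a chain is verifiable and
#' replayable in isolation, with no out-of-band key material.
#'
#' @name trialchain-ledger
NULL

GENESIS_HASH <- strrep("0", 64)

tx_signing_bytes <- function(tx) {
  canonical_bytes(list(
    index = tx$index, timestamp = tx$timestamp, caller = tx$caller,
    operation = tx$operation, payload = tx$payload,
    prev_hash = tx$prev_hash))
}

build_transaction <- function(index, timestamp, caller, operation, payload,
                              prev_hash, keypair) {
  tx <- list(index = index, timestamp = timestamp, caller = caller,
             operation = operation, payload = payload, prev_hash = prev_hash)
  bytes <- tx_signing_bytes(tx)
  tx$tx_hash <- sha256_hex(bytes)
  tx$signature <- paste(format(sign_payload(keypair, bytes)), collapse = "")
  structure(tx, class = "trialchain_tx")
}

#' @export
print.trialchain_tx <- function(x, ...) {
  cat(sprintf("<tx %d> %s by %s  hash %s...\n",
              x$index, x$operation, substr(x$caller, 1, 10),
              substr(x$tx_hash, 1, 12)))
  invisible(x)
}

new_chain <- function() structure(list(), class = "trialchain_chain")

#' @export
print.trialchain_chain <- function(x, ...) {
  cat("<trialchain_chain>", length(x), "transaction(s)\n")
  invisible(x)
}

#' Verify a ledger end to end
#'
#' Checks, transaction by transaction: sequential indices, non-decreasing
#' timestamps, `prev_hash` linkage (genesis = 64 zeros), recomputed
#' `tx_hash`, and the caller's signature against the public key that the
#' chain itself registered for that address (with the address re-derived
#' from the key). Returns `TRUE`, or `FALSE` with attributes
#' `first_invalid` (index of the first failing transaction) and `reason`.
#'
#' @param chain a `trialchain_chain` (or plain list of transactions)
#' @param upto optional index; verify only transactions `0..upto`
#' @return logical scalar with failure attributes when `FALSE`
#' @export
verify_chain <- function(chain, upto = NULL) {
  txs <- unclass(chain)
  if (!is.null(upto)) txs <- txs[seq_len(min(length(txs), upto + 1))]
  fail <- function(i, reason) {
    structure(FALSE, first_invalid = i, reason = reason)
  }
  pubkeys <- list()
  prev_hash <- GENESIS_HASH
  prev_ts <- -Inf
  for (i in seq_along(txs)) {
    tx <- txs[[i]]
    if (!identical(as.numeric(tx$index), as.numeric(i - 1)))
      return(fail(i - 1, "index not sequential"))
    if (tx$timestamp < prev_ts)
      return(fail(i - 1, "timestamp decreased"))
    if (!identical(tx$prev_hash, prev_hash))
      return(fail(i - 1, "prev_hash does not match predecessor"))
    bytes <- tx_signing_bytes(tx)
    if (!identical(sha256_hex(bytes), tx$tx_hash))
      return(fail(i - 1, "tx_hash does not match contents"))
    if (identical(tx$operation, "register_role")) {
      pk <- hex_to_raw(tx$payload$pubkey)
      if (!identical(derive_address(pk), tx$payload$address) ||
          !identical(tx$caller, tx$payload$address))
        return(fail(i - 1, "registered key does not derive its address"))
      pubkeys[[tx$payload$address]] <- pk
    }
    pk <- pubkeys[[tx$caller]]
    if (is.null(pk))
      return(fail(i - 1, "caller has no registered public key"))
    if (!verify_payload(tx$caller, pk, bytes, hex_to_raw(tx$signature)))
      return(fail(i - 1, "signature invalid"))
    prev_hash <- tx$tx_hash
    prev_ts <- tx$timestamp
  }
  TRUE
}

hex_to_raw <- function(hex) {
  if (!is.character(hex) || length(hex) != 1 || is.na(hex) ||
      nchar(hex) %% 2 != 0 || !grepl("^[0-9a-fA-F]*$", hex))
    return(raw(0))
  as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                          seq(2, nchar(hex), 2)), 16L))
}

#' Rebuild trial state by replaying a ledger
#'
#' Event-sourcing: folds the same reducer the live engine uses over the
#' (verified) chain, yielding a state byte-identical to the live engine's
#' after the same calls. With `upto`, replays only transactions `0..upto`.
#'
#' @param chain a verified `trialchain_chain`
#' @param upto optional last transaction index to apply
#' @return a `trial_state`
#' @export
replay_state <- function(chain, upto = NULL) {
  ok <- verify_chain(chain, upto = upto)
  if (!isTRUE(ok))
    tc_abort("chain_invalid",
             sprintf("chain fails verification at index %s (%s)",
                     attr(ok, "first_invalid"), attr(ok, "reason")))
  txs <- unclass(chain)
  if (!is.null(upto)) txs <- txs[seq_len(min(length(txs), upto + 1))]
  state <- new_trial_state()
  for (tx in txs) {
    state <- apply_operation(state, tx$operation, tx$payload,
                             tx$caller, tx$index)$state
  }
  state
}

#' List the events a ledger has emitted
#'
#' Events are broadcast notifications caused by exactly one transaction each
#' (regulatory stage decisions, patient enrollment and dropout, enrollment
#' completion, monitoring violations, SAE decisions, the final disclosure).
#' They are reconstructed deterministically from the chain.
#'
#' @param chain a `trialchain_chain`
#' @param filter optional event name to restrict to
#' @return a tibble with columns `event`, `emitted_at_tx`, `detail`
#'   (list-column of per-event fields)
#' @export
list_events <- function(chain, filter = NULL) {
  txs <- unclass(chain)
  state <- new_trial_state()
  rows <- list()
  for (tx in txs) {
    res <- apply_operation(state, tx$operation, tx$payload,
                           tx$caller, tx$index)
    state <- res$state
    for (ev in res$events) {
      rows[[length(rows) + 1]] <-
        list(event = ev$name, emitted_at_tx = tx$index, detail = ev$detail)
    }
  }
  out <- tibble::tibble(
    event = vapply(rows, `[[`, character(1), "event"),
    emitted_at_tx = vapply(rows, `[[`, numeric(1), "emitted_at_tx"),
    detail = lapply(rows, `[[`, "detail"))
  if (!is.null(filter)) out <- out[out$event %in% filter, ]
  out
}

# ---- export / import --------------------------------------------------------

tx_to_json <- function(tx) {
  # stable field order for the line format (hashing uses canonical_json)
  paste0("{",
    "\"index\":", canonical_json(tx$index), ",",
    "\"timestamp\":", canonical_json(tx$timestamp), ",",
    "\"caller\":", canonical_json(tx$caller), ",",
    "\"operation\":", canonical_json(tx$operation), ",",
    "\"payload\":", canonical_json(tx$payload), ",",
    "\"prev_hash\":", canonical_json(tx$prev_hash), ",",
    "\"tx_hash\":", canonical_json(tx$tx_hash), ",",
    "\"signature\":", canonical_json(tx$signature), "}")
}

#' Write a ledger as line-delimited JSON
#'
#' One transaction per line, stable field order. The file round-trips through
#' [read_ledger()] bit-exactly.
#'
#' @param chain a `trialchain_chain`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_ledger <- function(chain, path) {
  lines <- vapply(unclass(chain), tx_to_json, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a ledger from line-delimited JSON
#'
#' @param path file written by [write_ledger()]
#' @return a `trialchain_chain` (not yet verified — run [verify_chain()])
#' @export
read_ledger <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  txs <- lapply(lines, function(l) {
    # simplifyVector = FALSE keeps arrays as lists, so the canonical
    # serialization (and hence every tx_hash) survives the round trip
    tx <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    structure(tx, class = "trialchain_tx")
  })
  structure(txs, class = "trialchain_chain")
}
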