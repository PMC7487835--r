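#' Generate a synthetic patient cohort
#'
#' Produces `n` distinct pseudonymous patients for simulation runs: an
#' address each (derived from a throwaway key pair — patients never sign
#' anything, so the keys are discarded), a plausible adult age, and seeded
#' pseudo-random consent and medical-history documents with human-readable
#' headers. Fully deterministic for a fixed seed.
#'
#' @param n number of patients (≥ 1)
#' @param seed integer seed
#' @return a tibble (class `synthetic_cohort`) with columns `patient`
#'   (label), `address`, `age`, `consent` and `history` (list-columns of raw
#'   document bytes)
#' @examples
#' generate_cohort(3, seed = 1)
#' @export
generate_cohort <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != trunc(n))
    tc_abort("validation_error", "n must be a positive integer")
  sub <- local_seeded(seed, sample.int(.Machine$integer.max, n + 1))
  ages <- local_seeded(sub[n + 1], sample(18:79, n, replace = TRUE))
  rows <- lapply(seq_len(n), function(i) {
    tag <- sprintf("patient-%02d", i)
    list(
      patient = tag,
      address = generate_identity(seed = sub[i])$address,
      age = ages[i],
      consent = synth_document("informed-consent", sub[i], tag),
      history = synth_document("medical-history", sub[i] + 1, tag))
  })
  out <- tibble::tibble(
    patient = vapply(rows, `[[`, character(1), "patient"),
    address = vapply(rows, `[[`, character(1), "address"),
    age = vapply(rows, function(r) as.numeric(r$age), numeric(1)),
    consent = lapply(rows, `[[`, "consent"),
    history = lapply(rows, `[[`, "history"))
  class(out) <- c("synthetic_cohort", class(out))
  out
}

#' Generate a synthetic trial document
#'
#' A readable header (document kind plus tag) followed by seeded
#' pseudo-random hex content, so CIDs are stable per seed and demo ledgers
#' are inspectable.
#'
#' @param kind document kind, e.g. `"protocol"`, `"crf"`, `"sae-report"`
#' @param seed integer seed
#' @param tag free-text tag (e.g. a patient label or visit number)
#' @return raw bytes
#' @export
synth_document <- function(kind, seed, tag = "") {
  body <- local_seeded(seed,
    paste(sample(c(0:9, letters[1:6]), 96, replace = TRUE), collapse = ""))
  charToRaw(paste0("TRIALCHAIN SYNTHETIC DOCUMENT\n",
                   "kind: ", kind, "\n",
                   "tag: ", tag, "\n",
                   body, "\n"))
}
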