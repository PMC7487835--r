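#' Stakeholder identities, addresses and the permission matrix
#'
#' Every stakeholder in the simulated network holds an Ed25519 key pair and an
#' address derived from the public key, mimicking the shape of an Ethereum
#' address: `"0x"` followed by the lowercase hex of the last 20 bytes of the
#' SHA-256 digest of the 32-byte public key. The all-zeros address is reserved
#' as the placeholder written into the roster slot of a dropped patient and can
#' never be registered.
#'
#' Six single-entity roles exist: trial sponsor, FDA, IRB, principal
#' investigator, physician and medical lab scientist. Patients are passive —
#' they hold addresses (their pseudonymous identifiers) but never call
#' operations; the physician holds their keys.
#'
#' @name trialchain-identities
NULL

ROLES <- c("SPONSOR", "FDA", "IRB", "PI", "PHYSICIAN", "LAB_SCIENTIST")

#' The reserved all-zeros placeholder address
#' @return `"0x"` followed by 40 zeros
#' @export
zero_address <- function() paste0("0x", strrep("0", 40))

#' The six stakeholder roles
#' @return character vector of role names
#' @export
trial_roles <- function() ROLES

# PKCS#8 DER envelope for a raw 32-byte Ed25519 private key
ed25519_der <- function(seed32) {
  stopifnot(is.raw(seed32), length(seed32) == 32L)
  c(as.raw(c(0x30, 0x2e, 0x02, 0x01, 0x00, 0x30, 0x05, 0x06, 0x03,
             0x2b, 0x65, 0x70, 0x04, 0x22, 0x04, 0x20)), seed32)
}

keypair_from_raw <- function(seed32) {
  key <- openssl::read_key(ed25519_der(seed32), der = TRUE)
  pub <- key$pubkey$data
  structure(list(private = seed32, public = pub), class = "trialchain_keypair")
}

#' @export
print.trialchain_keypair <- function(x, ...) {
  cat("<trialchain_keypair>", derive_address(x$public), "\n")
  invisible(x)
}

#' Generate a fresh signing identity
#'
#' Creates an Ed25519 key pair and its derived address. With `seed` the result
#' is fully deterministic (the private key is drawn from R's RNG without
#' disturbing the caller's RNG state); without, the key is drawn from the
#' operating system's entropy source.
#'
#' @param seed optional integer; fixes the key pair
#' @return a list with elements `keypair` (class `trialchain_keypair`) and
#'   `address` (a `"0x"`-prefixed 40-hex-character string)
#' @examples
#' id <- generate_identity(seed = 1)
#' id$address
#' @export
generate_identity <- function(seed = NULL) {
  if (!is.null(seed)) {
    seed32 <- local_seeded(seed, as.raw(sample.int(256L, 32L, replace = TRUE) - 1L))
  } else {
    seed32 <- openssl::rand_bytes(32)
  }
  kp <- keypair_from_raw(seed32)
  list(keypair = kp, address = derive_address(kp$public))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
local_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive an address from a public key
#'
#' @param public_key raw vector (the 32-byte Ed25519 public key)
#' @return `"0x"` + lowercase hex of the last 20 bytes of `sha256(public_key)`
#' @export
derive_address <- function(public_key) {
  stopifnot(is.raw(public_key))
  dg <- openssl::sha256(public_key)
  paste0("0x", paste(format(utils::tail(dg, 20)), collapse = ""))
}

is_address <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) &&
    grepl("^0x[0-9a-f]{40}$", x)
}

#' Sign a payload with a key pair
#'
#' Ed25519 signatures are deterministic: the same key and payload always give
#' the same 64-byte signature, so a ledger built under a fixed seed is
#' byte-reproducible.
#'
#' @param keypair a `trialchain_keypair`
#' @param payload raw vector (the canonical serialization of a transaction)
#' @return raw 64-byte signature
#' @export
sign_payload <- function(keypair, payload) {
  stopifnot(inherits(keypair, "trialchain_keypair"), is.raw(payload))
  key <- openssl::read_key(ed25519_der(keypair$private), der = TRUE)
  openssl::ed25519_sign(payload, key)
}

#' Verify a signature against a public key and its address
#'
#' Returns `FALSE` (never raises) when the signature does not verify, the
#' public key does not hash to `address`, or the inputs are malformed.
#'
#' @param address the claimed signer's address
#' @param public_key raw 32-byte public key of the claimed signer
#' @param payload raw vector that was signed
#' @param signature raw 64-byte signature
#' @return logical
#' @export
verify_payload <- function(address, public_key, payload, signature) {
  if (!is.raw(public_key) || length(public_key) != 32L) return(FALSE)
  if (!is_address(address) || !identical(derive_address(public_key), address))
    return(FALSE)
  if (!is.raw(signature) || length(signature) != 64L) return(FALSE)
  pub <- tryCatch(openssl::read_pubkey(
    c(as.raw(c(0x30, 0x2a, 0x30, 0x05, 0x06, 0x03, 0x2b, 0x65, 0x70,
               0x03, 0x21, 0x00)), public_key), der = TRUE),
    error = function(e) NULL)
  if (is.null(pub)) return(FALSE)
  isTRUE(tryCatch(openssl::ed25519_verify(payload, signature, pubkey = pub),
                  error = function(e) FALSE))
}

# ---- permission matrix ------------------------------------------------------

# State-mutating operations -> set of roles allowed to call them.
# register_role is bootstrap plumbing and is guarded separately (self-signed,
# only while the role is unbound).
PERMISSIONS <- list(
  request_ind                = "SPONSOR",
  set_ind_approval           = "FDA",
  request_ct_initiation      = "SPONSOR",
  set_ct_initiation_decision = "FDA",
  enroll_patient             = "PHYSICIAN",
  complete_enrollment        = "PHYSICIAN",
  record_visit               = c("PHYSICIAN", "LAB_SCIENTIST"),
  monitoring_violation       = c("PHYSICIAN", "LAB_SCIENTIST"),
  drop_patient               = "PHYSICIAN",
  report_sae                 = "PI",
  set_sae_decision           = "IRB",
  complete_monitoring        = "SPONSOR",
  submit_final_report        = "SPONSOR",
  set_ct_decision            = "FDA",
  amend_protocol             = "SPONSOR",
  assign_arms                = "PHYSICIAN",
  record_arm_visit           = c("PHYSICIAN", "LAB_SCIENTIST"),
  advance_period             = "PHYSICIAN"
)

# Read-only queries, open to every registered participant in the network.
OPEN_OPERATIONS <- c("count_patients", "get_patient_roster",
                     "get_patient_record", "get_visit")

#' The permission matrix
#'
#' One row per (operation, role) pair with `allowed` saying whether that role
#' may invoke that state-mutating operation. Read-only queries are open to all
#' registered participants and are not listed.
#'
#' @return a tibble with columns `operation`, `role`, `allowed`
#' @export
permission_matrix <- function() {
  ops <- setdiff(names(PERMISSIONS), "monitoring_violation")
  tibble::tibble(
    operation = rep(ops, each = length(ROLES)),
    role = rep(ROLES, times = length(ops)),
    allowed = unlist(lapply(ops, function(op) ROLES %in% PERMISSIONS[[op]]),
                     use.names = FALSE)
  )
}

# ---- role registry ----------------------------------------------------------

#' Create an empty role registry
#'
#' Maps each of the six roles to exactly one address and keeps the public key
#' needed to verify that address's signatures. Single-entity assumption: a
#' role, once bound, cannot be rebound.
#'
#' @return a `trialchain_registry` (environment-backed, mutable)
#' @export
role_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$role_to_addr <- character(0)   # named by role
  reg$addr_to_role <- character(0)   # named by address
  reg$pubkeys <- list()              # named by address, raw 32 bytes
  class(reg) <- "trialchain_registry"
  reg
}

#' Bind a role to an address
#'
#' @param registry a `trialchain_registry`
#' @param address a well-formed, non-zero address
#' @param role one of [trial_roles()]
#' @param public_key raw 32-byte public key hashing to `address`
#' @return the registry, invisibly
#' @export
register_role <- function(registry, address, role, public_key) {
  stopifnot(inherits(registry, "trialchain_registry"))
  if (!role %in% ROLES)
    tc_abort("validation_error", paste0("unknown role: ", role))
  if (!is_address(address) || identical(address, zero_address()))
    tc_abort("invalid_address", paste0("not a registrable address: ", address))
  if (role %in% names(registry$role_to_addr))
    tc_abort("duplicate_role", paste0("role already bound: ", role))
  if (address %in% names(registry$addr_to_role))
    tc_abort("invalid_address", "address already bound to a role")
  if (!identical(derive_address(public_key), address))
    tc_abort("invalid_address", "public key does not derive the given address")
  registry$role_to_addr[[role]] <- address
  registry$addr_to_role[[address]] <- role
  registry$pubkeys[[address]] <- public_key
  invisible(registry)
}

registry_complete <- function(registry) {
  all(ROLES %in% names(registry$role_to_addr))
}

role_of <- function(registry, address) {
  if (address %in% names(registry$addr_to_role))
    registry$addr_to_role[[address]] else NA_character_
}

#' Check whether a caller may invoke an operation
#'
#' `TRUE` iff the caller's registered role is in the operation's permitted
#' set; read-only queries are allowed for any registered participant.
#' Unregistered addresses always get `FALSE`.
#'
#' @param registry a `trialchain_registry`
#' @param caller an address
#' @param operation an operation name
#' @return logical
#' @export
authorize <- function(registry, caller, operation) {
  role <- role_of(registry, caller)
  if (is.na(role)) return(FALSE)
  if (operation %in% OPEN_OPERATIONS) return(TRUE)
  perm <- PERMISSIONS[[operation]]
  if (is.null(perm)) return(FALSE)
  role %in% perm
}
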