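#' Content-addressed document store
#'
#' A stand-in for a distributed file system of the IPFS kind: documents are
#' arbitrary byte-sequences, addressed purely by content. The identifier (CID)
#' of a document is `"sha256:"` followed by the 64-hex-character SHA-256
#' digest of its bytes, so equal contents always share a CID and any amendment
#' to a document yields a new CID — the old version stays retrievable and the
#' store has no delete operation.
#'
#' Two backends: in-memory (default, for tests and scenario runs) and a flat
#' directory keyed by hex digest (survives the session).
#'
#' @param dir optional path; when given, documents are stored as files named
#'   by their hex digest under this directory
#' @return a `trialchain_docstore`
#' @examples
#' store <- docstore()
#' cid <- put_document(store, charToRaw("protocol v1"))
#' rawToChar(get_document(store, cid))
#' @export
docstore <- function(dir = NULL) {
  st <- new.env(parent = emptyenv())
  st$mode <- if (is.null(dir)) "memory" else "dir"
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    st$dir <- dir
  } else {
    st$blobs <- new.env(parent = emptyenv())
  }
  class(st) <- "trialchain_docstore"
  st
}

#' @export
print.trialchain_docstore <- function(x, ...) {
  n <- if (x$mode == "memory") length(ls(x$blobs)) else
    length(list.files(x$dir))
  cat("<trialchain_docstore>", x$mode, "backend,", n, "document(s)\n")
  invisible(x)
}

as_doc_bytes <- function(content) {
  if (is.character(content)) content <- charToRaw(paste(content, collapse = "\n"))
  if (!is.raw(content))
    tc_abort("validation_error", "document content must be raw bytes or text")
  content
}

#' Store a document, returning its content identifier
#'
#' Idempotent: re-storing identical content returns the same CID and changes
#' nothing. Empty content is allowed.
#'
#' @param store a [docstore()]
#' @param content raw vector (character is encoded as UTF-8 bytes)
#' @return the CID, `"sha256:"` + 64 lowercase hex characters
#' @export
put_document <- function(store, content) {
  stopifnot(inherits(store, "trialchain_docstore"))
  content <- as_doc_bytes(content)
  hex <- sha256_hex(content)
  if (store$mode == "memory") {
    assign(hex, content, envir = store$blobs)
  } else {
    path <- file.path(store$dir, hex)
    if (!file.exists(path)) writeBin(content, path)
  }
  paste0("sha256:", hex)
}

is_cid <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) &&
    grepl("^sha256:[0-9a-f]{64}$", x)
}

cid_hex <- function(cid) sub("^sha256:", "", cid)

#' Retrieve a document by content identifier
#'
#' The returned bytes are re-hashed on the way out; if the stored bytes no
#' longer match the CID (store corruption) an `integrity_error` is raised
#' rather than returning silently wrong content.
#'
#' @param store a [docstore()]
#' @param cid a CID previously returned by [put_document()]
#' @return raw vector
#' @export
get_document <- function(store, cid) {
  stopifnot(inherits(store, "trialchain_docstore"))
  if (!is_cid(cid)) tc_abort("not_found", paste0("malformed CID: ", cid))
  hex <- cid_hex(cid)
  bytes <- if (store$mode == "memory") {
    if (!exists(hex, envir = store$blobs, inherits = FALSE))
      tc_abort("not_found", paste0("no document stored under ", cid))
    get(hex, envir = store$blobs)
  } else {
    path <- file.path(store$dir, hex)
    if (!file.exists(path))
      tc_abort("not_found", paste0("no document stored under ", cid))
    readBin(path, "raw", n = file.size(path))
  }
  if (!identical(sha256_hex(bytes), hex))
    tc_abort("integrity_error",
             paste0("stored bytes no longer match ", cid))
  bytes
}

#' Does the store hold a document under this CID?
#' @param store a [docstore()]
#' @param cid a CID
#' @return logical
#' @export
has_document <- function(store, cid) {
  if (!is_cid(cid)) return(FALSE)
  hex <- cid_hex(cid)
  if (store$mode == "memory")
    exists(hex, envir = store$blobs, inherits = FALSE)
  else file.exists(file.path(store$dir, hex))
}
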