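#' Canonical JSON serialization
#'
#' Transactions are hashed and signed over a canonical byte representation:
#' JSON with object keys sorted bytewise, UTF-8, no insignificant whitespace,
#' scalars unboxed. The rule must be bit-exact — two serializations of the
#' same value must be identical bytes, or transaction hashes would not be
#' reproducible across sessions — which is why this is written out explicitly
#' rather than delegated to a general-purpose JSON writer (none of which
#' guarantee key ordering).
#'
#' Supported values: `NULL`/`NA` (-> `null`), logical, numeric (integers
#' rendered without exponent; non-integral doubles with 17 significant
#' digits), character, unnamed lists/vectors (-> arrays), named lists
#' (-> objects, keys sorted in the C locale).
#'
#' @param x an R value composed of the supported types
#' @return a length-1 character string of JSON
#' @examples
#' canonical_json(list(b = 1L, a = "x"))  # keys sorted: {"a":"x","b":1}
#' @export
canonical_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) {
      if (anyNA(nm) || any(nm == "")) {
        tc_abort("validation_error", "all elements of a JSON object need names")
      }
      nm <- sort(nm, method = "radix")
      body <- vapply(nm, function(k) {
        paste0(json_escape(k), ":", canonical_json(x[[k]]))
      }, character(1))
      return(paste0("{", paste0(body, collapse = ","), "}"))
    }
    body <- vapply(x, canonical_json, character(1))
    return(paste0("[", paste0(body, collapse = ","), "]"))
  }
  if (length(x) != 1) {
    return(canonical_json(as.list(x)))
  }
  if (is.character(x)) {
    if (is.na(x)) return("null")
    return(json_escape(x))
  }
  if (is.logical(x)) {
    if (is.na(x)) return("null")
    return(if (x) "true" else "false")
  }
  if (is.numeric(x)) {
    if (is.na(x)) return("null")
    if (is.finite(x) && x == trunc(x) && abs(x) < 2^53) {
      return(sprintf("%.0f", x))
    }
    return(sprintf("%.17g", x))
  }
  tc_abort("validation_error",
           paste0("cannot canonicalize value of class ", class(x)[1]))
}

json_escape <- function(s) {
  s <- enc2utf8(s)
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  # control characters must be escaped (NUL cannot occur in an R string)
  for (i in 1:31) {
    ch <- intToUtf8(i)
    if (grepl(ch, s, fixed = TRUE)) {
      s <- gsub(ch, sprintf("\\u%04x", i), s, fixed = TRUE)
    }
  }
  paste0("\"", s, "\"")
}

canonical_bytes <- function(x) charToRaw(canonical_json(x))

sha256_hex <- function(bytes) {
  # as.vector drops openssl's "hash" class so comparisons with strings
  # parsed back from JSON behave
  as.vector(as.character(openssl::sha256(bytes)))
}
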