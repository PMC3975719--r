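#' Namespaced term references
#'
#' A term reference ("TermRef") is the atom of all reasoning in this package:
#' a namespace-qualified code or name rendered as `namespace:local_id`, e.g.
#' `icd:D69.6` (an ICD-10 disease code), `atc:B01AC04` (an ATC drug code),
#' `sub:lisuride` (a substance name) or `cc:bradycardia` (a custom concept
#' collection). The recognised namespaces are fixed:
#'
#' * `icd` -- ICD-10 disease codes
#' * `atc` -- Anatomical Therapeutic Chemical drug codes
#' * `unii` -- Unique Ingredient Identifiers
#' * `ictv` -- virus taxonomy identifiers
#' * `sub` -- substance common names (the objects of recommendations)
#' * `cc`  -- custom concepts and custom concept collections
#'
#' `termRef()` normalises and validates raw strings: surrounding whitespace is
#' trimmed, and the legacy collection prefix `pnc-cc:` is rewritten to `cc:`.
#' Parsing then rendering is the identity on valid refs. The local part must be
#' non-empty and free of internal whitespace (hyphens and dots are fine, as in
#' `icd:D50-D89`).
#'
#' @param x character vector of raw term references.
#' @return `termRef()`: a normalised character vector of the same length.
#'   `termNamespace()`/`termLocal()`: the namespace / local part of each ref.
#'   `isTermRef()`: logical vector.
#' @examples
#' termRef(" icd:D69.6 ")
#' termRef("pnc-cc:deficiency-bone-marrow")
#' termNamespace("atc:B01AC04")
#' @export
termRef <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- trimws(as.character(x))
  x <- sub("^pnc-cc:", "cc:", x)
  bad <- !isTermRef(x)
  if (any(bad)) {
    stop("invalid term reference(s): ",
         paste(sQuote(x[bad]), collapse = ", "),
         "; expected 'namespace:local_id' with namespace in {",
         paste(RXR_NAMESPACES, collapse = ", "), "}", call. = FALSE)
  }
  x
}

#' @rdname termRef
#' @export
isTermRef <- function(x) {
  grepl(paste0("^(", paste(RXR_NAMESPACES, collapse = "|"), "):[^[:space:]:]+$"),
        as.character(x))
}

#' @rdname termRef
#' @export
termNamespace <- function(x) sub(":.*$", "", as.character(x))

#' @rdname termRef
#' @export
termLocal <- function(x) sub("^[^:]*:", "", as.character(x))

RXR_NAMESPACES <- c("icd", "atc", "unii", "ictv", "sub", "cc")
RXR_AGE_GROUPS <- c("child", "adult", "elder", "any")
RXR_SEX_GROUPS <- c("male", "female", "any")

## namespaces whose terms denote drugs/substances vs diseases/organisms;
## cc refs are classified per collection content (see evaluation module)
RXR_DRUG_NS <- c("atc", "unii", "sub")
RXR_DISEASE_NS <- c("icd", "ictv")
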