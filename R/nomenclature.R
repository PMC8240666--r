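#' Parse an HLA allele name
#'
#' Parses names of the form \code{LOCUS*f1:f2:f3:f4} with one to four numeric
#' colon-separated fields and an optional trailing expression suffix
#' (N, L, S, C, A or Q). A leading \code{"HLA-"} namespace prefix is accepted
#' and stripped. The designated absence token for the composite DRB3/4/5 slot
#' (e.g. \code{"DRB345*absent"}) parses to an allele with \code{absent = TRUE}
#' and no fields.
#'
#' @param text A single allele name.
#' @return An object of class \code{hla_allele}: a list with elements
#'   \code{locus}, \code{fields} (integer vector), \code{suffix}
#'   (character or \code{NA}) and \code{absent} (logical).
#' @examples
#' parse_allele("DRB1*15:01:01:01")
#' parse_allele("HLA-A*02:01")
#' @export
parse_allele <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("allele name must be a single non-empty string")
  s <- sub("^HLA-", "", trimws(text))
  star <- regexpr("*", s, fixed = TRUE)
  if (star < 0L) stop("malformed allele name (missing '*'): ", text)
  locus <- substr(s, 1L, star - 1L)
  rest <- substr(s, star + 1L, nchar(s))
  if (!locus %in% .hla_genes) stop("unknown HLA locus: '", locus, "'")
  if (identical(rest, "absent")) {
    if (!.gene_slot(locus) == "DRB345")
      stop("absence token only allowed for DRB3/4/5: ", text)
    return(structure(list(locus = locus, fields = integer(0),
                          suffix = NA_character_, absent = TRUE),
                     class = "hla_allele"))
  }
  suffix <- NA_character_
  if (grepl("[NLSCAQ]$", rest)) {
    suffix <- substr(rest, nchar(rest), nchar(rest))
    rest <- substr(rest, 1L, nchar(rest) - 1L)
  }
  if (!nzchar(rest)) stop("empty field list in allele name: ", text)
  parts <- strsplit(rest, ":", fixed = TRUE)[[1]]
  if (length(parts) < 1L || length(parts) > 4L ||
      any(!nzchar(parts)) || any(!grepl("^[0-9]+$", parts)))
    stop("malformed allele fields in: ", text)
  structure(list(locus = locus, fields = as.integer(parts),
                 suffix = suffix, absent = FALSE),
            class = "hla_allele")
}

#' Serialize an HLA allele name
#'
#' Inverse of [parse_allele()]: \code{format_allele(parse_allele(x))} returns
#' \code{x} with any \code{"HLA-"} prefix stripped.
#'
#' @param a An \code{hla_allele}.
#' @param prefix Prepend the \code{"HLA-"} namespace prefix?
#' @return Character scalar.
#' @export
format_allele <- function(a, prefix = FALSE) {
  stopifnot(inherits(a, "hla_allele"))
  body <- if (a$absent) "absent" else
    paste0(paste(sprintf("%02d", a$fields), collapse = ":"),
           if (!is.na(a$suffix)) a$suffix else "")
  paste0(if (prefix) "HLA-" else "", a$locus, "*", body)
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele> ", format_allele(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.hla_allele <- function(x, ...) format_allele(x)

#' @export
as.character.hla_allele <- function(x, ...) format_allele(x)

#' Truncate an allele name to a lower field count
#'
#' Keeps the first \code{min(n_fields, length(fields))} fields. The expression
#' suffix is dropped whenever fields are actually removed (it qualifies the
#' full-resolution name). Truncation of the absence token is the identity.
#' Truncation is idempotent and never increases the field count.
#'
#' @param a An \code{hla_allele} or a character vector of allele names.
#' @param n_fields Number of fields to retain (>= 1); use \code{Inf} for
#'   untruncated names.
#' @return Same type as the input.
#' @examples
#' truncate_allele("DRB1*15:01:01:01", 2)  # "DRB1*15:01"
#' @export
truncate_allele <- function(a, n_fields) {
  if (!is.infinite(n_fields) && (!is.numeric(n_fields) || n_fields < 1))
    stop("n_fields must be >= 1")
  UseMethod("truncate_allele")
}

#' @export
truncate_allele.hla_allele <- function(a, n_fields) {
  if (a$absent || length(a$fields) <= n_fields) return(a)
  a$fields <- a$fields[seq_len(n_fields)]
  a$suffix <- NA_character_
  a
}

#' @export
truncate_allele.character <- function(a, n_fields) {
  if (is.infinite(n_fields)) return(a)
  vapply(a, function(s) {
    if (is.na(s)) return(NA_character_)
    format_allele(truncate_allele(parse_allele(s), n_fields))
  }, "", USE.NAMES = FALSE)
}

#' Sort key defining the canonical allele order
#'
#' Total order used for "lowest-digit priority" choices: loci compare
#' lexicographically, then numeric field by field, with a shorter field list
#' sorting before any extension of it (\code{04:01} before \code{04:01:01}).
#' The absence token sorts after every real allele of its locus. Expression
#' suffixes are ignored. Keys are plain ASCII strings meant to be compared
#' byte-wise; use [allele_order()] / \code{sort(..., method = "radix")} so
#' the comparison is locale-independent.
#'
#' @param a An \code{hla_allele} or character vector of allele names.
#' @return Character key(s).
#' @export
allele_sort_key <- function(a) {
  UseMethod("allele_sort_key")
}

#' @export
allele_sort_key.hla_allele <- function(a) {
  body <- if (a$absent) "~absent" else
    paste(sprintf("%04d", a$fields), collapse = ":")
  sprintf("%-7s*%s", a$locus, body)
}

#' @export
allele_sort_key.character <- function(a) {
  vapply(a, function(s) allele_sort_key(parse_allele(s)), "", USE.NAMES = FALSE)
}

#' @rdname allele_sort_key
#' @param x Character vector of allele names.
#' @return \code{allele_order(x)} returns the permutation ordering \code{x}.
#' @export
allele_order <- function(x) {
  order(allele_sort_key(x), method = "radix")
}

# byte-wise minimum under the canonical order; x a character vector
.allele_min <- function(x) x[allele_order(x)[1L]]
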