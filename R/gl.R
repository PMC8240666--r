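#' Parse a Genotype List (GL) string
#'
#' GL strings encode HLA typing results with five operators, from loosest to
#' tightest binding: \code{^} separates loci, \code{|} separates alternative
#' phased genotypes (genotypic / "phase" ambiguity), \code{+} joins the two
#' copies of a genotype, \code{~} joins in-phase alleles of a haplotype, and
#' \code{/} separates allelically ambiguous names for one copy.
#'
#' @param text A GL string.
#' @return A \code{gl_node} tree. Interior nodes are lists with elements
#'   \code{op} (one of \code{"^" "|" "+" "~" "/"}) and \code{children};
#'   leaves have \code{op = "allele"} and the allele name in \code{allele}.
#'   Every leaf is validated with [parse_allele()]; \code{+} nodes have
#'   exactly two children.
#' @examples
#' g <- parse_gl("DPB1*04:01:01:01+DPB1*04:02:01:02|DPB1*105:01+DPB1*126:01")
#' format_gl(g)
#' @export
parse_gl <- function(text) {
  if (length(text) != 1L || is.na(text)) stop("GL string must be a single string")
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop("empty GL string")
  .gl_parse_level(s, 1L)
}

.gl_ops <- c("^", "|", "+", "~", "/")

.gl_parse_level <- function(s, level) {
  if (level > length(.gl_ops)) {
    a <- parse_allele(s)  # validates; raises on malformed leaves
    return(structure(list(op = "allele", allele = format_allele(a)),
                     class = "gl_node"))
  }
  op <- .gl_ops[level]
  first <- substr(s, 1L, 1L); last <- substr(s, nchar(s), nchar(s))
  if (first %in% .gl_ops || last %in% .gl_ops)
    stop("unbalanced '", if (first %in% .gl_ops) first else last,
         "' operator in GL string: ", s)
  parts <- strsplit(s, op, fixed = TRUE)[[1]]
  if (any(!nzchar(parts)) || length(parts) == 0L)
    stop("unbalanced '", op, "' operator in GL string: ", s)
  if (length(parts) == 1L) return(.gl_parse_level(s, level + 1L))
  if (op == "+" && length(parts) != 2L)
    stop("'+' must join exactly two copies: ", s)
  structure(list(op = op,
                 children = lapply(parts, .gl_parse_level, level = level + 1L)),
            class = "gl_node")
}

#' Serialize a GL genotype tree
#'
#' Inverse of [parse_gl()]: \code{format_gl(parse_gl(s))} equals \code{s} up
#' to whitespace, and \code{parse_gl(format_gl(g))} reproduces \code{g}.
#'
#' @param g A \code{gl_node}.
#' @return Character scalar.
#' @export
format_gl <- function(g) {
  stopifnot(inherits(g, "gl_node"))
  if (g$op == "allele") return(g$allele)
  paste(vapply(g$children, format_gl, ""), collapse = g$op)
}

#' @export
print.gl_node <- function(x, ...) {
  cat("<gl_node> ", format_gl(x), "\n", sep = "")
  invisible(x)
}

# Expand a single-locus GL genotype into its candidate unordered allele pairs.
# Returns a list of length-2 character vectors, each sorted canonically.
# Accepts '|' genotypic alternatives and '/' allelic ambiguity; a bare allele
# is interpreted as homozygous shorthand.
.gl_genotype_pairs <- function(text) {
  node <- parse_gl(text)
  if (node$op %in% c("^", "~"))
    stop("expected a single-locus genotype, got operator '", node$op, "': ", text)
  alts <- if (node$op == "|") node$children else list(node)
  pairs <- list()
  for (alt in alts) {
    if (alt$op == "+") {
      sides <- lapply(alt$children, .gl_allele_choices)
    } else {
      sides <- list(.gl_allele_choices(alt), .gl_allele_choices(alt))
    }
    for (x in sides[[1]]) for (y in sides[[2]]) {
      pr <- c(x, y)[allele_order(c(x, y))]
      pairs[[length(pairs) + 1L]] <- pr
    }
  }
  unique(pairs)
}

# allele choices of a '/' node or leaf
.gl_allele_choices <- function(node) {
  if (node$op == "allele") return(node$allele)
  if (node$op == "/") return(vapply(node$children, function(ch) {
    if (ch$op != "allele") stop("'/' may only join allele names")
    ch$allele
  }, ""))
  stop("unexpected operator '", node$op, "' inside a genotype copy")
}

# canonical unphased genotype string from an allele pair
.gl_pair_string <- function(pair) paste(pair, collapse = "+")
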