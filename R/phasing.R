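# ---- internal vectorized allele-name helpers (fast paths used throughout) ----

# locale-independent sort key, vectorized; assumes syntactically valid names
.akey <- function(x) {
  x <- sub("^HLA-", "", x)
  star <- regexpr("*", x, fixed = TRUE)
  locus <- substr(x, 1L, star - 1L)
  body <- substr(x, star + 1L, nchar(x))
  out <- character(length(x))
  ab <- body == "absent"
  if (any(ab)) out[ab] <- sprintf("%-7s*~absent", locus[ab])
  if (any(!ab)) {
    b <- sub("[NLSCAQ]$", "", body[!ab])
    padded <- vapply(strsplit(b, ":", fixed = TRUE), function(f)
      paste(sprintf("%04d", as.integer(f)), collapse = ":"), "")
    out[!ab] <- sprintf("%-7s*%s", locus[!ab], padded)
  }
  out
}

# vectorized truncation; n = 2 or Inf in the standard battery
.atrunc <- function(x, n) {
  if (is.infinite(n)) return(x)
  star <- regexpr("*", x, fixed = TRUE)
  locus <- substr(x, 1L, star - 1L)
  body <- substr(x, star + 1L, nchar(x))
  vapply(seq_along(x), function(i) {
    if (is.na(x[i]) || body[i] == "absent") return(x[i])
    f <- strsplit(body[i], ":", fixed = TRUE)[[1]]
    if (length(f) <= n) return(x[i])
    paste0(locus[i], "*", paste(f[seq_len(n)], collapse = ":"))
  }, NA_character_)
}

.agene <- function(x) sub("\\*.*$", "", sub("^HLA-", "", x))

.valid_allele_re <-
  "^(HLA-)?(A|C|B|DRB1|DRB3|DRB4|DRB5|DRB345|DQA1|DQB1|DPA1|DPB1)\\*([0-9]+(:[0-9]+){0,3}[NLSCAQ]?|absent)$"

# candidate unordered allele pairs of one genotype string; fast path for the
# unambiguous "a+b" form, full GL expansion otherwise
.genotype_pairs <- function(s) {
  if (!grepl("[|/~^]", s)) {
    al <- sub("^HLA-", "", strsplit(s, "+", fixed = TRUE)[[1]])
    if (length(al) == 1L) al <- c(al, al)
    if (length(al) != 2L || any(!grepl(.valid_allele_re, al)))
      stop("malformed genotype: ", s)
    return(list(al[order(.akey(al), method = "radix")]))
  }
  .gl_genotype_pairs(s)
}

.mendel_ok <- function(f, m, c) {
  (c[1] %in% f && c[2] %in% m) || (c[2] %in% f && c[1] %in% m)
}

.pair_other <- function(pair, allele) {
  if (pair[1] == allele) pair[2] else pair[1]
}

# choose the Mendel-consistent (child, father, mother) genotype combination,
# lowest-digit priority on ties; NULL when no combination is consistent
.resolve_locus <- function(pf, pm, pc) {
  cand <- list(); keys <- character(0)
  for (cc in pc) for (ff in pf) for (mm in pm) {
    if (.mendel_ok(ff, mm, cc)) {
      cand[[length(cand) + 1L]] <- list(c = cc, f = ff, m = mm)
      keys <- c(keys, paste(.akey(c(cc, ff, mm)), collapse = "\x01"))
    }
  }
  if (!length(cand)) return(NULL)
  cand[[order(keys, method = "radix")[1L]]]
}

#' Resolve allelic and genotypic ambiguity by family review
#'
#' For every subject-locus with \code{/} (allelic) or \code{|} (genotypic)
#' ambiguity, retains the genotype combination compatible with Mendelian
#' segregation across the trio. When several combinations remain (the family
#' is uninformative), the lowest-digit combination under the canonical allele
#' order is kept, child first, then father, then mother. The returned table
#' is free of \code{/} and \code{|} operators; the resolved genotype is
#' always drawn from the input's own ambiguity set. A locus where no
#' combination is Mendel-compatible is left at its per-subject lowest-digit
#' genotype and flagged as a Mendelian error.
#'
#' @param trios A trio table (see [read_trio_table()]).
#' @return The resolved trio table, with attribute \code{"flags"}: a data
#'   frame of \code{family_id}, \code{locus}, \code{flag}.
#' @export
resolve_family_ambiguity <- function(trios) {
  .validate_trio_table(trios)
  flags <- list()
  for (fam in unique(trios$family_id)) {
    rows <- which(trios$family_id == fam)
    ir <- rows[match(c("father", "mother", "child"), trios$relation[rows])]
    if (anyNA(ir)) stop("family ", fam, " is not a complete trio")
    for (loc in hla_loci()) {
      gs <- trios[[loc]][ir]
      if (!any(grepl("[|/]", gs))) next
      pf <- .genotype_pairs(gs[1]); pm <- .genotype_pairs(gs[2])
      pc <- .genotype_pairs(gs[3])
      res <- .resolve_locus(pf, pm, pc)
      if (is.null(res)) {
        flags[[length(flags) + 1L]] <-
          data.frame(family_id = fam, locus = loc, flag = "mendel_error")
        res <- list(f = .lowest_pair(pf), m = .lowest_pair(pm),
                    c = .lowest_pair(pc))
      }
      trios[[loc]][ir] <- c(.gl_pair_string(res$f), .gl_pair_string(res$m),
                            .gl_pair_string(res$c))
    }
  }
  attr(trios, "flags") <- if (length(flags)) do.call(rbind, flags) else
    data.frame(family_id = character(0), locus = character(0),
               flag = character(0))
  trios
}

.lowest_pair <- function(pairs) {
  keys <- vapply(pairs, function(p) paste(.akey(p), collapse = "\x01"), "")
  pairs[[order(keys, method = "radix")[1L]]]
}

#' Phase trio families into transmitted and non-transmitted haplotypes
#'
#' Resolves remaining ambiguity (via [resolve_family_ambiguity()]), then, per
#' locus, assigns the child's two alleles to the transmitting parents by
#' Mendelian segregation. Each resolved trio yields four haplotypes: the
#' paternal and maternal transmitted haplotypes (the alleles each parent gave
#' the child) and their non-transmitted complements.
#'
#' A locus where both assignment orders are Mendel-consistent (father, mother
#' and child heterozygous for the same two alleles) is flagged
#' \code{origin_ambiguous}; the sort-minimal child allele is assigned as
#' paternal, a choice that leaves allele-level transmission counts invariant.
#' A locus where the child carries an allele absent from a parent is flagged
#' \code{mendel_error} and set to \code{NA} in all four haplotypes; the family
#' is later excluded from blocks containing that locus only.
#'
#' @param trios A trio table.
#' @return An object of class \code{hla_phased}: list with
#'   \code{haplotypes} (data frame: \code{family_id}, \code{source}
#'   (\code{father}/\code{mother}), \code{transmitted} (logical), one column
#'   per slot) and \code{flags} (data frame: \code{family_id}, \code{locus},
#'   \code{flag}).
#' @export
phase_trios <- function(trios) {
  trios <- resolve_family_ambiguity(trios)
  flags <- attr(trios, "flags")
  fams <- unique(trios$family_id)
  loci <- hla_loci()
  nf <- length(fams)
  hap <- matrix(NA_character_, nrow = 4L * nf, ncol = length(loci),
                dimnames = list(NULL, loci))
  newflags <- list()
  for (k in seq_len(nf)) {
    fam <- fams[k]
    rows <- which(trios$family_id == fam)
    ir <- rows[match(c("father", "mother", "child"), trios$relation[rows])]
    base <- 4L * (k - 1L)
    for (j in seq_along(loci)) {
      loc <- loci[j]
      fp <- .genotype_pairs(trios[[loc]][ir[1]])[[1]]
      mp <- .genotype_pairs(trios[[loc]][ir[2]])[[1]]
      cp <- .genotype_pairs(trios[[loc]][ir[3]])[[1]]
      opt1 <- cp[1] %in% fp && cp[2] %in% mp
      opt2 <- cp[2] %in% fp && cp[1] %in% mp
      if (!opt1 && !opt2) {
        newflags[[length(newflags) + 1L]] <-
          data.frame(family_id = fam, locus = loc, flag = "mendel_error")
        next
      }
      if (opt1 && opt2 && cp[1] != cp[2]) {
        newflags[[length(newflags) + 1L]] <-
          data.frame(family_id = fam, locus = loc, flag = "origin_ambiguous")
      }
      if (opt1) { pat <- cp[1]; mat <- cp[2] } else { pat <- cp[2]; mat <- cp[1] }
      hap[base + 1L, j] <- pat
      hap[base + 2L, j] <- .pair_other(fp, pat)
      hap[base + 3L, j] <- mat
      hap[base + 4L, j] <- .pair_other(mp, mat)
    }
  }
  haplotypes <- data.frame(
    family_id = rep(fams, each = 4L),
    source = rep(c("father", "father", "mother", "mother"), nf),
    transmitted = rep(c(TRUE, FALSE, TRUE, FALSE), nf),
    hap, check.names = FALSE, stringsAsFactors = FALSE)
  allflags <- rbind(flags, if (length(newflags)) do.call(rbind, newflags))
  allflags <- unique(allflags)
  structure(list(haplotypes = haplotypes, flags = allflags,
                 families = fams),
            class = "hla_phased")
}

#' @export
print.hla_phased <- function(x, ...) {
  cat("<hla_phased> ", length(x$families), " trio families, ",
      nrow(x$haplotypes), " haplotypes; ",
      sum(x$flags$flag == "origin_ambiguous"), " origin-ambiguous and ",
      sum(x$flags$flag == "mendel_error"), " Mendel-inconsistent locus flags\n",
      sep = "")
  invisible(x)
}

# families excluded for a scope: Mendel errors always; origin ambiguity only
# for multi-locus blocks (allele-level counts are assignment-invariant)
.excluded_families <- function(phased, loci) {
  fl <- phased$flags
  fl <- fl[fl$locus %in% loci &
             (fl$flag == "mendel_error" |
                (fl$flag == "origin_ambiguous" & length(loci) > 1L)), ,
           drop = FALSE]
  unique(fl$family_id)
}

#' Project phased haplotypes onto an analysis scope
#'
#' Restricts each haplotype to the loci of a haplotype block (or one gene),
#' truncates allele names to the requested resolution, and joins them with
#' \code{~} into a block-haplotype key. Families with a Mendel-inconsistent
#' locus inside the scope are dropped; families with an origin-ambiguous
#' locus are additionally dropped for multi-locus blocks but retained for
#' single-gene scopes, where allele-level counts do not depend on the
#' assignment. For the DRB3/DRB4/DRB5 gene scopes, alleles of the sibling
#' paralogs (and true absence) project to \code{"<gene>*absent"}.
#'
#' @param phased An \code{hla_phased} object from [phase_trios()].
#' @param scope A scope name (gene, e.g. \code{"DPB1"}; or block, e.g.
#'   \code{"DRB345~DRB1"}) or a character vector of slot names.
#' @param n_fields Allele resolution: \code{2} for two-field, \code{Inf} for
#'   untruncated.
#' @return Data frame with \code{family_id}, \code{source},
#'   \code{transmitted}, \code{key}.
#' @export
decompose <- function(phased, scope, n_fields = Inf) {
  stopifnot(inherits(phased, "hla_phased"))
  sc <- if (length(scope) > 1L) .make_scope(paste(scope, collapse = "~"))
        else .make_scope(scope)
  h <- phased$haplotypes
  drop <- .excluded_families(phased, sc$loci)
  h <- h[!h$family_id %in% drop, , drop = FALSE]
  keep <- stats::complete.cases(h[, sc$loci, drop = FALSE])
  h <- h[keep, , drop = FALSE]
  keymat <- vapply(sc$loci, function(loc) {
    al <- h[[loc]]
    if (!is.na(sc$gene) && sc$gene %in% c("DRB3", "DRB4", "DRB5")) {
      al <- ifelse(.agene(al) == sc$gene, al, paste0(sc$gene, "*absent"))
    }
    .atrunc(al, n_fields)
  }, character(nrow(h)))
  if (nrow(h) == 1L) keymat <- matrix(keymat, nrow = 1L)
  data.frame(family_id = h$family_id, source = h$source,
             transmitted = h$transmitted,
             key = apply(keymat, 1L, paste, collapse = "~"),
             stringsAsFactors = FALSE)
}

#' Transmitted / non-transmitted counts per haplotype or allele
#'
#' Tabulates, over all counted parental meioses, how often each
#' block-haplotype (or allele) key was transmitted to the affected child
#' (\code{T}) and how often it was not (\code{U}). A parent homozygous for a
#' key contributes one count to both \code{T} and \code{U} — present in
#' raw segregation tables but uninformative for the TDT, which is restricted
#' to heterozygous parents via \code{het_only = TRUE}.
#'
#' @inheritParams decompose
#' @param het_only Count only parents heterozygous for the scope key.
#' @return Data frame with \code{unit}, \code{T}, \code{U}, ordered by key;
#'   attribute \code{"contributions"} logs the per-parent transmitted and
#'   untransmitted keys.
#' @export
count_transmissions <- function(phased, scope, n_fields = Inf,
                                het_only = FALSE) {
  d <- decompose(phased, scope, n_fields)
  w <- .pair_keys(d)
  if (het_only) w <- w[w$key_t != w$key_u, , drop = FALSE]
  units <- sort(unique(c(w$key_t, w$key_u)), method = "radix")
  out <- data.frame(
    unit = units,
    T = as.integer(table(factor(w$key_t, levels = units))),
    U = as.integer(table(factor(w$key_u, levels = units))),
    stringsAsFactors = FALSE)
  attr(out, "contributions") <- w
  out
}

# wide per-parent view: one row per (family, source) with transmitted and
# untransmitted keys
.pair_keys <- function(d) {
  t_part <- d[d$transmitted, c("family_id", "source", "key")]
  u_part <- d[!d$transmitted, c("family_id", "source", "key")]
  names(t_part)[3] <- "key_t"; names(u_part)[3] <- "key_u"
  merge(t_part, u_part, by = c("family_id", "source"), sort = TRUE)
}
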