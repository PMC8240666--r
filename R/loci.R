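#' Haplotype locus slots and analysis blocks
#'
#' The pipeline models 11 classical HLA genes (HLA-A, -C, -B, -DRB3, -DRB4,
#' -DRB5, -DRB1, -DQA1, -DQB1, -DPA1, -DPB1) as nine ordered haplotype slots:
#' the paralogous DRB3/DRB4/DRB5 genes occupy a single composite slot,
#' \code{"DRB345"}, because at most one of them is present on any haplotype.
#' A haplotype lacking all three carries the explicit absence allele
#' \code{"DRB345*absent"}.
#'
#' @return \code{hla_loci()} returns the nine slot names in chromosomal order.
#' @export
hla_loci <- function() {
  c("A", "C", "B", "DRB345", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1")
}

# genes accepted in allele names; DRB3/4/5 live in the DRB345 slot
.hla_genes <- c("A", "C", "B", "DRB1", "DRB3", "DRB4", "DRB5",
                "DQA1", "DQB1", "DPA1", "DPB1", "DRB345")

# slot that holds alleles of a gene
.gene_slot <- function(gene) {
  ifelse(gene %in% c("DRB3", "DRB4", "DRB5", "DRB345"), "DRB345", gene)
}

#' @rdname hla_loci
#' @details \code{hla_genes()} returns the 11 individually testable genes.
#' @export
hla_genes <- function() {
  c("A", "C", "B", "DRB3", "DRB4", "DRB5", "DRB1",
    "DQA1", "DQB1", "DPA1", "DPB1")
}

#' Default haplotype-block battery
#'
#' The 19 multi-locus haplotype blocks tested alongside the 11 single genes.
#' Blocks are ordered sublists of the slot order given by [hla_loci()]; they
#' range from two-locus fragments (e.g. \code{C~B}, \code{DRB345~DRB1}) to the
#' full nine-slot (11-gene) haplotype, and were chosen to separate primary
#' association signals from hitchhiking alleles carried by linkage
#' disequilibrium. Users may test any additional ordered sublist.
#'
#' @return Named list; each element is a character vector of slot names.
#' @export
hla_blocks <- function() {
  defs <- list(
    c("A", "C", "B"),
    c("A", "C", "B", "DRB1", "DQB1"),
    c("A", "C", "B", "DRB345", "DRB1", "DQA1", "DQB1"),
    c("B", "DQB1"),
    c("B", "DRB1"),
    c("C", "B"),
    c("C", "B", "DRB1", "DQB1"),
    c("C", "B", "DRB345", "DRB1", "DQA1", "DQB1"),
    c("C", "B", "DRB345", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1"),
    c("C", "DQB1"),
    c("C", "DRB1"),
    c("DPA1", "DPB1"),
    c("DQA1", "DQB1"),
    c("DRB345", "DRB1"),
    c("DRB1", "DQB1"),
    c("DRB1", "DQB1", "DPB1"),
    c("DRB345", "DRB1", "DQA1", "DQB1"),
    c("DRB345", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1"),
    c("A", "C", "B", "DRB345", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1")
  )
  names(defs) <- vapply(defs, paste, "", collapse = "~")
  defs
}

# an analysis scope: one gene or one block
#  - gene scope for DRB3/4/5 projects the composite slot onto that gene,
#    mapping alleles of the sibling paralogs (and true absence) to
#    "<gene>*absent"
.make_scope <- function(name) {
  blocks <- hla_blocks()
  if (name %in% names(blocks)) {
    list(name = name, type = "block", loci = blocks[[name]], gene = NA_character_)
  } else if (name %in% c("DRB3", "DRB4", "DRB5")) {
    list(name = name, type = "gene", loci = "DRB345", gene = name)
  } else if (name %in% hla_loci()) {
    list(name = name, type = "gene", loci = name, gene = name)
  } else {
    # custom block given as "L1~L2~..."
    loci <- strsplit(name, "~", fixed = TRUE)[[1]]
    bad <- setdiff(loci, hla_loci())
    if (length(bad))
      stop("unknown locus in scope '", name, "': ", paste(bad, collapse = ", "))
    if (is.unsorted(match(loci, hla_loci())))
      stop("block loci must respect chromosomal order: ", name)
    list(name = name, type = "block", loci = loci, gene = NA_character_)
  }
}

#' Scopes of the standard test battery
#'
#' The 30 analysis scopes of the default battery: the 11 HLA genes plus the
#' 19 haplotype blocks of [hla_blocks()]. Crossed with the two nomenclature
#' resolutions (untruncated and two-field) this yields the 60 standard test
#' groups.
#'
#' @return Character vector of 30 scope names.
#' @export
analysis_scopes <- function() {
  c(hla_genes(), names(hla_blocks()))
}
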