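# Fixture builders: trio tables constructed in code, with uninvolved loci
# held at a fixed homozygous genotype so single-locus scenarios stay simple.

baseline_genotypes <- function() {
  c(A = "A*01:01+A*01:01", C = "C*01:02+C*01:02", B = "B*07:02+B*07:02",
    DRB345 = "DRB345*absent+DRB345*absent", DRB1 = "DRB1*01:01+DRB1*01:01",
    DQA1 = "DQA1*01:01+DQA1*01:01", DQB1 = "DQB1*05:01+DQB1*05:01",
    DPA1 = "DPA1*01:03+DPA1*01:03", DPB1 = "DPB1*04:01+DPB1*04:01")
}

make_trio <- function(family_id = "T1", father = list(), mother = list(),
                      child = list()) {
  row <- function(rel, mods) {
    g <- baseline_genotypes()
    g[names(mods)] <- unlist(mods)
    cbind(data.frame(family_id = family_id,
                     subject_id = paste0(family_id, "_", rel),
                     relation = rel, stringsAsFactors = FALSE),
          as.data.frame(t(g), stringsAsFactors = FALSE))
  }
  rbind(row("father", father), row("mother", mother), row("child", child))
}

make_trios <- function(...) {
  specs <- list(...)
  do.call(rbind, lapply(seq_along(specs), function(i)
    do.call(make_trio, c(list(family_id = sprintf("T%02d", i)), specs[[i]]))))
}

# full haplotype key of phased haplotype rows, for ground-truth comparisons
hap_row_key <- function(h) {
  apply(h[, c("family_id", "source", "transmitted", hlatrio::hla_loci())],
        1L, paste, collapse = "|")
}

# heterozygous-parent T/U counts for one unit from a transmission table
unit_tu <- function(ct, unit) {
  w <- attr(ct, "contributions")
  c(T = sum(w$key_t == unit & w$key_u != unit),
    U = sum(w$key_u == unit & w$key_t != unit))
}

# small three-haplotype pool for focused simulations
mini_pool <- function() {
  pool <- hlatrio::default_pool()[1:6, ]
  pool$freq <- pool$freq / sum(pool$freq)
  pool
}
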