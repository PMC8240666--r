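test_that("genotypic ambiguity resolves by family review", {
  amb <- "DPB1*04:01:01:01+DPB1*04:02:01:02|DPB1*105:01+DPB1*126:01"
  trios <- make_trio(
    father = list(DPB1 = "DPB1*04:01:01:01+DPB1*03:01:01:01"),
    mother = list(DPB1 = "DPB1*04:02:01:02+DPB1*03:01:01:01"),
    child = list(DPB1 = amb))
  res <- resolve_family_ambiguity(trios)
  expect_equal(res$DPB1[res$relation == "child"],
               "DPB1*04:01:01:01+DPB1*04:02:01:02")
  expect_false(any(grepl("[|/]", unlist(res[hla_loci()]))))
  expect_equal(nrow(attr(res, "flags")), 0L)
})

test_that("uninformative families fall back to the lowest-digit combination", {
  amb <- "DPB1*04:01:01:01+DPB1*04:02:01:02|DPB1*105:01+DPB1*126:01"
  trios <- make_trio(
    father = list(DPB1 = "DPB1*04:01:01:01/DPB1*105:01+DPB1*04:02:01:02/DPB1*126:01"),
    mother = list(DPB1 = "DPB1*04:01:01:01/DPB1*105:01+DPB1*04:02:01:02/DPB1*126:01"),
    child = list(DPB1 = amb))
  res <- resolve_family_ambiguity(trios)
  expect_equal(res$DPB1[res$relation == "child"],
               "DPB1*04:01:01:01+DPB1*04:02:01:02")
})

test_that("unambiguous trios pass through resolution unchanged", {
  trios <- make_trio(
    father = list(A = "A*01:01+A*02:01"),
    mother = list(A = "A*03:01+A*03:01"),
    child = list(A = "A*02:01+A*03:01"))
  res <- resolve_family_ambiguity(trios)
  expect_identical(res[names(trios)], trios)
})

test_that("resolution never invents alleles outside the ambiguity set", {
  set.seed(31)
  rules <- list(
    list(type = "genotypic", locus = "DPB1",
         genotype = c("DPB1*04:01:01:01", "DPB1*04:02:01:01"),
         alternative = c("DPB1*105:01", "DPB1*126:01")),
    list(type = "allelic", locus = "DQB1",
         allele = "DQB1*03:01:01:01", with = "DQB1*03:276"))
  sim <- sample_trios(30, model = disease_model(1), seed = 99)
  amb <- inject_ambiguity(sim$trios, rules)
  res <- resolve_family_ambiguity(amb)
  for (loc in hla_loci()) {
    for (i in seq_len(nrow(res))) {
      resolved <- strsplit(res[[loc]][i], "+", fixed = TRUE)[[1]]
      offered <- unique(unlist(
        hlatrio:::.gl_genotype_pairs(amb[[loc]][i])))
      expect_true(all(resolved %in% offered))
    }
  }
})

test_that("phasing assigns forced transmissions and flags ambiguity/errors", {
  # forced assignment
  t1 <- make_trio("T01",
    father = list(A = "A*01:01+A*02:01"),
    mother = list(A = "A*03:01+A*03:01"),
    child = list(A = "A*02:01+A*03:01"))
  ph <- phase_trios(t1)
  h <- ph$haplotypes
  expect_equal(h$A[h$source == "father" & h$transmitted], "A*02:01")
  expect_equal(h$A[h$source == "father" & !h$transmitted], "A*01:01")
  expect_equal(h$A[h$source == "mother" & h$transmitted], "A*03:01")
  expect_equal(nrow(ph$flags), 0L)

  # all three heterozygous for the same alleles: origin-ambiguous, but
  # allele-level T/U counts are assignment-invariant
  t2 <- make_trio("T02",
    father = list(A = "A*01:01+A*02:01"),
    mother = list(A = "A*01:01+A*02:01"),
    child = list(A = "A*01:01+A*02:01"))
  ph2 <- phase_trios(t2)
  expect_true(any(ph2$flags$flag == "origin_ambiguous" &
                    ph2$flags$locus == "A"))
  ct <- count_transmissions(ph2, "A")
  expect_equal(ct$T[ct$unit == "A*01:01"], 1L)
  expect_equal(ct$U[ct$unit == "A*01:01"], 1L)
  expect_equal(ct$T[ct$unit == "A*02:01"], 1L)
  expect_equal(ct$U[ct$unit == "A*02:01"], 1L)

  # child allele absent from both parents
  t3 <- make_trio("T03",
    father = list(A = "A*01:01+A*01:01"),
    mother = list(A = "A*01:01+A*01:01"),
    child = list(A = "A*01:01+A*11:01"))
  ph3 <- phase_trios(t3)
  expect_true(any(ph3$flags$flag == "mendel_error" & ph3$flags$locus == "A"))
  expect_true(all(is.na(ph3$haplotypes$A)))
})

test_that("decomposition projects, truncates, and respects exclusion rules", {
  sim <- sample_trios(5, seed = 5)
  ph <- phase_trios(sim$trios)
  d4 <- decompose(ph, "DRB345~DRB1", Inf)
  expect_true("DRB5*01:01:01~DRB1*15:01:01:01" %in% d4$key ||
                all(grepl("~", d4$key)))
  d2 <- decompose(ph, "DRB345~DRB1", 2)
  expect_true(all(!grepl("(:[0-9]+){2,}", d2$key)))
  # two-field keys are a coarsening of untruncated keys
  coar <- vapply(strsplit(d4$key, "~", fixed = TRUE), function(al)
    paste(truncate_allele(al, 2), collapse = "~"), "")
  expect_identical(d2$key, coar)

  # single-locus allele keys carry no '~'
  dp <- decompose(ph, "DPB1", Inf)
  expect_false(any(grepl("~", dp$key)))

  # origin-ambiguous locus: kept for the single locus, dropped for blocks
  t2 <- make_trio("T02",
    father = list(A = "A*01:01+A*02:01"),
    mother = list(A = "A*01:01+A*02:01"),
    child = list(A = "A*01:01+A*02:01"))
  ph2 <- phase_trios(t2)
  expect_equal(nrow(decompose(ph2, "A")), 4L)
  expect_equal(nrow(decompose(ph2, "A~C~B")), 0L)
})

test_that("DRB3/4/5 gene scopes project the composite slot", {
  trios <- make_trio(
    father = list(DRB345 = "DRB3*01:01:02:01+DRB4*01:03:01:01"),
    mother = list(DRB345 = "DRB345*absent+DRB345*absent"),
    child = list(DRB345 = "DRB3*01:01:02:01+DRB345*absent"))
  ph <- phase_trios(trios)
  d3 <- decompose(ph, "DRB3")
  expect_setequal(unique(d3$key), c("DRB3*01:01:02:01", "DRB3*absent"))
  d4 <- decompose(ph, "DRB4")
  expect_setequal(unique(d4$key), c("DRB4*01:03:01:01", "DRB4*absent"))
})

test_that("transmission counts match hand enumeration and balance", {
  # heterozygous father transmits the unit, mother lacks it
  t1 <- make_trio("T01",
    father = list(B = "B*07:02+B*27:05"),
    mother = list(B = "B*08:01+B*08:01"),
    child = list(B = "B*27:05+B*08:01"))
  ct <- count_transmissions(phase_trios(t1), "B", het_only = TRUE)
  expect_equal(unname(unit_tu(ct, "B*27:05")), c(1L, 0L))

  # homozygous parent contributes to both T and U in raw counts
  t2 <- make_trio("T02",
    father = list(B = "B*27:05+B*27:05"),
    mother = list(B = "B*08:01+B*08:01"),
    child = list(B = "B*27:05+B*08:01"))
  ct2 <- count_transmissions(phase_trios(t2), "B", het_only = FALSE)
  expect_equal(ct2$T[ct2$unit == "B*27:05"], 1L)
  expect_equal(ct2$U[ct2$unit == "B*27:05"], 1L)

  # 10 synthetic trios against brute-force ground-truth enumeration
  sim <- sample_trios(10, seed = 123)
  ph <- phase_trios(sim$trios)
  for (scope in c("DPB1", "DRB345~DRB1")) {
    got <- count_transmissions(ph, scope)
    want <- count_transmissions(sim$truth, scope)
    expect_equal(got, want, ignore_attr = TRUE)
    # sum T = sum U = number of counted meioses
    expect_equal(sum(got$T), sum(got$U))
    expect_equal(sum(got$T), 2L * 10L)
  }
})

test_that("phasing recovers simulated ground truth", {
  sim <- sample_trios(120, seed = 202)
  ph <- phase_trios(sim$trios)
  amb_fams <- unique(ph$flags$family_id[ph$flags$flag == "origin_ambiguous"])
  h <- ph$haplotypes[!ph$haplotypes$family_id %in% amb_fams, ]
  h0 <- sim$truth$haplotypes[!sim$truth$haplotypes$family_id %in% amb_fams, ]
  expect_identical(hap_row_key(h), hap_row_key(h0))
  # allele-level counts match ground truth even with ambiguous families
  for (loc in c("A", "DQB1")) {
    expect_equal(count_transmissions(ph, loc),
                     count_transmissions(sim$truth, loc),
                     ignore_attr = TRUE)
  }
})
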