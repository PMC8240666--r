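# ---- unit keys -------------------------------------------------------------

# slots spanned by a unit key such as "DRB5*01:01:01~DRB1*15:01:01:01"
.unit_slots <- function(unit) {
  alleles <- strsplit(unit, "~", fixed = TRUE)[[1]]
  slots <- .gene_slot(.agene(alleles))
  if (anyDuplicated(slots)) stop("unit key repeats a haplotype slot: ", unit)
  if (is.unsorted(match(slots, hla_loci())))
    stop("unit key loci out of chromosomal order: ", unit)
  slots
}

# field depth of each allele in a unit key (absence token counts as Inf)
.unit_depths <- function(unit) {
  alleles <- strsplit(unit, "~", fixed = TRUE)[[1]]
  body <- sub("^[^*]+\\*", "", alleles)
  ifelse(body == "absent", Inf,
         lengths(strsplit(body, ":", fixed = TRUE)))
}

# project rows of a haplotype matrix/data frame onto a unit's slots and
# compare with the unit key; n_fields = NULL matches each slot at the unit
# allele's own field depth
.hap_matches_unit <- function(h, unit, n_fields = Inf) {
  slots <- .unit_slots(unit)
  depths <- if (is.null(n_fields)) .unit_depths(unit)
            else rep(n_fields, length(slots))
  keys <- vapply(seq_along(slots), function(j)
    .atrunc(h[[slots[j]]], depths[j]), character(nrow(h)))
  if (nrow(h) == 1L) keys <- matrix(keys, nrow = 1L)
  apply(keys, 1L, paste, collapse = "~") == unit
}

# ---- haplotype pool and disease model --------------------------------------

#' Default synthetic haplotype pool
#'
#' Thirty multi-locus haplotype templates with frequencies patterned on a
#' European-ancestry population, including a
#' \code{DRB5*01:01:01~DRB1*15:01:01:01}-bearing haplotype at frequency 0.14
#' and a \code{DPB1*104:01}-bearing haplotype at 0.018. Third- and
#' fourth-field name variants are largely haplotype-specific, as with
#' full-gene sequencing, which keeps origin-ambiguous loci rare in simulated
#' trios. Fully replaceable by any data frame with a \code{freq} column and
#' one allele column per slot of [hla_loci()].
#'
#' @return Data frame with columns \code{freq} and the nine slots.
#' @export
default_pool <- function() {
  rows <- c(
    "0.1400 A*03:01:01:01 C*07:02:01:03 B*07:02:01    DRB5*01:01:01    DRB1*15:01:01:01 DQA1*01:02:01:01 DQB1*06:02:01:01 DPA1*01:03:01:02 DPB1*04:01:01:01",
    "0.1000 A*01:01:01:01 C*07:01:01:01 B*08:01:01:01 DRB3*01:01:02:01 DRB1*03:01:01:01 DQA1*05:01:01:02 DQB1*02:01:01    DPA1*01:03:01:01 DPB1*01:01:01:01",
    "0.0800 A*02:01:01:01 C*05:01:01:02 B*44:02:01:01 DRB4*01:03:01:01 DRB1*04:01:01:01 DQA1*03:03:01:01 DQB1*03:01:01:01 DPA1*01:03:01:03 DPB1*03:01:01:01",
    "0.0700 A*29:02:01:01 C*16:01:01:01 B*44:03:01:01 DRB3*02:02:01:02 DRB1*11:01:01:01 DQA1*05:05:01:01 DQB1*03:01:01:03 DPA1*02:01:01:01 DPB1*14:01:01:01",
    "0.0600 A*02:01:01:01 C*03:04:01:01 B*40:01:02    DRB4*01:03:01:03 DRB1*04:04:01:01 DQA1*03:01:01:01 DQB1*03:02:01:01 DPA1*01:03:01:04 DPB1*04:02:01:02",
    "0.0550 A*01:01:01:02 C*06:02:01:01 B*57:01:01:01 DRB4*01:03:01:02N DRB1*07:01:01:01 DQA1*02:01:01:01 DQB1*03:03:02:01 DPA1*01:03:01:05 DPB1*04:01:01:02",
    "0.0450 A*03:01:01:02 C*02:02:02:01 B*27:05:02    DRB345*absent    DRB1*01:01:01    DQA1*01:01:01:01 DQB1*05:01:01:01 DPA1*01:03:01:06 DPB1*04:02:01:01",
    "0.0400 A*11:01:01:01 C*04:01:01:06 B*35:01:01:02 DRB345*absent    DRB1*01:01:01    DQA1*01:01:01:02 DQB1*05:01:01:02 DPA1*01:03:01:07 DPB1*02:01:02:01",
    "0.0180 A*02:01:01:03 C*03:03:01:01 B*15:01:01:01 DRB4*01:01:01:01 DRB1*04:02:01:01 DQA1*03:01:01:02 DQB1*03:02:01:02 DPA1*01:03:01:02 DPB1*104:01",
    "0.0060 A*24:02:01:01 C*12:03:01:01 B*18:01:01:02 DRB3*02:02:01:01 DRB1*13:02:01:01 DQA1*01:02:02:01 DQB1*06:04:01:01 DPA1*01:04:01:01 DPB1*09:01:01",
    "0.0250 A*24:02:01:02 C*04:01:01:01 B*35:02:01:01 DRB3*02:02:01:03 DRB1*13:01:01:01 DQA1*01:03:01:02 DQB1*06:03:01:01 DPA1*02:01:01:02 DPB1*10:01:01:01",
    "0.0250 A*25:01:01:01 C*12:03:01:02 B*18:01:01:01 DRB3*01:01:02:02 DRB1*13:03:01:01 DQA1*05:05:01:02 DQB1*03:01:01:02 DPA1*02:01:01:05 DPB1*05:01:01:01",
    "0.0230 A*26:01:01:01 C*12:03:01:03 B*38:01:01:01 DRB3*03:01:01:01 DRB1*13:02:01:02 DQA1*01:02:02:02 DQB1*06:09:01:01 DPA1*02:01:02:01 DPB1*06:01:01:01",
    "0.0220 A*32:01:01:01 C*07:02:01:01 B*39:06:02:01 DRB5*01:02:01:01 DRB1*15:02:01:01 DQA1*01:03:01:01 DQB1*06:01:01:01 DPA1*02:02:02:01 DPB1*13:01:01:01",
    "0.0220 A*68:01:02:01 C*07:04:01:01 B*44:02:01:03 DRB4*01:01:01:02 DRB1*07:01:01:02 DQA1*02:01:01:02 DQB1*02:02:01:01 DPA1*01:03:01:31 DPB1*11:01:01:01",
    "0.0220 A*23:01:01:01 C*04:01:01:05 B*44:03:01:02 DRB4*01:01:01:03 DRB1*04:05:01:01 DQA1*03:03:01:02 DQB1*03:02:01:03 DPA1*02:01:01:07 DPB1*17:01:01:01",
    "0.0220 A*30:01:01:01 C*06:02:01:02 B*13:02:01:01 DRB4*01:03:02:01 DRB1*07:01:01:03 DQA1*02:01:01:03 DQB1*03:03:02:02 DPA1*01:03:01:08 DPB1*16:01:01:01",
    "0.0210 A*33:01:01:01 C*08:02:01:01 B*14:02:01:01 DRB3*02:02:01:04 DRB1*01:02:01:01 DQA1*01:01:02:01 DQB1*05:01:01:03 DPA1*01:03:01:09 DPB1*15:01:01:01",
    "0.0200 A*02:05:01:01 C*16:02:01:01 B*51:01:01:01 DRB3*01:01:03:01 DRB1*14:01:01:01 DQA1*01:04:01:01 DQB1*05:03:01:01 DPA1*01:03:01:10 DPB1*19:01:01:01",
    "0.0190 A*30:02:01:01 C*05:01:01:01 B*18:01:01:03 DRB3*02:02:01:05 DRB1*03:02:01:01 DQA1*04:01:01:01 DQB1*04:02:01:01 DPA1*03:01:01:01 DPB1*105:01",
    "0.0190 A*31:01:02:01 C*15:02:01:01 B*51:01:01:02 DRB5*02:02:01:01  DRB1*16:01:01:01 DQA1*01:02:02:03 DQB1*05:02:01:01 DPA1*02:01:01:03 DPB1*126:01",
    "0.0180 A*68:02:01:01 C*15:05:01:01 B*15:01:01:04 DRB4*01:03:01:04 DRB1*04:07:01:01 DQA1*03:01:01:03 DQB1*03:01:01:04 DPA1*01:03:01:11 DPB1*20:01:01:01",
    "0.0170 A*02:06:01:01 C*01:02:01:01 B*39:01:01:01  DRB345*absent    DRB1*10:01:01:01 DQA1*01:05:01:01 DQB1*05:01:01:04 DPA1*01:03:01:12 DPB1*04:01:01:03",
    "0.0160 A*24:03:01:01 C*03:04:01:02 B*40:01:02    DRB4*01:03:01:05 DRB1*04:03:01:01 DQA1*03:01:01:04 DQB1*03:05:01:01 DPA1*01:03:01:13 DPB1*23:01:01:01",
    "0.0150 A*66:01:01:01 C*17:01:01:01 B*41:01:01:01 DRB3*02:02:01:06 DRB1*12:01:01:01 DQA1*05:05:01:03 DQB1*03:01:01:05 DPA1*02:01:01:04 DPB1*34:01:01:01",
    "0.0140 A*29:01:01:01 C*07:02:01:05 B*07:05:01:01 DRB5*01:02:01:02 DRB1*15:03:01:01 DQA1*01:02:01:02 DQB1*06:02:01:02 DPA1*01:03:01:14 DPB1*18:01:01:01",
    "0.0180 A*02:02:01:01 C*06:02:01:03 B*50:01:01:01 DRB3*01:01:02:03 DRB1*03:01:01:02 DQA1*05:01:01:03 DQB1*02:01:08    DPA1*01:03:01:15 DPB1*40:01:01:01",
    "0.0170 A*34:02:01:01 C*04:07:01:01 B*53:01:01:01 DRB3*03:01:03:01 DRB1*13:04:01:01 DQA1*05:05:01:04 DQB1*03:19:01:01 DPA1*02:01:01:06 DPB1*30:01:01:01",
    "0.0160 A*36:01:01:01 C*04:01:01:11 B*35:01:01:06 DRB4*01:03:03:01 DRB1*09:01:02:01 DQA1*03:02:01:01 DQB1*03:03:02:03 DPA1*01:03:01:16 DPB1*46:01:01:01",
    "0.0150 A*74:01:01:01 C*02:10:01:01 B*58:02:01:01 DRB5*01:01:02:01 DRB1*15:01:01:02 DQA1*01:02:01:03 DQB1*06:02:01:03 DPA1*01:03:01:17 DPB1*131:01:01:01"
  )
  mat <- do.call(rbind, strsplit(trimws(rows), "[[:space:]]+"))
  pool <- data.frame(freq = as.numeric(mat[, 1]),
                     mat[, -1, drop = FALSE], stringsAsFactors = FALSE)
  names(pool) <- c("freq", hla_loci())
  pool$freq <- pool$freq / sum(pool$freq)
  .validate_pool(pool)
  pool
}

.validate_pool <- function(pool) {
  need <- c("freq", hla_loci())
  miss <- setdiff(need, names(pool))
  if (length(miss)) stop("pool is missing column(s): ", paste(miss, collapse = ", "))
  if (any(pool$freq <= 0)) stop("pool frequencies must be positive")
  if (abs(sum(pool$freq) - 1) > 1e-9) stop("pool frequencies must sum to 1")
  keys <- apply(pool[, hla_loci()], 1L, paste, collapse = "~")
  if (anyDuplicated(keys)) stop("pool haplotypes must be distinct")
  for (loc in hla_loci()) {
    ok <- grepl(.valid_allele_re, pool[[loc]])
    if (!all(ok)) stop("invalid allele name(s) in pool column ", loc, ": ",
                       paste(pool[[loc]][!ok], collapse = ", "))
  }
  invisible(pool)
}

#' Disease model for the synthetic generator
#'
#' A multiplicative per-haplotype relative-risk model: the probability that a
#' child (or cohort subject) is affected is the baseline penetrance times the
#' product over risk units of \code{rr^dose} (\code{model = "multiplicative"})
#' or \code{rr^[dose == 2]} (\code{model = "recessive"}, homozygote-only
#' risk), where dose is the number of the subject's haplotypes matching the
#' unit at its field depth.
#'
#' @param penetrance Baseline probability of disease with no risk units.
#' @param effects Data frame with columns \code{unit}, \code{n_fields}
#'   (\code{2} or \code{Inf}), \code{rr}, \code{model}, and optionally
#'   \code{condition_unit}/\code{condition_n_fields} (the effect then applies
#'   only to subjects carrying at least one copy of the conditioning unit —
#'   a gene-gene interaction). \code{NULL} gives the null model (no
#'   association).
#' @return Object of class \code{hla_disease_model}.
#' @export
disease_model <- function(penetrance = 0.01, effects = NULL) {
  if (penetrance <= 0 || penetrance > 1) stop("penetrance must be in (0, 1]")
  if (is.null(effects))
    effects <- data.frame(unit = character(0), n_fields = numeric(0),
                          rr = numeric(0), model = character(0))
  stopifnot(all(c("unit", "n_fields", "rr", "model") %in% names(effects)))
  if (is.null(effects$condition_unit))
    effects$condition_unit <- rep(NA_character_, nrow(effects))
  if (is.null(effects$condition_n_fields))
    effects$condition_n_fields <- rep(Inf, nrow(effects))
  if (any(effects$rr <= 0)) stop("relative risks must be positive")
  if (!all(effects$model %in% c("multiplicative", "recessive")))
    stop("effect model must be 'multiplicative' or 'recessive'")
  structure(list(penetrance = penetrance, effects = effects),
            class = "hla_disease_model")
}

#' @rdname disease_model
#' @details \code{default_disease_model()} mirrors the magnitude of the
#'   principal published MS associations: risk for the
#'   \code{DRB5*01:01:01~DRB1*15:01:01:01} block (RR 3.42) and
#'   \code{DPB1*104:01} (RR 2.90); protection for \code{DRB1*01:01:01}
#'   (RR 0.38), two-field \code{DQB1*03:01} (RR 0.68) and two-field
#'   \code{B*27:05} (RR 0.38).
#' @export
default_disease_model <- function(penetrance = 0.01) {
  disease_model(penetrance, data.frame(
    unit = c("DRB5*01:01:01~DRB1*15:01:01:01", "DPB1*104:01",
             "DRB1*01:01:01", "DQB1*03:01", "B*27:05"),
    n_fields = c(Inf, Inf, Inf, 2, 2),
    rr = c(3.42, 2.90, 0.38, 0.68, 0.38),
    model = "multiplicative",
    stringsAsFactors = FALSE))
}

# per-pool-haplotype 0/1 indicator matrices for the model's units and any
# conditioning units
.pool_unit_ind <- function(pool, model) {
  eff <- model$effects
  if (!nrow(eff))
    return(list(unit = matrix(0, nrow(pool), 0),
                cond = matrix(0, nrow(pool), 0)))
  unit <- vapply(seq_len(nrow(eff)), function(e)
    as.numeric(.hap_matches_unit(pool, eff$unit[e], eff$n_fields[e])),
    numeric(nrow(pool)))
  cond <- vapply(seq_len(nrow(eff)), function(e) {
    if (is.na(eff$condition_unit[e])) return(rep(1, nrow(pool)))
    as.numeric(.hap_matches_unit(pool, eff$condition_unit[e],
                                 eff$condition_n_fields[e]))
  }, numeric(nrow(pool)))
  list(unit = matrix(unit, nrow(pool)), cond = matrix(cond, nrow(pool)))
}

# P(affected | two pool haplotype indices), vectorized over subjects
.affection_prob <- function(i1, i2, ind, model) {
  p <- rep(model$penetrance, length(i1))
  eff <- model$effects
  for (e in seq_len(nrow(eff))) {
    dose <- ind$unit[i1, e] + ind$unit[i2, e]
    active <- if (is.na(eff$condition_unit[e])) 1
              else (ind$cond[i1, e] + ind$cond[i2, e] >= 1) + 0
    mult <- if (eff$model[e] == "recessive") eff$rr[e]^((dose == 2) * active)
            else eff$rr[e]^(dose * active)
    p <- p * mult
  }
  pmin(p, 1)
}

# ---- trio and cohort sampling ----------------------------------------------

#' Simulate ascertained trio families with known phase
#'
#' Parents receive two haplotypes each, drawn i.i.d. from the pool; the child
#' receives one haplotype per parent, chosen uniformly; families are
#' rejection-sampled until the child is affected under the disease model
#' (affected-proband ascertainment, as in family studies of MS). Parents are
#' never ascertained. Ground-truth transmission labels are retained.
#'
#' @param n Number of trio families.
#' @param pool Haplotype pool (see [default_pool()]).
#' @param model An [disease_model()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return List of class \code{hla_trio_sim}: \code{trios} (genotype table,
#'   three rows per family), \code{truth} (ground-truth phased haplotypes in
#'   the shape returned by [phase_trios()]).
#' @export
sample_trios <- function(n, pool = default_pool(),
                         model = default_disease_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .validate_pool(pool)
  ind <- .pool_unit_ind(pool, model)
  np <- nrow(pool)
  acc <- matrix(integer(0), 0, 4)  # f_t, f_u, m_t, m_u pool indices
  first <- TRUE
  while (nrow(acc) < n) {
    m <- max(2L * (n - nrow(acc)), 500L)
    f1 <- sample.int(np, m, replace = TRUE, prob = pool$freq)
    f2 <- sample.int(np, m, replace = TRUE, prob = pool$freq)
    m1 <- sample.int(np, m, replace = TRUE, prob = pool$freq)
    m2 <- sample.int(np, m, replace = TRUE, prob = pool$freq)
    sf <- stats::runif(m) < 0.5
    sm <- stats::runif(m) < 0.5
    ft <- ifelse(sf, f1, f2); fu <- ifelse(sf, f2, f1)
    mt <- ifelse(sm, m1, m2); mu <- ifelse(sm, m2, m1)
    p <- .affection_prob(ft, mt, ind, model)
    if (first && mean(p) < 1e-6)
      stop("ascertainment acceptance probability below 1e-6; check the model")
    first <- FALSE
    keep <- stats::runif(m) < p
    acc <- rbind(acc, cbind(ft, fu, mt, mu)[keep, , drop = FALSE])
  }
  acc <- acc[seq_len(n), , drop = FALSE]
  fams <- sprintf("F%04d", seq_len(n))
  poolmat <- as.matrix(pool[, hla_loci()])

  truth <- data.frame(
    family_id = rep(fams, each = 4L),
    source = rep(c("father", "father", "mother", "mother"), n),
    transmitted = rep(c(TRUE, FALSE, TRUE, FALSE), n),
    poolmat[as.vector(t(acc)), , drop = FALSE],
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  geno <- function(i, j) {
    out <- matrix(NA_character_, length(i), length(hla_loci()),
                  dimnames = list(NULL, hla_loci()))
    for (loc in hla_loci()) {
      a1 <- poolmat[i, loc]; a2 <- poolmat[j, loc]
      k1 <- .akey(a1); k2 <- .akey(a2)
      swap <- vapply(seq_along(k1), function(r)
        order(c(k1[r], k2[r]), method = "radix")[1L] == 2L, NA)
      out[, loc] <- ifelse(swap, paste0(a2, "+", a1), paste0(a1, "+", a2))
    }
    out
  }
  trios <- data.frame(
    family_id = rep(fams, 3L),
    subject_id = c(paste0(fams, "_F"), paste0(fams, "_M"), paste0(fams, "_C")),
    relation = rep(c("father", "mother", "child"), each = n),
    rbind(geno(acc[, 1], acc[, 2]), geno(acc[, 3], acc[, 4]),
          geno(acc[, 1], acc[, 3])),
    check.names = FALSE, stringsAsFactors = FALSE)
  trios <- trios[order(trios$family_id,
                       match(trios$relation, c("father", "mother", "child"))), ]
  rownames(trios) <- NULL
  structure(list(trios = trios,
                 truth = structure(list(haplotypes = truth,
                                        flags = data.frame(
                                          family_id = character(0),
                                          locus = character(0),
                                          flag = character(0)),
                                        families = fams),
                                   class = "hla_phased")),
            class = "hla_trio_sim")
}

#' Simulate an unrelated case/control cohort
#'
#' Subjects receive two pool haplotypes i.i.d.; affected subjects fill the
#' case quota, unaffected ones the control quota. Ground-truth haplotypes are
#' kept in \code{hap1}/\code{hap2} columns (needed for haplotype-block
#' case-control tests, since cohort genotypes are unphased).
#'
#' @inheritParams sample_trios
#' @param n_cases,n_controls Group sizes; both must be positive.
#' @return Cohort data frame (see [read_cohort_table()]).
#' @export
sample_cohort <- function(n_cases, n_controls, pool = default_pool(),
                          model = default_disease_model(), seed = NULL) {
  if (n_cases < 1 || n_controls < 1)
    stop("n_cases and n_controls must both be positive")
  if (!is.null(seed)) set.seed(seed)
  .validate_pool(pool)
  ind <- .pool_unit_ind(pool, model)
  np <- nrow(pool)
  cases <- matrix(integer(0), 0, 2); ctrls <- matrix(integer(0), 0, 2)
  first <- TRUE
  while (nrow(cases) < n_cases || nrow(ctrls) < n_controls) {
    m <- max(2L * (n_cases + n_controls), 1000L)
    h1 <- sample.int(np, m, replace = TRUE, prob = pool$freq)
    h2 <- sample.int(np, m, replace = TRUE, prob = pool$freq)
    p <- .affection_prob(h1, h2, ind, model)
    if (first && (mean(p) < 1e-6 || mean(1 - p) < 1e-6))
      stop("group acceptance probability below 1e-6; check the model")
    first <- FALSE
    aff <- stats::runif(m) < p
    cases <- rbind(cases, cbind(h1, h2)[aff, , drop = FALSE])
    ctrls <- rbind(ctrls, cbind(h1, h2)[!aff, , drop = FALSE])
  }
  cases <- cases[seq_len(n_cases), , drop = FALSE]
  ctrls <- ctrls[seq_len(n_controls), , drop = FALSE]
  idx <- rbind(cases, ctrls)
  poolmat <- as.matrix(pool[, hla_loci()])
  geno <- matrix(NA_character_, nrow(idx), length(hla_loci()),
                 dimnames = list(NULL, hla_loci()))
  for (loc in hla_loci()) {
    a1 <- poolmat[idx[, 1], loc]; a2 <- poolmat[idx[, 2], loc]
    k1 <- .akey(a1); k2 <- .akey(a2)
    swap <- vapply(seq_along(k1), function(r)
      order(c(k1[r], k2[r]), method = "radix")[1L] == 2L, NA)
    geno[, loc] <- ifelse(swap, paste0(a2, "+", a1), paste0(a1, "+", a2))
  }
  hapstr <- function(i) apply(poolmat[i, , drop = FALSE], 1L, paste,
                              collapse = "~")
  data.frame(
    subject_id = sprintf("S%05d", seq_len(nrow(idx))),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    geno, hap1 = hapstr(idx[, 1]), hap2 = hapstr(idx[, 2]),
    check.names = FALSE, stringsAsFactors = FALSE)
}

# ---- ambiguity injection ---------------------------------------------------

#' Inject allelic and genotypic ambiguity into genotype tables
#'
#' Emulates typing ambiguity: an \code{allelic} rule replaces every occurrence
#' of one allele name at a locus with a \code{/}-joined ambiguity set; a
#' \code{genotypic} rule replaces a specific unphased genotype with a
#' \code{|}-joined pair of alternative genotypes. The true genotype is always
#' among the presented alternatives, so family review
#' ([resolve_family_ambiguity()]) recovers it whenever relatives are
#' informative; otherwise the lowest-digit rule applies.
#'
#' @param x A trio or cohort table.
#' @param rules List of rules. Allelic:
#'   \code{list(type = "allelic", locus, allele, with)}. Genotypic:
#'   \code{list(type = "genotypic", locus, genotype = c(a1, a2),
#'   alternative = c(b1, b2))}.
#' @return The table with ambiguity operators inserted.
#' @export
inject_ambiguity <- function(x, rules) {
  all_known <- unlist(lapply(rules, function(r)
    c(r$allele, r$with, r$genotype, r$alternative)))
  bad <- all_known[!grepl(.valid_allele_re, all_known)]
  if (length(bad)) stop("rule references malformed allele name(s): ",
                        paste(unique(bad), collapse = ", "))
  for (r in rules) {
    if (!r$locus %in% hla_loci()) stop("rule references unknown locus: ", r$locus)
    g <- x[[r$locus]]
    if (identical(r$type, "allelic")) {
      pair <- c(r$allele, r$with)
      amb <- paste(pair[order(.akey(pair), method = "radix")], collapse = "/")
      g <- vapply(g, function(s) {
        al <- strsplit(s, "+", fixed = TRUE)[[1]]
        paste(ifelse(al == r$allele, amb, al), collapse = "+")
      }, "", USE.NAMES = FALSE)
    } else if (identical(r$type, "genotypic")) {
      gt <- paste(r$genotype[order(.akey(r$genotype), method = "radix")],
                  collapse = "+")
      alt <- paste(r$alternative[order(.akey(r$alternative), method = "radix")],
                   collapse = "+")
      both <- c(gt, alt)
      joined <- paste(both[order(both, method = "radix")], collapse = "|")
      g <- ifelse(g == gt, joined, g)
    } else stop("unknown rule type: ", r$type)
    x[[r$locus]] <- g
  }
  x
}
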