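#' Risk/protective factor table for cumulative scoring
#'
#' Defines the alleles and haplotype fragments entering the cumulative risk
#' assessment, each with its match resolution, direction, and effect size on
#' the log odds scale (\code{ln OR} from a case-control analysis).
#'
#' @param unit Character vector of unit keys.
#' @param n_fields Matching resolution per unit (\code{2} or \code{Inf}).
#' @param direction \code{"risk"} or \code{"protective"} per unit.
#' @param effect Effect sizes, \code{ln(OR)}; risk factors should have
#'   positive and protective factors negative effects.
#' @return Data frame of class \code{hla_factors}.
#' @export
factor_table <- function(unit, n_fields, direction, effect) {
  if (anyDuplicated(unit)) stop("factor units must be unique")
  if (!all(direction %in% c("risk", "protective")))
    stop("direction must be 'risk' or 'protective'")
  mism <- (direction == "risk" & effect < 0) |
    (direction == "protective" & effect > 0)
  if (any(mism))
    warning("effect sign disagrees with direction for: ",
            paste(unit[mism], collapse = ", "))
  structure(data.frame(unit = unit, n_fields = n_fields,
                       direction = direction, effect = effect,
                       stringsAsFactors = FALSE),
            class = c("hla_factors", "data.frame"))
}

# per-subject dose (0/1/2) of each factor; subjects need genotype columns
# and, for multi-locus factors, phased hap1/hap2 columns
.factor_doses <- function(subjects, factors) {
  vapply(seq_len(nrow(factors)), function(i) {
    unit <- factors$unit[i]; nf <- factors$n_fields[i]
    slots <- .unit_slots(unit)
    if (length(slots) > 1L) {
      if (!all(c("hap1", "hap2") %in% names(subjects)))
        stop("haplotype factor '", unit, "' needs phased hap1/hap2 columns")
      m1 <- .hap_matches_unit(.hapstr_to_df(subjects$hap1), unit, nf)
      m2 <- .hap_matches_unit(.hapstr_to_df(subjects$hap2), unit, nf)
      as.integer(m1) + as.integer(m2)
    } else {
      a1 <- .atrunc(.split_geno(subjects[[slots]], 1L), nf)
      a2 <- .atrunc(.split_geno(subjects[[slots]], 2L), nf)
      (a1 == unit) + (a2 == unit)
    }
  }, integer(nrow(subjects)))
}

.category_rules <- function(n_risk, n_prot) {
  ifelse(n_risk + n_prot == 0L, "NeutralZero",
  ifelse(n_risk > n_prot, "Risk",
  ifelse(n_risk == n_prot, "NeutralRiskProtective",
  ifelse(n_risk >= 1L, "ProtectiveRisk", "Protective"))))
}

#' Cumulative risk score profiles
#'
#' Computes, per subject, the net risk score (+1 for each risk factor
#' present, -1 for each protective factor present; presence is carrier
#' status at the factor's resolution), the five-way category, and the HLA
#' genetic burden. Categories: \code{Risk} (positive score),
#' \code{NeutralZero} (no factor present), \code{NeutralRiskProtective}
#' (equal nonzero counts), \code{ProtectiveRisk} (negative score but at
#' least one risk factor), \code{Protective} (protective factors only). The
#' partition is exhaustive and mutually exclusive.
#'
#' @param subjects Data frame with \code{subject_id}, \code{group}, genotype
#'   columns, and phased \code{hap1}/\code{hap2} columns when haplotype
#'   factors are used (see [subjects_from_trios()] and [sample_cohort()]).
#' @param factors A [factor_table()].
#' @param hlagb_mode \code{"dose"} (allele dose times effect size, the
#'   default) or \code{"carrier"} (carrier status times effect size).
#' @return Data frame: \code{subject_id}, \code{group}, \code{n_risk},
#'   \code{n_protective}, \code{net_score}, \code{category}, \code{hlagb}.
#' @export
score_profiles <- function(subjects, factors, hlagb_mode = "dose") {
  doses <- .factor_doses(subjects, factors)
  if (nrow(subjects) == 1L) doses <- matrix(doses, nrow = 1L)
  present <- doses >= 1L
  n_risk <- as.integer(present %*% (factors$direction == "risk"))
  n_prot <- as.integer(present %*% (factors$direction == "protective"))
  data.frame(subject_id = subjects$subject_id, group = subjects$group,
             n_risk = n_risk, n_protective = n_prot,
             net_score = n_risk - n_prot,
             category = .category_rules(n_risk, n_prot),
             hlagb = hlagb(subjects, factors, mode = hlagb_mode),
             stringsAsFactors = FALSE)
}

#' HLA genetic burden score
#'
#' Per-subject sum over factors of allele dose times effect size
#' (\code{ln OR}); a polygenic-style HLA score. In \code{"carrier"} mode the
#' dose is replaced by carrier status (0/1).
#'
#' @inheritParams score_profiles
#' @param mode \code{"dose"} or \code{"carrier"}.
#' @return Numeric vector, one score per subject.
#' @export
hlagb <- function(subjects, factors, mode = "dose") {
  mode <- match.arg(mode, c("dose", "carrier"))
  doses <- .factor_doses(subjects, factors)
  if (nrow(subjects) == 1L) doses <- matrix(doses, nrow = 1L)
  if (mode == "carrier") doses <- (doses >= 1L) + 0L
  as.numeric(doses %*% factors$effect)
}

#' Category odds ratio against a reference category
#'
#' The 2 x 2 odds ratio (cases/controls by category membership) comparing
#' one score category against a reference (Neutral Zero by default), with
#' Woolf interval and Yates-corrected p-value.
#'
#' @param profiles Output of [score_profiles()].
#' @param cat_a Category of interest (e.g. \code{"Risk"}).
#' @param cat_b Reference category.
#' @return An [or_ci_yates()] result.
#' @export
category_or <- function(profiles, cat_a, cat_b = "NeutralZero") {
  a <- sum(profiles$group == "case" & profiles$category == cat_a)
  b <- sum(profiles$group == "case" & profiles$category == cat_b)
  c <- sum(profiles$group == "control" & profiles$category == cat_a)
  d <- sum(profiles$group == "control" & profiles$category == cat_b)
  or_ci_yates(a, b, c, d)
}

#' Compare HLA genetic burden between groups
#'
#' Medians and interquartile ranges per group and a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test.
#'
#' @param profiles Output of [score_profiles()] (or any data frame with
#'   \code{group} and \code{hlagb} columns).
#' @param group_a,group_b Group labels to compare.
#' @return List: per-group \code{median}, \code{iqr}, \code{n}; \code{p};
#'   \code{degenerate} flag when all values are tied.
#' @export
group_compare_hlagb <- function(profiles, group_a = "case",
                                group_b = "control") {
  xa <- profiles$hlagb[profiles$group == group_a]
  xb <- profiles$hlagb[profiles$group == group_b]
  if (length(xa) < 2L || length(xb) < 2L)
    stop("need at least two subjects per group")
  degenerate <- length(unique(c(xa, xb))) == 1L
  p <- if (degenerate) NA_real_ else
    suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
  list(groups = stats::setNames(list(
    list(n = length(xa), median = stats::median(xa),
         iqr = unname(stats::quantile(xa, c(0.25, 0.75)))),
    list(n = length(xb), median = stats::median(xb),
         iqr = unname(stats::quantile(xb, c(0.25, 0.75))))),
    c(group_a, group_b)),
    p = p, degenerate = degenerate)
}

#' Per-subject table from phased trios
#'
#' Builds the subject table used by the scoring functions from a trio table
#' and its phasing: each subject keeps their genotype columns and gains
#' phased \code{hap1}/\code{hap2} strings (for children, the two transmitted
#' parental haplotypes). The \code{group} column holds the familial relation
#' (\code{child} subjects are the affected probands).
#'
#' @param trios Trio table.
#' @param phased Optional pre-computed [phase_trios()] result.
#' @return Subject data frame compatible with [score_profiles()]. Subjects
#'   from families with unresolved loci get \code{NA} haplotype strings.
#' @export
subjects_from_trios <- function(trios, phased = NULL) {
  if (is.null(phased)) phased <- phase_trios(trios)
  h <- phased$haplotypes
  hapstr <- apply(as.matrix(h[, hla_loci()]), 1L, function(r)
    if (anyNA(r)) NA_character_ else paste(r, collapse = "~"))
  pick <- function(fam, src, trans) {
    i <- which(h$family_id == fam & h$source == src & h$transmitted == trans)
    if (length(i)) hapstr[i[1]] else NA_character_
  }
  out <- trios
  out$group <- out$relation
  out$hap1 <- NA_character_; out$hap2 <- NA_character_
  for (r in seq_len(nrow(out))) {
    fam <- out$family_id[r]
    out[r, c("hap1", "hap2")] <- switch(out$relation[r],
      father = c(pick(fam, "father", TRUE), pick(fam, "father", FALSE)),
      mother = c(pick(fam, "mother", TRUE), pick(fam, "mother", FALSE)),
      child = c(pick(fam, "father", TRUE), pick(fam, "mother", TRUE)))
  }
  out
}
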