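#' Odds ratio with Woolf interval and Yates-corrected chi-square
#'
#' For a 2x2 table of counts (\code{a}, \code{b} = group 1
#' carrier/non-carrier; \code{c}, \code{d} = group 2), computes
#' \code{OR = ad/bc}, the Woolf confidence interval
#' \code{exp(ln OR +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))}, and the
#' continuity-corrected chi-square
#' \code{N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))} with its 1-df
#' p-value. When any cell is zero, the Haldane-Anscombe correction (+0.5 to
#' every cell) is applied to the OR and interval; the chi-square keeps the
#' original counts. A zero margin leaves the OR undefined and is flagged.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Object of class \code{hla_or}: \code{or}, \code{ci},
#'   \code{chisq}, \code{p}, \code{carrier_pct} (per-group carrier
#'   percentages), \code{haldane}, \code{defined}.
#' @examples
#' or_ci_yates(9, 243, 42, 328)   # OR 0.29, CI 0.14-0.61, p 0.000892
#' @export
or_ci_yates <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  n <- sum(cells)
  margins <- c(a + b, c + d, a + c, b + d)
  defined <- all(margins > 0)
  haldane <- any(cells == 0)
  cc <- if (haldane) cells + 0.5 else cells
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  chisq <- if (defined) {
    n * max(0, abs(a * d - b * c) - n / 2)^2 / prod(margins)
  } else NA_real_
  structure(list(
    table = matrix(cells, 2, 2, byrow = TRUE,
                   dimnames = list(c("group1", "group2"),
                                   c("carrier", "non_carrier"))),
    or = unname(or), ci = unname(ci), chisq = unname(chisq),
    p = if (defined) stats::pchisq(chisq, 1, lower.tail = FALSE) else NA_real_,
    carrier_pct = c(group1 = 100 * a / (a + b), group2 = 100 * c / (c + d)),
    haldane = haldane, defined = defined), class = "hla_or")
}

#' @export
print.hla_or <- function(x, ...) {
  cat(sprintf("<hla_or> OR = %.3g (95%% CI %.3g-%.3g), Yates p = %.4g%s\n",
              x$or, x$ci[1], x$ci[2], x$p,
              if (x$haldane) " [Haldane corrected]" else ""))
  invisible(x)
}

#' Case-control association test for one locus or block
#'
#' Tests allele (or block-haplotype) frequency differences between unrelated
#' cases and controls. Units whose smaller expected cell count falls below
#' \code{bin_threshold} are pooled into a \code{"binned"} category; the
#' overall R x 2 chi-square is computed on the pooled table, and each
#' retained unit gets a 2 x 2 unit-versus-rest comparison via
#' [or_ci_yates()] on allele counts.
#'
#' @param case_keys,control_keys Character vectors of unit keys, two entries
#'   per subject (alleles of a gene, or projected block haplotypes), already
#'   at the desired field depth.
#' @param bin_threshold Minimum expected count for a unit to stand alone.
#' @return Object of class \code{hla_cc}: \code{overall} (chi-square, df, p,
#'   or a skip flag), \code{per_unit} data frame and \code{binned} unit
#'   names.
#' @export
locus_cc_test <- function(case_keys, control_keys, bin_threshold = 5) {
  units <- sort(unique(c(case_keys, control_keys)), method = "radix")
  ca <- table(factor(case_keys, levels = units))
  co <- table(factor(control_keys, levels = units))
  tab <- cbind(case = as.integer(ca), control = as.integer(co))
  rownames(tab) <- units
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  binned <- units[apply(expected, 1L, min) < bin_threshold]
  pooled <- tab[!rownames(tab) %in% binned, , drop = FALSE]
  if (length(binned))
    pooled <- rbind(pooled, binned = colSums(tab[binned, , drop = FALSE]))
  overall <- if (nrow(pooled) >= 2L && all(colSums(pooled) > 0)) {
    ch <- suppressWarnings(stats::chisq.test(pooled, correct = FALSE))
    list(skipped = FALSE, chisq = unname(ch$statistic),
         df = unname(ch$parameter), p = unname(ch$p.value))
  } else list(skipped = TRUE, chisq = NA_real_, df = NA_integer_,
              p = NA_real_)
  per_unit <- do.call(rbind, lapply(units, function(u) {
    o <- or_ci_yates(tab[u, "case"], sum(tab[, "case"]) - tab[u, "case"],
                     tab[u, "control"], sum(tab[, "control"]) - tab[u, "control"])
    data.frame(unit = u, case_count = tab[u, "case"],
               control_count = tab[u, "control"],
               or = o$or, ci_low = o$ci[1], ci_high = o$ci[2],
               p = o$p, binned = u %in% binned, stringsAsFactors = FALSE)
  }))
  rownames(per_unit) <- NULL
  structure(list(overall = overall, per_unit = per_unit, binned = binned,
                 counts = tab), class = "hla_cc")
}

#' @export
print.hla_cc <- function(x, ...) {
  if (x$overall$skipped) {
    cat("<hla_cc> overall test skipped (fewer than 2 units after binning)\n")
  } else {
    cat(sprintf("<hla_cc> overall chi-square = %.4g on %d df, p = %.4g; %d units (%d binned)\n",
                x$overall$chisq, x$overall$df, x$overall$p,
                nrow(x$per_unit), length(x$binned)))
  }
  invisible(x)
}

# ---- Hardy-Weinberg diagnostics --------------------------------------------

# canonicalize genotype input: 2-column matrix/data frame of allele names
.geno_pairs_input <- function(genotypes) {
  g <- as.matrix(genotypes)
  if (ncol(g) != 2L) stop("genotypes must have two allele columns")
  swap <- g[, 1] > g[, 2]
  cbind(ifelse(swap, g[, 2], g[, 1]), ifelse(swap, g[, 1], g[, 2]))
}

# log conditional probability core: terms that vary across tables with the
# same allele counts (heterozygosity bonus minus genotype-count factorials)
.hwe_logprob_stat <- function(counts_lo, counts_hi, tab) {
  het <- sum(tab[counts_lo != counts_hi])
  het * log(2) - sum(lfactorial(tab))
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test in the style of Guo and Thompson: given the sample
#' allele counts, the probability of the observed genotype table is compared
#' with tables obtained by randomly re-pairing the 2n allele copies. The
#' p-value is \code{(1 + #\{tables at most as probable as observed\}) /
#' (n_reps + 1)}.
#'
#' @param genotypes Two-column matrix or data frame of allele names, one row
#'   per diploid individual.
#' @param n_reps Monte-Carlo replicates (default 17000).
#' @param seed Optional seed.
#' @return Object of class \code{hla_hwe}: \code{p}, \code{n_reps},
#'   observed and HWE-expected genotype counts.
#' @export
hwe_exact_mc <- function(genotypes, n_reps = 17000L, seed = NULL) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  g <- .geno_pairs_input(genotypes)
  alleles <- sort(unique(as.vector(g)), method = "radix")
  k <- length(alleles)
  n <- nrow(g)
  i1 <- match(g[, 1], alleles); i2 <- match(g[, 2], alleles)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  code <- lo + k * (hi - 1L)
  obs_tab <- tabulate(code, k * k)
  geno_summary <- .hwe_expected(lo, hi, alleles, n)
  if (k < 2L)
    return(structure(list(p = 1, n_reps = 0L, monomorphic = TRUE,
                          genotypes = geno_summary), class = "hla_hwe"))
  pool <- c(g[, 1], g[, 2])
  ipool <- match(pool, alleles)
  obs_stat <- {
    codes <- which(obs_tab > 0)
    loj <- (codes - 1L) %% k + 1L; hij <- (codes - 1L) %/% k + 1L
    sum(obs_tab[codes][loj != hij]) * log(2) - sum(lfactorial(obs_tab))
  }
  count <- 0L
  for (r in seq_len(n_reps)) {
    perm <- sample(ipool)
    a1 <- perm[seq_len(n)]; a2 <- perm[n + seq_len(n)]
    l <- pmin(a1, a2); h <- pmax(a1, a2)
    tab <- tabulate(l + k * (h - 1L), k * k)
    stat <- sum((l != h)) * log(2) - sum(lfactorial(tab))
    if (stat <= obs_stat + 1e-9) count <- count + 1L
  }
  structure(list(p = (1 + count) / (n_reps + 1), n_reps = n_reps,
                 monomorphic = FALSE, genotypes = geno_summary),
            class = "hla_hwe")
}

# observed vs HWE-expected genotype counts from sample allele frequencies
.hwe_expected <- function(lo, hi, alleles, n) {
  k <- length(alleles)
  freq <- tabulate(c(lo, hi), k) / (2 * n)
  seen <- sort(unique(lo + k * (hi - 1L)))
  loj <- (seen - 1L) %% k + 1L; hij <- (seen - 1L) %/% k + 1L
  obs <- tabulate(lo + k * (hi - 1L), k * k)[seen]
  expd <- ifelse(loj == hij, n * freq[loj]^2, 2 * n * freq[loj] * freq[hij])
  data.frame(genotype = paste(alleles[loj], alleles[hij], sep = "+"),
             observed = obs, expected = expd, stringsAsFactors = FALSE)
}

#' @export
print.hla_hwe <- function(x, ...) {
  if (isTRUE(x$monomorphic)) cat("<hla_hwe> monomorphic locus, p = 1\n")
  else cat(sprintf("<hla_hwe> Monte-Carlo exact p = %.4g (%d replicates)\n",
                   x$p, x$n_reps))
  invisible(x)
}

#' Per-genotype deviation from HWE expectations
#'
#' Screens each observed genotype for excess or deficit relative to its
#' Hardy-Weinberg expectation: the table is collapsed to (this genotype vs
#' all others) x (observed vs expected) and assessed with a 1-df chi-square,
#' \code{(obs - exp)^2 * n / (exp * (n - exp))}. Genotypes with
#' \code{p < alpha} are flagged with the direction of the deviation.
#'
#' @inheritParams hwe_exact_mc
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame: \code{genotype}, \code{observed}, \code{expected},
#'   \code{chisq}, \code{p}, \code{direction}, \code{flagged}.
#' @export
genotype_outliers <- function(genotypes, alpha = 0.05) {
  g <- .geno_pairs_input(genotypes)
  alleles <- sort(unique(as.vector(g)), method = "radix")
  n <- nrow(g)
  i1 <- match(g[, 1], alleles); i2 <- match(g[, 2], alleles)
  ex <- .hwe_expected(pmin(i1, i2), pmax(i1, i2), alleles, n)
  ex <- ex[ex$expected > 0 & ex$expected < n, , drop = FALSE]
  chisq <- (ex$observed - ex$expected)^2 * n / (ex$expected * (n - ex$expected))
  p <- stats::pchisq(chisq, 1, lower.tail = FALSE)
  out <- data.frame(ex, chisq = chisq, p = p,
                    direction = ifelse(ex$observed >= ex$expected,
                                       "excess", "deficit"),
                    flagged = p < alpha, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ---- extracting unit keys from a cohort table ------------------------------

#' Unit keys of cohort subjects for one scope
#'
#' Returns the two per-subject unit keys used by [locus_cc_test()]: for gene
#' scopes, the truncated genotype alleles (DRB3/4/5 projected onto the
#' requested paralog); for block scopes, projections of the phased
#' \code{hap1}/\code{hap2} columns.
#'
#' @param cohort Cohort table.
#' @param scope Scope name (see [analysis_scopes()]).
#' @param n_fields Allele resolution.
#' @return Character matrix with two columns (one row per subject).
#' @export
cohort_keys <- function(cohort, scope, n_fields = Inf) {
  sc <- if (length(scope) > 1L) .make_scope(paste(scope, collapse = "~"))
        else .make_scope(scope)
  if (sc$type == "block" && length(sc$loci) > 1L) {
    if (!all(c("hap1", "hap2") %in% names(cohort)))
      stop("block-level case-control keys need phased hap1/hap2 columns")
    out <- vapply(c("hap1", "hap2"), function(col) {
      hd <- .hapstr_to_df(cohort[[col]])
      keys <- vapply(sc$loci, function(loc) .atrunc(hd[[loc]], n_fields),
                     character(nrow(hd)))
      if (nrow(hd) == 1L) keys <- matrix(keys, nrow = 1L)
      apply(keys, 1L, paste, collapse = "~")
    }, character(nrow(cohort)))
    return(out)
  }
  slot <- sc$loci
  a1 <- .split_geno(cohort[[slot]], 1L)
  a2 <- .split_geno(cohort[[slot]], 2L)
  proj <- function(al) {
    if (!is.na(sc$gene) && sc$gene %in% c("DRB3", "DRB4", "DRB5"))
      al <- ifelse(.agene(al) == sc$gene, al, paste0(sc$gene, "*absent"))
    .atrunc(al, n_fields)
  }
  cbind(hap1 = proj(a1), hap2 = proj(a2))
}
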