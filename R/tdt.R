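# ---- conditional-logistic core ---------------------------------------------

# One-parameter conditional logistic fit over 4-genotype risk sets.
# X: n x 4 matrix of genetic codings (child + 3 pseudo-controls),
# ci: column index of the observed child genotype per family.
# Non-informative rows (constant coding) drop out of the likelihood.
.clogit1 <- function(X, ci, max_iter = 50L, tol = 1e-10, cap = 15) {
  rng <- pmax(X[, 1], X[, 2], X[, 3], X[, 4]) - pmin(X[, 1], X[, 2], X[, 3], X[, 4])
  keep <- rng > 0
  X <- X[keep, , drop = FALSE]; ci <- ci[keep]
  n <- nrow(X)
  if (n == 0L)
    return(list(n = 0L, defined = FALSE, beta = NA_real_, se = NA_real_,
                loglik = NA_real_, score_stat = NA_real_, separated = FALSE))
  xc <- X[cbind(seq_len(n), ci)]
  # score pieces at beta = 0
  mu0 <- rowMeans(X)
  v0 <- rowMeans(X * X) - mu0^2
  U0 <- sum(xc - mu0); V0 <- sum(v0)
  score_stat <- if (V0 > 0) U0^2 / V0 else NA_real_
  beta <- 0; separated <- FALSE
  for (it in seq_len(max_iter)) {
    E <- exp(beta * X); S <- rowSums(E)
    mu <- rowSums(X * E) / S
    v <- rowSums(X * X * E) / S - mu^2
    g <- sum(xc - mu); I <- sum(v)
    if (!is.finite(I) || I <= 1e-12) { separated <- TRUE; break }
    step <- g / I
    step <- max(min(step, 2), -2)
    beta <- beta + step
    if (abs(beta) >= cap) { beta <- sign(beta) * cap; separated <- TRUE; break }
    if (abs(g) < tol) break
  }
  E <- exp(beta * X); S <- rowSums(E)
  mu <- rowSums(X * E) / S
  v <- rowSums(X * X * E) / S - mu^2
  I <- sum(v)
  list(n = n, defined = TRUE, beta = beta,
       se = if (I > 0) 1 / sqrt(I) else NA_real_,
       loglik = sum(beta * xc - log(S)),
       score_stat = score_stat, separated = separated,
       X = X, xc = xc)
}

# profile-likelihood bound for a separated fit: the finite endpoint of the
# one-sided 95% interval, where the conditional log likelihood drops
# qchisq(0.95, 1)/2 below its supremum
.profile_bound <- function(X, xc, direction) {
  ext <- if (direction > 0) apply(X, 1L, max) else apply(X, 1L, min)
  m <- rowSums(X == ext)
  l_sup <- -sum(log(m))
  target <- l_sup - stats::qchisq(0.95, 1) / 2
  f <- function(b) sum(b * xc - log(rowSums(exp(b * X)))) - target
  lo <- if (direction > 0) -40 else 40
  hi <- if (direction > 0) 40 else -40
  out <- try(stats::uniroot(f, sort(c(lo, hi)))$root, silent = TRUE)
  if (inherits(out, "try-error")) NA_real_ else out
}

.code_dose <- function(D, model) {
  switch(model,
         additive = D,
         dominant = (D >= 1) + 0,
         recessive = (D == 2) + 0,
         stop("unknown genetic model: ", model))
}

# wide per-family keys for one scope: key_t_f, key_u_f, key_t_m, key_u_m
.family_keys <- function(phased, scope, n_fields = Inf) {
  w <- .pair_keys(decompose(phased, scope, n_fields))
  fa <- w[w$source == "father", ]; mo <- w[w$source == "mother", ]
  merge(fa, mo, by = "family_id", suffixes = c("_f", "_m"), sort = TRUE)
}

# per-family transmitted/untransmitted unit indicators for one scope
# returns data frame: family_id, it_f, iu_f, it_m, iu_m (0/1)
.unit_indicators <- function(phased, unit, n_fields = Inf, scope = NULL,
                             fk = NULL) {
  if (is.null(fk)) {
    if (is.null(scope)) scope <- paste(.unit_slots(unit), collapse = "~")
    fk <- .family_keys(phased, scope, n_fields)
  }
  data.frame(family_id = fk$family_id,
             it_f = (fk$key_t_f == unit) + 0, iu_f = (fk$key_u_f == unit) + 0,
             it_m = (fk$key_t_m == unit) + 0, iu_m = (fk$key_u_m == unit) + 0)
}

# dose matrix over the 4-genotype risk set; column 1 is the observed child
.dose_matrix <- function(ind) {
  cbind(ind$it_f + ind$it_m, ind$it_f + ind$iu_m,
        ind$iu_f + ind$it_m, ind$iu_f + ind$iu_m)
}

#' Genotypic transmission disequilibrium test
#'
#' Tests over-transmission of one allele or block haplotype (the unit,
#' treated as biallelic: unit versus all others) to affected children. The
#' child's genotype is compared with the three pseudo-control genotypes
#' formed by the alternative transmissible combinations of parental
#' haplotypes, by maximizing the conditional likelihood of the observed
#' genotype within each family's 4-genotype risk set under an additive,
#' dominant or recessive coding of the unit dose. Reports the relative risk
#' \code{exp(beta)} with Wald confidence interval and p-value; the score
#' statistic at \code{beta = 0} under the additive coding equals the classic
#' allelic TDT statistic \code{(T-U)^2/(T+U)} on heterozygous-parent
#' transmissions.
#'
#' Complete separation (e.g. every informative parent transmits the unit) is
#' flagged; the relative risk is then reported as infinite (or zero) with a
#' one-sided profile-likelihood bound and the score-test p-value.
#'
#' @param phased An \code{hla_phased} object.
#' @param unit Unit key, e.g. \code{"DPB1*104:01"} or
#'   \code{"DRB5*01:01:01~DRB1*15:01:01:01"}.
#' @param n_fields Resolution at which haplotypes are matched to the unit.
#' @param model \code{"additive"}, \code{"dominant"} or \code{"recessive"}.
#' @param scope Scope to decompose on; defaults to the unit's own loci. Pass
#'   \code{"DRB3"}, \code{"DRB4"} or \code{"DRB5"} for single-paralog units.
#' @return Object of class \code{hla_gtdt}.
#' @export
gtdt <- function(phased, unit, n_fields = Inf, model = "additive",
                 scope = NULL) {
  ind <- .unit_indicators(phased, unit, n_fields, scope)
  D <- .dose_matrix(ind)
  fit <- .clogit1(.code_dose(D, model), rep(1L, nrow(D)))
  .gtdt_result(fit, unit, model)
}

# gTDT for one unit from precomputed family keys (workflow fast path)
.gtdt_on_keys <- function(fk, unit, model) {
  ind <- .unit_indicators(NULL, unit, fk = fk)
  D <- .dose_matrix(ind)
  fit <- .clogit1(.code_dose(D, model), rep(1L, nrow(D)))
  .gtdt_result(fit, unit, model)
}

.gtdt_result <- function(fit, unit, model) {
  if (!fit$defined || fit$n == 0L)
    return(structure(list(unit = unit, model = model, n_informative = fit$n,
                          defined = FALSE, beta = NA_real_, rr = NA_real_,
                          ci = c(NA_real_, NA_real_), p = NA_real_,
                          score_stat = NA_real_, separated = FALSE),
                     class = "hla_gtdt"))
  z <- fit$beta / fit$se
  if (fit$separated) {
    dirn <- sign(fit$beta)
    bound <- .profile_bound(fit$X, fit$xc, dirn)
    rr <- if (dirn > 0) Inf else 0
    ci <- if (dirn > 0) c(exp(bound), Inf) else c(0, exp(bound))
    p <- stats::pchisq(fit$score_stat, 1, lower.tail = FALSE)
    return(structure(list(unit = unit, model = model,
                          n_informative = fit$n, defined = TRUE,
                          beta = dirn * Inf, rr = rr, ci = ci, se = NA_real_,
                          p = p, score_stat = fit$score_stat,
                          separated = TRUE),
                     class = "hla_gtdt"))
  }
  structure(list(unit = unit, model = model, n_informative = fit$n,
                 defined = TRUE, beta = fit$beta, rr = exp(fit$beta),
                 ci = exp(fit$beta + c(-1, 1) * 1.96 * fit$se), se = fit$se,
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 wald_chisq = z^2, score_stat = fit$score_stat,
                 separated = FALSE),
            class = "hla_gtdt")
}

#' @export
print.hla_gtdt <- function(x, ...) {
  cat("<hla_gtdt> ", x$unit, " [", x$model, "]\n", sep = "")
  if (!x$defined || x$n_informative == 0L) {
    cat("  no informative families\n"); return(invisible(x))
  }
  cat(sprintf("  RR = %.3g (95%% CI %.3g-%.3g), p = %.3g, n = %d%s\n",
              x$rr, x$ci[1], x$ci[2], x$p, x$n_informative,
              if (x$separated) " [separated]" else ""))
  invisible(x)
}

# Wald chi-square of one coding, for the MAX statistic; separated fits give
# the Wald value at the likelihood cap (large, finite)
.wald_chisq <- function(X, ci) {
  fit <- .clogit1(X, ci)
  if (!fit$defined || fit$n == 0L || is.na(fit$se) || fit$se <= 0) return(0)
  (fit$beta / fit$se)^2
}

#' MAX genotypic TDT with permutation p-values
#'
#' Computes the maximum of the additive, dominant and recessive gTDT Wald
#' chi-squares for one unit and assesses it by permutation: within each
#' parent, the transmitted and non-transmitted haplotype labels are swapped
#' with probability 1/2 (which holds under the null of no transmission
#' distortion), and the maximum statistic is recomputed. The reported
#' p-value is \code{(1 + #\{perm >= observed\}) / (n_perm + 1)}.
#'
#' @inheritParams gtdt
#' @param n_perm Number of permutations (>= 1; 1000 by default).
#' @param seed Optional seed.
#' @return Object of class \code{hla_maxgtdt}: observed per-model statistics,
#'   the MAX statistic and the permutation p-value.
#' @export
max_gtdt <- function(phased, unit, n_fields = Inf, n_perm = 1000L,
                     seed = NULL, scope = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ind <- .unit_indicators(phased, unit, n_fields, scope)
  D <- .dose_matrix(ind)
  n <- nrow(D)
  Xs <- lapply(c("additive", "dominant", "recessive"), .code_dose, D = D)
  names(Xs) <- c("additive", "dominant", "recessive")
  ci0 <- rep(1L, n)
  obs_each <- vapply(Xs, .wald_chisq, 0, ci = ci0)
  obs <- max(obs_each)
  count <- 0L
  for (b in seq_len(n_perm)) {
    sf <- stats::runif(n) < 0.5
    sm <- stats::runif(n) < 0.5
    ci <- 1L + 2L * sf + sm
    stat <- max(vapply(Xs, .wald_chisq, 0, ci = ci))
    if (stat >= obs) count <- count + 1L
  }
  structure(list(unit = unit, stat = obs, stats = obs_each,
                 p = (1 + count) / (n_perm + 1), n_perm = n_perm,
                 n_informative = sum(D[, 1] != D[, 4] | D[, 2] != D[, 3])),
            class = "hla_maxgtdt")
}

#' @export
print.hla_maxgtdt <- function(x, ...) {
  cat("<hla_maxgtdt> ", x$unit, "\n", sep = "")
  cat(sprintf("  MAX chi-square = %.4g, permutation p = %.4g (%d perms)\n",
              x$stat, x$p, x$n_perm))
  invisible(x)
}

# ---- Bradley-Terry multiallelic TDT ----------------------------------------

# connected components of an undirected adjacency matrix
.components <- function(adj) {
  k <- nrow(adj)
  comp <- rep(NA_integer_, k); cur <- 0L
  for (s in seq_len(k)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Bradley-Terry worth parameters by MM iteration on one comparison matrix
.bt_fit <- function(N, tol = 1e-10, max_iter = 10000L) {
  k <- nrow(N)
  tot <- N + t(N)
  adj <- tot > 0
  comp <- .components(adj)
  pi_hat <- numeric(k)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    m <- length(idx)
    if (m == 1L) { pi_hat[idx] <- 1; next }
    Nc <- N[idx, idx, drop = FALSE]; totc <- tot[idx, idx, drop = FALSE]
    w <- rowSums(Nc)
    p <- rep(1 / m, m)
    for (it in seq_len(max_iter)) {
      psum <- outer(p, p, "+")
      frac <- ifelse(totc > 0, totc / psum, 0)
      denom <- rowSums(frac)
      pnew <- ifelse(w > 0, w / denom, 0)
      s <- sum(pnew)
      if (s <= 0) break
      pnew <- pnew / s
      if (max(abs(pnew - p)) < tol * max(p)) { p <- pnew; break }
      p <- pnew
    }
    pi_hat[idx] <- p
  }
  pi_hat
}

#' Multiallelic TDT by the Bradley-Terry model
#'
#' Treats each transmission from a parent heterozygous for the marker as a
#' pairwise contest: the transmitted allele (or block haplotype) "beats" the
#' non-transmitted one. Bradley-Terry worth parameters are fitted by maximum
#' likelihood (MM iterations to relative tolerance 1e-10, worths normalized
#' to sum to one for identifiability) and compared against the null of
#' symmetric transmission (every contest a fair coin) with a likelihood-ratio
#' chi-square on \code{#alleles - 1} degrees of freedom. If the comparison
#' graph is disconnected the model is fitted per connected component and the
#' degrees of freedom add up as \code{sum(k_c - 1)}.
#'
#' @inheritParams decompose
#' @return Object of class \code{hla_mtdt}: allele set, pairwise transmission
#'   matrix \code{N} (\code{N[i, j]} = transmissions of i over j), worth
#'   estimates, LR statistic, df and p-value.
#' @export
mtdt <- function(phased, scope, n_fields = Inf) {
  ct <- count_transmissions(phased, scope, n_fields, het_only = TRUE)
  w <- attr(ct, "contributions")
  units <- sort(unique(c(w$key_t, w$key_u)), method = "radix")
  k <- length(units)
  if (k < 2L)
    return(structure(list(scope = if (length(scope) > 1) paste(scope, collapse = "~") else scope,
                          units = units, N = NULL, lr = NA_real_, df = NA_integer_,
                          p = NA_real_, worth = NULL, n_components = 0L),
                     class = "hla_mtdt"))
  N <- matrix(0L, k, k, dimnames = list(units, units))
  for (r in seq_len(nrow(w)))
    N[w$key_t[r], w$key_u[r]] <- N[w$key_t[r], w$key_u[r]] + 1L
  pi_hat <- .bt_fit(N)
  tot <- N + t(N)
  psum <- outer(pi_hat, pi_hat, "+")
  ll_terms <- ifelse(N > 0, N * log(pi_hat[row(N)] / psum), 0)
  logl <- sum(ll_terms)
  logl0 <- sum(tot[upper.tri(tot)]) * log(0.5)
  comp <- .components(tot > 0)
  df <- sum(table(comp) - 1L)
  lr <- 2 * (logl - logl0)
  structure(list(scope = if (length(scope) > 1) paste(scope, collapse = "~") else scope,
                 units = units, N = N, worth = stats::setNames(pi_hat, units),
                 lr = lr, df = as.integer(df),
                 p = if (df >= 1) stats::pchisq(lr, df, lower.tail = FALSE) else NA_real_,
                 n_components = length(unique(comp))),
            class = "hla_mtdt")
}

#' @export
print.hla_mtdt <- function(x, ...) {
  cat("<hla_mtdt> ", x$scope, ": ", length(x$units), " units\n", sep = "")
  if (!is.na(x$lr))
    cat(sprintf("  LR = %.4g on %d df, p = %.4g\n", x$lr, x$df, x$p))
  else cat("  too few units for a test\n")
  invisible(x)
}

# ---- conditional-logistic TDT with gene-gene interaction -------------------

#' Conditional-logistic TDT with a family-level exposure interaction
#'
#' Extends the additive gTDT for a target unit with an interaction against a
#' binary family-level exposure E (the family carries at least one copy of
#' the conditioning unit in any member): the linear predictor over the
#' 4-genotype risk set is \code{beta_G * x + beta_GxE * x * E}. Reports the
#' relative risk in the exposed stratum \code{exp(beta_G + beta_GxE)} (and
#' \code{exp(beta_G)} for the unexposed stratum, since published conventions
#' differ) with a 2-degree-of-freedom Wald test on
#' \code{(beta_G, beta_GxE)}.
#'
#' @inheritParams gtdt
#' @param exposure_unit Conditioning unit key (must differ from \code{unit}).
#' @param exposure_n_fields Resolution for the exposure match.
#' @return Object of class \code{hla_gxe}.
#' @export
conditional_gtdt_interaction <- function(phased, unit, exposure_unit,
                                         n_fields = Inf,
                                         exposure_n_fields = n_fields,
                                         scope = NULL) {
  if (identical(unit, exposure_unit)) stop("unit and exposure_unit must differ")
  ind <- .unit_indicators(phased, unit, n_fields, scope)
  h <- phased$haplotypes
  ok <- stats::complete.cases(h[, .unit_slots(exposure_unit), drop = FALSE])
  hm <- logical(nrow(h)); hm[ok] <- .hap_matches_unit(h[ok, , drop = FALSE],
                                                      exposure_unit,
                                                      exposure_n_fields)
  E_fam <- tapply(hm, h$family_id, any)
  E <- as.numeric(E_fam[as.character(ind$family_id)])
  D <- .dose_matrix(ind)
  rng <- pmax(D[, 1], D[, 2], D[, 3], D[, 4]) - pmin(D[, 1], D[, 2], D[, 3], D[, 4])
  keep <- rng > 0
  X <- D[keep, , drop = FALSE]; Ei <- E[keep]
  n <- nrow(X)
  if (n == 0L || length(unique(Ei)) < 2L) {
    g0 <- gtdt(phased, unit, n_fields, "additive", scope)
    return(structure(list(unit = unit, exposure_unit = exposure_unit,
                          degenerate = TRUE, fit = g0,
                          beta_g = g0$beta, beta_gxe = NA_real_,
                          rr_exposed = NA_real_, rr_unexposed = g0$rr,
                          ci_exposed = c(NA_real_, NA_real_),
                          wald = NA_real_, df = NA_integer_, p = NA_real_,
                          n_informative = n,
                          note = "exposure constant; interaction dropped"),
                     class = "hla_gxe"))
  }
  Z <- X * Ei
  ci <- rep(1L, n)
  xc <- X[cbind(seq_len(n), ci)]; zc <- Z[cbind(seq_len(n), ci)]
  b <- c(0, 0)
  for (it in seq_len(50L)) {
    eta <- b[1] * X + b[2] * Z
    Ew <- exp(eta); S <- rowSums(Ew)
    mx <- rowSums(X * Ew) / S; mz <- rowSums(Z * Ew) / S
    vxx <- rowSums(X * X * Ew) / S - mx^2
    vzz <- rowSums(Z * Z * Ew) / S - mz^2
    vxz <- rowSums(X * Z * Ew) / S - mx * mz
    g <- c(sum(xc - mx), sum(zc - mz))
    I <- matrix(c(sum(vxx), sum(vxz), sum(vxz), sum(vzz)), 2, 2)
    sol <- try(solve(I, g), silent = TRUE)
    if (inherits(sol, "try-error")) break
    sol <- pmin(pmax(sol, -2), 2)
    b <- b + sol
    b <- pmin(pmax(b, -15), 15)
    if (max(abs(g)) < 1e-10) break
  }
  eta <- b[1] * X + b[2] * Z
  Ew <- exp(eta); S <- rowSums(Ew)
  mx <- rowSums(X * Ew) / S; mz <- rowSums(Z * Ew) / S
  vxx <- rowSums(X * X * Ew) / S - mx^2
  vzz <- rowSums(Z * Z * Ew) / S - mz^2
  vxz <- rowSums(X * Z * Ew) / S - mx * mz
  I <- matrix(c(sum(vxx), sum(vxz), sum(vxz), sum(vzz)), 2, 2)
  V <- solve(I)
  wald <- drop(t(b) %*% I %*% b)
  se_exposed <- sqrt(V[1, 1] + V[2, 2] + 2 * V[1, 2])
  structure(list(unit = unit, exposure_unit = exposure_unit,
                 degenerate = FALSE,
                 beta_g = b[1], beta_gxe = b[2], vcov = V,
                 rr_exposed = exp(b[1] + b[2]),
                 ci_exposed = exp(b[1] + b[2] + c(-1, 1) * 1.96 * se_exposed),
                 rr_unexposed = exp(b[1]),
                 ci_unexposed = exp(b[1] + c(-1, 1) * 1.96 * sqrt(V[1, 1])),
                 rr_interaction = exp(b[2]),
                 wald = wald, df = 2L,
                 p = stats::pchisq(wald, 2, lower.tail = FALSE),
                 n_informative = n, n_exposed = sum(Ei > 0)),
            class = "hla_gxe")
}

#' @export
print.hla_gxe <- function(x, ...) {
  cat("<hla_gxe> ", x$unit, " conditioned on ", x$exposure_unit, "\n", sep = "")
  if (x$degenerate) { cat("  ", x$note, "\n"); return(invisible(x)) }
  cat(sprintf("  RR(exposed) = %.3g (95%% CI %.3g-%.3g); RR(unexposed) = %.3g\n",
              x$rr_exposed, x$ci_exposed[1], x$ci_exposed[2], x$rr_unexposed))
  cat(sprintf("  2-df Wald = %.4g, p = %.4g (n = %d informative, %d exposed)\n",
              x$wald, x$p, x$n_informative, x$n_exposed))
  invisible(x)
}

# ---- stratification ---------------------------------------------------------

#' Stratification: exclude carriers of a unit
#'
#' Implements the stratified reruns: \code{stratify_trios()} removes every
#' family with at least one member carrying the unit (the four parental
#' haplotypes cover all alleles present in the trio);
#' \code{stratify_cohort()} removes individual carrier subjects. Haplotype
#' (multi-locus) units in a cohort require the phased \code{hap1}/\code{hap2}
#' columns.
#'
#' @param trios A trio table.
#' @param unit,n_fields Unit key and match resolution; the default
#'   (\code{NULL}) matches at the unit's own field depth, so a two-field
#'   exclusion key excludes every carrier of any finer-resolution variant.
#' @param phased Optional pre-computed [phase_trios()] result for the table.
#' @return The filtered table; attribute \code{"excluded"} lists removals.
#' @export
stratify_trios <- function(trios, unit, n_fields = NULL, phased = NULL) {
  if (is.null(phased)) phased <- phase_trios(trios)
  h <- phased$haplotypes
  ok <- stats::complete.cases(h[, .unit_slots(unit), drop = FALSE])
  hm <- logical(nrow(h)); hm[ok] <- .hap_matches_unit(h[ok, , drop = FALSE],
                                                      unit, n_fields)
  carrier <- names(which(tapply(hm, h$family_id, any)))
  out <- trios[!trios$family_id %in% carrier, , drop = FALSE]
  attr(out, "excluded") <- carrier
  out
}

#' @rdname stratify_trios
#' @param cohort A cohort table.
#' @export
stratify_cohort <- function(cohort, unit, n_fields = NULL) {
  slots <- .unit_slots(unit)
  if (length(slots) > 1L) {
    if (!all(c("hap1", "hap2") %in% names(cohort)))
      stop("haplotype-level stratification needs phased hap1/hap2 columns")
    carrier <- .cohort_hap_matches(cohort, unit, n_fields)
  } else {
    nf <- if (is.null(n_fields)) .unit_depths(unit) else n_fields
    al <- c(.split_geno(cohort[[slots]], 1L), .split_geno(cohort[[slots]], 2L))
    hit <- matrix(.atrunc(al, nf) == unit, ncol = 2L)
    carrier <- hit[, 1] | hit[, 2]
  }
  out <- cohort[!carrier, , drop = FALSE]
  attr(out, "excluded") <- cohort$subject_id[carrier]
  out
}

.split_geno <- function(g, side) {
  vapply(strsplit(g, "+", fixed = TRUE), `[`, "", side)
}

# does either phased cohort haplotype match a unit?
.cohort_hap_matches <- function(cohort, unit, n_fields) {
  hit <- rep(FALSE, nrow(cohort))
  for (col in c("hap1", "hap2")) {
    hd <- .hapstr_to_df(cohort[[col]])
    hit <- hit | .hap_matches_unit(hd, unit, n_fields)
  }
  hit
}

.hapstr_to_df <- function(s) {
  nl <- length(hla_loci())
  blank <- paste(rep("NA", nl), collapse = "~")
  m <- do.call(rbind, strsplit(ifelse(is.na(s), blank, s), "~", fixed = TRUE))
  m[m == "NA"] <- NA_character_
  if (ncol(m) != length(hla_loci()))
    stop("phased haplotype strings must carry all ", length(hla_loci()), " slots")
  colnames(m) <- hla_loci()
  as.data.frame(m, stringsAsFactors = FALSE)
}
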