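#' Configuration for the standard analysis battery
#'
#' Controls which scopes, resolutions and tests [run_all()] executes. The
#' default battery covers the 30 standard scopes (11 genes + 19 blocks) at
#' both resolutions — 60 test groups.
#'
#' @param scopes Scope names (default [analysis_scopes()]).
#' @param depths Named numeric vector of resolutions
#'   (default \code{c(untruncated = Inf, two_field = 2)}).
#' @param tests Subset of \code{c("gtdt", "mtdt", "cc")}.
#' @param gtdt_model Genetic coding for the per-unit gTDT rows.
#' @param alpha Significance threshold for [report_significant()].
#' @param bin_threshold Minimum expected count before a case-control unit is
#'   binned.
#' @param min_informative Minimum informative families for a gTDT unit row.
#' @param stratify_units Unit keys; the whole battery is rerun once per unit
#'   on the carrier-excluded subset.
#' @param seed Seed recorded in the run metadata (the base battery is
#'   deterministic; the seed feeds optional permutation-based follow-ups).
#' @return List of class \code{hla_config}.
#' @export
analysis_config <- function(scopes = analysis_scopes(),
                            depths = c(untruncated = Inf, two_field = 2),
                            tests = c("gtdt", "mtdt", "cc"),
                            gtdt_model = "additive",
                            alpha = 0.05, bin_threshold = 5,
                            min_informative = 5L,
                            stratify_units = character(0),
                            seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stopifnot(all(tests %in% c("gtdt", "mtdt", "cc")))
  for (s in scopes) .make_scope(s)  # validates
  for (u in stratify_units) .unit_slots(u)
  structure(list(scopes = scopes, depths = depths, tests = tests,
                 gtdt_model = gtdt_model, alpha = alpha,
                 bin_threshold = bin_threshold,
                 min_informative = as.integer(min_informative),
                 stratify_units = stratify_units, seed = seed),
            class = "hla_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Reads the fields of [analysis_config()] from YAML; omitted fields keep
#' their defaults. \code{depths} may use the string \code{"Inf"}.
#'
#' @param path YAML file path.
#' @return An \code{hla_config}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$depths)) raw$depths <- vapply(raw$depths, function(x)
    if (identical(x, "Inf")) Inf else as.numeric(x), 0)
  do.call(analysis_config, raw)
}

.empty_results <- function() {
  data.frame(stratum = character(0), scope = character(0),
             scope_type = character(0), depth = character(0),
             test = character(0), model = character(0), unit = character(0),
             estimate = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
             statistic = numeric(0), p = numeric(0), n = integer(0),
             note = character(0), stringsAsFactors = FALSE)
}

.row <- function(stratum, scope, scope_type, depth, test, model, unit,
                 estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 statistic = NA_real_, p = NA_real_, n = NA_integer_,
                 note = "") {
  data.frame(stratum = stratum, scope = scope, scope_type = scope_type,
             depth = depth, test = test, model = model, unit = unit,
             estimate = estimate, ci_low = ci_low, ci_high = ci_high,
             statistic = statistic, p = p, n = n, note = note,
             stringsAsFactors = FALSE)
}

#' Run the unified association battery
#'
#' Phases the trio families once, then runs, for every configured scope and
#' resolution, the per-unit genotypic TDT, the multiallelic Bradley-Terry
#' TDT, and (when a cohort is supplied) the case-control locus test —
#' one unified results table mirroring a 60-test summary report. Optional
#' stratified reruns repeat the battery after excluding carriers of the
#' configured units. Failures of individual stages are recorded in the
#' \code{note} column and do not stop the run.
#'
#' @param trios Trio table (may be ambiguous; resolved internally). May be
#'   \code{NULL} to run case-control only.
#' @param cohort Optional cohort table for case-control tests.
#' @param config An [analysis_config()].
#' @return Object of class \code{hla_run}: \code{results} data frame,
#'   \code{exclusions} (per family/subject audit log), \code{meta}.
#' @export
run_all <- function(trios, cohort = NULL, config = analysis_config()) {
  t0 <- Sys.time()
  exclusions <- data.frame(stratum = character(0), id = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  results <- list()
  phased <- NULL
  if (!is.null(trios) && nrow(trios)) {
    phased <- phase_trios(trios)
    if (nrow(phased$flags))
      exclusions <- rbind(exclusions, data.frame(
        stratum = "all", id = phased$flags$family_id,
        reason = paste0(phased$flags$flag, ":", phased$flags$locus),
        stringsAsFactors = FALSE))
  }
  results[[length(results) + 1L]] <-
    .run_battery("all", phased, cohort, config)
  for (u in config$stratify_units) {
    st <- paste0("excl:", u)
    tr2 <- ph2 <- NULL
    if (!is.null(phased)) {
      tr2 <- stratify_trios(trios, u, phased = phased)
      if (length(attr(tr2, "excluded")))
        exclusions <- rbind(exclusions, data.frame(
          stratum = st, id = attr(tr2, "excluded"),
          reason = "stratification_carrier", stringsAsFactors = FALSE))
      ph2 <- if (nrow(tr2)) phase_trios(tr2) else NULL
    }
    co2 <- NULL
    if (!is.null(cohort)) {
      co2 <- stratify_cohort(cohort, u)
      if (length(attr(co2, "excluded")))
        exclusions <- rbind(exclusions, data.frame(
          stratum = st, id = attr(co2, "excluded"),
          reason = "stratification_carrier", stringsAsFactors = FALSE))
    }
    results[[length(results) + 1L]] <- .run_battery(st, ph2, co2, config)
  }
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  structure(list(results = res, exclusions = exclusions,
                 meta = list(seed = config$seed,
                             n_families = if (is.null(phased)) 0L else
                               length(phased$families),
                             n_cases = if (is.null(cohort)) 0L else
                               sum(cohort$group == "case"),
                             n_controls = if (is.null(cohort)) 0L else
                               sum(cohort$group == "control"),
                             scopes = config$scopes,
                             depths = names(config$depths),
                             started = format(t0, usetz = TRUE))),
            class = "hla_run")
}

.run_battery <- function(stratum, phased, cohort, config) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  for (scope in config$scopes) {
    sc <- .make_scope(scope)
    for (di in seq_along(config$depths)) {
      depth_name <- names(config$depths)[di]
      nf <- config$depths[[di]]
      if ("gtdt" %in% config$tests && !is.null(phased)) {
        ct <- try(count_transmissions(phased, scope, nf, het_only = TRUE),
                  silent = TRUE)
        if (inherits(ct, "try-error")) {
          add(.row(stratum, scope, sc$type, depth_name, "gtdt",
                   config$gtdt_model, "", note = attr(ct, "condition")$message))
        } else {
          units <- ct$unit
          fk <- .family_keys(phased, scope, nf)
          for (u in units) {
            g <- try(.gtdt_on_keys(fk, u, config$gtdt_model), silent = TRUE)
            if (inherits(g, "try-error")) {
              add(.row(stratum, scope, sc$type, depth_name, "gtdt",
                       config$gtdt_model, u,
                       note = attr(g, "condition")$message))
            } else if (g$n_informative >= config$min_informative) {
              add(.row(stratum, scope, sc$type, depth_name, "gtdt",
                       config$gtdt_model, u, estimate = g$rr,
                       ci_low = g$ci[1], ci_high = g$ci[2],
                       statistic = g$score_stat, p = g$p,
                       n = g$n_informative,
                       note = if (g$separated) "separated" else ""))
            }
          }
        }
      }
      if ("mtdt" %in% config$tests && !is.null(phased)) {
        m <- try(mtdt(phased, scope, nf), silent = TRUE)
        if (inherits(m, "try-error")) {
          add(.row(stratum, scope, sc$type, depth_name, "mtdt", "", "",
                   note = attr(m, "condition")$message))
        } else {
          add(.row(stratum, scope, sc$type, depth_name, "mtdt", "", "",
                   statistic = m$lr, p = m$p,
                   n = if (is.null(m$N)) 0L else sum(m$N),
                   note = if (is.na(m$lr)) "too few units" else ""))
        }
      }
      if ("cc" %in% config$tests && !is.null(cohort) && nrow(cohort)) {
        keys <- try(cohort_keys(cohort, scope, nf), silent = TRUE)
        if (inherits(keys, "try-error")) {
          add(.row(stratum, scope, sc$type, depth_name, "cc", "", "",
                   note = attr(keys, "condition")$message))
        } else {
          is_case <- cohort$group == "case"
          cc <- locus_cc_test(as.vector(keys[is_case, ]),
                              as.vector(keys[!is_case, ]),
                              config$bin_threshold)
          add(.row(stratum, scope, sc$type, depth_name, "cc", "overall", "",
                   statistic = cc$overall$chisq, p = cc$overall$p,
                   n = sum(cc$counts),
                   note = if (cc$overall$skipped) "skipped" else ""))
          pu <- cc$per_unit[!cc$per_unit$binned, , drop = FALSE]
          for (r in seq_len(nrow(pu))) {
            add(.row(stratum, scope, sc$type, depth_name, "cc", "allele",
                     pu$unit[r], estimate = pu$or[r],
                     ci_low = pu$ci_low[r], ci_high = pu$ci_high[r],
                     p = pu$p[r],
                     n = pu$case_count[r] + pu$control_count[r]))
          }
        }
      }
    }
  }
  if (!length(rows)) return(.empty_results())
  do.call(rbind, rows)
}

#' @export
print.hla_run <- function(x, ...) {
  cat("<hla_run> ", nrow(x$results), " result rows over ",
      length(unique(paste(x$results$scope, x$results$depth))),
      " scope-depth groups (", x$meta$n_families, " families, ",
      x$meta$n_cases, "/", x$meta$n_controls, " cases/controls)\n", sep = "")
  invisible(x)
}

#' Filter the unified results to significant rows
#'
#' Keeps rows with \code{p < alpha}; optionally appends a
#' Benjamini-Hochberg FDR column (computed over all testable rows before
#' filtering).
#'
#' @param run An \code{hla_run} or its \code{results} data frame.
#' @param alpha Significance threshold.
#' @param fdr Append a \code{p_bh} column?
#' @return Filtered results data frame.
#' @export
report_significant <- function(run, alpha = 0.05, fdr = FALSE) {
  res <- if (inherits(run, "hla_run")) run$results else run
  if (fdr) res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res[!is.na(res$p) & res$p < alpha, , drop = FALSE]
}

#' Write a run to disk
#'
#' Writes \code{results.csv}, \code{exclusions.csv} and \code{meta.json}
#' (seeds, sizes, package version) into a directory.
#'
#' @param run An \code{hla_run}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "hla_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(run$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(run$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  meta <- run$meta
  meta$package_version <- as.character(utils::packageVersion("hlatrio"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
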