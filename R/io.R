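#' Read a trio-family genotype table
#'
#' Input is UTF-8 delimited text (tab- or comma-separated, chosen by file
#' extension) with columns \code{family_id}, \code{subject_id},
#' \code{relation} (\code{father}/\code{mother}/\code{child}) and one
#' GL-string genotype column per haplotype slot (see [hla_loci()]).
#'
#' @param path File path.
#' @param sep Field separator; defaults to \code{","} for \code{.csv} files
#'   and \code{"\t"} otherwise.
#' @return A data frame, one row per subject.
#' @export
read_trio_table <- function(path, sep = NULL) {
  df <- .read_delim(path, sep)
  .validate_trio_table(df)
  df
}

#' @rdname read_trio_table
#' @param df A trio table.
#' @export
write_trio_table <- function(df, path, sep = NULL) {
  .validate_trio_table(df)
  .write_delim(df, path, sep)
}

#' Read an unrelated case/control genotype table
#'
#' Columns: \code{subject_id}, \code{group} (\code{case}/\code{control}), one
#' GL-string genotype column per slot, and optionally \code{hap1}/\code{hap2}
#' columns holding phased \code{~}-joined haplotype strings (emitted by the
#' synthetic generator; required for haplotype-block case-control tests).
#'
#' @inheritParams read_trio_table
#' @return A data frame, one row per subject.
#' @export
read_cohort_table <- function(path, sep = NULL) {
  df <- .read_delim(path, sep)
  .validate_cohort_table(df)
  df
}

#' @rdname read_cohort_table
#' @param df A cohort table.
#' @export
write_cohort_table <- function(df, path, sep = NULL) {
  .validate_cohort_table(df)
  .write_delim(df, path, sep)
}

#' Export phased haplotypes and transmission counts
#'
#' \code{write_phased()} writes one row per haplotype (family, source,
#' transmitted flag, and the \code{~}-joined haplotype string);
#' \code{write_transmissions()} writes the per-scope transmitted /
#' non-transmitted count table (scope, unit key, T, U) for any set of
#' scopes, the shape of a raw segregation-count supplement.
#'
#' @param phased An \code{hla_phased} object from [phase_trios()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_phased <- function(phased, path) {
  stopifnot(inherits(phased, "hla_phased"))
  h <- phased$haplotypes
  hap <- apply(as.matrix(h[, hla_loci()]), 1L, function(r)
    if (anyNA(r)) NA_character_ else paste(r, collapse = "~"))
  out <- data.frame(family_id = h$family_id, source = h$source,
                    transmitted = h$transmitted, haplotype = hap,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phased
#' @param scopes Scope names to tabulate (default: the full battery).
#' @param n_fields Allele resolution.
#' @param het_only Restrict to heterozygous parents (the TDT view); the
#'   default keeps homozygous-parent meioses, which contribute equally to
#'   T and U.
#' @export
write_transmissions <- function(phased, path, scopes = analysis_scopes(),
                                n_fields = Inf, het_only = FALSE) {
  stopifnot(inherits(phased, "hla_phased"))
  out <- do.call(rbind, lapply(scopes, function(sc) {
    ct <- count_transmissions(phased, sc, n_fields, het_only)
    if (!nrow(ct)) return(NULL)
    data.frame(scope = sc, ct, stringsAsFactors = FALSE)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

.read_delim <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", encoding = "UTF-8")
}

.write_delim <- function(df, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.validate_trio_table <- function(df) {
  need <- c("family_id", "subject_id", "relation", hla_loci())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trio table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$relation), c("father", "mother", "child"))
  if (length(bad))
    stop("unknown relation value(s): ", paste(bad, collapse = ", "))
  invisible(df)
}

.validate_cohort_table <- function(df) {
  need <- c("subject_id", "group", hla_loci())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad))
    stop("unknown group value(s): ", paste(bad, collapse = ", "))
  invisible(df)
}
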