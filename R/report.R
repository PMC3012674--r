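# Genome and validation summary reports with a fixed, documented rounding
# rule (half away from zero) applied uniformly to printed percentages.

#' Round half away from zero
#'
#' Unlike base `round()` (banker's rounding), halves always move away from
#' zero: `round_half_away(0.5) == 1`, `round_half_away(-0.5) == -1`.
#' @param x Numeric vector.
#' @param digits Decimal digits (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summarize a genome's general statistics
#'
#' Computes the standard genome-table quantities: CDS count, counts and
#' percentages of function-assigned vs hypothetical CDS, mean CDS length,
#' percent of the genome that is coding, and RNA feature counts. Accepts
#' either a full [genome_record()] (coding bp summed from gene
#' coordinates) or the summary inputs directly (`cds_count` and
#' `mean_cds_length`, in which case coding bp = count x mean length).
#' All percentages are rounded half away from zero to integers; the
#' rounding rule is recorded in the output.
#'
#' @param record A [genome_record()], or `NULL` when supplying summary
#'   inputs.
#' @param size_bp Genome size (required with summary inputs).
#' @param cds_count,mean_cds_length Summary inputs used when `record` is
#'   `NULL`.
#' @param assigned Either an integer count of CDS with assigned function,
#'   or (with a record) a character vector of gene ids with assigned
#'   function.
#' @return Object of class `GenomeSummary` (a list): `size_bp`,
#'   `cds_count`, `assigned`, `hypothetical`, `pct_assigned`,
#'   `pct_hypothetical`, `mean_cds_length`, `pct_coding`, `rna_counts`,
#'   `rounding`.
#' @export
summarize_genome <- function(record = NULL, size_bp = NULL, cds_count = NULL,
                             mean_cds_length = NULL, assigned = NULL) {
  if (!is.null(record)) {
    stopifnot(inherits(record, "GenomeRecord"))
    size_bp <- record$size_bp
    cds <- record$genes[record$genes$is_cds, , drop = FALSE]
    cds_count <- nrow(cds)
    coding_bp <- sum(cds$end - cds$start)
    mean_cds_length <- if (cds_count) coding_bp / cds_count else 0
    rna <- record$rna_counts
    if (is.character(assigned)) assigned <- sum(cds$gene_id %in% assigned)
  } else {
    if (is.null(size_bp) || is.null(cds_count) || is.null(mean_cds_length)) {
      stop("need size_bp, cds_count and mean_cds_length without a record")
    }
    coding_bp <- cds_count * mean_cds_length
    rna <- c(rRNA = NA_integer_, ncRNA = NA_integer_, tRNA = NA_integer_)
  }
  if (size_bp <= 0) stop("genome size must be positive")
  assigned <- if (is.null(assigned)) NA_integer_ else as.integer(assigned)
  hypo <- if (is.na(assigned)) NA_integer_ else cds_count - assigned
  structure(
    list(size_bp = size_bp,
         cds_count = cds_count,
         assigned = assigned,
         hypothetical = hypo,
         pct_assigned = if (is.na(assigned)) NA_real_ else
           round_half_away(100 * assigned / cds_count),
         pct_hypothetical = if (is.na(hypo)) NA_real_ else
           round_half_away(100 * hypo / cds_count),
         mean_cds_length = mean_cds_length,
         pct_coding = round_half_away(100 * coding_bp / size_bp),
         rna_counts = rna,
         rounding = "half-away-from-zero to integer percent"),
    class = "GenomeSummary")
}

#' @export
print.GenomeSummary <- function(x, ...) {
  cat("GenomeSummary\n")
  cat(sprintf("  genome size: %s bp\n", format(x$size_bp, big.mark = ",")))
  cat(sprintf("  CDS: %s (assigned %s = %s%%, hypothetical %s = %s%%)\n",
              format(x$cds_count, big.mark = ","),
              format(x$assigned, big.mark = ","), x$pct_assigned,
              format(x$hypothetical, big.mark = ","), x$pct_hypothetical))
  cat(sprintf("  mean CDS length: %s nt; percent coding: %s%%\n",
              format(round(x$mean_cds_length)), x$pct_coding))
  invisible(x)
}

#' Summarize an expression-validation experiment
#'
#' Given the number of predicted features confirmed by hybridization and
#' the total predicted, reports the confirmed / not-detected counts and
#' their integer percentages (rounded half away from zero).
#'
#' @param confirmed Number confirmed (0 <= confirmed <= total).
#' @param total Total predicted (> 0).
#' @return List: `confirmed`, `not_detected`, `pct_confirmed`,
#'   `pct_not_detected`, `rounding`.
#' @export
validation_summary <- function(confirmed, total) {
  if (total <= 0) stop("total must be positive")
  if (confirmed < 0 || confirmed > total) {
    stop("confirmed must be between 0 and total")
  }
  list(confirmed = confirmed,
       not_detected = total - confirmed,
       pct_confirmed = round_half_away(100 * confirmed / total),
       pct_not_detected = round_half_away(100 * (total - confirmed) / total),
       rounding = "half-away-from-zero to integer percent")
}
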