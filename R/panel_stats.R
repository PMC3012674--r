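# Cross-genome panel statistics: standardized category counts, the combined
# score used to rank genomes across the panel, count-vs-size regression,
# percentile flagging, and COG-profile correlation clustering.

#' Construct a panel matrix
#'
#' A `PanelMatrix` holds, for a panel of genomes, the genome sizes and the
#' per-genome count of each gene category. It is the input to all panel
#' statistics.
#'
#' @param genome_id Character vector of genome ids (unique).
#' @param size_bp Numeric vector of genome sizes in bp.
#' @param counts `data.frame` or matrix of nonnegative integer counts, one
#'   row per genome, one column per category. Missing values are treated
#'   as 0.
#' @return Object of class `PanelMatrix`.
#' @export
panel_matrix <- function(genome_id, size_bp, counts) {
  stopifnot(length(genome_id) == length(size_bp),
            nrow(counts) == length(genome_id))
  if (anyDuplicated(genome_id)) stop("genome ids must be unique")
  if (any(size_bp <= 0)) stop("genome sizes must be positive")
  counts <- as.matrix(counts)
  counts[is.na(counts)] <- 0
  if (any(counts < 0)) stop("counts must be nonnegative")
  rownames(counts) <- genome_id
  structure(list(genome_id = genome_id, size_bp = as.numeric(size_bp),
                 counts = counts, categories = colnames(counts)),
            class = "PanelMatrix")
}

#' @export
print.PanelMatrix <- function(x, ...) {
  cat("PanelMatrix:", length(x$genome_id), "genomes x",
      length(x$categories), "categories (",
      paste(x$categories, collapse = ", "), ")\n")
  invisible(x)
}

#' Read/write a panel matrix as TSV
#'
#' Columns: `genome_id`, `size_bp`, then one column per category.
#' @param panel A [panel_matrix()].
#' @param path File path.
#' @return `read_panel_tsv()` returns a `PanelMatrix`.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- data.frame(genome_id = panel$genome_id, size_bp = panel$size_bp,
                   panel$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  panel_matrix(df$genome_id, df$size_bp,
               df[, setdiff(names(df), c("genome_id", "size_bp")), drop = FALSE])
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardize panel counts to z-scores
#'
#' For each category c the count of genome g is standardized as
#' z = (x - mu_c) / sigma_c with the panel mean mu_c and *population*
#' standard deviation sigma_c (divisor n): the panel is treated as the
#' population of interest. A zero-variance category yields all-zero
#' z-scores with a warning.
#'
#' @param panel A [panel_matrix()].
#' @param per_mbp If `TRUE`, standardize gene densities (counts per Mbp of
#'   genome) instead of raw counts.
#' @return Numeric matrix of z-scores (genomes x categories).
#' @export
zscore_table <- function(panel, per_mbp = FALSE) {
  stopifnot(inherits(panel, "PanelMatrix"))
  if (length(panel$genome_id) < 2L) {
    stop("z-scores require a panel of at least 2 genomes")
  }
  x <- panel$counts
  if (per_mbp) x <- x / (panel$size_bp / 1e6)
  z <- x
  for (j in seq_len(ncol(x))) {
    s <- pop_sd(x[, j])
    if (s == 0) {
      warning("category '", colnames(x)[j],
              "' has zero variance; its z-scores are set to 0")
      z[, j] <- 0
    } else {
      z[, j] <- (x[, j] - mean(x[, j])) / s
    }
  }
  z
}

#' Per-genome combined score across the designated categories
#'
#' The combined score of a genome is the unweighted mean of its per-category
#' z-scores over the four designated categories (two-component system,
#' transcription factor, transport, defense by default): a dimensionless
#' measure of how far, in standard deviations, a genome's regulatory and
#' transport gene complement sits above or below the panel. The normalized
#' variant standardizes gene densities (counts per Mbp) before averaging,
#' removing the trivial dependence of absolute counts on genome size.
#'
#' @param panel A [panel_matrix()].
#' @param categories The categories averaged (all must be present).
#' @param normalized If `TRUE`, use per-Mbp densities (see [zscore_table()]).
#' @return Named numeric vector of scores, one per genome.
#' @export
combined_scores <- function(panel,
                            categories = c("tcs", "tf", "transport", "defense"),
                            normalized = FALSE) {
  stopifnot(inherits(panel, "PanelMatrix"))
  miss <- setdiff(categories, panel$categories)
  if (length(miss)) {
    stop("configuration error: categories missing from panel: ",
         paste(miss, collapse = ", "))
  }
  z <- zscore_table(panel, per_mbp = normalized)
  rowMeans(z[, categories, drop = FALSE])
}

#' Ordinary least squares fit of category count against genome size
#'
#' @param panel A [panel_matrix()].
#' @param category Category column to fit.
#' @return List with `slope_per_mbp`, `intercept`, `r` (signed Pearson
#'   correlation) and the underlying `lm` fit.
#' @export
fit_count_size_regression <- function(panel, category) {
  stopifnot(inherits(panel, "PanelMatrix"))
  if (!category %in% panel$categories) {
    stop("configuration error: unknown category '", category, "'")
  }
  size_mbp <- panel$size_bp / 1e6
  if (length(unique(size_mbp)) < 2L) {
    stop("degenerate fit: all genome sizes identical")
  }
  if (length(size_mbp) < 3L) stop("regression requires at least 3 genomes")
  y <- panel$counts[, category]
  fit <- stats::lm(y ~ size_mbp)
  list(slope_per_mbp = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(size_mbp, y),
       fit = fit)
}

#' Percentile ranks and top-fraction flags
#'
#' The percentile rank of a value is the fraction of panel members with a
#' strictly smaller value; ties share the lower rank (conservative
#' flagging). A genome is flagged when its rank is at least
#' `1 - top_fraction`, i.e. it lies in the upper `top_fraction` of the
#' panel.
#'
#' @param values Named numeric vector (e.g. counts or combined scores).
#' @param top_fraction Fraction defining the upper tail, in (0, 1).
#' @return `data.frame` with columns `value`, `rank` (in \[0, 1\]) and
#'   `flagged`.
#' @export
rank_and_flag <- function(values, top_fraction = 0.01) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  if (!length(values)) stop("empty panel")
  n <- length(values)
  rnk <- vapply(values, function(v) sum(values < v) / n, 0)
  data.frame(value = as.numeric(values), rank = rnk,
             flagged = rnk >= 1 - top_fraction,
             row.names = names(values), stringsAsFactors = FALSE)
}

#' Pearson-correlation clustering of COG abundance profiles
#'
#' Computes the genome-by-genome Pearson correlation matrix of COG
#' abundance vectors (absent COGs count 0) and orders the genomes by
#' average-linkage hierarchical clustering on the distance 1 - r.
#' A zero-variance profile gets correlation 0 with every other genome,
#' with a warning.
#'
#' @param profiles Numeric matrix: genomes in rows, COG ids in columns.
#' @return List with `correlation` (symmetric, unit diagonal), `order`
#'   (leaf order, genome ids), `hclust` (the tree).
#' @export
cog_profile_cluster <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 genomes")
  sds <- apply(profiles, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(profiles)))
  if (any(sds == 0)) {
    warning("zero-variance COG profile(s): ",
            paste(rownames(profiles)[sds == 0], collapse = ", "),
            "; their correlations are set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(correlation = r, order = rownames(profiles)[hc$order], hclust = hc)
}
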