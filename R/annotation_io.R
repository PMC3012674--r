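# Readers/writers for the annotation formats the pipeline touches, and the
# in-memory genome model every downstream module consumes.
#
# Coordinate convention: genes are stored 0-based half-open; all file I/O is
# 1-based inclusive (GFF3 convention), so length arithmetic is always
# end - start with no off-by-one corrections.

#' Construct a genome record
#'
#' A `GenomeRecord` bundles everything known about one annotated genome:
#' its genes (with coordinates and strand on named replicons), protein-domain
#' hits, COG assignments and RNA feature counts. It is the unit of input for
#' inventories, two-component-system topology analysis and genome summaries.
#'
#' @param genome_id Single string identifying the genome.
#' @param size_bp Total genome size in bp (positive integer). May be a named
#'   vector of per-replicon sizes; the genome size is then their sum.
#' @param genes `data.frame` with columns `gene_id`, `replicon_id`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`), `product`, `is_cds`.
#' @param domain_hits `data.frame` with columns `gene_id`, `accession`,
#'   `e_value`, `bit_score` (as returned by [read_domain_hits()]).
#' @param cog_assignments `data.frame` with columns `gene_id`, `cog_id`,
#'   `categories` (string of single-letter functional category codes).
#' @param rna_counts Named integer vector with elements `rRNA`, `ncRNA`,
#'   `tRNA` (missing entries default to 0).
#'
#' @return An object of class `GenomeRecord`. Genes are sorted by
#'   `(replicon_id, start)`.
#' @export
genome_record <- function(genome_id, size_bp, genes,
                          domain_hits = empty_domain_hits(),
                          cog_assignments = empty_cog_assignments(),
                          rna_counts = c(rRNA = 0L, ncRNA = 0L, tRNA = 0L)) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (any(size_bp <= 0)) stop("size_bp must be positive")
  genes <- validate_genes(genes)
  if (!is.null(names(size_bp))) {
    sizes <- size_bp
    total <- sum(size_bp)
  } else {
    stopifnot(length(size_bp) == 1L)
    sizes <- NULL
    total <- as.numeric(size_bp)
  }
  if (nrow(genes) > 0L) {
    if (!is.null(sizes)) {
      bad <- genes$end > sizes[genes$replicon_id]
      if (any(bad, na.rm = TRUE) || anyNA(bad)) {
        stop("gene coordinates exceed replicon size (or unknown replicon)")
      }
    } else if (any(genes$end > total)) {
      stop("gene coordinates exceed genome size")
    }
  }
  rc <- c(rRNA = 0L, ncRNA = 0L, tRNA = 0L)
  rc[names(rna_counts)] <- as.integer(rna_counts)
  if (any(rc < 0)) stop("rna_counts must be nonnegative")
  structure(
    list(genome_id = genome_id, size_bp = total, replicon_sizes = sizes,
         genes = genes, domain_hits = domain_hits,
         cog_assignments = cog_assignments, rna_counts = rc),
    class = "GenomeRecord"
  )
}

validate_genes <- function(genes) {
  need <- c("gene_id", "replicon_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes is missing columns: ", paste(miss, collapse = ", "))
  if (!"product" %in% names(genes)) genes$product <- ""
  if (!"is_cds" %in% names(genes)) genes$is_cds <- TRUE
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (nrow(genes) && any(genes$start >= genes$end)) stop("gene start must be < end")
  if (nrow(genes) && !all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  genes <- genes[order(genes$replicon_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

empty_genes <- function() {
  data.frame(gene_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character(),
             product = character(), is_cds = logical(),
             stringsAsFactors = FALSE)
}

empty_domain_hits <- function() {
  data.frame(gene_id = character(), accession = character(),
             e_value = numeric(), bit_score = numeric(),
             stringsAsFactors = FALSE)
}

empty_cog_assignments <- function() {
  data.frame(gene_id = character(), cog_id = character(),
             categories = character(), stringsAsFactors = FALSE)
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat("GenomeRecord", x$genome_id, "\n")
  cat("  size:", format(x$size_bp, big.mark = ","), "bp;",
      nrow(x$genes), "genes on",
      length(unique(x$genes$replicon_id)), "replicon(s)\n")
  cat("  domain hits:", nrow(x$domain_hits),
      " COG assignments:", nrow(x$cog_assignments), "\n")
  cat("  RNA features:", paste(names(x$rna_counts), x$rna_counts,
                               sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read genome features into a GenomeRecord
#'
#' Supports GFF3 (parsed with \pkg{rtracklayer} after a line-level validation
#' pass so malformed rows are reported with their line number) and a simple
#' tab-separated feature table with header columns `feature`, `replicon_id`,
#' `start`, `end`, `strand`, `gene_id`, `product`. File coordinates are
#' 1-based inclusive and converted to the internal 0-based half-open
#' convention.
#'
#' Feature types `rRNA`, `ncRNA` and `tRNA` are tallied into `rna_counts`
#' rather than stored as genes; `CDS` and `gene` rows become gene entries
#' (`is_cds` reflects the type).
#'
#' @param path Path to the feature file.
#' @param format `"gff3"` or `"genbank_table"`.
#' @param genome_id Genome identifier; defaults to the file base name.
#' @param size_bp Optional genome/replicon sizes. For GFF3, taken from
#'   `##sequence-region` directives when present, else the maximum feature
#'   end per replicon.
#' @return A [genome_record()].
#' @export
read_features <- function(path, format = c("gff3", "genbank_table"),
                          genome_id = NULL, size_bp = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "gff3") read_features_gff3(path, genome_id, size_bp)
  else read_features_table(path, genome_id, size_bp)
}

read_features_gff3 <- function(path, genome_id, size_bp) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  seqreg <- grep("^##sequence-region", lines, value = TRUE)
  for (i in which(body)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) {
      stop("malformed GFF3 line ", i, ": expected >= 8 tab-separated fields")
    }
    s <- suppressWarnings(as.numeric(f[4L]))
    e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e)) {
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
    }
    if (e < s) stop("coordinate error at GFF3 line ", i, ": end < start")
  }
  if (!any(body)) {
    sizes <- parse_sequence_regions(seqreg)
    return(genome_record(genome_id,
                         if (length(sizes)) sizes else stop_if_null(size_bp),
                         empty_genes()))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  rna <- c(rRNA = sum(type == "rRNA"), ncRNA = sum(type == "ncRNA"),
           tRNA = sum(type == "tRNA"))
  keep <- type %in% c("gene", "CDS")
  gr2 <- gr[keep]
  ids <- gr2$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr2))
  if (!is.null(gr2$locus_tag)) {
    ids <- ifelse(is.na(ids), gr2$locus_tag, ids)
  }
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  prod <- gr2$product
  if (is.null(prod)) prod <- rep("", length(gr2))
  prod[is.na(prod)] <- ""
  genes <- data.frame(
    gene_id = as.character(ids),
    replicon_id = as.character(GenomicRanges::seqnames(gr2)),
    start = GenomicRanges::start(gr2) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr2),
    strand = as.character(GenomicRanges::strand(gr2)),
    product = as.character(prod),
    is_cds = type[keep] == "CDS",
    stringsAsFactors = FALSE
  )
  sizes <- parse_sequence_regions(seqreg)
  if (!length(sizes)) {
    if (!is.null(size_bp)) {
      sizes <- size_bp
    } else {
      sizes <- tapply(genes$end, genes$replicon_id, max)
      sizes <- stats::setNames(as.numeric(sizes), names(sizes))
    }
  }
  genome_record(genome_id, sizes, genes, rna_counts = rna)
}

parse_sequence_regions <- function(lines) {
  if (!length(lines)) return(numeric())
  f <- strsplit(trimws(sub("^##sequence-region", "", lines)), "\\s+")
  stats::setNames(vapply(f, function(x) as.numeric(x[3L]), 0),
                  vapply(f, `[`, "", 1L))
}

stop_if_null <- function(x) {
  if (is.null(x)) stop("size_bp required for a feature-less file")
  x
}

read_features_table <- function(path, genome_id, size_bp) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", blank.lines.skip = TRUE)
  need <- c("feature", "replicon_id", "start", "end", "strand", "gene_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("feature table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(tab$start) || !is.numeric(tab$end)) {
    stop("parse error: non-numeric coordinates in feature table")
  }
  if (nrow(tab) && any(tab$end < tab$start)) {
    stop("coordinate error: end < start in feature table row ",
         which(tab$end < tab$start)[1L])
  }
  rna <- c(rRNA = sum(tab$feature == "rRNA"),
           ncRNA = sum(tab$feature == "ncRNA"),
           tRNA = sum(tab$feature == "tRNA"))
  keep <- tab$feature %in% c("gene", "CDS")
  genes <- data.frame(
    gene_id = tab$gene_id[keep],
    replicon_id = tab$replicon_id[keep],
    start = as.integer(tab$start[keep]) - 1L,
    end = as.integer(tab$end[keep]),
    strand = tab$strand[keep],
    product = if ("product" %in% names(tab)) tab$product[keep] else "",
    is_cds = tab$feature[keep] == "CDS",
    stringsAsFactors = FALSE
  )
  if (is.null(size_bp)) {
    size_bp <- tapply(genes$end, genes$replicon_id, max)
    size_bp <- stats::setNames(as.numeric(size_bp), names(size_bp))
  }
  genome_record(genome_id, size_bp, genes, rna_counts = rna)
}

#' Write a GenomeRecord's features as GFF3
#'
#' Inverse of [read_features()] for the feature subset this package models;
#' internal 0-based half-open coordinates are emitted 1-based inclusive.
#'
#' @param record A [genome_record()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(record, path) {
  stopifnot(inherits(record, "GenomeRecord"))
  g <- record$genes
  sizes <- record$replicon_sizes
  if (is.null(sizes)) {
    sizes <- stats::setNames(record$size_bp,
                             if (nrow(g)) unique(g$replicon_id) else record$genome_id)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", names(sizes),
                     as.integer(sizes)), con)
  if (nrow(g)) {
    attrs <- sprintf("ID=%s", g$gene_id)
    has_prod <- nzchar(g$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=", g$product[has_prod])
    writeLines(paste(g$replicon_id, "genopanel",
                     ifelse(g$is_cds, "CDS", "gene"),
                     g$start + 1L, g$end, ".", g$strand, ".",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read protein-domain hits from an hmmscan-style tabular file
#'
#' Parses the whitespace-separated `--tblout` dialect: `#` lines are
#' comments; columns are target name, target accession, query (gene) name,
#' query accession, full-sequence E-value, full-sequence bit score, ... .
#' The domain accession is taken from the target accession column (version
#' suffixes such as `.12` are stripped), falling back to the target name
#' when the accession is `-`.
#'
#' Rows whose full-sequence E-value exceeds `e_max` are dropped; the number
#' dropped is reported via `message()` and attached as attribute
#' `n_filtered`.
#'
#' @param path Path to the tabular file.
#' @param e_max Inclusion threshold on the full-sequence E-value
#'   (default `1e-5`).
#' @return `data.frame` with columns `gene_id`, `accession`, `e_value`,
#'   `bit_score`.
#' @export
read_domain_hits <- function(path, e_max = 1e-5) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- empty_domain_hits()
    attr(out, "n_filtered") <- 0L
    return(out)
  }
  f <- strsplit(trimws(lines), "\\s+")
  short <- lengths(f) < 6L
  if (any(short)) stop("parse error: fewer than 6 columns in domain-hit row ",
                       which(short)[1L])
  target <- vapply(f, `[`, "", 1L)
  acc <- vapply(f, `[`, "", 2L)
  acc <- ifelse(acc == "-", target, sub("\\.\\d+$", "", acc))
  e_val <- suppressWarnings(as.numeric(vapply(f, `[`, "", 5L)))
  if (anyNA(e_val)) {
    stop("parse error: non-numeric e-value in domain-hit row ",
         which(is.na(e_val))[1L])
  }
  score <- suppressWarnings(as.numeric(vapply(f, `[`, "", 6L)))
  out <- data.frame(gene_id = vapply(f, `[`, "", 3L), accession = acc,
                    e_value = e_val, bit_score = score,
                    stringsAsFactors = FALSE)
  drop <- out$e_value > e_max
  if (any(drop)) {
    message(sum(drop), " domain hit(s) above E-value threshold ", e_max,
            " filtered out")
  }
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(drop)
  out
}

#' Read gene-to-COG assignments
#'
#' Tab-separated file with columns `gene_id`, `cog_id`, category letters
#' (a string such as `"KT"`; split into a set by consumers). A gene may
#' appear in several rows (one per COG).
#'
#' @param path Path to the TSV file (no header required; a header row whose
#'   first field is `gene_id` is skipped).
#' @return `data.frame` with columns `gene_id`, `cog_id`, `categories`.
#' @export
read_cog_assignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) && grepl("^gene_id\t", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) return(empty_cog_assignments())
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(f) < 3L
  if (any(short)) {
    stop("parse error: COG assignment row ", which(short)[1L],
         " has fewer than 3 tab-separated columns")
  }
  out <- data.frame(gene_id = trimws(vapply(f, `[`, "", 1L)),
                    cog_id = trimws(vapply(f, `[`, "", 2L)),
                    categories = trimws(vapply(f, `[`, "", 3L)),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$cog_id))) stop("parse error: empty cog_id")
  if (any(!nzchar(out$categories))) stop("parse error: empty category field")
  out
}

#' Write a COG assignment table
#' @param cogs `data.frame` as from [read_cog_assignments()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cog_assignments <- function(cogs, path) {
  utils::write.table(cogs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write / read a category inventory as TSV
#'
#' Deterministic column order (`genome_id`, `category`, `count`, `gene_ids`
#' with members semicolon-joined in sorted order); categories are written in
#' sorted order so a write/read round trip is the identity.
#'
#' @param inventory A `CategoryInventory` (see [build_inventory()]).
#' @param path Output path.
#' @return `write_inventory_tsv()`: invisibly, `path`;
#'   `read_inventory_tsv()`: a `CategoryInventory`.
#' @export
write_inventory_tsv <- function(inventory, path) {
  stopifnot(inherits(inventory, "CategoryInventory"))
  cats <- sort(names(inventory$counts))
  df <- data.frame(
    genome_id = rep(inventory$genome_id, length(cats)),
    category = cats,
    count = as.integer(inventory$counts[cats]),
    gene_ids = vapply(cats, function(cc) {
      paste(sort(inventory$members[[cc]]), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_inventory_tsv
#' @export
read_inventory_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_ids = "character"))
  members <- lapply(df$gene_ids, function(s) {
    if (!nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1L]]
  })
  names(members) <- df$category
  structure(
    list(genome_id = if (nrow(df)) df$genome_id[1L] else NA_character_,
         counts = stats::setNames(as.integer(df$count), df$category),
         members = members),
    class = "CategoryInventory"
  )
}
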