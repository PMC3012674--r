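# Assembly quality control: N50, contig-onto-scaffold placement and
# reconciliation metrics, windowed coverage with outlier flags and
# coverage-based copy number, scaffold-end repeat statistics and the
# genome repeat catalogue (global / inverted / tandem).
#
# Sequences are handled as named character vectors of A/C/G/T/N;
# Biostrings objects are accepted and coerced.

as_seqs <- function(x) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("sequences must have unique names")
  }
  x <- toupper(x)
  if (any(grepl("[^ACGTN]", x))) {
    stop("parse error: sequence contains characters outside A/C/G/T/N")
  }
  x
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over \pkg{Biostrings} returning/accepting named character
#' vectors restricted to the A/C/G/T/N alphabet.
#' @param path FASTA file path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  as_seqs(Biostrings::readDNAStringSet(path))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_seqs(seqs)), path)
  invisible(path)
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length at least L together
#' cover at least half the total assembly span.
#'
#' @param lengths Positive integer vector.
#' @return Single integer length.
#' @export
compute_n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length set")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  half <- sum(s) / 2
  s[which(cumsum(s) >= half)[1L]]
}

#' Place contigs onto scaffolds by unique k-mer seeding
#'
#' Each contig (both orientations) is anchored by locating a k-mer that is
#' unique within a scaffold, then the full contig is compared ungapped at
#' the implied offset; a placement is accepted when the mismatch fraction
#' over the contig is at most `max_mismatch_frac`. Several probe k-mers
#' along the contig are tried so isolated substitutions cannot mask the
#' seed. When no unique seed exists, ambiguous (repeated) seed positions
#' are tried and the candidate with the fewest mismatches wins; a tie
#' between distinct locations leaves the contig unplaced (determinism over
#' guessing).
#'
#' @param contigs,scaffolds Named character vectors (or `DNAStringSet`s).
#' @param k Seed k-mer length (default 31, minimum 11).
#' @param max_mismatch_frac Maximum mismatches / contig length (default
#'   0.01; must be < 0.1).
#' @return `data.frame` of placements: `contig_id`, `scaffold_id`, `start`,
#'   `end` (0-based half-open scaffold coordinates), `orientation`
#'   (`"forward"`/`"revcomp"`), `mismatches`, `identity`. Unplaced contigs
#'   are listed in attribute `unplaced` (`contig_id`, `reason`).
#' @export
place_contigs <- function(contigs, scaffolds, k = 31, max_mismatch_frac = 0.01) {
  stopifnot(k >= 11, max_mismatch_frac >= 0, max_mismatch_frac < 0.1)
  contigs <- as_seqs(contigs)
  scaffolds <- as_seqs(scaffolds)
  sc_dna <- lapply(scaffolds, Biostrings::DNAString)
  placements <- list()
  unplaced <- list()
  for (cid in names(contigs)) {
    cseq <- contigs[[cid]]
    clen <- nchar(cseq)
    if (clen < k) {
      unplaced[[cid]] <- "shorter than seed k-mer"
      next
    }
    # probe k-mers along both orientations; exact matches located with
    # matchPDict (Aho-Corasick), so seeding scales to long scaffolds
    offs <- unique(c(seq(1L, clen - k + 1L, by = k), clen - k + 1L))
    oris <- c(rep("forward", length(offs)), rep("revcomp", length(offs)))
    offs2 <- c(offs, offs)
    qseq <- c(forward = cseq, revcomp = revcomp(cseq))
    probes <- c(substring(qseq[["forward"]], offs, offs + k - 1L),
                substring(qseq[["revcomp"]], offs, offs + k - 1L))
    keep <- !grepl("N", probes, fixed = TRUE)
    if (!any(keep)) {
      unplaced[[cid]] <- "no acceptable seed/extension"
      next
    }
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(probes[keep]))
    kidx <- which(keep)
    cands <- list()
    for (sid in names(scaffolds)) {
      slen <- nchar(scaffolds[[sid]])
      if (slen < k) next
      mp <- Biostrings::matchPDict(pd, sc_dna[[sid]])
      nocc <- lengths(mp)
      seen <- character()
      for (pj in which(nocc > 0L)) {
        j <- kidx[pj]
        uniq <- nocc[pj] == 1L
        for (pos in Biostrings::startIndex(mp)[[pj]]) {
          st <- pos - offs2[j] + 1L          # 1-based scaffold start
          if (st < 1L || st + clen - 1L > slen) next
          key <- paste(oris[j], st)
          if (key %in% seen) next
          seen <- c(seen, key)
          q <- qseq[[oris[j]]]
          mism <- sum(charToRaw(substr(scaffolds[[sid]], st, st + clen - 1L)) !=
                        charToRaw(q))
          if (mism / clen <= max_mismatch_frac) {
            cands[[length(cands) + 1L]] <- list(
              scaffold_id = sid, start = st - 1L, end = st - 1L + clen,
              orientation = oris[j], mismatches = mism, unique_seed = uniq)
          }
        }
      }
    }
    if (!length(cands)) {
      unplaced[[cid]] <- "no acceptable seed/extension"
      next
    }
    # prefer unique-seeded candidates; then fewest mismatches
    key <- vapply(cands, function(cc) {
      paste(cc$scaffold_id, cc$start, cc$orientation)
    }, "")
    cands <- cands[!duplicated(key)]
    uq <- vapply(cands, `[[`, TRUE, "unique_seed")
    if (any(uq)) cands <- cands[uq]
    mm <- vapply(cands, `[[`, 0, "mismatches")
    best <- which(mm == min(mm))
    if (length(best) > 1L) {
      unplaced[[cid]] <- "ambiguous placement (tied candidates)"
      next
    }
    b <- cands[[best]]
    placements[[cid]] <- data.frame(
      contig_id = cid, scaffold_id = b$scaffold_id, start = b$start,
      end = b$end, orientation = b$orientation, mismatches = b$mismatches,
      identity = 1 - b$mismatches / clen, stringsAsFactors = FALSE)
  }
  out <- if (length(placements)) do.call(rbind, placements) else
    data.frame(contig_id = character(), scaffold_id = character(),
               start = integer(), end = integer(), orientation = character(),
               mismatches = integer(), identity = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unplaced") <- data.frame(
    contig_id = names(unplaced),
    reason = unlist(unplaced, use.names = FALSE) %||% character(),
    stringsAsFactors = FALSE)
  out
}

#' Reconcile contig placements against scaffolds
#'
#' Summarizes how completely and accurately one contig set reconstructs a
#' scaffold set: the fraction of scaffold bases covered by at least one
#' placed contig, the total uncovered (missing) bases, the mean signed
#' distance between consecutive placements on a scaffold (negative =
#' overlap), and the base-weighted mean identity of the placements.
#'
#' @param placements `data.frame` from [place_contigs()].
#' @param scaffolds Named character vector (or `DNAStringSet`).
#' @return Object of class `ReconciliationReport`: `coverage_fraction`,
#'   `missing_bp`, `mean_distance_bp`, `mean_identity`, `n_placements`,
#'   `distances` (all signed inter-contig distances).
#' @export
reconcile <- function(placements, scaffolds) {
  scaffolds <- as_seqs(scaffolds)
  bad <- setdiff(placements$scaffold_id, names(scaffolds))
  if (length(bad)) stop("placements reference unknown scaffold(s): ",
                        paste(bad, collapse = ", "))
  total_bp <- sum(nchar(scaffolds))
  covered <- 0
  dists <- numeric()
  for (sid in names(scaffolds)) {
    p <- placements[placements$scaffold_id == sid, , drop = FALSE]
    if (!nrow(p)) next
    ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    covered <- covered + sum(IRanges::width(ir))
    if (nrow(p) >= 2L) {
      p <- p[order(p$start), , drop = FALSE]
      dists <- c(dists, p$start[-1L] - p$end[-nrow(p)])
    }
  }
  w <- placements$end - placements$start
  structure(
    list(coverage_fraction = covered / total_bp,
         missing_bp = total_bp - covered,
         mean_distance_bp = if (length(dists)) mean(dists) else NA_real_,
         mean_identity = if (length(w)) sum(placements$identity * w) / sum(w)
                         else NA_real_,
         n_placements = nrow(placements),
         distances = dists),
    class = "ReconciliationReport")
}

#' @export
print.ReconciliationReport <- function(x, ...) {
  cat(sprintf(paste0("ReconciliationReport: coverage %.4f%%, missing %d bp, ",
                     "mean inter-contig distance %s bp, identity %.4f ",
                     "(%d placements)\n"),
              100 * x$coverage_fraction, as.integer(x$missing_bp),
              format(x$mean_distance_bp), x$mean_identity, x$n_placements))
  invisible(x)
}

#' Build a windowed coverage track from per-base depth
#'
#' Depth is averaged in consecutive non-overlapping windows of fixed width;
#' the final window may be shorter. Genome-wide mean and standard deviation
#' of the window depths are stored for flagging.
#'
#' @param depth Numeric vector of per-base depth, or a `data.frame` with
#'   columns `replicon`, `start`, `end`, `depth` (precomputed windows,
#'   bedGraph-style, 0-based half-open).
#' @param width Window width in bp (default 5000).
#' @param replicon Replicon name used when `depth` is a vector.
#' @return Object of class `CoverageTrack`: a `data.frame` (`replicon`,
#'   `start`, `end`, `depth`) with attributes `mean` and `sd`.
#' @export
coverage_track <- function(depth, width = 5000, replicon = "chr") {
  if (is.data.frame(depth)) {
    win <- depth
    stopifnot(all(c("replicon", "start", "end", "depth") %in% names(win)))
  } else {
    n <- length(depth)
    stopifnot(n > 0, width > 0)
    starts <- seq(0L, n - 1L, by = width)
    ends <- pmin(starts + width, n)
    mu <- vapply(seq_along(starts), function(i) {
      mean(depth[(starts[i] + 1L):ends[i]])
    }, 0)
    win <- data.frame(replicon = replicon, start = starts, end = ends,
                      depth = mu, stringsAsFactors = FALSE)
  }
  structure(win, class = c("CoverageTrack", "data.frame"),
            mean = mean(win$depth), sd = stats::sd(win$depth))
}

#' Flag coverage windows outside mean +/- n_sd standard deviations
#'
#' @param track A [coverage_track()].
#' @param n_sd Number of standard deviations defining the normal band
#'   (default 2).
#' @return The track with a `flag` column (`"high"`, `"low"`, `"normal"`).
#' @export
coverage_flags <- function(track, n_sd = 2) {
  stopifnot(inherits(track, "CoverageTrack"), n_sd > 0)
  mu <- attr(track, "mean")
  sd <- attr(track, "sd")
  if (is.na(sd)) sd <- 0
  track$flag <- ifelse(track$depth > mu + n_sd * sd, "high",
                       ifelse(track$depth < mu - n_sd * sd, "low", "normal"))
  track
}

#' Estimate copy number of a region from relative coverage
#'
#' The ratio of the region's mean window depth to the genome-wide mean
#' depth; a collapsed repeat present in k identical copies shows roughly
#' k-fold depth over its single assembled locus.
#'
#' @param track A [coverage_track()].
#' @param replicon,start,end Region of interest (0-based half-open).
#' @return List with `ratio` (real copy-number estimate) and `copies`
#'   (nearest integer).
#' @export
estimate_copy_number <- function(track, replicon, start, end) {
  stopifnot(inherits(track, "CoverageTrack"))
  mu <- attr(track, "mean")
  if (is.na(mu) || mu <= 0) stop("zero genome-wide mean depth")
  sel <- track$replicon == replicon & track$end > start & track$start < end
  if (!any(sel)) stop("region overlaps no coverage window")
  ratio <- mean(track$depth[sel]) / mu
  list(ratio = ratio, copies = as.integer(round(ratio)))
}

#' Write / read a bedGraph-style coverage track
#' @param track A [coverage_track()].
#' @param path File path.
#' @return `read_bedgraph()` returns a `CoverageTrack`.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("replicon", "start", "end", "depth")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("replicon", "start", "end", "depth"),
                          stringsAsFactors = FALSE)
  coverage_track(df)
}

# longest common substring length between two strings (byte DP, rolling row)
lcs_length <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- length(rb)
  prev <- integer(n)
  best <- 0L
  for (i in seq_along(ra)) {
    eq <- rb == ra[i]
    cur <- ifelse(eq, c(0L, prev[-n]) + 1L, 0L)
    m <- max(cur)
    if (m > best) best <- m
    prev <- cur
  }
  best
}

#' Repeat statistics of scaffold ends
#'
#' Takes the terminal `end_len` bp of both ends of every scaffold (whole
#' scaffold when shorter, with a message) and, for each end, finds the
#' longest exact substring of length at least `min_match` shared with any
#' other end, considering both strands of the partner. Ends sharing such a
#' substring are "repetitive": assemblies whose scaffolds terminate in
#' repeats typically cannot be joined further.
#'
#' @param scaffolds Named character vector (or `DNAStringSet`).
#' @param end_len Length of each terminal segment (default 100).
#' @param min_match Minimum shared substring length (default 20).
#' @return List: `fraction_with_repeat` (over all ends), `mean_repeat_len`
#'   and `mean_ends_matched` (over ends with a match), `per_end`
#'   `data.frame` (`end_id`, `longest_match`, `n_ends_matched`).
#' @export
scaffold_end_repeat_stats <- function(scaffolds, end_len = 100, min_match = 20) {
  stopifnot(end_len >= min_match, min_match >= 8)
  scaffolds <- as_seqs(scaffolds)
  ends <- list()
  for (sid in names(scaffolds)) {
    s <- scaffolds[[sid]]
    n <- nchar(s)
    if (n < end_len) {
      message("scaffold ", sid, " shorter than end_len; whole sequence used")
      ends[[paste0(sid, ":5p")]] <- s
      ends[[paste0(sid, ":3p")]] <- s
    } else {
      ends[[paste0(sid, ":5p")]] <- substr(s, 1L, end_len)
      ends[[paste0(sid, ":3p")]] <- substr(s, n - end_len + 1L, n)
    }
  }
  m <- length(ends)
  ids <- names(ends)
  rc_ends <- lapply(ends, revcomp)
  longest <- integer(m)
  nmatched <- integer(m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      l <- max(lcs_length(ends[[i]], ends[[j]]),
               lcs_length(ends[[i]], rc_ends[[j]]))
      if (l >= min_match) {
        nmatched[i] <- nmatched[i] + 1L
        if (l > longest[i]) longest[i] <- l
      }
    }
  }
  has <- longest >= min_match
  list(fraction_with_repeat = mean(has),
       mean_repeat_len = if (any(has)) mean(longest[has]) else NA_real_,
       mean_ends_matched = if (any(has)) mean(nmatched[has]) else NA_real_,
       per_end = data.frame(end_id = ids, longest_match = longest,
                            n_ends_matched = nmatched,
                            stringsAsFactors = FALSE))
}

#' Catalogue global, inverted and tandem repeats in a sequence
#'
#' Global repeats: maximal exact match pairs of length at least `l_g`
#' between two distinct positions (k-mer anchored, extended to maximality
#' in both directions). Local inverted repeats: two arms of length at least
#' `l_i` that are exact reverse complements, separated by a loop of at most
#' `loop_max` bp, extended to maximality inward and outward. Tandem
#' repeats: maximal runs of a period in `period_range` with at least
#' `c_min` full copies; a run is suppressed when its interval lies inside a
#' run already found at a smaller period (so a homopolymer is not also
#' reported at periods 2, 3, ...). All coordinates are 1-based inclusive.
#'
#' @param sequence Single sequence string (A/C/G/T/N).
#' @param l_g Minimum global repeat length (default 25).
#' @param l_i Minimum inverted-repeat arm length (default 10).
#' @param loop_max Maximum loop between inverted-repeat arms (default 100).
#' @param period_range Tandem periods scanned (default 1:6).
#' @param c_min Minimum number of full tandem copies (default 3).
#' @return Object of class `RepeatCatalog`: list of data frames `global`
#'   (`start1`, `end1`, `start2`, `end2`, `length`), `inverted` (`start1`,
#'   `end1`, `start2`, `end2`, `arm`, `loop`), `tandem` (`start`, `end`,
#'   `period`, `copies`).
#' @export
find_repeats <- function(sequence, l_g = 25, l_i = 10, loop_max = 100,
                         period_range = 1:6, c_min = 3) {
  sequence <- as_seqs(stats::setNames(sequence, "seq"))[[1L]]
  structure(
    list(global = find_global_repeats(sequence, l_g),
         inverted = find_inverted_repeats(sequence, l_i, loop_max),
         tandem = find_tandem_repeats(sequence, period_range, c_min)),
    class = "RepeatCatalog")
}

#' @export
print.RepeatCatalog <- function(x, ...) {
  cat("RepeatCatalog:", nrow(x$global), "global,", nrow(x$inverted),
      "inverted,", nrow(x$tandem), "tandem repeats\n")
  invisible(x)
}

find_global_repeats <- function(s, l_g) {
  out <- data.frame(start1 = integer(), end1 = integer(), start2 = integer(),
                    end2 = integer(), length = integer(),
                    stringsAsFactors = FALSE)
  n <- nchar(s)
  if (n < 2 * 1 || n < l_g) return(out)
  raw <- charToRaw(s)
  k <- l_g
  if (n - k + 1L < 2L) return(out)
  km <- substring(s, 1:(n - k + 1L), k:n)
  posmap <- split(seq_along(km), km)
  posmap <- posmap[lengths(posmap) >= 2L]
  seen <- character()
  recs <- list()
  for (pos in posmap) {
    for (a in seq_len(length(pos) - 1L)) {
      for (b in (a + 1L):length(pos)) {
        i <- pos[a]; j <- pos[b]
        # extend left
        while (i > 1L && j > 1L && raw[i - 1L] == raw[j - 1L]) {
          i <- i - 1L; j <- j - 1L
        }
        e1 <- pos[a] + k - 1L; e2 <- pos[b] + k - 1L
        while (e2 < n && raw[e1 + 1L] == raw[e2 + 1L]) {
          e1 <- e1 + 1L; e2 <- e2 + 1L
        }
        if (i == j) next
        key <- paste(i, j)
        if (key %in% seen) next
        seen <- c(seen, key)
        recs[[length(recs) + 1L]] <-
          c(start1 = i, end1 = e1, start2 = j, end2 = e2, length = e1 - i + 1L)
      }
    }
  }
  if (!length(recs)) return(out)
  m <- as.data.frame(do.call(rbind, recs))
  m <- m[m$length >= l_g, , drop = FALSE]
  m <- m[order(m$start1, m$start2), , drop = FALSE]
  rownames(m) <- NULL
  m
}

find_inverted_repeats <- function(s, l_i, loop_max) {
  out <- data.frame(start1 = integer(), end1 = integer(), start2 = integer(),
                    end2 = integer(), arm = integer(), loop = integer(),
                    stringsAsFactors = FALSE)
  n <- nchar(s)
  if (n < 2 * l_i) return(out)
  raw <- charToRaw(s)
  comp <- charToRaw(chartr("ACGTN", "TGCAN", s))
  k <- l_i
  km <- substring(s, 1:(n - k + 1L), k:n)
  rck <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  posmap <- split(seq_along(km), km)
  seen <- character()
  recs <- list()
  for (i in seq_along(km)) {
    js <- posmap[[rck[i]]]
    if (is.null(js)) next
    js <- js[js >= i + k & js <= i + k + loop_max]
    for (j in js) {
      a1 <- i; a2 <- i + k - 1L          # arm A
      b1 <- j; b2 <- j + k - 1L          # arm B = revcomp(A)
      repeat {
        ext <- FALSE
        # outward: A grows left, B grows right
        if (a1 > 1L && b2 < n && raw[b2 + 1L] == comp[a1 - 1L]) {
          a1 <- a1 - 1L; b2 <- b2 + 1L; ext <- TRUE
        }
        # inward: A grows right, B grows left (loop shrinks by 2)
        if (b1 - a2 - 1L >= 2L && raw[a2 + 1L] == comp[b1 - 1L]) {
          a2 <- a2 + 1L; b1 <- b1 - 1L; ext <- TRUE
        }
        if (!ext) break
      }
      loop <- b1 - a2 - 1L
      if (loop < 0L || loop > loop_max) next
      key <- paste(a1, b2)
      if (key %in% seen) next
      seen <- c(seen, key)
      recs[[length(recs) + 1L]] <-
        c(start1 = a1, end1 = a2, start2 = b1, end2 = b2,
          arm = a2 - a1 + 1L, loop = loop)
    }
  }
  if (!length(recs)) return(out)
  m <- as.data.frame(do.call(rbind, recs))
  m <- m[m$arm >= l_i, , drop = FALSE]
  m <- m[order(m$start1, m$start2), , drop = FALSE]
  rownames(m) <- NULL
  m
}

find_tandem_repeats <- function(s, period_range, c_min) {
  n <- nchar(s)
  raw <- charToRaw(s)
  recs <- list()
  for (p in sort(period_range)) {
    if (n < p * c_min) next
    eq <- raw[seq_len(n - p) + p] == raw[seq_len(n - p)]
    r <- rle(eq)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (t in which(r$values)) {
      start <- starts_idx[t]
      end <- ends_idx[t] + p          # region = run + one period
      len <- end - start + 1L
      copies <- len %/% p
      if (copies < c_min) next
      contained <- any(vapply(recs, function(rr) {
        rr["period"] < p && rr["start"] <= start && rr["end"] >= end
      }, TRUE))
      if (contained) next
      recs[[length(recs) + 1L]] <-
        c(start = start, end = end, period = p, copies = copies)
    }
  }
  if (!length(recs)) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      copies = integer(), stringsAsFactors = FALSE))
  }
  m <- as.data.frame(do.call(rbind, recs))
  m <- m[order(m$start, m$period), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Write repeat or flag intervals as BED
#'
#' BED is 0-based half-open; the catalogue's 1-based inclusive coordinates
#' are converted.
#' @param catalog A [find_repeats()] result.
#' @param path Output path.
#' @param replicon Sequence name for the BED column.
#' @return Invisibly, `path`.
#' @export
write_repeats_bed <- function(catalog, path, replicon = "seq") {
  stopifnot(inherits(catalog, "RepeatCatalog"))
  rows <- character()
  g <- catalog$global
  if (nrow(g)) {
    rows <- c(rows,
              paste(replicon, g$start1 - 1L, g$end1, "global_repeat", sep = "\t"),
              paste(replicon, g$start2 - 1L, g$end2, "global_repeat", sep = "\t"))
  }
  iv <- catalog$inverted
  if (nrow(iv)) {
    rows <- c(rows,
              paste(replicon, iv$start1 - 1L, iv$end2, "inverted_repeat", sep = "\t"))
  }
  td <- catalog$tandem
  if (nrow(td)) {
    rows <- c(rows,
              paste(replicon, td$start - 1L, td$end,
                    paste0("tandem_p", td$period), sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
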