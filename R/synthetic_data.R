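# Seeded generators for synthetic inputs carrying the statistical
# structure each analysis stage assumes: genome panels with category
# counts linear in genome size, annotated genomes with planted
# two-component-system arrangements, fragmented assemblies with planted
# overlaps/mutations/collapsed repeats, and alignments evolved on a known
# tree. Every generator is deterministic given its seed and returns a
# machine-readable ground-truth record.

#' Derive an independent per-stream seed from one global seed
#'
#' Changing one fixture's stream leaves all others bit-identical.
#' @param seed Global integer seed.
#' @param stream Small nonnegative integer identifying the consumer.
#' @return Integer seed below 2^31.
#' @export
fanout_seed <- function(seed, stream = 0L) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %%
               2147483647)
}

#' Generate a synthetic genome panel
#'
#' Emulates a panel of bacterial genomes whose per-category gene counts
#' grow linearly with genome size plus Gaussian noise:
#' `count = round(slope * size_Mbp + N(0, sd))`, floored at zero. One
#' designated outlier genome is offset upward by `outlier_offset_sd`
#' realized panel standard deviations in every category; its size is fixed
#' at the middle of the size range (outliers of interest in comparative
#' panels are mid-sized genomes whose counts, not sizes, are exceptional).
#'
#' @param n Number of genomes (default 500).
#' @param size_range Genome size range in bp (default 2-10 Mbp).
#' @param slopes Named per-Mbp slopes for the four categories.
#' @param noise_sd Named noise standard deviations (count units).
#' @param outlier_offset_sd Outlier offset in panel-sd units (default 3);
#'   set to 0 (or `outlier = FALSE`) for no outlier.
#' @param outlier Plant the outlier? (default `TRUE`).
#' @param seed Integer seed.
#' @return List: `panel` (a [panel_matrix()]), `truth` (list with
#'   `outlier_id`, `slopes`, `noise_sd`, `sizes`).
#' @export
gen_panel <- function(n = 500,
                      size_range = c(2e6, 1e7),
                      slopes = c(tcs = 10, tf = 26, transport = 55, defense = 10),
                      noise_sd = c(tcs = 8, tf = 30, transport = 40, defense = 10),
                      outlier_offset_sd = 3,
                      outlier = TRUE,
                      seed = 1) {
  stopifnot(n >= 2, identical(names(slopes), names(noise_sd)))
  set.seed(seed)
  sizes <- stats::runif(n, size_range[1L], size_range[2L])
  ids <- sprintf("genome_%03d", seq_len(n))
  outlier_id <- NULL
  if (outlier && outlier_offset_sd != 0) {
    outlier_id <- ids[n]
    sizes[n] <- mean(size_range)
  }
  counts <- sapply(names(slopes), function(cc) {
    pmax(0, round(slopes[[cc]] * sizes / 1e6 +
                    stats::rnorm(n, 0, noise_sd[[cc]])))
  })
  if (!is.null(outlier_id)) {
    for (cc in names(slopes)) {
      counts[n, cc] <- counts[n, cc] +
        round(outlier_offset_sd * pop_sd(counts[-n, cc]))
    }
  }
  list(panel = panel_matrix(ids, sizes, counts),
       truth = list(outlier_id = outlier_id, slopes = slopes,
                    noise_sd = noise_sd, sizes = sizes))
}

rule_tcs_hits <- function(gene_id, role) {
  rec <- data.frame(gene_id = gene_id, accession = "PF00072",
                    e_value = 1e-30, bit_score = 80, stringsAsFactors = FALSE)
  kin <- data.frame(gene_id = gene_id,
                    accession = c("PF00512", "PF02518"),
                    e_value = c(1e-25, 1e-20), bit_score = c(90, 70),
                    stringsAsFactors = FALSE)
  switch(role, RR = rec, HK = kin, hybrid = rbind(rec, kin))
}

#' Generate an annotated genome with planted functional structure
#'
#' Lays genes along one replicon in shuffled blocks: HK-RR pairs (internal
#' gap below the pairing threshold), isolated orphan TCS genes, complex
#' clusters of three TCS genes, single transcription-factor / transporter /
#' defense genes (tagged via the default rule lists), and unclassified
#' filler genes. Blocks are separated by gaps well above the pairing
#' threshold so only the planted arrangements form runs.
#'
#' @param n_pairs,n_orphans,n_clusters Planted TCS arrangements (a cluster
#'   has 3 TCS genes).
#' @param n_tf,n_transport,n_defense,n_filler Planted single-gene counts.
#' @param pair_gap_range Intra-block gap range in bp (default 20-150,
#'   below the 200 bp pairing default).
#' @param block_gap_range Inter-block gap range (default 300-600, above it).
#' @param gene_len_range Gene length range in bp.
#' @param seed Integer seed.
#' @return List: `genome` (a [genome_record()] with hits and COGs
#'   attached), `truth` (`data.frame` of planted labels: `gene_id`,
#'   `category`, `role`, `organization`).
#' @export
gen_annotated_genome <- function(n_pairs = 5, n_orphans = 3, n_clusters = 2,
                                 n_tf = 5, n_transport = 3, n_defense = 2,
                                 n_filler = 10,
                                 pair_gap_range = c(20, 150),
                                 block_gap_range = c(300, 600),
                                 gene_len_range = c(600, 1200),
                                 seed = 1) {
  set.seed(seed)
  blocks <- c(rep("pair", n_pairs), rep("orphan", n_orphans),
              rep("cluster", n_clusters), rep("tf", n_tf),
              rep("transport", n_transport), rep("defense", n_defense),
              rep("filler", n_filler))
  blocks <- sample(blocks)
  genes <- list(); hits <- list(); cogs <- list(); truth <- list()
  pos <- 0L
  gid_n <- 0L
  next_id <- function() {
    gid_n <<- gid_n + 1L
    sprintf("g%04d", gid_n)
  }
  lay_gene <- function(gap) {
    len <- round(stats::runif(1, gene_len_range[1L], gene_len_range[2L]))
    start <- pos + round(gap)
    pos <<- start + len
    c(start = start, end = start + len)
  }
  orphan_roles <- c("RR", "HK", "hybrid")
  for (b in blocks) {
    block_gap <- stats::runif(1, block_gap_range[1L], block_gap_range[2L])
    in_gap <- function() stats::runif(1, pair_gap_range[1L], pair_gap_range[2L])
    if (b == "pair") {
      id1 <- next_id(); co1 <- lay_gene(block_gap)
      id2 <- next_id(); co2 <- lay_gene(in_gap())
      genes[[id1]] <- co1; genes[[id2]] <- co2
      hits[[id1]] <- rule_tcs_hits(id1, "HK")
      hits[[id2]] <- rbind(rule_tcs_hits(id2, "RR"),
                           data.frame(gene_id = id2, accession = "PF00486",
                                      e_value = 1e-15, bit_score = 60,
                                      stringsAsFactors = FALSE))
      truth[[id1]] <- c(id1, "tcs", "HK", "paired")
      truth[[id2]] <- c(id2, "tcs", "RR", "paired")
    } else if (b == "orphan") {
      role <- sample(orphan_roles, 1)
      id <- next_id(); genes[[id]] <- lay_gene(block_gap)
      hits[[id]] <- rule_tcs_hits(id, role)
      truth[[id]] <- c(id, "tcs", role, "orphan")
    } else if (b == "cluster") {
      roles <- c("HK", "RR", sample(orphan_roles, 1))
      for (k in 1:3) {
        id <- next_id()
        genes[[id]] <- lay_gene(if (k == 1) block_gap else in_gap())
        hits[[id]] <- rule_tcs_hits(id, roles[k])
        truth[[id]] <- c(id, "tcs", roles[k], "complex")
      }
    } else if (b == "tf") {
      id <- next_id(); genes[[id]] <- lay_gene(block_gap)
      hits[[id]] <- data.frame(gene_id = id, accession = "PF00165",
                               e_value = 1e-20, bit_score = 55,
                               stringsAsFactors = FALSE)
      truth[[id]] <- c(id, "tf", NA, NA)
    } else if (b == "transport") {
      id <- next_id(); genes[[id]] <- lay_gene(block_gap)
      cogs[[id]] <- data.frame(gene_id = id, cog_id = "COG0477",
                               categories = "P", stringsAsFactors = FALSE)
      truth[[id]] <- c(id, "transport", NA, NA)
    } else if (b == "defense") {
      id <- next_id(); genes[[id]] <- lay_gene(block_gap)
      cogs[[id]] <- data.frame(gene_id = id, cog_id = "COG1680",
                               categories = "V", stringsAsFactors = FALSE)
      truth[[id]] <- c(id, "defense", NA, NA)
    } else {
      id <- next_id(); genes[[id]] <- lay_gene(block_gap)
      cogs[[id]] <- data.frame(gene_id = id, cog_id = "COG9999",
                               categories = "S", stringsAsFactors = FALSE)
      truth[[id]] <- c(id, "none", NA, NA)
    }
  }
  gdf <- data.frame(
    gene_id = names(genes),
    replicon_id = "chr1",
    start = vapply(genes, `[[`, 0, "start"),
    end = vapply(genes, `[[`, 0, "end"),
    strand = sample(c("+", "-"), length(genes), replace = TRUE),
    product = "",
    is_cds = TRUE,
    stringsAsFactors = FALSE)
  tm <- do.call(rbind, truth)
  truth_df <- data.frame(gene_id = tm[, 1L], category = tm[, 2L],
                         role = tm[, 3L], organization = tm[, 4L],
                         stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  rec <- genome_record(
    "synthetic_genome", pos + 500,
    gdf,
    domain_hits = if (length(hits)) do.call(rbind, unname(hits))
                  else empty_domain_hits(),
    cog_assignments = if (length(cogs)) do.call(rbind, unname(cogs))
                      else empty_cog_assignments())
  list(genome = rec, truth = truth_df)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, eps) {
  if (eps <= 0) return(list(seq = s, n_mut = 0L))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < eps)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  list(seq = paste(ch, collapse = ""), n_mut = length(hit))
}

#' Generate an assembly-reconciliation fixture
#'
#' Produces a random reference sequence (serving as the single hybrid
#' scaffold), two contig sets that tile it with configured signed
#' inter-contig offsets (negative = overlap) and independent per-base
#' substitution rates, and a per-window coverage track in which the
#' planted collapsed-repeat locus carries `copy_number` times the baseline
#' depth. The repeat locus is window-aligned so windowed depth reflects
#' the full multiplier.
#'
#' @param ref_len Reference length in bp (default 500 kb).
#' @param contig_len_range Contig length range (default 2-4 kb).
#' @param offset_a,offset_b Signed distance between consecutive contigs of
#'   set A / set B (default -5 and -10 bp overlap).
#' @param eps_a,eps_b Per-base substitution rate of each contig set.
#' @param repeat_len Collapsed-repeat locus length (default 5000,
#'   one window).
#' @param copy_number Collapsed copy number k (default 5).
#' @param depth Baseline read depth (default 100).
#' @param window Coverage window width (default 5000).
#' @param seed Integer seed.
#' @return List: `reference`, `scaffolds`, `contigs_a`, `contigs_b` (named
#'   character vectors), `track` (a [coverage_track()]), `truth` (list
#'   with breakpoints, offsets, rates, repeat locus and `copy_number`).
#' @export
gen_assembly_fixture <- function(ref_len = 5e5,
                                 contig_len_range = c(2000, 4000),
                                 offset_a = -5, offset_b = -10,
                                 eps_a = 0.002, eps_b = 0.002,
                                 repeat_len = 5000, copy_number = 5,
                                 depth = 100, window = 5000,
                                 seed = 1) {
  stopifnot(ref_len >= 10 * window)
  set.seed(seed)
  ref <- random_dna(ref_len)
  scaffolds <- c(scaffold_1 = ref)
  cut_contigs <- function(offset, eps, prefix) {
    starts <- integer(); ends <- integer()
    s <- 1L
    while (s <= ref_len) {
      len <- round(stats::runif(1, contig_len_range[1L], contig_len_range[2L]))
      e <- min(s + len - 1L, ref_len)
      starts <- c(starts, s); ends <- c(ends, e)
      if (e >= ref_len) break
      s <- e + 1L + offset       # next start; negative offset = overlap
    }
    seqs <- character(length(starts))
    muts <- integer(length(starts))
    for (i in seq_along(starts)) {
      mm <- mutate_seq(substr(ref, starts[i], ends[i]), eps)
      seqs[i] <- mm$seq
      muts[i] <- mm$n_mut
    }
    names(seqs) <- sprintf("%s_%03d", prefix, seq_along(seqs))
    list(seqs = seqs, starts = starts, ends = ends, n_mut = muts)
  }
  ca <- cut_contigs(offset_a, eps_a, "ctgA")
  cb <- cut_contigs(offset_b, eps_b, "ctgB")
  # window-aligned collapsed-repeat locus in the middle of the reference
  rep_start <- (floor(ref_len / (2 * window))) * window       # 0-based
  rep_end <- rep_start + repeat_len
  per_base <- stats::rpois(ref_len, depth)
  idx <- (rep_start + 1L):rep_end
  per_base[idx] <- per_base[idx] * copy_number
  track <- coverage_track(per_base, width = window, replicon = "scaffold_1")
  list(reference = c(reference = ref),
       scaffolds = scaffolds,
       contigs_a = ca$seqs, contigs_b = cb$seqs,
       track = track,
       truth = list(
         breakpoints_a = data.frame(start = ca$starts, end = ca$ends,
                                    n_mut = ca$n_mut),
         breakpoints_b = data.frame(start = cb$starts, end = cb$ends,
                                    n_mut = cb$n_mut),
         offset_a = offset_a, offset_b = offset_b,
         eps_a = eps_a, eps_b = eps_b,
         repeat_start = rep_start, repeat_end = rep_end,
         copy_number = copy_number, depth = depth))
}

#' Evolve an alignment on a known tree under Jukes-Cantor
#'
#' Sites evolve independently: along a branch of length t (substitutions
#' per site) each site changes with probability `3/4 (1 - exp(-4t/3))`, to
#' one of the three other bases uniformly.
#'
#' @param tree An `ape` `phylo` with branch lengths, or `NULL` to draw a
#'   random `ntaxa`-leaf topology with branch lengths scaled by `scale`.
#' @param ntaxa Number of taxa when `tree` is `NULL` (default 8).
#' @param nsites Alignment length (default 1000).
#' @param scale Branch-length multiplier for the random tree (default 0.1).
#' @param seed Integer seed.
#' @return List: `alignment` (named character vector), `tree` (the
#'   generating `phylo`).
#' @export
gen_alignment <- function(tree = NULL, ntaxa = 8, nsites = 1000,
                          scale = 0.1, seed = 1) {
  set.seed(seed)
  if (is.null(tree)) {
    tree <- ape::rtree(ntaxa)
    tree$edge.length <- tree$edge.length * scale
  }
  stopifnot(length(tree$tip.label) >= 3)
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample(bases, nsites, replace = TRUE)
  # preorder traversal: parents appear before children in reorder()
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    p_sub <- 0.75 * (1 - exp(-4 * lens[e] / 3))
    s <- seqs[[par]]
    hit <- which(stats::runif(nsites) < p_sub)
    for (i in hit) s[i] <- sample(setdiff(bases, s[i]), 1)
    seqs[[child]] <- s
  }
  aln <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(aln) <- tree$tip.label
  list(alignment = aln, tree = tree)
}
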