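# Structural classification of two-component-system (TCS) genes, their
# chromosomal organization (paired / orphan / complex) and functional
# profiling of their gene neighborhoods.

#' Default response-regulator output-domain family map
#'
#' Maps DNA-binding output-domain accessions to the conventional
#' response-regulator family labels (winged-HTH OmpR-like, AraC-like,
#' NarL/FixJ-like GerE domain, LytTR). Anything unmapped is reported as
#' `"other"`.
#' @return Named character vector (accession -> family label).
#' @export
default_rr_family_map <- function() {
  c(PF00486 = "OmpR-like",   # Trans_reg_C winged HTH
    PF00165 = "AraC-like",
    PF00196 = "NarL-like",   # GerE HTH
    PF04397 = "LytTR")
}

#' Classify a response regulator into an output-domain family
#'
#' The family of the best-scoring (highest bit score) hit whose accession is
#' present in `family_map`; `"other"` when the gene carries no mapped output
#' domain (e.g. a receiver-only regulator).
#'
#' @param hits Domain hits for one gene (`data.frame` with `accession`,
#'   `bit_score`).
#' @param family_map Named vector accession -> family label.
#' @return Single family label string.
#' @export
classify_rr_family <- function(hits, family_map = default_rr_family_map()) {
  h <- hits[hits$accession %in% names(family_map), , drop = FALSE]
  if (!nrow(h)) return("other")
  unname(family_map[h$accession[which.max(h$bit_score)]])
}

#' Extract TCS records from a genome
#'
#' Convenience constructor: classifies genes with [build_inventory()] and
#' returns one row per TCS gene with its role and (for response regulators)
#' output-domain family.
#'
#' @inheritParams build_inventory
#' @param family_map Passed to [classify_rr_family()].
#' @return `data.frame` with columns `gene_id`, `role`, `rr_family`.
#' @export
tcs_records <- function(genome, rules = default_category_rules(),
                        family_map = default_rr_family_map()) {
  inv <- build_inventory(genome, rules)
  ids <- inv$members$tcs
  role <- rep(NA_character_, length(ids))
  role[ids %in% inv$members$tcs_RR] <- "RR"
  role[ids %in% inv$members$tcs_HK] <- "HK"
  role[ids %in% inv$members$tcs_hybrid] <- "hybrid"
  hits_by <- split(genome$domain_hits, genome$domain_hits$gene_id)
  fam <- rep(NA_character_, length(ids))
  is_rr <- role == "RR"
  fam[is_rr] <- vapply(ids[is_rr], function(g) {
    classify_rr_family(hits_by[[g]] %||% empty_domain_hits(), family_map)
  }, "")
  data.frame(gene_id = ids, role = role, rr_family = fam,
             stringsAsFactors = FALSE)
}

#' Classify the chromosomal organization of TCS genes
#'
#' TCS genes are sorted by position; maximal runs in which consecutive TCS
#' genes (on the same replicon) are separated by at most `pair_gap_bp` are
#' formed, ignoring strand. A run of exactly two genes consisting of one
#' HK-like gene (histidine kinase or hybrid kinase) and one response
#' regulator makes both members `paired` and mutual partners; a run of
#' three or more TCS genes makes all members `complex`; singleton runs and
#' two-gene runs that are not one-HK-like-plus-one-RR are `orphan`.
#'
#' @param genome A [genome_record()].
#' @param tcs `data.frame` from [tcs_records()] (columns `gene_id`, `role`).
#' @param pair_gap_bp Maximum gap between consecutive TCS genes in a run
#'   (default 200 bp, a typical operon-internal intergenic distance).
#' @return `tcs` with columns `organization` (`paired`/`orphan`/`complex`)
#'   and `partners` (semicolon-joined gene ids, empty for orphans) added.
#' @export
organize_tcs <- function(genome, tcs, pair_gap_bp = 200) {
  stopifnot(pair_gap_bp > 0)
  g <- genome$genes
  missing <- setdiff(tcs$gene_id, g$gene_id)
  if (length(missing)) {
    stop("consistency error: TCS gene id(s) not in genome: ",
         paste(missing, collapse = ", "))
  }
  if (!nrow(tcs)) {
    tcs$organization <- character()
    tcs$partners <- character()
    return(tcs)
  }
  pos <- g[match(tcs$gene_id, g$gene_id), c("replicon_id", "start", "end")]
  ord <- order(pos$replicon_id, pos$start)
  t2 <- tcs[ord, , drop = FALSE]
  p2 <- pos[ord, , drop = FALSE]
  n <- nrow(t2)
  new_rep <- c(TRUE, p2$replicon_id[-1L] != p2$replicon_id[-n])
  gap <- c(Inf, p2$start[-1L] - p2$end[-n])
  run <- cumsum(new_rep | gap > pair_gap_bp)
  org <- character(n)
  partners <- character(n)
  for (idx in split(seq_len(n), run)) {
    roles <- t2$role[idx]
    if (length(idx) >= 3L) {
      org[idx] <- "complex"
      partners[idx] <- vapply(idx, function(i) {
        paste(t2$gene_id[setdiff(idx, i)], collapse = ";")
      }, "")
    } else if (length(idx) == 2L &&
               sum(roles %in% c("HK", "hybrid")) == 1L &&
               sum(roles == "RR") == 1L) {
      org[idx] <- "paired"
      partners[idx] <- rev(t2$gene_id[idx])
    } else {
      org[idx] <- "orphan"
    }
  }
  t2$organization <- org
  t2$partners <- partners
  t2[order(match(t2$gene_id, tcs$gene_id)), , drop = FALSE]
}

#' Default neighborhood function map
#'
#' Maps COG functional category letters to the coarse neighborhood classes:
#' transport (inorganic ion transport, P), regulatory (transcription, K),
#' energy metabolism (energy production/conversion C, carbohydrate
#' transport and metabolism G). Unlisted letters fall in `other`.
#' @return Named character vector (COG letter -> class).
#' @export
default_function_map <- function() {
  c(P = "transport", K = "regulatory", C = "energy", G = "energy")
}

#' Functional profile of the genes neighboring TCS genes
#'
#' Collects every non-TCS gene within `window_genes` positions (in gene
#' order along the replicon) of any TCS gene, de-duplicated across
#' overlapping windows, and tallies the functional classes assigned from
#' the genes' COG category letters via `function_map`. Genes with a COG
#' assignment but no mapped letter count as `other`; genes with no COG
#' assignment are reported separately as `unclassified` and excluded from
#' the fractions, which sum to 1 over classified neighbors.
#'
#' @param genome A [genome_record()].
#' @param tcs `data.frame` with column `gene_id` (TCS genes).
#' @param window_genes Window half-width in genes (default 5).
#' @param function_map Named vector COG letter -> class.
#' @return `data.frame` with columns `class`, `count`, `fraction`
#'   (fraction is `NA` for the `unclassified` row). Empty when `tcs` is
#'   empty.
#' @export
neighborhood_profile <- function(genome, tcs, window_genes = 5,
                                 function_map = default_function_map()) {
  stopifnot(window_genes >= 1)
  if (!nrow(tcs)) {
    return(data.frame(class = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  g <- genome$genes
  neighbors <- character()
  for (rep_id in unique(g$replicon_id)) {
    gr <- g[g$replicon_id == rep_id, , drop = FALSE]
    tcs_idx <- which(gr$gene_id %in% tcs$gene_id)
    if (!length(tcs_idx)) next
    win <- unique(unlist(lapply(tcs_idx, function(i) {
      seq(max(1L, i - window_genes), min(nrow(gr), i + window_genes))
    })))
    win <- setdiff(win, tcs_idx)
    neighbors <- c(neighbors, gr$gene_id[win])
  }
  neighbors <- unique(neighbors)
  cogs <- genome$cog_assignments
  cls <- vapply(neighbors, function(gid) {
    rows <- cogs[cogs$gene_id == gid, , drop = FALSE]
    if (!nrow(rows)) return("unclassified")
    letters <- unique(unlist(strsplit(rows$categories, "", fixed = TRUE)))
    mapped <- unique(unname(function_map[letters]))
    mapped <- mapped[!is.na(mapped)]
    if (!length(mapped)) "other" else mapped[1L]
  }, "")
  tab <- table(cls)
  classified <- sum(tab[names(tab) != "unclassified"])
  out <- data.frame(class = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$fraction <- ifelse(out$class == "unclassified", NA_real_,
                         out$count / classified)
  out[order(-out$count), , drop = FALSE]
}
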