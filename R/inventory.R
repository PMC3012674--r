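# Rule-driven classification of genes into functional categories
# (two-component systems, transcription factors, transporters, defense
# genes) and per-genome inventories built from those labels.

#' Load category classification rules
#'
#' Rules are a YAML file with one section per category carrying `pfam`,
#' `cog_id` and `cog_cat` id lists; the `tcs` section additionally carries
#' `role_logic` with `receiver` and `kinase_core` Pfam accession lists used
#' to resolve two-component-system roles (receiver only = response
#' regulator, kinase core only = histidine kinase, both = hybrid kinase).
#'
#' The rules shipped with the package are a curated approximation of the
#' commonly used family lists; substitute an exact list via `path` when one
#' is available.
#'
#' @param path Path to a rules YAML file; default is the file shipped under
#'   `inst/extdata/category_rules.yaml`.
#' @return A named list of class `CategoryRules` (one element per category).
#' @export
read_category_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "category_rules.yaml", package = "genopanel")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$categories) || !length(raw$categories)) {
    stop("configuration error: rules file defines no categories")
  }
  rules <- lapply(raw$categories, function(r) {
    list(pfam = as.character(unlist(r$pfam)),
         cog_id = as.character(unlist(r$cog_id)),
         cog_cat = as.character(unlist(r$cog_cat)),
         role_logic = if (!is.null(r$role_logic)) {
           list(receiver = as.character(unlist(r$role_logic$receiver)),
                kinase_core = as.character(unlist(r$role_logic$kinase_core)))
         })
  })
  ok <- vapply(rules, function(r) {
    length(r$pfam) + length(r$cog_id) + length(r$cog_cat) > 0L ||
      !is.null(r$role_logic)
  }, TRUE)
  if (!all(ok)) {
    stop("configuration error: category without any id list: ",
         paste(names(rules)[!ok], collapse = ", "))
  }
  structure(rules, class = "CategoryRules")
}

#' @rdname read_category_rules
#' @export
default_category_rules <- function() read_category_rules()

#' Classify one gene into functional categories
#'
#' Labels are resolved from the gene's domain hits and COG assignments
#' against the rule lists. Two-component-system (TCS) role resolution:
#' receiver domain only gives role `RR`, kinase-core domain only `HK`, both
#' `hybrid`. A gene labelled TCS is excluded from the transcription-factor
#' category even when it carries a listed DNA-binding domain, so the four
#' category counts used by the panel statistics do not double-count signal
#' transduction genes. Transport and defense labels come from COG id /
#' category membership and are independent of the other labels.
#'
#' @param hits Domain hits for this gene (`data.frame` with `accession`).
#' @param cogs COG assignments for this gene (`data.frame` with `cog_id`,
#'   `categories`).
#' @param rules A [read_category_rules()] object.
#' @return `data.frame` with columns `category`, `role` (role is `NA`
#'   except for TCS); zero rows when nothing matches.
#' @export
classify_gene <- function(hits, cogs, rules) {
  if (!inherits(rules, "CategoryRules") || !length(rules)) {
    stop("configuration error: empty rule set")
  }
  acc <- unique(hits$accession)
  cog_ids <- unique(cogs$cog_id)
  cog_cats <- unique(unlist(strsplit(cogs$categories, "", fixed = TRUE)))
  out <- list()
  is_tcs <- FALSE
  tcs <- rules$tcs
  if (!is.null(tcs) && !is.null(tcs$role_logic)) {
    has_rec <- any(acc %in% tcs$role_logic$receiver)
    has_kin <- any(acc %in% tcs$role_logic$kinase_core)
    if (has_rec || has_kin) {
      role <- if (has_rec && has_kin) "hybrid" else if (has_rec) "RR" else "HK"
      out[[length(out) + 1L]] <- c("tcs", role)
      is_tcs <- TRUE
    }
  }
  for (cat in setdiff(names(rules), "tcs")) {
    r <- rules[[cat]]
    hit <- any(acc %in% r$pfam) || any(cog_ids %in% r$cog_id) ||
      any(cog_cats %in% r$cog_cat)
    if (hit && !(cat == "tf" && is_tcs)) {
      out[[length(out) + 1L]] <- c(cat, NA_character_)
    }
  }
  if (!length(out)) {
    return(data.frame(category = character(), role = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  data.frame(category = m[, 1L], role = m[, 2L], stringsAsFactors = FALSE)
}

#' Build a per-genome category inventory
#'
#' Applies [classify_gene()] to every gene and tallies category membership.
#' TCS role subcounts (`tcs_RR`, `tcs_HK`, `tcs_hybrid`) are included; their
#' sum always equals the `tcs` count.
#'
#' @param genome A [genome_record()].
#' @param rules A [read_category_rules()] object.
#' @return Object of class `CategoryInventory`: `genome_id`, named integer
#'   vector `counts`, list `members` of gene-id vectors per category.
#' @export
build_inventory <- function(genome, rules = default_category_rules()) {
  stopifnot(inherits(genome, "GenomeRecord"))
  if (!inherits(rules, "CategoryRules") || !length(rules)) {
    stop("configuration error: empty rule set")
  }
  cats <- names(rules)
  members <- stats::setNames(
    rep(list(character()), length(cats) + 3L),
    c(cats, "tcs_RR", "tcs_HK", "tcs_hybrid"))
  hits_by <- split(genome$domain_hits, genome$domain_hits$gene_id)
  cogs_by <- split(genome$cog_assignments, genome$cog_assignments$gene_id)
  for (gid in genome$genes$gene_id) {
    lab <- classify_gene(hits_by[[gid]] %||% empty_domain_hits(),
                         cogs_by[[gid]] %||% empty_cog_assignments(),
                         rules)
    for (k in seq_len(nrow(lab))) {
      cc <- lab$category[k]
      members[[cc]] <- c(members[[cc]], gid)
      if (cc == "tcs") {
        sub <- paste0("tcs_", lab$role[k])
        members[[sub]] <- c(members[[sub]], gid)
      }
    }
  }
  members <- lapply(members, sort)
  structure(
    list(genome_id = genome$genome_id,
         counts = vapply(members, length, 0L),
         members = members),
    class = "CategoryInventory"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.CategoryInventory <- function(x, ...) {
  cat("CategoryInventory for", x$genome_id, "\n")
  print(x$counts)
  invisible(x)
}

#' Cluster same-category genes into chromosomal loci
#'
#' Two genes of the same category on the same replicon whose inter-gene gap
#' (next start minus previous end) is at most `max_gap_bp` belong to one
#' locus; membership is closed transitively, so chains of closely spaced
#' genes form a single locus. Used for kilobase-scale gene clusters such as
#' flagellar loci or secondary-metabolite gene cluster spans.
#'
#' @param genome A [genome_record()].
#' @param category Category name present in `rules`.
#' @param max_gap_bp Maximum inter-gene gap within a locus (default 5000).
#' @param rules A [read_category_rules()] object.
#' @param members Optional precomputed character vector of member gene ids
#'   (bypasses classification).
#' @return `data.frame` with columns `replicon_id`, `start`, `end`,
#'   `span_bp`, `n_genes`, `gene_ids` (semicolon-joined), in coordinate
#'   order.
#' @export
cluster_category_loci <- function(genome, category, max_gap_bp = 5000,
                                  rules = default_category_rules(),
                                  members = NULL) {
  stopifnot(max_gap_bp > 0)
  if (is.null(members)) {
    if (!category %in% names(rules)) {
      stop("configuration error: unknown category '", category, "'")
    }
    inv <- build_inventory(genome, rules)
    members <- inv$members[[category]]
  }
  g <- genome$genes[genome$genes$gene_id %in% members, , drop = FALSE]
  if (!nrow(g)) {
    return(data.frame(replicon_id = character(), start = integer(),
                      end = integer(), span_bp = integer(),
                      n_genes = integer(), gene_ids = character(),
                      stringsAsFactors = FALSE))
  }
  g <- g[order(g$replicon_id, g$start), , drop = FALSE]
  new_rep <- c(TRUE, g$replicon_id[-1L] != g$replicon_id[-nrow(g)])
  # gap to the furthest end seen so far on the replicon, so contained or
  # overlapping genes cannot break the transitive closure
  reach <- stats::ave(g$end, cumsum(new_rep), FUN = cummax)
  gap <- c(Inf, g$start[-1L] - reach[-nrow(g)])
  locus <- cumsum(new_rep | gap > max_gap_bp)
  out <- do.call(rbind, lapply(split(seq_len(nrow(g)), locus), function(idx) {
    data.frame(replicon_id = g$replicon_id[idx[1L]],
               start = min(g$start[idx]), end = max(g$end[idx]),
               span_bp = max(g$end[idx]) - min(g$start[idx]),
               n_genes = length(idx),
               gene_ids = paste(g$gene_id[idx], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$replicon_id, out$start), , drop = FALSE]
}
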