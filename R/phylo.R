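# Distance-based phylogenetics for 16S rRNA panels: pairwise distances
# under simple nucleotide models, deterministic neighbor-joining, and
# bootstrap bipartition support.

#' Read a multiple sequence alignment from FASTA
#'
#' @param path FASTA file; sequences must be equal length over
#'   `A/C/G/T/-/N` (case-insensitive).
#' @return Named character vector (the alignment rows).
#' @export
read_alignment <- function(path) {
  x <- toupper(as.character(Biostrings::readDNAStringSet(path)))
  validate_alignment(x)
}

validate_alignment <- function(x) {
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("alignment taxa must have unique names")
  }
  if (length(unique(nchar(x))) != 1L) {
    stop("alignment rows must all have the same length")
  }
  if (any(grepl("[^ACGTN-]", x))) {
    stop("alignment contains characters outside A/C/G/T/-/N")
  }
  x
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
}

#' Pairwise evolutionary distances from an alignment
#'
#' Sites containing `-` or `N` in either sequence of a pair are excluded
#' for that pair (pairwise deletion). Models:
#' \describe{
#'   \item{`p`}{observed mismatch fraction.}
#'   \item{`jc`}{Jukes-Cantor, `-(3/4) log(1 - 4p/3)`.}
#'   \item{`tn93_pooled`}{Tamura-Nei (1993) distance with base frequencies
#'     pooled over the whole alignment and the transition/transversion
#'     partition estimated from counts pooled across all pairs; each
#'     pair's observed difference fraction is split by the pooled
#'     proportions before applying the TN93 formula. This is a
#'     composite-likelihood-style estimator: with equal base frequencies
#'     and equal rates it reduces to Jukes-Cantor.}
#' }
#'
#' @param aln Named character vector (see [read_alignment()]).
#' @param model One of `"p"`, `"jc"`, `"tn93_pooled"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
compute_distances <- function(aln, model = c("p", "jc", "tn93_pooled")) {
  model <- match.arg(model)
  aln <- validate_alignment(aln)
  if (length(aln) < 2L) stop("need at least 2 taxa")
  m <- aln_matrix(aln)
  ntax <- nrow(m)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  D <- matrix(0, ntax, ntax, dimnames = list(names(aln), names(aln)))

  pooled <- NULL
  if (model == "tn93_pooled") {
    base <- table(factor(m[ok], levels = c("A", "C", "G", "T")))
    pi <- as.numeric(base) / sum(base)
    names(pi) <- c("A", "C", "G", "T")
    ts1 <- 0; ts2 <- 0; tv <- 0; ntot <- 0
    for (i in seq_len(ntax - 1L)) {
      for (j in (i + 1L):ntax) {
        use <- ok[i, ] & ok[j, ]
        a <- m[i, use]; b <- m[j, use]
        ntot <- ntot + sum(use)
        diff <- a != b
        pairkey <- paste0(pmin(a[diff], b[diff]), pmax(a[diff], b[diff]))
        ts1 <- ts1 + sum(pairkey == "AG")
        ts2 <- ts2 + sum(pairkey == "CT")
        tv <- tv + sum(!pairkey %in% c("AG", "CT"))
      }
    }
    tot <- ts1 + ts2 + tv
    pooled <- list(pi = pi,
                   w1 = if (tot > 0) ts1 / tot else 1 / 3,
                   w2 = if (tot > 0) ts2 / tot else 1 / 3,
                   wq = if (tot > 0) tv / tot else 1 / 3)
  }

  for (i in seq_len(ntax - 1L)) {
    for (j in (i + 1L):ntax) {
      use <- ok[i, ] & ok[j, ]
      nshared <- sum(use)
      if (nshared == 0L) {
        stop("no shared ungapped sites between ", names(aln)[i], " and ",
             names(aln)[j])
      }
      p <- sum(m[i, use] != m[j, use]) / nshared
      D[i, j] <- D[j, i] <- switch(
        model,
        p = p,
        jc = {
          if (p >= 0.75) {
            stop("Jukes-Cantor distance undefined (p >= 3/4) for pair ",
                 names(aln)[i], " / ", names(aln)[j])
          }
          -0.75 * log(1 - 4 * p / 3)
        },
        tn93_pooled = tn93_distance(p, pooled, names(aln)[c(i, j)])
      )
    }
  }
  D
}

tn93_distance <- function(p, pooled, pair) {
  if (p == 0) return(0)
  pi <- pooled$pi
  piR <- pi["A"] + pi["G"]
  piY <- pi["C"] + pi["T"]
  k1 <- 2 * pi["A"] * pi["G"] / piR
  k2 <- 2 * pi["T"] * pi["C"] / piY
  k3 <- 2 * (piR * piY - pi["A"] * pi["G"] * piY / piR -
               pi["T"] * pi["C"] * piR / piY)
  P1 <- pooled$w1 * p
  P2 <- pooled$w2 * p
  Q <- pooled$wq * p
  t1 <- 1 - P1 / k1 - Q / (2 * piR)
  t2 <- 1 - P2 / k2 - Q / (2 * piY)
  t3 <- 1 - Q / (2 * piR * piY)
  if (t1 <= 0 || t2 <= 0 || t3 <= 0) {
    stop("TN93 distance undefined (saturated) for pair ",
         paste(pair, collapse = " / "))
  }
  unname(-k1 * log(t1) - k2 * log(t2) - k3 * log(t3))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining on the Q criterion. Deterministic: ties in Q
#' are broken by the lexicographically lowest pair of current node indices;
#' negative branch lengths are clamped to zero. Returns an unrooted
#' `ape::phylo` tree (represented with a basal trifurcation).
#'
#' @param D Symmetric numeric matrix with taxon dimnames.
#' @return An `ape` `phylo` object.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining requires at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must have taxon names")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric")
  labs <- rownames(D)
  frag <- labs                        # newick fragment per active node
  d <- D
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    idx <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    li <- max(0, li); lj <- max(0, lj)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    frag <- c(frag[keep], newfrag)
    d <- d2
  }
  # final three nodes: three-point formulas
  l1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1L], l1, frag[2L], l2, frag[3L], l3)
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is canonicalized
#' as the sorted side not containing the reference taxon, serialized with
#' `|`. Used to compare topologies and to count bootstrap support.
#'
#' @param tree An `ape` `phylo` object.
#' @param ref Reference taxon (default: alphabetically first tip).
#' @return Character vector of canonical bipartition keys (may be empty
#'   for star trees).
#' @export
tree_bipartitions <- function(tree, ref = NULL) {
  ntip <- length(tree$tip.label)
  if (is.null(ref)) ref <- sort(tree$tip.label)[1L]
  root <- ntip + 1L
  internal <- setdiff(unique(tree$edge[, 2L][tree$edge[, 2L] > ntip]), root)
  keys <- character()
  for (node in internal) {
    tips <- tips_below(tree, node)
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    side <- sort(tree$tip.label[tips])
    if (ref %in% side) side <- sort(setdiff(tree$tip.label, side))
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v <= ntip) {
      out <- c(out, v)
    } else {
      stack <- c(stack, tree$edge[tree$edge[, 1L] == v, 2L])
    }
  }
  out
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `replicates` times; each internal bipartition
#' of the full-data tree is annotated with the percentage of replicate
#' trees containing it. Output is reproducible for a given seed.
#'
#' @param aln Named character vector alignment.
#' @param model Distance model (see [compute_distances()]).
#' @param replicates Number of bootstrap replicates (default 500).
#' @param seed Integer RNG seed.
#' @return The full-data `phylo` tree with `node.label` holding support
#'   percentages (root label empty), plus attribute `support` (named
#'   vector keyed by bipartition).
#' @export
bootstrap_support <- function(aln, model = "jc", replicates = 500, seed = 1) {
  aln <- validate_alignment(aln)
  stopifnot(replicates >= 1)
  nsite <- nchar(aln[[1L]])
  if (nsite < 4L) stop("alignment too short to bootstrap (< 4 columns)")
  full_tree <- neighbor_joining(compute_distances(aln, model))
  parts <- tree_bipartitions(full_tree)
  hits <- stats::setNames(numeric(length(parts)), parts)
  m <- aln_matrix(aln)
  set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample.int(nsite, nsite, replace = TRUE)
    rep_aln <- stats::setNames(apply(m[, cols, drop = FALSE], 1L, paste,
                                     collapse = ""), names(aln))
    rep_tree <- try(neighbor_joining(compute_distances(rep_aln, model)),
                    silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    rp <- tree_bipartitions(rep_tree)
    hits[parts %in% rp] <- hits[parts %in% rp] + 1
  }
  support <- 100 * hits / replicates
  # attach as node labels
  ntip <- length(full_tree$tip.label)
  ref <- sort(full_tree$tip.label)[1L]
  labels <- character(full_tree$Nnode)
  for (node in (ntip + 1L):(ntip + full_tree$Nnode)) {
    if (node == ntip + 1L) next    # root of the basal trifurcation
    tips <- tips_below(full_tree, node)
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    side <- sort(full_tree$tip.label[tips])
    if (ref %in% side) side <- sort(setdiff(full_tree$tip.label, side))
    key <- paste(side, collapse = "|")
    if (key %in% names(support)) {
      labels[node - ntip] <- format(support[[key]], digits = 4)
    }
  }
  full_tree$node.label <- labels
  attr(full_tree, "support") <- support
  full_tree
}

#' Do two trees share the same unrooted topology?
#' @param t1,t2 `phylo` objects over the same tip set.
#' @return `TRUE` when every non-trivial bipartition matches.
#' @export
same_topology <- function(t1, t2) {
  setequal(tree_bipartitions(t1), tree_bipartitions(t2))
}
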