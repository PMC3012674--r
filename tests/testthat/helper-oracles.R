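# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. Each oracle re-derives the quantity from its
# definition, by enumeration, without reusing package internals.

oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# connected components under "same replicon and gap <= max_gap" via
# union-find over all gene pairs
oracle_locus_components <- function(genes, max_gap) {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (genes$replicon_id[i] != genes$replicon_id[j]) next
      gap <- max(genes$start[j] - genes$end[i], genes$start[i] - genes$end[j])
      if (gap <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  split(genes$gene_id, comp)
}

# TCS organization by explicit reachability (BFS over the pairwise gap
# relation), then the paired/orphan/complex rules applied per component
oracle_organize <- function(genes, roles, pair_gap) {
  n <- nrow(genes)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || genes$replicon_id[i] != genes$replicon_id[j]) next
      lo <- if (genes$start[i] < genes$start[j]) i else j
      hi <- if (lo == i) j else i
      # adjacency means consecutive in coordinate order with a small gap:
      between <- any(genes$replicon_id == genes$replicon_id[i] &
                       genes$start > genes$start[lo] &
                       genes$start < genes$start[hi] &
                       seq_len(n) != lo & seq_len(n) != hi)
      if (!between && genes$start[hi] - genes$end[lo] <= pair_gap) {
        adj[i, j] <- TRUE
      }
    }
  }
  seen <- rep(FALSE, n)
  org <- character(n)
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      queue <- c(queue, nb)
    }
    rr <- roles[comp]
    lab <- if (length(comp) >= 3L) "complex"
      else if (length(comp) == 2L && sum(rr %in% c("HK", "hybrid")) == 1L &&
               sum(rr == "RR") == 1L) "paired"
      else "orphan"
    org[comp] <- lab
  }
  org
}

# all maximal exact match pairs of length >= l_g, by pairwise extension
oracle_global_repeats <- function(s, l_g) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1L]]
  recs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (ch[i] != ch[j]) next
      left_max <- i == 1L || ch[i - 1L] != ch[j - 1L]
      if (!left_max) next
      L <- 0L
      while (j + L <= n && ch[i + L] == ch[j + L]) L <- L + 1L
      if (L >= l_g) {
        recs[[length(recs) + 1L]] <-
          c(start1 = i, end1 = i + L - 1L, start2 = j, end2 = j + L - 1L,
            length = L)
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      length = integer()))
  }
  m <- as.data.frame(do.call(rbind, recs))
  m <- m[order(m$start1, m$start2), , drop = FALSE]
  rownames(m) <- NULL
  m
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# all maximal inverted repeats with arm >= l_i, loop in [0, loop_max]
oracle_inverted_repeats <- function(s, l_i, loop_max) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1L]]
  is_arm <- function(a1, a2, b1, b2) {
    all(ch[b2:b1] == comp_base(ch[a1:a2]))
  }
  recs <- list()
  for (a1 in seq_len(n)) {
    for (b2 in seq_len(n)) {
      if (b2 <= a1) next
      max_arm <- (b2 - a1 + 1L) %/% 2L
      if (max_arm < l_i) next
      for (arm in l_i:max_arm) {
        a2 <- a1 + arm - 1L
        b1 <- b2 - arm + 1L
        loop <- b1 - a2 - 1L
        if (loop < 0L || loop > loop_max) next
        if (!is_arm(a1, a2, b1, b2)) next
        out_ext <- a1 > 1L && b2 < n && ch[b2 + 1L] == comp_base(ch[a1 - 1L])
        in_ext <- loop >= 2L && ch[a2 + 1L] == comp_base(ch[b1 - 1L])
        if (out_ext || in_ext) next
        recs[[length(recs) + 1L]] <-
          c(start1 = a1, end1 = a2, start2 = b1, end2 = b2,
            arm = arm, loop = loop)
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      arm = integer(), loop = integer()))
  }
  m <- as.data.frame(do.call(rbind, recs))
  m <- unique(m)
  m <- m[order(m$start1, m$start2), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# maximal tandem runs per period, minimal-period containment filter
oracle_tandem_repeats <- function(s, periods, c_min) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1L]]
  recs <- list()
  for (p in sort(periods)) {
    i <- 1L
    while (i + p <= n) {
      if (ch[i] == ch[i + p]) {
        left_max <- i == 1L || ch[i - 1L] != ch[i - 1L + p]
        if (left_max) {
          e <- i
          while (e + p <= n && ch[e] == ch[e + p]) e <- e + 1L
          end <- e - 1L + p
          copies <- (end - i + 1L) %/% p
          if (copies >= c_min) {
            contained <- any(vapply(recs, function(r) {
              r["period"] < p && r["start"] <= i && r["end"] >= end
            }, TRUE))
            if (!contained) {
              recs[[length(recs) + 1L]] <-
                c(start = i, end = end, period = p, copies = copies)
            }
          }
        }
      }
      i <- i + 1L
    }
  }
  if (!length(recs)) {
    return(data.frame(start = integer(), end = integer(),
                      period = integer(), copies = integer()))
  }
  m <- as.data.frame(do.call(rbind, recs))
  m <- m[order(m$start, m$period), , drop = FALSE]
  rownames(m) <- NULL
  m
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small genome with explicit gene coordinates (0-based half-open)
make_genes <- function(starts, lens = 100, replicon = "chr1",
                       ids = sprintf("g%02d", seq_along(starts))) {
  if (!length(starts)) {
    return(data.frame(gene_id = character(), replicon_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), product = character(),
                      is_cds = logical(), stringsAsFactors = FALSE))
  }
  data.frame(gene_id = ids, replicon_id = replicon,
             start = starts, end = starts + lens,
             strand = "+", product = "", is_cds = TRUE,
             stringsAsFactors = FALSE)
}

# genome record whose genes carry TCS domain hits with the given roles
make_tcs_genome <- function(starts, roles, lens = 100) {
  genes <- make_genes(starts, lens)
  hits <- do.call(rbind, lapply(seq_along(roles), function(i) {
    role <- roles[i]
    if (is.na(role)) return(NULL)
    acc <- switch(role, RR = "PF00072", HK = "PF00512",
                  hybrid = c("PF00072", "PF00512"))
    data.frame(gene_id = genes$gene_id[i], accession = acc,
               e_value = 1e-20, bit_score = 50, stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) {
    hits <- data.frame(gene_id = character(), accession = character(),
                       e_value = numeric(), bit_score = numeric(),
                       stringsAsFactors = FALSE)
  }
  genome_record("toy", max(genes$end) + 100, genes, domain_hits = hits)
}
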