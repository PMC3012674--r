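rules <- default_category_rules()

hit_row <- function(gene, acc, score = 50) {
  data.frame(gene_id = gene, accession = acc, e_value = 1e-20,
             bit_score = score, stringsAsFactors = FALSE)
}
cog_row <- function(gene, cog, cats) {
  data.frame(gene_id = gene, cog_id = cog, categories = cats,
             stringsAsFactors = FALSE)
}
no_hits <- hit_row("x", "x")[0, ]
no_cogs <- cog_row("x", "x", "x")[0, ]

test_that("TCS roles resolve from receiver and kinase-core domains", {
  rr <- classify_gene(hit_row("g", "PF00072"), no_cogs, rules)
  expect_equal(rr$category, "tcs")
  expect_equal(rr$role, "RR")

  hk <- classify_gene(hit_row("g", "PF00512"), no_cogs, rules)
  expect_equal(hk$role, "HK")

  hyb <- classify_gene(rbind(hit_row("g", "PF00072"),
                             hit_row("g", "PF02518"),
                             hit_row("g", "PF00512")), no_cogs, rules)
  expect_equal(hyb$role, "hybrid")

  none <- classify_gene(no_hits, no_cogs, rules)
  expect_equal(nrow(none), 0L)
})

test_that("TCS genes are excluded from the TF category", {
  both <- classify_gene(rbind(hit_row("g", "PF00072"),
                              hit_row("g", "PF00165")), no_cogs, rules)
  expect_true("tcs" %in% both$category)
  expect_false("tf" %in% both$category)

  tf_only <- classify_gene(hit_row("g", "PF00165"), no_cogs, rules)
  expect_equal(tf_only$category, "tf")
})

test_that("transport and defense labels come from COG ids and categories", {
  tr <- classify_gene(no_hits, cog_row("g", "COG0477", "G"), rules)
  expect_equal(tr$category, "transport")
  def_cat <- classify_gene(no_hits, cog_row("g", "COG9999", "V"), rules)
  expect_equal(def_cat$category, "defense")
  both <- classify_gene(no_hits, cog_row("g", "COG1132", "V"), rules)
  expect_setequal(both$category, c("transport", "defense"))
})

test_that("classification fails on an empty rule set", {
  expect_error(classify_gene(no_hits, no_cogs, structure(list(),
                                                         class = "CategoryRules")),
               "empty rule set")
})

test_that("inventory counts planted categories and TCS roles add up", {
  g <- gen_annotated_genome(n_pairs = 4, n_orphans = 2, n_clusters = 1,
                            n_tf = 5, n_transport = 3, n_defense = 2,
                            seed = 9)
  inv <- build_inventory(g$genome)
  truth_counts <- table(g$truth$category)
  expect_equal(inv$counts[["tf"]], unname(truth_counts[["tf"]]))
  expect_equal(inv$counts[["transport"]], unname(truth_counts[["transport"]]))
  expect_equal(inv$counts[["defense"]], unname(truth_counts[["defense"]]))
  expect_equal(inv$counts[["tcs"]], unname(truth_counts[["tcs"]]))
  expect_equal(inv$counts[["tcs"]],
               inv$counts[["tcs_RR"]] + inv$counts[["tcs_HK"]] +
                 inv$counts[["tcs_hybrid"]])
  expect_equal(unname(inv$counts[names(inv$counts)]),
               unname(lengths(inv$members[names(inv$counts)])))
})

test_that("inventory of an empty genome is all zeros", {
  empty <- genome_record("none", 1000, make_genes(integer(0)))
  inv <- build_inventory(empty)
  expect_true(all(inv$counts == 0L))
})

test_that("inventory is invariant to gene input order", {
  g <- gen_annotated_genome(seed = 21)
  rec <- g$genome
  shuffled <- rec$genes[sample(nrow(rec$genes)), ]
  rec2 <- genome_record(rec$genome_id, rec$size_bp, shuffled,
                        domain_hits = rec$domain_hits[sample(nrow(rec$domain_hits)), ],
                        cog_assignments = rec$cog_assignments)
  expect_equal(build_inventory(rec2)$counts, build_inventory(rec)$counts)
})

test_that("locus clustering follows the gap threshold and transitivity", {
  # gaps of 100 bp and 10,000 bp with a 5,000 bp threshold: two loci
  genes <- make_genes(c(0L, 200L, 10400L), lens = 100L)
  rec <- genome_record("toy", 20000, genes)
  loci <- cluster_category_loci(rec, "any", max_gap_bp = 5000,
                                members = genes$gene_id)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$n_genes, c(2L, 1L))

  # transitive: gaps 50, 50 merge all three
  genes3 <- make_genes(c(0L, 150L, 300L), lens = 100L)
  rec3 <- genome_record("toy", 1000, genes3)
  loci3 <- cluster_category_loci(rec3, "any", max_gap_bp = 60,
                                 members = genes3$gene_id)
  expect_equal(nrow(loci3), 1L)
  expect_equal(loci3$n_genes, 3L)
  expect_equal(loci3$span_bp, 400L)

  # single gene: span equals gene length
  one <- cluster_category_loci(rec, "any", max_gap_bp = 10,
                               members = "g01")
  expect_equal(one$span_bp, 100L)

  expect_error(cluster_category_loci(rec, "nonexistent"), "unknown category")
})

test_that("locus clustering matches the union-find oracle on random layouts", {
  set.seed(404)
  for (trial in 1:20) {
    n <- sample(5:50, 1)
    starts <- sort(sample.int(50000, n))
    genes <- make_genes(starts, lens = sample(50:200, n, replace = TRUE))
    genes$replicon_id <- sample(c("c1", "c2"), n, replace = TRUE)
    # keep starts sorted within replicons after reassignment
    genes <- genes[order(genes$replicon_id, genes$start), ]
    rec <- genome_record("toy", 100000,
                         genes[, c("gene_id", "replicon_id", "start", "end",
                                   "strand", "product", "is_cds")])
    gap <- sample(c(100, 500, 2000), 1)
    loci <- cluster_category_loci(rec, "any", max_gap_bp = gap,
                                  members = genes$gene_id)
    got <- sort(vapply(strsplit(loci$gene_ids, ";"), function(x) {
      paste(sort(x), collapse = ",")
    }, ""))
    want <- unname(sort(vapply(oracle_locus_components(rec$genes, gap),
                               function(x) paste(sort(x), collapse = ","), "")))
    expect_equal(got, want)
  }
})
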