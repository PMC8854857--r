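test_that("NG86 matches closed-form and symmetric expectations", {
  same <- ng86_pair(strrep("ATGAAA", 5), strrep("ATGAAA", 5))
  expect_equal(same$Sd, 0)
  expect_equal(same$Nd, 0)
  expect_equal(same$dS, 0)
  expect_equal(same$dN, 0)
  expect_true(is.na(same$omega))

  # ten Phe codons, one synonymous third-position change
  a <- strrep("TTT", 10)
  b <- paste0(strrep("TTT", 9), "TTC")
  r <- ng86_pair(a, b)
  expect_equal(r$S, 10 / 3)
  expect_equal(r$Sd, 1)
  expect_equal(r$pS, 0.3)
  expect_equal(r$dS, -0.75 * log(1 - 0.4))
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)

  # symmetry and site conservation S + N = 3 * codons
  set.seed(19)
  x <- simulate_codon_descendants(.random_cds(60), 2, n_changes = 25,
                                  seed = 4)
  r12 <- ng86_pair(x[1], x[2])
  r21 <- ng86_pair(x[2], x[1])
  expect_equal(r12$Sd, r21$Sd)
  expect_equal(r12$Nd, r21$Nd)
  expect_equal(r12$S, r21$S)
  expect_equal(r12$S + r12$N, 3 * r12$codons_used, tolerance = 1e-9)

  # gap/ambiguity codons are dropped pairwise
  gap <- ng86_pair("ATGNNNAAA", "ATGAAAAAA")
  expect_equal(gap$codons_used, 2L)
})

test_that("multi-hit codons average over minimal pathways", {
  # TTT -> GTA: 2 differences, enumerate both orders by hand
  #   TTT -(1)-> GTT (F->V, nonsyn) -(3)-> GTA (V->V, syn)
  #   TTT -(3)-> TTA (F->L, nonsyn) -(1)-> GTA (L->V, nonsyn)
  r <- ng86_pair("TTT", "GTA")
  expect_equal(r$Sd, 0.5)
  expect_equal(r$Nd, 1.5)

  # pathway through a stop codon is excluded: AGA -> TCA
  #   AGA -(1)-> TGA is a stop; only the order via TCA remains... both
  #   orders checked against the recursive oracle instead of by hand
  for (pair in list(c("AGA", "TCA"), c("TGG", "TAC"), c("ATG", "TGA"),
                    c("AAA", "GGG"))) {
    got <- plastidcomp:::.pathway_counts(pair[1], pair[2],
                                         plastidcomp:::ng86_tables())
    want <- oracle_pathway_counts(pair[1], pair[2])
    if (is.null(want)) next
    expect_equal(unname(got["sd"]), unname(want["sd"]), tolerance = 1e-12)
    expect_equal(unname(got["nd"]), unname(want["nd"]), tolerance = 1e-12)
  }
})

test_that("codon alignments keep shared clean genes and log exclusions", {
  g1 <- circular_genome("g1", paste0(
    strrep("ACGTT", 20), "ATGAAATAA", strrep("GATCC", 20),
    "ATGCCCGGGTAA", strrep("TTGCA", 20)))
  g2 <- circular_genome("g2", g1$seq)
  mk_ft <- function(g, pseudo_b = FALSE, with_c = TRUE) {
    f <- data.frame(
      feature_id = c("a", "b"), name = c("geneA", "geneB"),
      kind = "gene", strand = "+",
      start = c(101L, 210L), end = c(109L, 221L), part = 1L,
      pseudo = c(FALSE, pseudo_b), stringsAsFactors = FALSE)
    if (!with_c) f <- f[f$name != "geneB", ]
    feature_table(g, f)
  }
  # both genes shared and clean: stops stripped, alphabetical order
  ca <- build_codon_alignment(list(g1 = g1, g2 = g2),
                              list(g1 = mk_ft(g1), g2 = mk_ft(g2)))
  expect_equal(ca$genes_used, c("geneA", "geneB"))
  expect_equal(unname(ca$seqs["g1"]), "ATGAAAATGCCCGGG")

  # a gene absent from one taxon is excluded with its reason
  ca2 <- build_codon_alignment(
    list(g1 = g1, g2 = g2),
    list(g1 = mk_ft(g1), g2 = mk_ft(g2, with_c = FALSE)))
  expect_equal(ca2$genes_used, "geneA")
  expect_match(ca2$genes_excluded$reason[
    ca2$genes_excluded$gene == "geneB"], "absent")

  # pseudo in one taxon excludes the gene everywhere
  ca3 <- build_codon_alignment(
    list(g1 = g1, g2 = g2),
    list(g1 = mk_ft(g1), g2 = mk_ft(g2, pseudo_b = TRUE)))
  expect_equal(ca3$genes_used, "geneA")
  expect_match(ca3$genes_excluded$reason[
    ca3$genes_excluded$gene == "geneB"], "pseudogene")
})

test_that("minus-strand and spliced CDS extraction is exact", {
  synth <- small_synth(seed = 17)
  ft <- synth$features
  # clpP is planted on the minus strand with two introns
  cds <- extract_cds(synth$genome, ft, "clpP")
  expect_equal(nchar(cds), 591L)
  expect_equal(substr(cds, 1, 3), "ATG")
  expect_equal(substr(cds, 589, 591), "TAA")
  tabs <- plastidcomp:::ng86_tables()
  nc <- nchar(cds) %/% 3
  starts <- 3 * (seq_len(nc - 1) - 1) + 1
  expect_false(any(substring(cds, starts, starts + 2) %in% tabs$stops))
})

test_that("extreme-value filters flag but keep pairs", {
  x <- simulate_codon_descendants(.random_cds(80, seed = 3), 3,
                                  n_changes = 12, seed = 9)
  ca <- structure(list(ids = names(x), seqs = x,
                       genes_used = "sim", code = "standard",
                       genes_excluded = NULL),
                  class = "CodonAlignment")
  tab <- dnds_matrix(ca, ds_min = 10)   # force the low-dS rule
  diverged <- tab[tab$dS > 0, ]
  expect_true(all(diverged$filtered))
  expect_true(all(grepl("dS <", diverged$reason)))

  tab2 <- dnds_matrix(ca, dn_max = 1e-9)
  expect_true(any(grepl("dN >", tab2$reason[tab2$filtered])))

  # an identical pair reports NA omega and is never filtered
  y <- c(a = strrep("ATGAAA", 10), b = strrep("ATGAAA", 10))
  ca2 <- structure(list(ids = names(y), seqs = y, genes_used = "sim",
                        code = "standard", genes_excluded = NULL),
                   class = "CodonAlignment")
  tab3 <- dnds_matrix(ca2)
  expect_true(is.na(tab3$omega))
  expect_false(tab3$filtered)

  fm <- format_dnds_matrix(tab)
  expect_true(any(grepl("\\*", fm)))
})
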