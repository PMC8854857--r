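toy_aln <- function(...) {
  seqs <- c(...)
  aligned_matrix(seqs)
}

test_that("alignment reading builds column maps and round-trips rows", {
  aln <- toy_aln(a = "AC-GT", b = "ACAGT")
  expect_equal(aln$column_map$a, c(1L, 2L, NA, 3L, 4L))
  expect_equal(aln$column_map$b, 1:5)
  expect_equal(ungapped_sequence(aln, "a"), "ACGT")

  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGT-ACGT", ">r2", "ACGTTACGT"), tmp)
  back <- read_alignment(tmp)
  expect_equal(ncol(back$mat), 9L)
  expect_equal(back$reference_id, "r1")
  expect_error(toy_aln(a = "ACGT", b = "ACG"), "ragged")
})

test_that("site classes follow their definitions", {
  aln <- toy_aln(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA")
  sc <- classify_sites(aln)
  expect_equal(sc$variable_sites, 0L)
  expect_equal(sc$parsimony_informative_sites, 0L)

  # column 1: A/A/C/C informative; column 2: A/A/A/G singleton
  aln2 <- toy_aln(a = "AA", b = "AA", c = "CA", d = "CG")
  sc2 <- classify_sites(aln2)
  expect_equal(sc2$variable_sites, 2L)
  expect_equal(sc2$parsimony_informative_sites, 1L)
  expect_equal(sc2$singleton_sites, 1L)

  # gap or N anywhere removes the column from the gap-free set
  aln3 <- toy_aln(a = "A-CN", b = "AACA", c = "AACA")
  sc3 <- classify_sites(aln3)
  expect_equal(sc3$gap_free_columns, 2L)

  expect_error(classify_sites(toy_aln(a = "ACGT")), "at least 2")

  # random alignment agrees with a per-column reimplementation
  set.seed(5)
  mat <- matrix(sample(c("A", "C", "G", "T", "-"), 4 * 500, replace = TRUE,
                       prob = c(rep(0.23, 4), 0.08)), nrow = 4)
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- paste0("s", 1:4)
  sc4 <- classify_sites(aligned_matrix(seqs))
  col_truth <- apply(mat, 2, function(col) {
    if (any(col %in% c("-", "N"))) return(c(0L, 0L, 0L))
    tab <- table(col)
    v <- as.integer(length(tab) >= 2L)
    inf <- as.integer(sum(tab >= 2L) >= 2L && length(tab) >= 2L)
    c(1L, v, inf)
  })
  expect_equal(sc4$gap_free_columns, sum(col_truth[1, ]))
  expect_equal(sc4$variable_sites, sum(col_truth[2, ]))
  expect_equal(sc4$parsimony_informative_sites, sum(col_truth[3, ]))
})

test_that("pi and theta match hand-computed values", {
  two_same <- toy_aln(a = "ACGTACGTAC", b = "ACGTACGTAC")
  d0 <- nucleotide_diversity(two_same)
  expect_equal(d0$pi, 0)
  expect_equal(d0$theta, 0)

  two_diff <- toy_aln(a = "ACGTACGTAC", b = "ACGTACGTAT")
  d1 <- nucleotide_diversity(two_diff)
  expect_equal(d1$pi, 0.1)
  expect_equal(d1$theta, 0.1)  # a_1 = 1

  three <- toy_aln(a = "ACGTACGTAC", b = "ACGTACGTAT", c = "ACGAACGTAT")
  d3 <- nucleotide_diversity(three)
  expect_equal(d3$pi, 4 / 30)
  expect_equal(d3$S, 2L)
  expect_equal(d3$theta, 2 / (1.5 * 10))

  # pi equals the brute-force mean over all pairs on random rows
  set.seed(11)
  seqs <- setNames(vapply(1:5, function(i) {
    paste(random_dna(200), collapse = "")
  }, ""), paste0("s", 1:5))
  aln <- aligned_matrix(seqs)
  dd <- nucleotide_diversity(aln)
  brute <- mean(apply(utils::combn(5, 2), 2, function(pr) {
    a <- strsplit(seqs[[pr[1]]], "")[[1]]
    b <- strsplit(seqs[[pr[2]]], "")[[1]]
    mean(a != b)
  }))
  expect_equal(dd$pi, brute)

  expect_error(nucleotide_diversity(toy_aln(a = "----", b = "AAAA")),
               "undefined statistic")
})

test_that("sliding windows advance correctly and conserve pi", {
  set.seed(3)
  seqs <- setNames(vapply(1:3, function(i) {
    paste(random_dna(1000), collapse = "")
  }, ""), paste0("s", 1:3))
  aln <- aligned_matrix(seqs)
  w <- sliding_windows(aln, window = 600, step = 200)
  expect_equal(w$start, c(1L, 201L, 401L))
  expect_equal(w$end, c(600L, 800L, 1000L))
  expect_false(any(w$partial))

  # a trailing remainder becomes one flagged partial window
  seqs2 <- setNames(vapply(1:3, function(i) {
    paste(random_dna(1050), collapse = "")
  }, ""), paste0("s", 1:3))
  aln2 <- aligned_matrix(seqs2)
  w2 <- sliding_windows(aln2, window = 600, step = 200)
  expect_equal(tail(w2$end, 1), 1050L)
  expect_true(tail(w2$partial, 1))

  # window larger than the alignment collapses to one window
  w3 <- sliding_windows(aln, window = 5000, step = 200)
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$end, 1000L)

  # non-overlapping windows partition the columns: weighted mean equals
  # whole-alignment pi (gap-free genome so weights are window lengths)
  wp <- sliding_windows(aln, window = 200, step = 200)
  lens <- wp$end - wp$start + 1L
  expect_equal(sum(wp$pi * lens) / sum(lens),
               nucleotide_diversity(aln)$pi)
})

test_that("hypervariable ranking finds planted peaks with annotation", {
  set.seed(21)
  base <- random_dna(4000)
  rows <- list(r1 = base, r2 = base, r3 = base)
  # plant two hotspots: a strong one at 1001-1200, weaker at 3001-3200
  for (nm in c("r2", "r3")) {
    x <- rows[[nm]]
    hot1 <- sample(1001:1200, 60)
    hot2 <- sample(3001:3200, 25)
    for (p in c(hot1, hot2)) x[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                    x[p]), 1)
    rows[[nm]] <- x
  }
  aln <- aligned_matrix(vapply(rows, paste, "", collapse = ""))
  w <- sliding_windows(aln, window = 300, step = 100)
  ft <- feature_table(
    circular_genome("r1", paste(base, collapse = "")),
    data.frame(feature_id = c("g1", "g2"), name = c("clpP", "ccsA"),
               kind = "gene", strand = "+",
               start = c(950L, 2950L), end = c(1250L, 3250L), part = 1L,
               pseudo = FALSE, stringsAsFactors = FALSE))
  hv <- hypervariable_regions(w, aln = aln, features = ft, k = 2)
  expect_equal(nrow(hv), 2L)
  # strongest peak covers the first hotspot and is annotated with its gene
  expect_true(hv$start[1] <= 1200 && hv$end[1] >= 1001)
  expect_match(hv$features[1], "clpP")
  expect_true(hv$start[2] <= 3200 && hv$end[2] >= 3001)
  expect_gt(hv$peak_pi[1], hv$peak_pi[2])
  expect_warning(hypervariable_regions(w, k = 50), "hypervariable regions")
})

test_that("pairwise indel events and substitutions follow the definitions", {
  aln <- toy_aln(a = "AC---GT", b = "ACAAAGT")
  d <- pairwise_divergence(aln, "a", "b")
  expect_equal(d$indel_events, 1L)
  expect_equal(d$substitutions, 0L)

  aln2 <- toy_aln(a = "ACGT", b = "TCGA")
  d2 <- pairwise_divergence(aln2, 1, 2)
  expect_equal(d2$indel_events, 0L)
  expect_equal(d2$substitutions, 2L)

  # both-gap columns vanish: a run split only by a shared gap is one event
  aln3 <- toy_aln(a = "A--CG", b = "A-ACG", c = "AAACG")
  d3 <- pairwise_divergence(aln3, "a", "b")
  expect_equal(d3$indel_events, 1L)
  # against the ungapped row both gaps of 'a' merge across the shared gap
  d3c <- pairwise_divergence(aln3, "a", "c")
  expect_equal(d3c$indel_events, 1L)

  # symmetry and zero diagonal
  set.seed(8)
  seqs <- setNames(vapply(1:3, function(i) {
    s <- random_dna(300)
    s[sample(300, 20)] <- "-"
    paste(s, collapse = "")
  }, ""), paste0("s", 1:3))
  aln4 <- aligned_matrix(seqs)
  for (i in 1:3) {
    expect_equal(pairwise_divergence(aln4, i, i)$substitutions, 0L)
    for (j in seq_len(3)) {
      a <- pairwise_divergence(aln4, i, j)
      b <- pairwise_divergence(aln4, j, i)
      expect_equal(a$indel_events, b$indel_events)
      expect_equal(a$substitutions, b$substitutions)
    }
  }
  m <- divergence_matrix(aln4)
  expect_true(all(is.na(diag(m))))
})

test_that("per-region variability reflects conservation, divergence and loss", {
  set.seed(14)
  base <- random_dna(900)
  refseq <- paste(base, collapse = "")
  # r2: diverged in 301-400 only; r3: region 601-700 deleted entirely
  x2 <- base
  for (p in sample(301:400, 30)) {
    x2[p] <- sample(setdiff(c("A", "C", "G", "T"), x2[p]), 1)
  }
  x3 <- base; x3[601:700] <- "-"
  aln <- aligned_matrix(c(ref = refseq,
                          r2 = paste(x2, collapse = ""),
                          r3 = paste(x3, collapse = "")))
  ft <- feature_table(
    circular_genome("ref", refseq),
    data.frame(feature_id = c("g1", "g2", "g3"),
               name = c("quietA", "hotB", "lostC"), kind = "gene",
               strand = "+", start = c(101L, 301L, 601L),
               end = c(200L, 400L, 700L), part = 1L, pseudo = FALSE,
               stringsAsFactors = FALSE))
  rv <- region_variability(aln, ft)
  expect_equal(rv$percent[rv$name == "quietA"], 0)
  expect_equal(rv$percent[rv$name == "hotB"], 30)
  expect_equal(rv$percent[rv$name == "lostC"], 100)
  pooled <- attr(rv, "pooled")
  expect_true(pooled[["coding"]] > 0)
  # monotone in the planted rate: hotB above quietA
  expect_gt(rv$percent[rv$name == "hotB"],
            rv$percent[rv$name == "quietA"])
})
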