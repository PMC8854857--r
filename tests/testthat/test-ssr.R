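test_that("motif canonicalization minimizes over rotations and revcomp", {
  expect_equal(canonical_motif("TA"), "AT")
  expect_equal(canonical_motif("GAA"), "AAG")
  expect_equal(canonical_motif("T"), "A")
  expect_equal(canonical_motif("tgc"), "AGC")  # lowercase accepted
  expect_error(canonical_motif("ATAT"), "non-primitive")
  expect_error(canonical_motif(""), "empty motif")
  # canonicalization is constant on the equivalence class
  rots_rc <- c("AGC", "GCA", "CAG", "GCT", "CTG", "TGC")
  expect_length(unique(vapply(rots_rc, canonical_motif, "")), 1L)
})

test_that("thresholds gate detection and loci are maximal", {
  pad <- function(core) {
    # embed in a fixed non-repetitive context that cannot extend the core
    paste0("GACTGCATGCGTACGATCGC", core, "TCAGCTAGCATGGATCCGTG")
  }
  expect_equal(nrow(find_ssrs(pad(strrep("A", 7)))), 0L)
  one <- find_ssrs(pad(strrep("A", 8)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$canonical_motif, "A")
  expect_equal(one$copies, 8L)
  expect_equal(one$start, 21L)

  tetra <- find_ssrs(pad("ACGTACGTACGT"))
  expect_equal(nrow(tetra), 1L)
  expect_equal(tetra$unit_len, 4L)
  expect_equal(tetra$copies, 3L)

  # a 9-base run is still one 8-copy locus plus nothing else (floor rule)
  nine <- find_ssrs(pad(strrep("A", 9)))
  expect_equal(nrow(nine), 1L)
  expect_equal(nine$copies, 9L)

  # smallest-primitive-unit rule: a poly-A run is never an AA dimer locus
  expect_false(any(find_ssrs(pad(strrep("A", 12)))$unit_len > 1L))
})

test_that("loci crossing the circular origin are found once", {
  set.seed(9)
  x <- random_dna(200)
  # plant (AT)5 wrapping the origin: 5 bases at the end, 5 at the start
  x[196:200] <- c("A", "T", "A", "T", "A")
  x[1:5] <- c("T", "A", "T", "A", "T")
  x[195] <- "C"   # break left extension (x[195] != x[197])
  x[6] <- "G"     # break right extension (x[6] != x[4])
  g <- circular_genome("wrap", paste(x, collapse = ""))
  loci <- find_ssrs(g)
  wrapped <- loci[loci$canonical_motif == "AT" & loci$start > loci$end, ]
  expect_equal(nrow(wrapped), 1L)
  expect_equal(wrapped$copies, 5L)
  expect_equal(wrapped$start, 196L)
  expect_equal(wrapped$end, 5L)
})

test_that("classification follows the midpoint with gene > intron precedence", {
  synth <- small_synth(seed = 13)
  part <- detect_quadripartite(synth$genome)
  can <- canonical_rotation(synth$genome, part)
  # generator output is already in canonical layout when not flipped;
  # use planted coordinates directly against the unrotated genome
  p0 <- part; p0$rotation_offset <- 0L; p0$strand_flipped <- FALSE
  loci <- find_ssrs(synth$genome)
  cls <- classify_ssrs(loci, p0, synth$features)
  merged <- merge(cls, synth$ssrs, by = c("start", "end"))
  expect_equal(nrow(merged), nrow(synth$ssrs))
  expect_equal(merged$structural_region, merged$region)
  # planted defaults live outside genes
  expect_true(all(merged$functional_region == "intergenic"))

  # constructed locus straddling JSB with midpoint in SSC
  straddle <- data.frame(genome_id = "x", motif = "AT",
                         canonical_motif = "AT", unit_len = 2L,
                         copies = 5L, start = p0$jsb - 4L,
                         end = p0$jsb + 5L, length = 10L,
                         stringsAsFactors = FALSE)
  got <- classify_ssrs(straddle, p0, synth$features)
  expect_equal(got$structural_region, "SSC")

  # a locus whose midpoint falls into a planted exon is classified "gene"
  f <- synth$features$features
  ex <- f[f$kind == "exon" | (f$kind == "gene" &
            !f$feature_id %in% f$feature_id[f$kind == "exon"]), ][1, ]
  mid_in_exon <- data.frame(genome_id = "x", motif = "A",
                            canonical_motif = "A", unit_len = 1L,
                            copies = 8L, start = ex$start + 2L,
                            end = ex$start + 9L, length = 8L,
                            stringsAsFactors = FALSE)
  got2 <- classify_ssrs(mid_in_exon, p0, synth$features)
  expect_equal(got2$functional_region, "gene")
})

test_that("summaries add up and densities scale correctly", {
  synth <- small_synth(seed = 2)
  part <- detect_quadripartite(synth$genome)
  p0 <- part; p0$rotation_offset <- 0L; p0$strand_flipped <- FALSE
  loci <- classify_ssrs(find_ssrs(synth$genome), p0, synth$features)
  summ <- ssr_summary(loci, setNames(list(p0), synth$genome$id))
  br <- summ$by_region
  total <- br$count[br$region == "Total"]
  expect_equal(sum(br$count[br$region %in% c("Intergenic", "Gene",
                                             "Intron")]), total)
  expect_equal(sum(br$count[br$region %in% c("LSC", "SSC", "IRa",
                                             "IRb")]), total)
  expect_equal(br$percent[br$region == "Total"], 100)
  # per-genome IRa and IRb counts mirror exactly
  expect_equal(br$count[br$region == "IRa"], br$count[br$region == "IRb"])

  # doubling the genomes doubles pooled counts but not densities
  loci2 <- loci; loci2$genome_id <- "copy"
  parts2 <- setNames(list(p0, p0), c(synth$genome$id, "copy"))
  summ2 <- ssr_summary(rbind(loci, loci2), parts2)
  expect_equal(summ2$density$n_ssr, 2L * summ$density$n_ssr)
  expect_equal(summ2$density$per_kb, summ$density$per_kb)

  # closed form: 10 loci in a 5000 bp LSC give 2 per kb
  toy <- loci[seq_len(10), ]
  toy$structural_region <- "LSC"
  toy_part <- p0
  toy_part$lsc_len <- 5000L
  summ3 <- ssr_summary(toy, setNames(list(toy_part), synth$genome$id))
  expect_equal(summ3$density$per_kb[summ3$density$region == "LSC"], 2)
})
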