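test_that("generation is deterministic and structurally exact", {
  spec <- plastome_spec(lsc_len = 20000, ir_len = 5000, ssc_len = 800,
                        genes = FALSE, ssrs = FALSE, seed = 42)
  g1 <- generate_plastome(spec)
  g2 <- generate_plastome(spec)
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_equal(g1$genome$length, 20000L + 2L * 5000L + 800L)

  # IRa is the exact reverse complement of IRb by construction
  irb <- substr(g1$genome$seq, 20001, 25000)
  ira <- substr(g1$genome$seq, 25801, 30800)
  expect_identical(ira, revcomp(irb))

  # quadripartite closure
  p <- detect_quadripartite(g1$genome)
  expect_equal(c(p$lsc_len, p$irb_len, p$ssc_len), c(20000L, 5000L, 800L))
})

test_that("planted gene annotations are internally consistent", {
  synth <- small_synth(seed = 31)
  f <- synth$features$features
  genes <- f[f$kind == "gene" & !f$pseudo, ]
  for (nm in genes$name) {
    cds <- extract_cds(synth$genome, synth$features, nm)
    expect_equal(nchar(cds) %% 3L, 0L)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
  }
  # IR genes appear twice, once per copy, on opposite strands
  rrn <- f[f$name == "rrn16" & f$kind == "rRNA", ]
  expect_equal(nrow(rrn), 2L)
  expect_setequal(rrn$strand, c("+", "-"))
})

test_that("zero-rate evolution is the identity with a gap-free truth alignment", {
  synth <- generate_plastome(plastome_spec(lsc_len = 12000, ir_len = 3000,
                                           ssc_len = 500, genes = FALSE,
                                           ssrs = FALSE, seed = 8))
  p <- detect_quadripartite(synth$genome)
  out <- evolve(synth$genome, evolution_spec(sub_prob = 0, indel_rate = 0,
                                             seed = 1), 2, partition = p)
  expect_equal(nrow(out$events), 0L)
  for (d in out$descendants) expect_identical(d$seq, synth$genome$seq)
  expect_false(any(out$alignment$mat == "-"))
})

test_that("substitution counts land in the binomial envelope", {
  synth <- generate_plastome(plastome_spec(lsc_len = 40000, ir_len = 4000,
                                           ssc_len = 900, genes = FALSE,
                                           ssrs = FALSE, seed = 12))
  p <- detect_quadripartite(synth$genome)
  pr <- 0.01
  out <- evolve(synth$genome,
                evolution_spec(sub_prob = pr, indel_rate = 0, seed = 3),
                1, partition = p)
  L <- synth$genome$length
  obs <- sum(out$alignment$mat[1, ] != out$alignment$mat[2, ])
  expect_lt(abs(obs - L * pr), 3 * sqrt(L * pr * (1 - pr)))
})

test_that("IR homogenization keeps descendant IR copies mirrored", {
  synth <- generate_plastome(plastome_spec(lsc_len = 15000, ir_len = 4000,
                                           ssc_len = 600, genes = FALSE,
                                           ssrs = FALSE, seed = 23))
  p <- detect_quadripartite(synth$genome)
  out <- evolve(synth$genome,
                evolution_spec(sub_prob = 0.01, indel_rate = 5e-4,
                               indel_mean_len = 3, seed = 6),
                2, partition = p)
  for (d in out$descendants) {
    pd <- detect_quadripartite(d, min_ir_len = 1000)
    expect_equal(pd$irb_len, 4000L)
    reg <- partition_regions(pd)
    can <- canonical_rotation(d, pd)$genome$seq
    irb <- substr(can, reg$start[2], reg$end[2])
    expect_identical(substr(can, reg$start[4], reg$end[4]), revcomp(irb))
  }
  # mirrored substitution events are logged for both copies
  mirr <- out$events[out$events$mirrored, ]
  expect_gt(nrow(mirr), 0L)
  expect_true(all(mirr$type == "sub"))
  # no indel event falls inside an IR
  indel <- out$events[out$events$type != "sub", ]
  in_ir <- indel$pos >= p$jlb & indel$pos <= p$jsb - 1L |
    indel$pos >= p$jsa
  expect_false(any(in_ir))
})

test_that("event logs replay exactly and match the truth alignment", {
  set.seed(99)
  anc <- circular_genome("anc", paste(random_dna(20000), collapse = ""))
  out <- evolve(anc, evolution_spec(sub_prob = 0.003, indel_rate = 3e-4,
                                    indel_mean_len = 4,
                                    ir_homogenize = FALSE, seed = 17), 2)
  for (id in names(out$descendants)) {
    expect_identical(replay_events(anc, out$events, id),
                     out$descendants[[id]]$seq)
    expect_identical(ungapped_sequence(out$alignment, id),
                     out$descendants[[id]]$seq)
  }
  expect_identical(ungapped_sequence(out$alignment, "anc"), anc$seq)
})

test_that("hotspot multipliers raise local window diversity", {
  set.seed(5)
  anc <- circular_genome("anc", paste(random_dna(30000), collapse = ""))
  hot <- data.frame(start = 12001L, end = 13200L, multiplier = 12)
  out <- evolve(anc, evolution_spec(sub_prob = 0.004, indel_rate = 0,
                                    hotspots = hot, ir_homogenize = FALSE,
                                    seed = 2), 3)
  w <- sliding_windows(out$alignment, window = 600, step = 200)
  top <- w[which.max(w$pi), ]
  expect_true(top$start <= 13200 && top$end >= 12001)
})
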