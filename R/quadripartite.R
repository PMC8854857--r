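# Detection of the quadripartite LSC/IRb/SSC/IRa plastome architecture.
#
# The inverted-repeat pair is found as the maximal-length pair of disjoint
# exact reverse-complement repeats on the circle, via k-mer seeding on the
# doubled sequence: a maximal exact inverted match of length m contains
# m - k + 1 consecutive seed hits on one anti-diagonal, so maximal matches
# are exactly the maximal runs of consecutive seeds per diagonal.

#' All maximal exact inverted-repeat matches on a circular sequence
#'
#' @param seq nucleotide string (treated as circular).
#' @param min_len minimum match length to report.
#' @param k seed length; 31 is collision-free in practice at plastome scale.
#' @return data.frame with columns `start1`, `start2` (1-based circular
#'   starts of the two copies, each read on the forward strand) and `len`.
#' @keywords internal
inverted_repeat_matches <- function(seq, min_len, k = 31L) {
  L <- nchar(seq)
  if (L < min_len || min_len < k) k <- min(k, max(4L, min_len %/% 2L))
  D <- paste0(seq, seq)
  R <- revcomp(D)
  nk <- 2L * L - k + 1L
  starts <- seq_len(nk)
  fk <- substring(D, starts, starts + k - 1L)
  rk <- substring(R, starts, starts + k - 1L)
  common <- intersect(unique(fk), unique(rk))
  if (length(common) == 0L) return(NULL)
  fpos <- split(starts[fk %in% common], fk[fk %in% common])
  rpos <- split(starts[rk %in% common], rk[rk %in% common])
  a <- integer(0); b <- integer(0)
  for (km in common) {
    pa <- fpos[[km]]; pb <- rpos[[km]]
    a <- c(a, rep(pa, each = length(pb)))
    b <- c(b, rep(pb, times = length(pa)))
  }
  d <- a - b
  ord <- order(d, a)
  a <- a[ord]; d <- d[ord]
  # maximal runs of consecutive seeds within a diagonal
  brk <- c(TRUE, diff(a) != 1L | diff(d) != 0L)
  run_id <- cumsum(brk)
  a0 <- tapply(a, run_id, min)
  n_seed <- tabulate(run_id)
  m <- n_seed + k - 1L
  b0 <- a0 - tapply(d, run_id, `[`, 1L)
  keep <- m >= min_len & m <= L
  if (!any(keep)) return(NULL)
  a0 <- a0[keep]; b0 <- b0[keep]; m <- m[keep]
  # copy1 in genome coords; copy2 is the image of the revcomp interval
  s1 <- circ_pos(a0, L)
  s2 <- circ_pos(2L * L - b0 - m + 2L, L)
  res <- data.frame(start1 = as.integer(pmin(s1, s2)),
                    start2 = as.integer(pmax(s1, s2)),
                    len = as.integer(m))
  unique(res)
}

circ_intervals_disjoint <- function(s1, s2, m, L) {
  p1 <- split_wrap(s1, circ_pos(s1 + m - 1L, L), L)
  p2 <- split_wrap(s2, circ_pos(s2 + m - 1L, L), L)
  ir1 <- IRanges::IRanges(start = p1[, "start"], end = p1[, "end"])
  ir2 <- IRanges::IRanges(start = p2[, "start"], end = p2[, "end"])
  length(IRanges::findOverlaps(ir1, ir2)) == 0L
}

#' Detect the quadripartite structure of a plastome
#'
#' Finds the maximal-length pair of disjoint exact reverse-complement
#' repeats of length at least `min_ir_len` on the circle; the two repeat
#' copies are the inverted repeats, the shorter single-copy arc between them
#' is labelled SSC and the longer LSC. The partition is reported in
#' canonical coordinates (LSC starting at base 1, region order
#' LSC, IRb, SSC, IRa); `rotation_offset` and `strand_flipped` record the
#' transform from the input sequence to canonical form.
#'
#' @param genome a [circular_genome()].
#' @param min_ir_len minimum IR length in bp (default 1000, at least 100).
#' @param max_mismatch only 0 (exact repeats) is supported; plastome IR
#'   copies are near-identical and exactness keeps detection deterministic.
#' @param k seed length for the k-mer scan.
#' @return an object of class `QuadripartitePartition` with fields
#'   `lsc_len`, `irb_len`, `ssc_len`, `ira_len`, the junction coordinates
#'   `jlb`, `jsb`, `jsa`, `jla` (1-based; JLB/JSB/JSA are the first base of
#'   the downstream region, JLA the last base of IRa), `rotation_offset`
#'   and `strand_flipped`.
#' @export
detect_quadripartite <- function(genome, min_ir_len = 1000L,
                                 max_mismatch = 0L, k = 31L) {
  stopifnot(inherits(genome, "CircularGenome"))
  if (min_ir_len < 100L) stop("min_ir_len must be at least 100")
  if (max_mismatch != 0L) {
    stop("only exact inverted repeats (max_mismatch = 0) are supported")
  }
  L <- genome$length
  cand <- inverted_repeat_matches(genome$seq, min_ir_len, k = k)
  if (is.null(cand) || nrow(cand) == 0L) {
    stop("no quadripartite structure: no inverted repeat of length >= ",
         min_ir_len, " in genome '", genome$id, "'")
  }
  disjoint <- vapply(seq_len(nrow(cand)), function(i) {
    cand$start1[i] != cand$start2[i] &&
      circ_intervals_disjoint(cand$start1[i], cand$start2[i], cand$len[i], L)
  }, TRUE)
  if (!any(disjoint)) {
    stop("structural error: best inverted repeat pair overlaps itself in ",
         "genome '", genome$id, "'")
  }
  cand <- cand[disjoint, , drop = FALSE]
  best <- cand[cand$len == max(cand$len), , drop = FALSE]
  parts <- lapply(seq_len(nrow(best)), function(i) {
    .build_partition(genome, best$start1[i], best$start2[i], best$len[i])
  })
  ord <- order(vapply(parts, function(p) p$jlb, 0L),
               vapply(parts, function(p) p$rotation_offset, 0L))
  parts[[ord[1]]]
}

.build_partition <- function(genome, s1, s2, m, k = 31L) {
  L <- genome$length
  e1 <- circ_pos(s1 + m - 1L, L)
  e2 <- circ_pos(s2 + m - 1L, L)
  # arcs between the two copies
  arc_a <- c(start = circ_pos(e1 + 1L, L), end = circ_pos(s2 - 1L, L))
  arc_b <- c(start = circ_pos(e2 + 1L, L), end = circ_pos(s1 - 1L, L))
  len_a <- circ_len(arc_a["start"], arc_a["end"], L)
  len_b <- circ_len(arc_b["start"], arc_b["end"], L)
  if (len_a + len_b + 2L * m != L) {
    stop("structural error: repeat pair does not partition the circle")
  }
  if (len_a >= len_b) {
    lsc <- arc_a; lsc_len <- len_a; ssc_len <- len_b
  } else {
    lsc <- arc_b; lsc_len <- len_b; ssc_len <- len_a
  }
  lsc_start <- as.integer(lsc["start"])
  lsc_end <- as.integer(lsc["end"])
  canon_fwd <- rotate_seq(genome$seq, lsc_start)
  canon_rc <- rotate_seq(revcomp(genome$seq), L - lsc_end + 1L)
  flipped <- canon_rc < canon_fwd
  offset <- if (flipped) L - lsc_end else lsc_start - 1L
  structure(list(
    genome_id = genome$id,
    genome_length = L,
    lsc_len = as.integer(lsc_len),
    irb_len = as.integer(m),
    ssc_len = as.integer(ssc_len),
    ira_len = as.integer(m),
    jlb = as.integer(lsc_len + 1L),
    jsb = as.integer(lsc_len + m + 1L),
    jsa = as.integer(lsc_len + m + ssc_len + 1L),
    jla = as.integer(L),
    rotation_offset = as.integer(offset),
    strand_flipped = flipped
  ), class = "QuadripartitePartition")
}

#' @export
print.QuadripartitePartition <- function(x, ...) {
  cat(sprintf(
    "<QuadripartitePartition> %s: LSC %d | IRb %d | SSC %d | IRa %d bp\n",
    x$genome_id, x$lsc_len, x$irb_len, x$ssc_len, x$ira_len))
  cat(sprintf("  JLB %d  JSB %d  JSA %d  JLA %d  (offset %d%s)\n",
              x$jlb, x$jsb, x$jsa, x$jla, x$rotation_offset,
              if (x$strand_flipped) ", strand flipped" else ""))
  invisible(x)
}

#' Region spans of a canonical partition
#'
#' @param partition a `QuadripartitePartition`.
#' @return data.frame with columns `region` (LSC/IRb/SSC/IRa), `start`,
#'   `end` in canonical coordinates.
#' @export
partition_regions <- function(partition) {
  data.frame(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(1L, partition$jlb, partition$jsb, partition$jsa),
    end = c(partition$jlb - 1L, partition$jsb - 1L, partition$jsa - 1L,
            partition$jla),
    stringsAsFactors = FALSE)
}

#' Structural region containing each position of a canonical genome
#' @keywords internal
region_of_position <- function(pos, partition) {
  reg <- partition_regions(partition)
  out <- character(length(pos))
  for (i in seq_len(nrow(reg))) {
    sel <- pos >= reg$start[i] & pos <= reg$end[i]
    out[sel] <- reg$region[i]
  }
  out
}

#' Rotate (and possibly strand-flip) a genome to canonical quadripartite form
#'
#' The canonical form starts the LSC at base 1 with region order
#' LSC, IRb, SSC, IRa along ascending coordinates. Between the two strands
#' (both of which satisfy that layout) the lexicographically smaller rotated
#' sequence is chosen, which makes canonicalization idempotent and
#' rotation/strand invariant.
#'
#' @param genome a [circular_genome()].
#' @param partition the partition from [detect_quadripartite()] on the same
#'   genome.
#' @return list with elements `genome` (canonical) and `partition` (same
#'   region lengths, `rotation_offset` 0, `strand_flipped` `FALSE`).
#' @export
canonical_rotation <- function(genome, partition) {
  stopifnot(inherits(partition, "QuadripartitePartition"),
            genome$length == partition$genome_length)
  seq <- genome$seq
  if (partition$strand_flipped) seq <- revcomp(seq)
  seq <- rotate_seq(seq, partition$rotation_offset + 1L)
  out_g <- circular_genome(genome$id, seq, circular = genome$circular)
  out_p <- partition
  out_p$rotation_offset <- 0L
  out_p$strand_flipped <- FALSE
  list(genome = out_g, partition = out_p)
}

#' Flanking-gene context of the four region junctions
#'
#' For each junction (taken as the boundary edge immediately before its
#' coordinate; for JLA, the origin edge) the nearest gene-level feature on
#' each side is reported: distance in bp from the feature to the edge (0
#' when the feature covers the adjacent base) and, when the feature covers
#' the edge, how many of its bp lie on the reported side.
#'
#' @param partition canonical `QuadripartitePartition`.
#' @param features `FeatureTable` on the canonical genome.
#' @return data.frame with one row per junction and side.
#' @export
junction_context <- function(partition, features) {
  L <- partition$genome_length
  g <- features$features[features$features$kind %in% GENE_KINDS, ,
                         drop = FALSE]
  juncs <- c(JLB = partition$jlb, JSB = partition$jsb,
             JSA = partition$jsa, JLA = 1L)
  rows <- list()
  for (jn in names(juncs)) {
    J <- juncs[[jn]]
    for (side in c("upstream", "downstream")) {
      adj <- if (side == "upstream") circ_pos(J - 1L, L) else J
      if (nrow(g) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          junction = jn, side = side, feature = "none",
          distance = NA_integer_, overlap = NA_integer_,
          stringsAsFactors = FALSE)
        next
      }
      covering <- which(g$start <= adj & g$end >= adj)
      if (length(covering) > 0L) {
        i <- covering[1]
        # bp of the feature lying on this side of the junction edge
        ov <- if (side == "upstream") adj - g$start[i] + 1L
              else g$end[i] - adj + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          junction = jn, side = side, feature = g$name[i],
          distance = 0L, overlap = as.integer(max(ov, 0L)),
          stringsAsFactors = FALSE)
      } else {
        if (side == "upstream") {
          d <- (adj - g$end) %% L
          i <- which.min(d)
        } else {
          d <- (g$start - adj) %% L
          i <- which.min(d)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          junction = jn, side = side, feature = g$name[i],
          distance = as.integer(d[i]), overlap = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
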