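# Perfect microsatellite (SSR) detection and classification.
#
# A locus is a maximal perfect tandem run of a primitive 1-6 bp motif whose
# copy number meets the per-unit-length threshold. Detection works on a
# circular match vector cmp_u[i] = (seq[i] == seq[i+u]) so the maximal runs
# of TRUE are exactly the maximal tandem spans; the smallest-primitive-unit
# rule falls out of rejecting non-primitive motifs (a poly-A run never
# resurfaces as an "AA" dinucleotide locus).

#' Default minimum copy numbers per motif length (mono- to hexanucleotide)
#' @export
DEFAULT_SSR_THRESHOLDS <- c(8L, 4L, 4L, 3L, 3L, 3L)

#' Is a motif primitive (not a repetition of a shorter unit)?
#' @keywords internal
is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  for (p in seq_len(u %/% 2L)) {
    if (u %% p == 0L &&
        motif == paste(rep(substr(motif, 1L, p), u %/% p), collapse = "")) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical representative of an SSR motif
#'
#' Cyclic rotations of a motif and of its reverse complement describe the
#' same repeat; the canonical motif is the lexicographically smallest
#' member of that equivalence class (e.g. "TA" -> "AT", "GAA" -> "AAG").
#'
#' @param motif repeat unit of length 1-6 over A/C/G/T.
#' @return the canonical motif.
#' @export
canonical_motif <- function(motif) {
  if (length(motif) != 1L || !nzchar(motif)) stop("domain error: empty motif")
  motif <- toupper(motif)
  u <- nchar(motif)
  if (u > 6L) stop("motif longer than 6 bp")
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over A/C/G/T")
  if (!is_primitive_motif(motif)) {
    stop("validation error: non-primitive motif '", motif, "'")
  }
  rots <- function(m) {
    vapply(seq_len(nchar(m)), function(i) {
      paste0(substr(m, i, nchar(m)), substr(m, 1L, i - 1L))
    }, "")
  }
  min(c(rots(motif), rots(revcomp(motif))))
}

#' Scan a genome for perfect microsatellites
#'
#' Finds every maximal perfect tandem repeat of a primitive 1-6 bp motif
#' meeting the copy-number threshold for its unit length. Each genomic run
#' is reported once, under its smallest primitive unit. The reported locus
#' starts at the leftmost base of the maximal run and covers `copies`
#' complete units (a trailing partial unit does not extend the locus).
#' Loci crossing the circular origin are detected; `end < start` marks a
#' wrapping locus.
#'
#' @param genome a [circular_genome()] (or plain nucleotide string, then
#'   treated as circular).
#' @param thresholds integer vector of length 6: minimum copies for unit
#'   lengths 1-6. Defaults to [DEFAULT_SSR_THRESHOLDS].
#' @return data.frame with columns `genome_id`, `motif`, `canonical_motif`,
#'   `unit_len`, `copies`, `start`, `end`, `length`, sorted by `start`.
#' @export
find_ssrs <- function(genome, thresholds = DEFAULT_SSR_THRESHOLDS) {
  if (inherits(genome, "CircularGenome")) {
    seq <- genome$seq; gid <- genome$id
  } else {
    seq <- toupper(genome); gid <- NA_character_
  }
  stopifnot(length(thresholds) == 6L, all(thresholds >= 2L))
  L <- nchar(seq)
  empty <- data.frame(genome_id = character(), motif = character(),
                      canonical_motif = character(), unit_len = integer(),
                      copies = integer(), start = integer(), end = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  if (L < 8L) return(empty)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  loci <- list()
  for (u in 1:6) {
    thr <- thresholds[u]
    if (u * thr > L) next
    nxt <- x[circ_pos(seq_len(L) + u, L)]
    cmp <- x == nxt & x %in% c("A", "C", "G", "T")
    if (all(cmp)) {
      # fully periodic circle: one locus covering the whole genome
      motif <- substr(seq, 1L, u)
      if (is_primitive_motif(motif) && L %/% u >= thr) {
        copies <- L %/% u
        loci[[length(loci) + 1L]] <- data.frame(
          genome_id = gid, motif = motif,
          canonical_motif = canonical_motif(motif), unit_len = u,
          copies = copies, start = 1L,
          end = as.integer(copies * u), length = as.integer(copies * u),
          stringsAsFactors = FALSE)
      }
      next
    }
    # rotate the circular match vector to open it at a FALSE position
    anchor <- which(!cmp)[1]
    rot_idx <- circ_pos(anchor + seq_len(L) - 1L, L)
    r <- rle(cmp[rot_idx])
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    good <- which(r$values)
    for (gidx in good) {
      span <- r$lengths[gidx] + u          # tandem span in bp
      copies <- span %/% u
      if (copies < thr) next
      s <- circ_pos(anchor + run_start[gidx] - 1L, L)
      motif <- circ_substr(seq, s, circ_pos(s + u - 1L, L))
      if (!grepl("^[ACGT]+$", motif) || !is_primitive_motif(motif)) next
      len <- copies * u
      if (len > L) next
      e <- circ_pos(s + len - 1L, L)
      loci[[length(loci) + 1L]] <- data.frame(
        genome_id = gid, motif = motif,
        canonical_motif = canonical_motif(motif), unit_len = u,
        copies = as.integer(copies), start = as.integer(s),
        end = as.integer(e), length = as.integer(len),
        stringsAsFactors = FALSE)
    }
  }
  if (length(loci) == 0L) return(empty)
  out <- do.call(rbind, loci)
  out[order(out$start, out$unit_len), , drop = FALSE]
}

#' Assign structural and functional regions to SSR loci
#'
#' The structural region (LSC/IRb/SSC/IRa) is the partition span containing
#' the locus midpoint; the functional region is `gene` if the midpoint lies
#' in an exon (or a gene without annotated exons), `intron` if in a derived
#' intron, else `intergenic`. Precedence gene > intron > intergenic.
#'
#' @param loci data.frame from [find_ssrs()] on the canonical genome.
#' @param partition canonical `QuadripartitePartition`.
#' @param features `FeatureTable` on the canonical genome.
#' @return `loci` with `structural_region`, `functional_region` and
#'   `midpoint` columns added.
#' @export
classify_ssrs <- function(loci, partition, features) {
  L <- partition$genome_length
  if (nrow(loci) > 0L && any(loci$start < 1L | loci$start > L)) {
    stop("internal error: SSR locus outside genome bounds")
  }
  mid <- circ_mid(loci$start, loci$length, L)
  loci$midpoint <- mid
  loci$structural_region <- region_of_position(mid, partition)
  f <- features$features
  has_exons <- unique(f$feature_id[f$kind == "exon"])
  # gene bodies without exon rows count as exonic over their whole extent
  exonic <- rbind(f[f$kind == "exon", c("start", "end")],
                  f[f$kind %in% GENE_KINDS &
                      !f$feature_id %in% has_exons, c("start", "end")])
  intronic <- f[f$kind == "intron", c("start", "end")]
  in_any <- function(pos, iv) {
    if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
    vapply(pos, function(p) any(iv$start <= p & iv$end >= p), TRUE)
  }
  fr <- rep("intergenic", nrow(loci))
  fr[in_any(mid, intronic)] <- "intron"
  fr[in_any(mid, exonic)] <- "gene"
  loci$functional_region <- fr
  loci
}

#' Summarize classified SSR loci across genomes
#'
#' @param loci classified loci (possibly several genomes, row-bound).
#' @param partitions named list of canonical partitions keyed by genome id
#'   (used for region lengths in the density table).
#' @return list with components `by_unit` (per-genome counts by unit
#'   length), `by_region` (per-genome counts and percentages by structural
#'   and functional region, shaped like a per-region count table) and
#'   `density` (pooled SSRs per kb by structural region, 2 decimals).
#' @export
ssr_summary <- function(loci, partitions) {
  gids <- unique(loci$genome_id)
  unit_names <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  by_unit <- do.call(rbind, lapply(gids, function(g) {
    sub <- loci[loci$genome_id == g, ]
    counts <- vapply(1:6, function(u) sum(sub$unit_len == u), 0L)
    data.frame(genome_id = g, unit = unit_names, unit_len = 1:6,
               count = counts, stringsAsFactors = FALSE)
  }))
  regions <- c("Intergenic" = "intergenic", "Gene" = "gene",
               "Intron" = "intron")
  sregions <- c("LSC", "SSC", "IRa", "IRb")
  by_region <- do.call(rbind, lapply(gids, function(g) {
    sub <- loci[loci$genome_id == g, ]
    tot <- nrow(sub)
    fcounts <- vapply(regions, function(r) sum(sub$functional_region == r), 0L)
    scounts <- vapply(sregions, function(r) sum(sub$structural_region == r), 0L)
    data.frame(genome_id = g,
               region = c(names(regions), sregions, "Total"),
               count = c(fcounts, scounts, tot),
               percent = round(100 * c(fcounts, scounts, tot) / tot, 2),
               stringsAsFactors = FALSE)
  }))
  # pooled density per structural region
  reg_len <- sapply(c("LSC", "SSC", "IR"), function(r) {
    sum(vapply(gids, function(g) {
      p <- partitions[[g]]
      switch(r, LSC = p$lsc_len, SSC = p$ssc_len,
             IR = p$irb_len + p$ira_len)
    }, 0L))
  })
  reg_count <- c(
    LSC = sum(loci$structural_region == "LSC"),
    SSC = sum(loci$structural_region == "SSC"),
    IR = sum(loci$structural_region %in% c("IRa", "IRb")))
  density <- data.frame(
    region = names(reg_len),
    total_length = as.integer(reg_len),
    n_ssr = as.integer(reg_count[names(reg_len)]),
    per_kb = round(1000 * reg_count[names(reg_len)] / reg_len, 2),
    stringsAsFactors = FALSE)
  rownames(density) <- NULL
  list(by_unit = by_unit, by_region = by_region, density = density)
}
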