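# Synthetic plastome generator. Builds circular quadripartite genomes
# (LSC + IRb + SSC + revcomp(IRb)) with planted genes, introns, intergenic
# spacers and SSR loci at recorded coordinates, and evolves descendant
# genomes under a known substitution + indel event log with an exactly
# bookkept truth alignment. Everything is deterministic under the seed.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.sample_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.sample_cds <- function(cds_len) {
  stopifnot(cds_len %% 3L == 0L, cds_len >= 9L)
  n_mid <- cds_len %/% 3L - 2L
  codons <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(codons, codons, paste0), codons,
                                paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  paste0("ATG", paste(sample(sense, n_mid, replace = TRUE), collapse = ""),
         "TAA")
}

#' Default planted gene models for a synthetic plastome
#'
#' A small plastome-like complement: LSC photosynthesis/housekeeping genes
#' (one with two introns, mirroring clpP), a pseudogene, one SSC tRNA, and
#' IR genes (duplicated automatically into IRa), scaled to the region
#' lengths of `spec`.
#' @keywords internal
default_gene_models <- function(lsc_len, ir_len, ssc_len) {
  g <- function(name, region, at, cds_len, strand = "+", introns = "",
                pseudo = FALSE, kind = "gene") {
    data.frame(name = name, region = region, offset = at,
               cds_len = cds_len, strand = strand, introns = introns,
               pseudo = pseudo, kind = kind, stringsAsFactors = FALSE)
  }
  rbind(
    g("psbA", "LSC", round(lsc_len * 0.02), 1062, "-"),
    g("matK", "LSC", round(lsc_len * 0.10), 1530, "-"),
    g("atpA", "LSC", round(lsc_len * 0.25), 1524, "-"),
    g("rbcL", "LSC", round(lsc_len * 0.40), 1428, "+"),
    g("clpP", "LSC", round(lsc_len * 0.55), 591, "-", introns = "120,90"),
    g("ndhK", "LSC", round(lsc_len * 0.70), 678, "-", pseudo = TRUE),
    g("rpl22", "LSC", max(1L, lsc_len - 420L), 363, "+"),
    g("trnL", "SSC", max(1L, round(ssc_len * 0.3)), 81, "+", kind = "tRNA"),
    g("rpl2", "IRb", round(ir_len * 0.05), 822, "-", introns = "150"),
    g("rrn16", "IRb", round(ir_len * 0.45), 900, "+", kind = "rRNA"),
    g("ndhB", "IRb", round(ir_len * 0.75), 1530, "-", pseudo = TRUE))
}

#' Default planted SSR set for a synthetic plastome
#' @keywords internal
default_ssr_models <- function(lsc_len, ir_len, ssc_len) {
  s <- function(motif, copies, region, at) {
    data.frame(motif = motif, copies = copies, region = region,
               offset = at, stringsAsFactors = FALSE)
  }
  rbind(
    s("A", 10L, "LSC", round(lsc_len * 0.07)),
    s("T", 8L, "LSC", round(lsc_len * 0.18)),
    s("AT", 5L, "LSC", round(lsc_len * 0.33)),
    s("AAG", 4L, "LSC", round(lsc_len * 0.48)),
    s("AATT", 3L, "LSC", round(lsc_len * 0.62)),
    s("AATAG", 3L, "LSC", round(lsc_len * 0.80)),
    s("T", 9L, "SSC", max(1L, round(ssc_len * 0.7))),
    s("A", 8L, "IRb", round(ir_len * 0.25)),
    s("AG", 4L, "IRb", round(ir_len * 0.60)))
}

#' Specification of a synthetic plastome
#'
#' Defaults emulate the structure reported for slipper-orchid plastomes:
#' an LSC of ~86 kb, expanded IRs of ~34 kb, a very short SSC of ~1.8 kb,
#' and region GC fractions of 0.335/0.239/0.395 (LSC/SSC/IR).
#'
#' @param lsc_len,ir_len,ssc_len region lengths in bp (`lsc_len` must
#'   exceed `ssc_len`).
#' @param gc named numeric vector of GC fractions for LSC, SSC, IR.
#' @param genes data.frame of gene models (`name`, `region` in
#'   LSC/SSC/IRb, `offset` within the region, `cds_len`, `strand`,
#'   `introns` comma-separated lengths, `pseudo`, `kind`), or `NULL` for
#'   the default complement; `FALSE` for none.
#' @param ssrs data.frame of planted SSRs (`motif`, `copies`, `region`,
#'   `offset`), `NULL` for defaults, `FALSE` for none.
#' @param seed integer random seed.
#' @return a `PlastomeSpec` list.
#' @export
plastome_spec <- function(lsc_len = 86459L, ir_len = 34101L,
                          ssc_len = 1834L,
                          gc = c(LSC = 0.335, SSC = 0.239, IR = 0.395),
                          genes = NULL, ssrs = NULL, seed = 1L) {
  stopifnot(lsc_len > ssc_len, ir_len >= 100L, ssc_len >= 100L)
  if (is.null(genes)) genes <- default_gene_models(lsc_len, ir_len, ssc_len)
  if (isFALSE(genes)) genes <- NULL
  if (is.null(ssrs)) ssrs <- default_ssr_models(lsc_len, ir_len, ssc_len)
  if (isFALSE(ssrs)) ssrs <- NULL
  structure(list(lsc_len = as.integer(lsc_len), ir_len = as.integer(ir_len),
                 ssc_len = as.integer(ssc_len), gc = gc, genes = genes,
                 ssrs = ssrs, seed = as.integer(seed)),
            class = "PlastomeSpec")
}

.region_abs <- function(spec, region, offset) {
  base <- switch(region, LSC = 0L, IRb = spec$lsc_len,
                 SSC = spec$lsc_len + spec$ir_len,
                 stop("plantable regions are LSC, IRb, SSC"))
  base + as.integer(offset)
}

.region_bounds <- function(spec, region) {
  switch(region,
         LSC = c(1L, spec$lsc_len),
         IRb = c(spec$lsc_len + 1L, spec$lsc_len + spec$ir_len),
         SSC = c(spec$lsc_len + spec$ir_len + 1L,
                 spec$lsc_len + spec$ir_len + spec$ssc_len))
}

#' Generate a synthetic quadripartite plastome with ground truth
#'
#' @param spec a [plastome_spec()].
#' @return list with `genome` (a [circular_genome()]), `features` (a
#'   `FeatureTable` including the IRa mirror copies of IRb genes),
#'   `ssrs` (data.frame of planted loci with absolute coordinates,
#'   including IRa mirrors), and `spec`.
#' @export
generate_plastome <- function(spec) {
  stopifnot(inherits(spec, "PlastomeSpec"))
  set.seed(spec$seed)
  pre_len <- spec$lsc_len + spec$ir_len + spec$ssc_len
  L <- pre_len + spec$ir_len
  gc_of <- function(region) {
    unname(spec$gc[[if (region == "IRb") "IR" else region]])
  }
  x <- character(pre_len)
  for (r in c("LSC", "IRb", "SSC")) {
    b <- .region_bounds(spec, r)
    x[b[1]:b[2]] <- .sample_bases(b[2] - b[1] + 1L, gc_of(r))
  }

  margin <- 25L
  occupied <- data.frame(start = integer(), end = integer())
  claim <- function(s, e, what) {
    b_ok <- s >= 1L && e <= pre_len
    clash <- any(occupied$start <= e + margin & occupied$end >= s - margin)
    if (!b_ok || clash) {
      stop("spec error: planted element '", what,
           "' does not fit without overlap")
    }
    occupied <<- rbind(occupied, data.frame(start = s, end = e))
  }

  feats <- empty_features_df()
  gene_idx <- 0L
  if (!is.null(spec$genes)) {
    for (gi in seq_len(nrow(spec$genes))) {
      gm <- spec$genes[gi, ]
      b <- .region_bounds(spec, gm$region)
      s_abs <- .region_abs(spec, gm$region, gm$offset)
      introns <- if (nzchar(gm$introns)) {
        as.integer(strsplit(gm$introns, ",", fixed = TRUE)[[1]])
      } else integer()
      body <- if (gm$kind == "gene") .sample_cds(gm$cds_len) else {
        paste(.sample_bases(gm$cds_len, gc_of(gm$region)), collapse = "")
      }
      n_ex <- length(introns) + 1L
      ex_len <- rep(nchar(body) %/% n_ex, n_ex)
      ex_len[n_ex] <- nchar(body) - sum(ex_len[-n_ex])
      # construct = e1 i1 e2 i2 ... in transcript order
      pieces <- list()
      off <- 0L
      for (k in seq_len(n_ex)) {
        pieces[[length(pieces) + 1L]] <-
          list(type = "exon", seq = substr(body, off + 1L, off + ex_len[k]))
        off <- off + ex_len[k]
        if (k <= length(introns)) {
          pieces[[length(pieces) + 1L]] <- list(
            type = "intron",
            seq = paste(.sample_bases(introns[k], gc_of(gm$region)),
                        collapse = ""))
        }
      }
      construct <- paste(vapply(pieces, `[[`, "", "seq"), collapse = "")
      span <- nchar(construct)
      e_abs <- s_abs + span - 1L
      if (s_abs < b[1] + margin || e_abs > b[2] - margin) {
        stop("spec error: gene '", gm$name, "' too close to a region edge")
      }
      claim(s_abs, e_abs, gm$name)
      genomic <- if (gm$strand == "-") revcomp(construct) else construct
      x[s_abs:e_abs] <- strsplit(genomic, "", fixed = TRUE)[[1]]
      # exon intervals in genomic coordinates
      piece_len <- vapply(pieces, function(p) nchar(p$seq), 0L)
      piece_end <- cumsum(piece_len)
      piece_start <- piece_end - piece_len + 1L
      gene_idx <- gene_idx + 1L
      fid <- paste0("g", gene_idx)
      rows <- data.frame(feature_id = fid, name = gm$name, kind = gm$kind,
                         strand = gm$strand, start = s_abs, end = e_abs,
                         part = 1L, pseudo = gm$pseudo,
                         stringsAsFactors = FALSE)
      if (n_ex > 1L) {
        for (k in seq_along(pieces)) {
          if (pieces[[k]]$type != "exon") next
          a <- piece_start[k]; bb <- piece_end[k]
          if (gm$strand == "-") {
            ge_s <- s_abs + (span - bb); ge_e <- s_abs + (span - a)
          } else {
            ge_s <- s_abs + a - 1L; ge_e <- s_abs + bb - 1L
          }
          rows <- rbind(rows, data.frame(
            feature_id = fid, name = gm$name, kind = "exon",
            strand = gm$strand, start = ge_s, end = ge_e, part = k,
            pseudo = gm$pseudo, stringsAsFactors = FALSE))
        }
      }
      feats <- rbind(feats, rows)
    }
  }

  planted <- data.frame(motif = character(), copies = integer(),
                        start = integer(), end = integer(),
                        region = character(), stringsAsFactors = FALSE)
  if (!is.null(spec$ssrs)) {
    for (si in seq_len(nrow(spec$ssrs))) {
      sm <- spec$ssrs[si, ]
      motif <- toupper(sm$motif)
      u <- nchar(motif)
      len <- u * sm$copies
      s_abs <- .region_abs(spec, sm$region, sm$offset)
      e_abs <- s_abs + len - 1L
      b <- .region_bounds(spec, sm$region)
      if (s_abs < b[1] + margin || e_abs > b[2] - margin) {
        stop("spec error: SSR '", motif, "' too close to a region edge")
      }
      claim(s_abs, e_abs, paste0("SSR ", motif))
      x[s_abs:e_abs] <- rep(strsplit(motif, "", fixed = TRUE)[[1]],
                            sm$copies)
      # break single-character extension on both flanks
      bases <- c("A", "C", "G", "T")
      x[s_abs - 1L] <- sample(setdiff(bases, x[s_abs + u - 1L]), 1L)
      x[e_abs + 1L] <- sample(setdiff(bases, x[e_abs + 1L - u]), 1L)
      planted <- rbind(planted, data.frame(
        motif = motif, copies = as.integer(sm$copies), start = s_abs,
        end = e_abs, region = sm$region, stringsAsFactors = FALSE))
    }
  }

  # keep the planted IR pair maximal: the base before IRb must not pair
  # with the base after IRa (= LSC[1]) and symmetrically for the SSC flank
  bases <- c("A", "C", "G", "T")
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  if (x[spec$lsc_len] == comp1(x[1L])) {
    x[spec$lsc_len] <- sample(setdiff(bases, comp1(x[1L])), 1L)
  }
  if (x[pre_len] == comp1(x[spec$lsc_len + spec$ir_len + 1L])) {
    x[pre_len] <- sample(setdiff(bases, comp1(x[spec$lsc_len +
                                                  spec$ir_len + 1L])), 1L)
  }

  assemble <- function(x) {
    irb <- paste(x[(spec$lsc_len + 1L):(spec$lsc_len + spec$ir_len)],
                 collapse = "")
    paste0(paste(x, collapse = ""), revcomp(irb))
  }

  # mirror map between IRb and IRa positions
  B2 <- spec$lsc_len + spec$ir_len
  mirror_pos <- function(p) pre_len + B2 - p + 1L
  in_irb <- function(p) p > spec$lsc_len & p <= B2

  # genomic positions of each planted CDS in transcript (codon) order, so
  # repairs inside coding exons can avoid creating stop codons
  cds_maps <- list()
  for (fid in unique(feats$feature_id[feats$kind == "gene"])) {
    grow <- feats[feats$feature_id == fid & feats$kind == "gene", ][1, ]
    ex <- feats[feats$feature_id == fid & feats$kind == "exon", ,
                drop = FALSE]
    if (nrow(ex) == 0L) ex <- grow
    if (grow$strand == "+") {
      ex <- ex[order(ex$start), , drop = FALSE]
      posv <- unlist(lapply(seq_len(nrow(ex)),
                            function(k) ex$start[k]:ex$end[k]))
    } else {
      ex <- ex[order(-ex$start), , drop = FALSE]
      posv <- unlist(lapply(seq_len(nrow(ex)),
                            function(k) ex$end[k]:ex$start[k]))
    }
    cds_maps[[fid]] <- list(pos = posv, strand = grow$strand)
  }
  makes_stop <- function(x, pos, b) {
    for (m in cds_maps) {
      idx <- match(pos, m$pos)
      if (is.na(idx)) next
      ci <- (idx - 1L) %/% 3L
      cpos <- m$pos[(ci * 3L + 1L):(ci * 3L + 3L)]
      cod <- x[cpos]
      cod[cpos == pos] <- b
      if (m$strand == "-") cod <- comp1(cod)
      if (paste(cod, collapse = "") %in% STOP_CODONS) return(TRUE)
    }
    FALSE
  }
  safe_repair <- function(x, pos) {
    cur <- x[pos]
    cand <- setdiff(bases, c(cur,
                             if (pos - 6L >= 1L) x[pos - (1:6)],
                             if (pos + 6L <= pre_len) x[pos + (1:6)]))
    if (length(cand) == 0L) cand <- setdiff(bases, cur)
    for (b in sample(cand)) {
      if (!makes_stop(x, pos, b)) { x[pos] <- b; return(x) }
    }
    for (b in sample(setdiff(bases, c(cur, cand)))) {
      if (!makes_stop(x, pos, b)) { x[pos] <- b; return(x) }
    }
    x[pos] <- sample(setdiff(bases, cur), 1L)
    x
  }

  planted_keys <- paste(planted$start, planted$end)
  mirrored_keys <- paste(mirror_pos(planted$end), mirror_pos(planted$start))
  for (iter in 1:60) {
    g_try <- circular_genome("tmp", assemble(x))
    found <- find_ssrs(g_try)
    keys <- paste(found$start, found$end)
    stray <- found[!keys %in% c(planted_keys, mirrored_keys), ,
                   drop = FALSE]
    if (nrow(stray) == 0L) break
    for (r in seq_len(nrow(stray))) {
      mid <- circ_mid(stray$start[r], stray$length[r], L)
      if (mid > pre_len) mid <- mirror_pos(mid)   # repair IRa via IRb
      if (mid < 1L || mid > pre_len) mid <- stray$start[r]
      x <- safe_repair(x, mid)
    }
    if (iter == 60L) stop("could not clear accidental SSRs from background")
  }

  seq_full <- assemble(x)
  genome <- circular_genome(paste0("synth", spec$seed), seq_full)

  # mirror IRb features into IRa
  irb_feats <- feats[feats$start > spec$lsc_len & feats$end <= B2, ,
                     drop = FALSE]
  if (nrow(irb_feats) > 0L) {
    mir <- irb_feats
    mir$feature_id <- paste0(mir$feature_id, "_ira")
    s_new <- mirror_pos(irb_feats$end)
    e_new <- mirror_pos(irb_feats$start)
    mir$start <- s_new; mir$end <- e_new
    mir$strand <- ifelse(irb_feats$strand == "+", "-", "+")
    feats <- rbind(feats, mir)
  }
  ft <- feature_table(genome, feats)

  if (nrow(planted) > 0L) {
    irb_ssr <- planted[planted$region == "IRb", , drop = FALSE]
    if (nrow(irb_ssr) > 0L) {
      mir <- irb_ssr
      mir$motif <- vapply(irb_ssr$motif, revcomp, "")
      mir$start <- mirror_pos(irb_ssr$end)
      mir$end <- mirror_pos(irb_ssr$start)
      mir$region <- "IRa"
      planted <- rbind(planted, mir)
    }
    planted <- planted[order(planted$start), , drop = FALSE]
    rownames(planted) <- NULL
  }

  list(genome = genome, features = ft, ssrs = planted, spec = spec)
}

#' Specification of a star-phylogeny evolution run
#'
#' @param sub_prob per-site substitution probability.
#' @param indel_rate per-site indel event probability.
#' @param indel_mean_len mean of the geometric indel length distribution.
#' @param hotspots optional data.frame (`start`, `end`, `multiplier`)
#'   multiplying the substitution probability inside given ancestor spans.
#' @param ir_homogenize mirror every IR event into the other copy and keep
#'   indels out of the IRs (default `TRUE`; requires a partition).
#' @param seed integer random seed.
#' @return an `EvolutionSpec` list.
#' @export
evolution_spec <- function(sub_prob = 0.01, indel_rate = 0,
                           indel_mean_len = 4, hotspots = NULL,
                           ir_homogenize = TRUE, seed = 1L) {
  stopifnot(sub_prob >= 0, sub_prob <= 1, indel_rate >= 0, indel_rate <= 1)
  structure(list(sub_prob = sub_prob, indel_rate = indel_rate,
                 indel_mean_len = indel_mean_len, hotspots = hotspots,
                 ir_homogenize = isTRUE(ir_homogenize),
                 seed = as.integer(seed)),
            class = "EvolutionSpec")
}

#' Evolve independent descendants from an ancestor with a truth alignment
#'
#' Each descendant receives independent substitutions (per-site Bernoulli,
#' uniform among the three alternative bases) and indel events (geometric
#' lengths; insertions draw uniform bases). With IR homogenization on, a
#' substitution in IRb is mirrored as the complementary change at the
#' image position in IRa and indel positions are restricted to the
#' single-copy regions, so descendant IR copies stay exact reverse
#' complements. The truth alignment is built by event bookkeeping: one
#' column per ancestor base plus one block of columns per insertion event.
#'
#' @param ancestor a [circular_genome()].
#' @param evo_spec an [evolution_spec()].
#' @param n_descendants number of independent descendants.
#' @param partition optional canonical `QuadripartitePartition` of the
#'   ancestor (required when `ir_homogenize` is `TRUE`).
#' @return list with `descendants` (list of [circular_genome()]),
#'   `events` (data.frame log), `alignment` (truth `AlignedMatrix`
#'   including the ancestor row).
#' @export
evolve <- function(ancestor, evo_spec, n_descendants, partition = NULL) {
  stopifnot(inherits(ancestor, "CircularGenome"),
            inherits(evo_spec, "EvolutionSpec"), n_descendants >= 1L)
  set.seed(evo_spec$seed)
  L <- ancestor$length
  anc <- strsplit(ancestor$seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

  homog <- evo_spec$ir_homogenize && !is.null(partition)
  if (evo_spec$ir_homogenize && is.null(partition)) {
    warning("no partition supplied: IR homogenization disabled")
  }
  if (homog) {
    irb <- c(partition$jlb, partition$jsb - 1L)
    ira <- c(partition$jsa, partition$jla)
    mirror_pos <- function(p) ira[2] - (p - irb[1])
    sub_eligible <- seq_len(L)[-(ira[1]:ira[2])]   # IRa follows IRb
    indel_eligible <- seq_len(L)[-c(irb[1]:irb[2], ira[1]:ira[2])]
  } else {
    sub_eligible <- seq_len(L)
    indel_eligible <- seq_len(L)
  }

  p_site <- rep(evo_spec$sub_prob, L)
  if (!is.null(evo_spec$hotspots)) {
    for (h in seq_len(nrow(evo_spec$hotspots))) {
      span <- evo_spec$hotspots$start[h]:evo_spec$hotspots$end[h]
      p_site[span] <- pmin(1, p_site[span] * evo_spec$hotspots$multiplier[h])
    }
  }
  if (mean(p_site) > 0.5) {
    warning("substitution probability above 0.5: most sites will mutate")
  }

  events <- list()
  log_event <- function(desc, type, pos, length, from, to, seq,
                        mirrored) {
    events[[length(events) + 1L]] <<- data.frame(
      descendant = desc, type = type, pos = pos, length = length,
      from = from, to = to, seq = seq, mirrored = mirrored,
      stringsAsFactors = FALSE)
  }

  # per-descendant state: substituted bases over ancestor coords, deletion
  # mask, and insertion blocks keyed by ancestor position they follow
  desc_ids <- paste0(ancestor$id, "_d", seq_len(n_descendants))
  sub_base <- list(); del_mask <- list(); ins_blocks <- list()
  for (d in seq_len(n_descendants)) {
    id <- desc_ids[d]
    sb <- anc
    dm <- rep(FALSE, L)
    ins <- list()

    # indel events first so substitutions can avoid deleted spans
    if (evo_spec$indel_rate > 0) {
      hit <- indel_eligible[stats::runif(length(indel_eligible)) <
                              evo_spec$indel_rate]
      taken <- rep(FALSE, L)
      for (pos in hit) {
        len <- stats::rgeom(1L, 1 / evo_spec$indel_mean_len) + 1L
        if (stats::runif(1L) < 0.5) {
          span_end <- min(pos + len - 1L, L)
          if (homog) {
            # clip deletions at region boundaries so IRs stay untouched
            lim <- indel_eligible[indel_eligible >= pos]
            lim <- lim[seq_len(min(len, length(lim)))]
            lim <- lim[lim - pos == seq_along(lim) - 1L]
            span_end <- if (length(lim) > 0L) max(lim) else pos
          }
          span <- pos:span_end
          if (any(taken[span])) next
          taken[span] <- TRUE
          dm[span] <- TRUE
          log_event(id, "del", pos, length(span),
                    paste(anc[span], collapse = ""), "", "", FALSE)
        } else {
          if (taken[pos]) next
          taken[pos] <- TRUE
          iseq <- paste(sample(bases, len, replace = TRUE), collapse = "")
          ins[[as.character(pos)]] <- c(ins[[as.character(pos)]], iseq)
          log_event(id, "ins", pos, len, "", "", iseq, FALSE)
        }
      }
    }

    if (evo_spec$sub_prob > 0) {
      elig <- sub_eligible[!dm[sub_eligible]]
      hit <- elig[stats::runif(length(elig)) < p_site[elig]]
      for (pos in hit) {
        old <- sb[pos]
        if (!old %in% bases) next
        new <- sample(setdiff(bases, old), 1L)
        sb[pos] <- new
        log_event(id, "sub", pos, 1L, old, new, "", FALSE)
        if (homog && pos >= irb[1] && pos <= irb[2]) {
          mp <- mirror_pos(pos)
          sb[mp] <- comp_map[[new]]
          log_event(id, "sub", mp, 1L, comp_map[[old]], comp_map[[new]],
                    "", TRUE)
        }
      }
    }
    sub_base[[id]] <- sb
    del_mask[[id]] <- dm
    ins_blocks[[id]] <- ins
  }

  # truth alignment: ancestor columns interleaved with insertion blocks
  any_ins <- any(vapply(ins_blocks, length, 0L) > 0L)
  ins_here <- if (!any_ins) NULL else lapply(seq_len(L), function(pos) {
    blocks <- list()
    for (id in desc_ids) {
      bl <- ins_blocks[[id]][[as.character(pos)]]
      if (!is.null(bl)) {
        for (s in bl) blocks[[length(blocks) + 1L]] <- list(id = id, seq = s)
      }
    }
    blocks
  })
  ins_len_at <- if (!any_ins) integer(L) else vapply(ins_here, function(b) {
    sum(vapply(b, function(z) nchar(z$seq), 0L))
  }, 0L)
  W <- L + sum(ins_len_at)
  # column of each ancestor base: its position plus all insertions before it
  anc_col <- seq_len(L) + c(0L, cumsum(ins_len_at))[seq_len(L)]
  rows <- matrix("-", nrow = n_descendants + 1L, ncol = W,
                 dimnames = list(c(ancestor$id, desc_ids), NULL))
  rows[1, anc_col] <- anc
  for (d in seq_len(n_descendants)) {
    id <- desc_ids[d]
    v <- sub_base[[id]]
    v[del_mask[[id]]] <- "-"
    rows[d + 1L, anc_col] <- v
  }
  for (pos in which(ins_len_at > 0L)) {
    col <- anc_col[pos]
    for (b in ins_here[[pos]]) {
      n <- nchar(b$seq)
      rows[match(b$id, desc_ids) + 1L, col + seq_len(n)] <-
        strsplit(b$seq, "", fixed = TRUE)[[1]]
      col <- col + n
    }
  }
  seqs <- apply(rows, 1L, paste, collapse = "")
  aln <- aligned_matrix(seqs, reference_id = ancestor$id)
  descendants <- lapply(desc_ids, function(id) {
    circular_genome(id, ungapped_sequence(aln, id))
  })
  names(descendants) <- desc_ids
  ev <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(descendant = character(), type = character(),
               pos = integer(), length = integer(), from = character(),
               to = character(), seq = character(), mirrored = logical(),
               stringsAsFactors = FALSE)
  list(descendants = descendants, events = ev, alignment = aln)
}

#' Replay an event log against the ancestor to rebuild one descendant
#'
#' Substitutions are applied in ancestor coordinates, then deletions
#' remove their spans and insertions splice their sequence after their
#' anchor position.
#'
#' @param ancestor a [circular_genome()].
#' @param events event-log data.frame from [evolve()].
#' @param descendant_id descendant to rebuild.
#' @return the rebuilt sequence as a string.
#' @export
replay_events <- function(ancestor, events, descendant_id) {
  ev <- events[events$descendant == descendant_id, , drop = FALSE]
  x <- strsplit(ancestor$seq, "", fixed = TRUE)[[1]]
  for (r in which(ev$type == "sub")) x[ev$pos[r]] <- ev$to[r]
  keep <- rep(TRUE, length(x))
  for (r in which(ev$type == "del")) {
    keep[ev$pos[r]:(ev$pos[r] + ev$length[r] - 1L)] <- FALSE
  }
  ins_after <- split(ev$seq[ev$type == "ins"], ev$pos[ev$type == "ins"])
  out <- character()
  for (pos in seq_along(x)) {
    if (keep[pos]) out <- c(out, x[pos])
    blk <- ins_after[[as.character(pos)]]
    if (!is.null(blk)) out <- c(out, strsplit(paste(blk, collapse = ""),
                                              "", fixed = TRUE)[[1]])
  }
  paste(out, collapse = "")
}

#' Simulate descendant coding sequences with a synonymous:nonsynonymous bias
#'
#' Evolves `n` independent descendants of an in-frame ancestor CDS by
#' proposing random single-base codon changes and accepting synonymous
#' proposals with higher probability than nonsynonymous ones, emulating
#' purifying selection.
#'
#' @param ancestor_cds in-frame coding sequence without stops.
#' @param n number of descendants.
#' @param n_changes accepted changes per descendant.
#' @param syn_bias odds ratio favouring synonymous changes (default 3).
#' @param code genetic code.
#' @param seed random seed.
#' @return named character vector of descendant sequences.
#' @export
simulate_codon_descendants <- function(ancestor_cds, n, n_changes = 30L,
                                       syn_bias = 3, code = "standard",
                                       seed = 1L) {
  set.seed(seed)
  tabs <- ng86_tables(code)
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  for (d in seq_len(n)) {
    x <- strsplit(toupper(ancestor_cds), "", fixed = TRUE)[[1]]
    made <- 0L
    while (made < n_changes) {
      pos <- sample(length(x), 1L)
      new <- sample(setdiff(bases, x[pos]), 1L)
      cs <- ((pos - 1L) %/% 3L) * 3L + 1L
      old_cod <- paste(x[cs:(cs + 2L)], collapse = "")
      cod <- x[cs:(cs + 2L)]; cod[pos - cs + 1L] <- new
      new_cod <- paste(cod, collapse = "")
      if (new_cod %in% tabs$stops) next
      syn <- tabs$aa[[old_cod]] == tabs$aa[[new_cod]]
      accept_p <- if (syn) syn_bias / (syn_bias + 1) else 1 / (syn_bias + 1)
      if (stats::runif(1L) < accept_p) {
        x[pos] <- new
        made <- made + 1L
      }
    }
    out[d] <- paste(x, collapse = "")
  }
  names(out) <- paste0("taxon", seq_len(n))
  out
}
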