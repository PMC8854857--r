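# Sequence and annotation I/O, plus the circular-coordinate contract shared
# by every downstream module.

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")

#' Construct a circular genome object
#'
#' @param id character identifier.
#' @param seq nucleotide string over the IUPAC alphabet (lowercase accepted,
#'   stored uppercased).
#' @param circular logical; plastomes are circular by default.
#' @return an object of class `CircularGenome` with fields `id`, `seq`,
#'   `circular` and `length`.
#' @export
circular_genome <- function(id, seq, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence for genome '", id, "'")
  bad <- which(!strsplit(seq, "", fixed = TRUE)[[1]] %in% IUPAC_CHARS)
  if (length(bad) > 0L) {
    stop("non-IUPAC character '", substr(seq, bad[1], bad[1]),
         "' at position ", bad[1], " in genome '", id, "'")
  }
  structure(list(id = id, seq = seq, circular = isTRUE(circular),
                 length = nchar(seq)),
            class = "CircularGenome")
}

#' @export
print.CircularGenome <- function(x, ...) {
  cat(sprintf("<CircularGenome> %s: %s bp (%s)\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read plastome sequences from a FASTA file
#'
#' @param path FASTA file with at least one record.
#' @param circular logical flag applied to every record (default `TRUE`).
#' @return a named list of [circular_genome()] objects.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    circular_genome(ids[i], as.character(set[[i]]), circular = circular)
  })
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes a [circular_genome()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "CircularGenome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

empty_features_df <- function() {
  data.frame(feature_id = character(), name = character(),
             kind = character(), strand = character(),
             start = integer(), end = integer(), part = integer(),
             pseudo = logical(), stringsAsFactors = FALSE)
}

#' Construct a feature table for one genome
#'
#' Holds annotated features (one row per linear interval; a feature wrapping
#' the origin occupies two rows sharing a `feature_id`) and derives introns
#' (gaps between exons of one gene) and intergenic spacers (complement of
#' gene extents on the circle, named `geneA-geneB` in genome order).
#'
#' @param genome a [circular_genome()].
#' @param features data.frame with columns `feature_id`, `name`, `kind`
#'   (gene/tRNA/rRNA/exon), `strand`, `start`, `end`, `part`, `pseudo`.
#' @param derive derive introns and intergenic spacers (default `TRUE`).
#' @return an object of class `FeatureTable`.
#' @export
feature_table <- function(genome, features, derive = TRUE) {
  stopifnot(inherits(genome, "CircularGenome"))
  if (is.null(features) || nrow(features) == 0L) {
    features <- empty_features_df()
  }
  needed <- c("feature_id", "name", "kind", "strand", "start", "end",
              "part", "pseudo")
  miss <- setdiff(needed, names(features))
  if (length(miss) > 0L) stop("feature table missing columns: ",
                              paste(miss, collapse = ", "))
  bad <- features$start < 1L | features$end < 1L |
    features$start > genome$length | features$end > genome$length
  if (any(bad)) {
    stop("feature interval outside genome bounds: ",
         features$name[which(bad)[1]])
  }
  if (any(features$end < features$start)) {
    stop("validation error: end < start for feature '",
         features$name[which(features$end < features$start)[1]],
         "' (wrapping features must be split into two intervals)")
  }
  ft <- structure(list(genome_id = genome$id,
                       genome_length = genome$length,
                       features = features[order(features$start), ,
                                           drop = FALSE]),
                  class = "FeatureTable")
  if (derive) {
    ft <- derive_introns(ft)
    ft <- derive_intergenic(ft)
  }
  ft
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("<FeatureTable> %s (%d bp): %d feature rows\n",
              x$genome_id, x$genome_length, nrow(x$features)))
  print(table(x$features$kind))
  invisible(x)
}

GENE_KINDS <- c("gene", "tRNA", "rRNA")

#' Derive introns as gaps between the exons of each gene
#' @param ft a `FeatureTable`.
#' @return the table with `intron` rows appended.
#' @export
derive_introns <- function(ft) {
  f <- ft$features
  f <- f[f$kind != "intron", , drop = FALSE]
  ex <- f[f$kind == "exon", , drop = FALSE]
  introns <- empty_features_df()
  for (fid in unique(ex$feature_id)) {
    e <- ex[ex$feature_id == fid, , drop = FALSE]
    if (nrow(e) < 2L) next
    e <- e[order(e$start), , drop = FALSE]
    gname <- f$name[f$feature_id == fid & f$kind != "exon"][1]
    if (is.na(gname)) gname <- e$name[1]
    for (k in seq_len(nrow(e) - 1L)) {
      gap_s <- e$end[k] + 1L
      gap_e <- e$start[k + 1L] - 1L
      if (gap_e < gap_s) next
      introns <- rbind(introns, data.frame(
        feature_id = paste0(fid, ".intron", k), name = gname,
        kind = "intron", strand = e$strand[1], start = gap_s, end = gap_e,
        part = 1L, pseudo = e$pseudo[1], stringsAsFactors = FALSE))
    }
  }
  ft$features <- rbind(f, introns)
  ft$features <- ft$features[order(ft$features$start), , drop = FALSE]
  ft
}

#' Derive intergenic spacers as the complement of gene extents on the circle
#' @param ft a `FeatureTable`.
#' @return the table with `intergenic` rows appended (previous ones dropped).
#' @export
derive_intergenic <- function(ft) {
  f <- ft$features[ft$features$kind != "intergenic", , drop = FALSE]
  len <- ft$genome_length
  g <- f[f$kind %in% GENE_KINDS, , drop = FALSE]
  if (nrow(g) == 0L) {
    ft$features <- f
    return(ft)
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = g$start, end = g$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = len)
  gs <- IRanges::start(gaps); ge <- IRanges::end(gaps)
  # join the two flanking gaps across the origin into one wrapping spacer
  wrap <- length(gs) >= 2L && gs[1] == 1L && ge[length(ge)] == len &&
    min(IRanges::start(ir)) > 1L
  spacers <- empty_features_df()
  left_gene <- function(pos) {
    # gene whose extent ends immediately before pos on the circle
    g$name[which.min((pos - g$end - 1L) %% len)]
  }
  right_gene <- function(pos) {
    g$name[which.min((g$start - pos - 1L) %% len)]
  }
  add_spacer <- function(s, e, idx) {
    a <- left_gene(s); b <- right_gene(e)
    nm <- paste0(a, "-", b, if (e < s) "(wrap)" else "")
    pieces <- split_wrap(s, e, len)
    rbind(spacers, data.frame(
      feature_id = paste0("igs", idx), name = nm, kind = "intergenic",
      strand = "+", start = as.integer(pieces[, "start"]),
      end = as.integer(pieces[, "end"]),
      part = seq_len(nrow(pieces)), pseudo = FALSE,
      stringsAsFactors = FALSE))
  }
  idx <- 0L
  if (wrap) {
    idx <- idx + 1L
    spacers <- add_spacer(gs[length(gs)], ge[1], idx)
    keep <- seq_along(gs)[-c(1L, length(gs))]
  } else {
    keep <- seq_along(gs)
  }
  for (k in keep) {
    idx <- idx + 1L
    spacers <- add_spacer(gs[k], ge[k], idx)
  }
  ft$features <- rbind(f, spacers)
  ft$features <- ft$features[order(ft$features$start), , drop = FALSE]
  ft
}

#' Read a GFF3 annotation into a feature table
#'
#' Parses the GFF3 subset used by the pipeline: `gene`, `tRNA`, `rRNA` and
#' `exon` records with attribute keys `ID`, `Name`, `Parent` and `pseudo`.
#' Introns and intergenic spacers are derived, not read.
#'
#' @param path GFF3 file.
#' @param genome the [circular_genome()] the annotation belongs to; its id
#'   must match the GFF3 `seqid`.
#' @return a `FeatureTable`.
#' @export
read_features <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  seqids <- as.character(GenomicRanges::seqnames(gr))
  if (length(gr) > 0L && !genome$id %in% seqids) {
    stop("lookup error: genome id '", genome$id,
         "' not found among GFF3 seqids (",
         paste(unique(seqids), collapse = ", "), ")")
  }
  gr <- gr[seqids == genome$id]
  md <- S4Vectors::mcols(gr)
  kind <- as.character(md$type)
  keep <- kind %in% c(GENE_KINDS, "exon")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]; kind <- kind[keep]
  get_attr <- function(col, default) {
    if (col %in% names(md)) {
      v <- md[[col]]
      if (inherits(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) if (length(x) == 0L) NA_character_
                    else as.character(x[1]), "")
      }
      as.character(v)
    } else rep(default, length(gr))
  }
  id <- get_attr("ID", NA_character_)
  parent <- get_attr("Parent", NA_character_)
  nm <- get_attr("Name", NA_character_)
  pseudo <- tolower(get_attr("pseudo", "false")) %in% c("true", "1", "yes")
  pseudo[is.na(get_attr("pseudo", "false"))] <- FALSE
  fid <- ifelse(kind == "exon" & !is.na(parent), parent, id)
  fid[is.na(fid)] <- paste0("f", seq_along(fid))[is.na(fid)]
  nm[is.na(nm)] <- fid[is.na(nm)]
  feats <- data.frame(feature_id = fid, name = nm, kind = kind,
                      strand = as.character(BiocGenerics::strand(gr)),
                      start = BiocGenerics::start(gr),
                      end = BiocGenerics::end(gr),
                      part = 1L, pseudo = pseudo, stringsAsFactors = FALSE)
  feats$strand[!feats$strand %in% c("+", "-")] <- "+"
  # number the parts of multi-interval features in genome order
  for (u in unique(feats$feature_id[duplicated(paste(feats$feature_id,
                                                     feats$kind))])) {
    sel <- feats$feature_id == u & feats$kind != "exon"
    if (sum(sel) > 1L) feats$part[sel] <- order(feats$start[sel])
  }
  feature_table(genome, feats)
}

#' Write a feature table to GFF3
#'
#' Only annotated features are written; derived introns and intergenic
#' spacers are recomputed on read.
#'
#' @param ft a `FeatureTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(ft, path) {
  f <- ft$features[!ft$features$kind %in% c("intron", "intergenic"), ,
                   drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(f) > 0L) {
    attrs <- ifelse(
      f$kind == "exon",
      paste0("ID=", f$feature_id, ".e", seq_len(nrow(f)),
             ";Parent=", f$feature_id, ";Name=", f$name),
      paste0("ID=", f$feature_id, ";Name=", f$name,
             ";pseudo=", tolower(as.character(f$pseudo))))
    writeLines(paste(ft$genome_id, "plastidcomp", f$kind, f$start, f$end,
                     ".", f$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' GC content of a genome or circular interval
#'
#' Fraction (G + C) / (A + C + G + T); ambiguity codes are excluded from
#' both numerator and denominator.
#'
#' @param genome a [circular_genome()] (or a plain nucleotide string).
#' @param start,end optional 1-based inclusive interval; `end < start` wraps
#'   through the origin. Defaults to the whole sequence.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(genome, start = NULL, end = NULL) {
  seq <- if (inherits(genome, "CircularGenome")) genome$seq else toupper(genome)
  if (!is.null(start)) {
    seq <- circ_substr(seq, start, end)
  }
  if (nchar(seq) == 0L) stop("domain error: zero-length interval")
  counts <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  gc <- sum(counts[names(counts) %in% c("G", "C")])
  at <- sum(counts[names(counts) %in% c("A", "T")])
  if (gc + at == 0L) stop("domain error: interval has no unambiguous bases")
  gc / (gc + at)
}
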