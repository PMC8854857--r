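# Pairwise dN/dS by the Nei-Gojobori (1986) pathway-counting method with
# Jukes-Cantor correction, on a concatenated shared-gene codon alignment.
#
# Site counting: each codon position contributes the fraction of its three
# possible changes that are synonymous (changes to stop codons count as
# nonsynonymous); sites are averaged over the two sequences. Difference
# counting: codons differing at several positions are resolved by averaging
# synonymous/nonsynonymous steps over all minimal mutational pathways,
# excluding pathways that pass through a stop codon.

.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function(code = "standard") {
  key <- code
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  gc_id <- switch(code, standard = "1", plastid = "11", bacterial = "11",
                  code)
  aa <- Biostrings::getGeneticCode(gc_id)
  codons <- names(aa)
  bases <- c("A", "C", "G", "T")
  syn_frac <- vapply(codons, function(cd) {
    ch <- strsplit(cd, "", fixed = TRUE)[[1]]
    f <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, ch[p])) {
        alt <- ch; alt[p] <- b
        altc <- paste(alt, collapse = "")
        if (aa[[altc]] != "*" && aa[[altc]] == aa[[cd]]) f <- f + 1 / 3
      }
    }
    f
  }, 0)
  tabs <- list(aa = aa, codons = codons, syn_frac = syn_frac,
               stops = codons[aa == "*"])
  .ng86_cache[[key]] <- tabs
  tabs
}

# average (syn, nonsyn) step counts over minimal mutational pathways
.pathway_counts <- function(c1, c2, tabs) {
  ch1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  ch2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  diffs <- which(ch1 != ch2)
  nd <- length(diffs)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(diffs) else {
    if (nd == 2L) list(diffs, rev(diffs)) else {
      # all 6 orders of three positions
      idx <- expand.grid(1:3, 1:3, 1:3)
      idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 3L), ]
      lapply(seq_len(nrow(idx)), function(r) diffs[unlist(idx[r, ])])
    }
  }
  eval_path <- function(ord) {
    cur <- ch1
    sd <- 0; nsd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- ch2[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (to %in% tabs$stops && !identical(nxt, ch2)) return(NULL)
      if (tabs$aa[[to]] == "*" || tabs$aa[[from]] == "*") {
        # endpoint stops should not occur; count as nonsynonymous
        nsd <- nsd + 1
      } else if (tabs$aa[[from]] == tabs$aa[[to]]) {
        sd <- sd + 1
      } else {
        nsd <- nsd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nsd)
  }
  res <- lapply(perms, eval_path)
  ok <- res[!vapply(res, is.null, TRUE)]
  if (length(ok) == 0L) {
    # every pathway passes through a stop; fall back to counting all
    res <- lapply(perms, function(ord) {
      cur <- ch1; sd <- 0; nsd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- ch2[p]
        from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
        if (tabs$aa[[from]] != "*" && tabs$aa[[to]] != "*" &&
            tabs$aa[[from]] == tabs$aa[[to]]) sd <- sd + 1 else nsd <- nsd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nsd)
    })
    ok <- res
  }
  colMeans(do.call(rbind, ok))
}

#' Jukes-Cantor correction of a raw proportion of differences
#' @param p proportion of differing sites.
#' @return corrected distance, or `NA` when `p >= 3/4` (saturated).
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' NG86 synonymous/nonsynonymous rates for one sequence pair
#'
#' @param seq_i,seq_j equal-length in-frame coding sequences without stop
#'   codons. Codons containing gaps or ambiguity codes in either sequence
#'   are dropped pairwise.
#' @param code genetic code: `"standard"` (default) or `"plastid"`
#'   (bacterial/plastid table, identical amino-acid assignments).
#' @return list of class `CodonPairRates`: `S`, `N` (site counts averaged
#'   over the pair), `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`,
#'   `codons_used`, `saturated`.
#' @export
ng86_pair <- function(seq_i, seq_j, code = "standard") {
  seq_i <- toupper(seq_i); seq_j <- toupper(seq_j)
  if (nchar(seq_i) != nchar(seq_j)) stop("sequences differ in length")
  if (nchar(seq_i) %% 3L != 0L) stop("sequence length not divisible by 3")
  tabs <- ng86_tables(code)
  nc <- nchar(seq_i) %/% 3L
  starts <- 3L * (seq_len(nc) - 1L) + 1L
  cod_i <- substring(seq_i, starts, starts + 2L)
  cod_j <- substring(seq_j, starts, starts + 2L)
  usable <- grepl("^[ACGT]{3}$", cod_i) & grepl("^[ACGT]{3}$", cod_j) &
    !(cod_i %in% tabs$stops) & !(cod_j %in% tabs$stops)
  cod_i <- cod_i[usable]; cod_j <- cod_j[usable]
  if (length(cod_i) == 0L) stop("domain error: no comparable codons")
  S <- (sum(tabs$syn_frac[cod_i]) + sum(tabs$syn_frac[cod_j])) / 2
  N <- 3 * length(cod_i) - S
  Sd <- 0; Nd <- 0
  diff <- which(cod_i != cod_j)
  for (k in diff) {
    cnt <- .pathway_counts(cod_i[k], cod_j[k], tabs)
    Sd <- Sd + cnt[["sd"]]
    Nd <- Nd + cnt[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jukes_cantor(pS)
  dN <- jukes_cantor(pN)
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 codons_used = length(cod_i),
                 saturated = is.na(dS) || is.na(dN)),
            class = "CodonPairRates")
}

#' @export
print.CodonPairRates <- function(x, ...) {
  cat(sprintf(
    "<CodonPairRates> %d codons: dN=%.4f dS=%.4f omega=%s\n",
    x$codons_used, x$dN, x$dS,
    if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega)))
  invisible(x)
}

#' Extract the spliced, strand-aware CDS of one gene
#'
#' @param genome a [circular_genome()].
#' @param ft its `FeatureTable`.
#' @param gene_name gene to extract.
#' @return nucleotide string (exons joined in genome order; minus-strand
#'   genes reverse-complemented).
#' @export
extract_cds <- function(genome, ft, gene_name) {
  f <- ft$features
  gene <- f[f$kind == "gene" & f$name == gene_name, , drop = FALSE]
  if (nrow(gene) == 0L) stop("gene '", gene_name, "' not annotated in ",
                             genome$id)
  # IR-duplicated genes have one feature per copy; the copies are identical
  # by IR symmetry, so extract the first
  gene <- gene[gene$feature_id == gene$feature_id[1], , drop = FALSE]
  ex <- f[f$kind == "exon" & f$feature_id %in% gene$feature_id, ,
          drop = FALSE]
  if (nrow(ex) == 0L) ex <- gene
  ex <- ex[order(ex$start), , drop = FALSE]
  seq <- paste(vapply(seq_len(nrow(ex)), function(k) {
    substr(genome$seq, ex$start[k], ex$end[k])
  }, ""), collapse = "")
  if (gene$strand[1] == "-") seq <- revcomp(seq)
  seq
}

#' Build the concatenated shared-gene codon alignment
#'
#' Protein-coding genes annotated (and not pseudo) in every genome are
#' extracted as spliced CDS, stripped of their terminal stop codon and
#' concatenated in alphabetical gene order. Genes missing from any genome,
#' pseudo in any genome, out of frame, containing an internal stop, or of
#' unequal CDS length across genomes are excluded with a logged reason.
#'
#' @param genomes named list of [circular_genome()] objects.
#' @param feature_tables named list of matching `FeatureTable`s.
#' @param code genetic code for stop-codon checks.
#' @return list of class `CodonAlignment`: `ids`, `seqs` (named,
#'   equal-length, in-frame), `genes_used`, `genes_excluded` (data.frame
#'   `gene`, `reason`).
#' @export
build_codon_alignment <- function(genomes, feature_tables,
                                  code = "standard") {
  stopifnot(length(genomes) >= 2L,
            identical(names(genomes), names(feature_tables)))
  tabs <- ng86_tables(code)
  ids <- names(genomes)
  per_genome_genes <- lapply(feature_tables, function(ft) {
    f <- ft$features
    f[f$kind == "gene", c("name", "pseudo"), drop = FALSE]
  })
  all_names <- sort(unique(unlist(lapply(per_genome_genes, `[[`, "name"))))
  used <- character()
  excluded <- data.frame(gene = character(), reason = character(),
                         stringsAsFactors = FALSE)
  parts <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) parts[[id]] <- character()
  exclude <- function(g, why) {
    excluded <<- rbind(excluded, data.frame(gene = g, reason = why,
                                            stringsAsFactors = FALSE))
  }
  for (g in all_names) {
    present <- vapply(per_genome_genes, function(pg) g %in% pg$name, TRUE)
    if (!all(present)) {
      exclude(g, paste0("absent in ",
                        paste(ids[!present], collapse = ",")))
      next
    }
    pseudo <- vapply(per_genome_genes, function(pg) {
      any(pg$pseudo[pg$name == g])
    }, TRUE)
    if (any(pseudo)) {
      exclude(g, paste0("pseudogene in ",
                        paste(ids[pseudo], collapse = ",")))
      next
    }
    cds <- vapply(ids, function(id) {
      extract_cds(genomes[[id]], feature_tables[[id]], g)
    }, "")
    # strip the terminal stop codon where present
    cds <- vapply(cds, function(s) {
      if (nchar(s) %% 3L == 0L &&
          substr(s, nchar(s) - 2L, nchar(s)) %in% tabs$stops) {
        substr(s, 1L, nchar(s) - 3L)
      } else s
    }, "")
    if (any(nchar(cds) %% 3L != 0L)) {
      exclude(g, "CDS length not divisible by 3")
      next
    }
    if (length(unique(nchar(cds))) != 1L) {
      exclude(g, "CDS length differs between genomes (not aligned)")
      next
    }
    internal_stop <- vapply(cds, function(s) {
      nc <- nchar(s) %/% 3L
      if (nc == 0L) return(FALSE)
      st <- 3L * (seq_len(nc) - 1L) + 1L
      any(substring(s, st, st + 2L) %in% tabs$stops)
    }, TRUE)
    if (any(internal_stop)) {
      warning("gene '", g, "' contains an internal stop; excluded")
      exclude(g, "internal stop codon")
      next
    }
    used <- c(used, g)
    for (id in ids) parts[[id]] <- c(parts[[id]], cds[[id]])
  }
  if (length(used) == 0L) stop("no shared in-frame genes to concatenate")
  seqs <- vapply(parts, paste, "", collapse = "")
  structure(list(ids = ids, seqs = seqs, genes_used = used,
                 genes_excluded = excluded, code = code),
            class = "CodonAlignment")
}

#' @export
print.CodonAlignment <- function(x, ...) {
  cat(sprintf("<CodonAlignment> %d taxa, %d genes, %d codons\n",
              length(x$ids), length(x$genes_used),
              nchar(x$seqs[[1]]) %/% 3L))
  invisible(x)
}

#' Pairwise dN/dS table with extreme-value filtering
#'
#' Every sequence pair is run through [ng86_pair()]; pairs exceeding the
#' extreme-value filters (defaults: dN > 0.5, dS > 5, dS < 0.0005) are
#' flagged `filtered` with the triggered rule and excluded from summary
#' statistics, but their values are still reported.
#'
#' @param codon_aln a `CodonAlignment`.
#' @param dn_max,ds_max,ds_min filter bounds.
#' @return data.frame with one row per unordered pair: `id_i`, `id_j`,
#'   `dN`, `dS`, `omega`, `filtered`, `reason`.
#' @export
dnds_matrix <- function(codon_aln, dn_max = 0.5, ds_max = 5,
                        ds_min = 0.0005) {
  ids <- codon_aln$ids
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      r <- ng86_pair(codon_aln$seqs[[ids[i]]], codon_aln$seqs[[ids[j]]],
                     code = codon_aln$code)
      reason <- NA_character_
      if (!is.na(r$dN) && r$dN > dn_max) reason <- sprintf("dN > %g", dn_max)
      else if (!is.na(r$dS) && r$dS > ds_max) {
        reason <- sprintf("dS > %g", ds_max)
      } else if (!is.na(r$dS) && r$dS < ds_min && !(r$dS == 0 && r$dN == 0)) {
        # an identical pair has omega undefined but is not an extreme value
        reason <- sprintf("dS < %g", ds_min)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id_i = ids[i], id_j = ids[j], S = r$S, N = r$N, Sd = r$Sd,
        Nd = r$Nd, dN = r$dN, dS = r$dS, omega = r$omega,
        filtered = !is.na(reason), reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Format a dN/dS table as a lower-triangle character matrix
#'
#' Cells read `omega (dN/dS)`; filtered pairs are suffixed with `*`.
#'
#' @param tab data.frame from [dnds_matrix()].
#' @return character matrix.
#' @export
format_dnds_matrix <- function(tab) {
  ids <- unique(c(tab$id_i, tab$id_j))
  m <- matrix("", length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(tab))) {
    i <- match(tab$id_i[r], ids); j <- match(tab$id_j[r], ids)
    cell <- if (is.na(tab$omega[r])) {
      sprintf("NA (%.4f/%.4f)", tab$dN[r], tab$dS[r])
    } else {
      sprintf("%.4f (%.4f/%.4f)", tab$omega[r], tab$dN[r], tab$dS[r])
    }
    if (isTRUE(tab$filtered[r])) cell <- paste0(cell, "*")
    m[max(i, j), min(i, j)] <- cell
  }
  m
}
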