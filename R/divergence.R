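# Alignment-based divergence statistics: site classification, nucleotide
# diversity (pi) and Watterson's theta, sliding windows, hypervariable
# region ranking, pairwise indel/substitution counts and per-region
# variability. Gap policy follows the complete-deletion convention of
# DnaSP: a column enters pi/theta/site classification only when no sequence
# has a gap there, and 'N' counts as a gap.

#' Construct an aligned matrix from gapped sequences
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   over A/C/G/T/N/-.
#' @param reference_id id anchoring feature coordinates (default first).
#' @return object of class `AlignedMatrix`: fields `ids`, `mat` (N x L
#'   character matrix), `reference_id`, `column_map` (per-id integer vector
#'   giving the ungapped coordinate of each column, `NA` at gaps).
#' @export
aligned_matrix <- function(seqs, reference_id = NULL) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("format error: ragged alignment rows")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  bad <- !mat %in% c("A", "C", "G", "T", "N", "-")
  if (any(bad)) stop("format error: unexpected alignment character '",
                     mat[which(bad)[1]], "'")
  if (is.null(reference_id)) reference_id <- names(seqs)[1]
  if (!reference_id %in% names(seqs)) {
    stop("reference id '", reference_id, "' not among alignment rows")
  }
  column_map <- lapply(names(seqs), function(id) {
    nongap <- mat[id, ] != "-"
    m <- rep(NA_integer_, L)
    m[nongap] <- cumsum(nongap)[nongap]
    m
  })
  names(column_map) <- names(seqs)
  structure(list(ids = names(seqs), mat = mat,
                 reference_id = reference_id, column_map = column_map),
            class = "AlignedMatrix")
}

#' @export
print.AlignedMatrix <- function(x, ...) {
  cat(sprintf("<AlignedMatrix> %d sequences x %d columns (reference %s)\n",
              length(x$ids), ncol(x$mat), x$reference_id))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA; all records must have equal length.
#' @param reference_id optional reference id (default: first record).
#' @return an [aligned_matrix()].
#' @export
read_alignment <- function(path, reference_id = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("format error: empty alignment ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  aligned_matrix(seqs, reference_id = reference_id)
}

#' Ungapped sequence of one alignment row
#' @param aln an `AlignedMatrix`.
#' @param id row identifier.
#' @return the row with gaps removed, as a string.
#' @export
ungapped_sequence <- function(aln, id) {
  row <- aln$mat[id, ]
  paste(row[row != "-"], collapse = "")
}

.col_base_counts <- function(mat) {
  rbind(A = colSums(mat == "A"), C = colSums(mat == "C"),
        G = colSums(mat == "G"), T = colSums(mat == "T"))
}

#' Classify alignment columns into site classes
#'
#' A column is gap-free when no row has '-' or 'N'; variable when gap-free
#' with at least two distinct bases; parsimony-informative when at least
#' two distinct bases each occur in at least two rows; singleton when
#' variable but not informative.
#'
#' @param aln an `AlignedMatrix` with at least 2 rows.
#' @param partition optional canonical `QuadripartitePartition` of the
#'   reference genome; when supplied, counts are also broken down by
#'   structural region (columns assigned via the reference column map;
#'   reference-gap columns are left unassigned).
#' @return list of class `SiteClassCounts`: `total_columns`,
#'   `gap_free_columns`, `variable_sites`, `singleton_sites`,
#'   `parsimony_informative_sites`, and optionally `by_region`.
#' @export
classify_sites <- function(aln, partition = NULL) {
  mat <- aln$mat
  if (nrow(mat) < 2L) stop("domain error: need at least 2 sequences")
  gap_free <- colSums(mat == "-" | mat == "N") == 0L
  bc <- .col_base_counts(mat)
  n_distinct <- colSums(bc > 0L)
  n_shared <- colSums(bc >= 2L)
  variable <- gap_free & n_distinct >= 2L
  informative <- gap_free & n_shared >= 2L & n_distinct >= 2L
  res <- list(total_columns = ncol(mat),
              gap_free_columns = sum(gap_free),
              variable_sites = sum(variable),
              singleton_sites = sum(variable & !informative),
              parsimony_informative_sites = sum(informative))
  if (!is.null(partition)) {
    ref_map <- aln$column_map[[aln$reference_id]]
    reg <- rep(NA_character_, ncol(mat))
    ok <- !is.na(ref_map)
    reg[ok] <- region_of_position(ref_map[ok], partition)
    reg[reg %in% c("IRa", "IRb")] <- "IR"
    res$by_region <- do.call(rbind, lapply(c("LSC", "SSC", "IR"), function(r) {
      sel <- !is.na(reg) & reg == r
      data.frame(region = r, columns = sum(sel),
                 gap_free = sum(gap_free & sel),
                 variable = sum(variable & sel),
                 informative = sum(informative & sel),
                 stringsAsFactors = FALSE)
    }))
  }
  class(res) <- "SiteClassCounts"
  res
}

#' @export
print.SiteClassCounts <- function(x, ...) {
  cat(sprintf(paste0("<SiteClassCounts> %d columns; %d gap-free; ",
                     "%d variable (%d singleton, %d informative)\n"),
              x$total_columns, x$gap_free_columns, x$variable_sites,
              x$singleton_sites, x$parsimony_informative_sites))
  invisible(x)
}

#' Nucleotide diversity and Watterson's theta
#'
#' pi is the mean proportion of differing sites over all sequence pairs,
#' computed on gap-free columns (complete deletion); theta is
#' S / (a_n * L) with a_n the harmonic number of n - 1 and S the number of
#' segregating (variable) gap-free columns.
#'
#' @param aln an `AlignedMatrix` (N >= 2).
#' @param cols optional column indices restricting the computation (used by
#'   the sliding-window scan).
#' @return list of class `DiversityStats`: `pi`, `theta`, `n`, `L`
#'   (gap-free columns used), `S`.
#' @export
nucleotide_diversity <- function(aln, cols = NULL) {
  mat <- aln$mat
  if (!is.null(cols)) mat <- mat[, cols, drop = FALSE]
  n <- nrow(mat)
  if (n < 2L) stop("domain error: need at least 2 sequences")
  gap_free <- colSums(mat == "-" | mat == "N") == 0L
  Lgf <- sum(gap_free)
  if (Lgf == 0L) {
    stop("undefined statistic: no gap-free columns in the requested span")
  }
  sub <- mat[, gap_free, drop = FALSE]
  total_diff <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      total_diff <- total_diff + sum(sub[i, ] != sub[j, ])
    }
  }
  npairs <- n * (n - 1) / 2
  pi <- total_diff / (npairs * Lgf)
  bc <- .col_base_counts(sub)
  S <- sum(colSums(bc > 0L) >= 2L)
  a_n <- sum(1 / seq_len(n - 1L))
  structure(list(pi = pi, theta = S / (a_n * Lgf), n = n, L = Lgf, S = S),
            class = "DiversityStats")
}

#' @export
print.DiversityStats <- function(x, ...) {
  cat(sprintf("<DiversityStats> n=%d L=%d S=%d pi=%.5f theta=%.5f\n",
              x$n, x$L, x$S, x$pi, x$theta))
  invisible(x)
}

#' Sliding-window nucleotide diversity
#'
#' Windows are defined on alignment columns, starting at column 1 and
#' advancing by `step`; a final shorter window is appended (and flagged)
#' when full windows do not reach the last column. pi within each window
#' uses complete deletion restricted to that window; a window with no
#' gap-free column gets `NA`.
#'
#' @param aln an `AlignedMatrix`.
#' @param window window length in columns (default 600).
#' @param step step length in columns (default 200).
#' @return data.frame with `start`, `end`, `midpoint`, `pi`, `partial`.
#' @export
sliding_windows <- function(aln, window = 600L, step = 200L) {
  stopifnot(window >= step, step >= 1L)
  L <- ncol(aln$mat)
  if (window >= L) {
    starts <- 1L
    ends <- L
  } else {
    starts <- seq.int(1L, L - window + 1L, by = step)
    ends <- starts + window - 1L
    if (max(ends) < L) {
      starts <- c(starts, starts[length(starts)] + step)
      ends <- c(ends, L)
    }
  }
  pi <- vapply(seq_along(starts), function(i) {
    tryCatch(nucleotide_diversity(aln, cols = starts[i]:ends[i])$pi,
             error = function(e) NA_real_)
  }, 0)
  data.frame(start = starts, end = ends,
             midpoint = (starts + ends) %/% 2L, pi = pi,
             partial = (ends - starts + 1L) < window)
}

#' Rank hypervariable regions from a window profile
#'
#' Windows with positive pi are taken in decreasing pi order (ties broken
#' by alignment coordinate) and accumulated; overlapping or bookended
#' windows merge into one region, and accumulation stops as soon as `k`
#' distinct regions exist. Each region's peak pi is the maximum window pi
#' inside it. When fewer than `k` disjoint peaks exist, all of them are
#' returned with a warning. When `aln` and `features` are given, each
#' region is annotated with the names of the reference features it
#' overlaps.
#'
#' @param windows data.frame from [sliding_windows()].
#' @param aln optional `AlignedMatrix` (for feature annotation).
#' @param features optional reference `FeatureTable`.
#' @param k number of regions to return (default 10).
#' @return data.frame with `start`, `end`, `peak_pi`, `features`.
#' @export
hypervariable_regions <- function(windows, aln = NULL, features = NULL,
                                  k = 10L) {
  w <- windows[!is.na(windows$pi) & windows$pi > 0, , drop = FALSE]
  if (nrow(w) == 0L) return(data.frame(start = integer(), end = integer(),
                                       peak_pi = numeric(),
                                       features = character()))
  w <- w[order(-w$pi, w$start), , drop = FALSE]
  taken <- 0L
  repeat {
    taken <- taken + 1L
    ir <- IRanges::reduce(IRanges::IRanges(w$start[seq_len(taken)],
                                           w$end[seq_len(taken)]))
    if (length(ir) >= k || taken == nrow(w)) break
  }
  cand <- w[seq_len(taken), , drop = FALSE]
  regions <- data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  regions$peak_pi <- vapply(seq_len(nrow(regions)), function(i) {
    max(cand$pi[cand$start <= regions$end[i] & cand$end >= regions$start[i]])
  }, 0)
  regions <- regions[order(-regions$peak_pi, regions$start), , drop = FALSE]
  if (k > nrow(regions)) {
    warning("only ", nrow(regions), " hypervariable regions found")
    k <- nrow(regions)
  }
  regions <- regions[seq_len(k), , drop = FALSE]
  regions$features <- NA_character_
  if (!is.null(aln) && !is.null(features)) {
    ref_map <- aln$column_map[[aln$reference_id]]
    f <- features$features[features$features$kind != "exon", , drop = FALSE]
    regions$features <- vapply(seq_len(nrow(regions)), function(i) {
      refpos <- ref_map[regions$start[i]:regions$end[i]]
      refpos <- refpos[!is.na(refpos)]
      if (length(refpos) == 0L) return("")
      lo <- min(refpos); hi <- max(refpos)
      hit <- f$name[f$start <= hi & f$end >= lo]
      paste(unique(hit), collapse = ",")
    }, "")
  }
  rownames(regions) <- NULL
  regions
}

#' Pairwise indel and substitution counts
#'
#' The two rows are projected by dropping columns where both have '-';
#' each maximal run of '-' remaining in either row then counts as one
#' indel event, and substitutions are the columns where both rows carry
#' unambiguous bases that differ.
#'
#' @param aln an `AlignedMatrix`.
#' @param i,j row ids or indices.
#' @return list of class `PairwiseDivergence`: `id_i`, `id_j`,
#'   `indel_events`, `substitutions`.
#' @export
pairwise_divergence <- function(aln, i, j) {
  ids <- aln$ids
  if (is.character(i)) i <- match(i, ids)
  if (is.character(j)) j <- match(j, ids)
  stopifnot(!is.na(i), !is.na(j), i >= 1L, j >= 1L,
            i <= length(ids), j <= length(ids))
  ri <- aln$mat[i, ]; rj <- aln$mat[j, ]
  if (i == j) {
    return(structure(list(id_i = ids[i], id_j = ids[j],
                          indel_events = 0L, substitutions = 0L),
                     class = "PairwiseDivergence"))
  }
  keep <- !(ri == "-" & rj == "-")
  ri <- ri[keep]; rj <- rj[keep]
  count_runs <- function(x) {
    r <- rle(x == "-")
    sum(r$values)
  }
  indels <- count_runs(ri) + count_runs(rj)
  bases <- c("A", "C", "G", "T")
  subs <- sum(ri %in% bases & rj %in% bases & ri != rj)
  structure(list(id_i = ids[i], id_j = ids[j],
                 indel_events = as.integer(indels),
                 substitutions = as.integer(subs)),
            class = "PairwiseDivergence")
}

#' Full pairwise indel/substitution matrix
#'
#' @param aln an `AlignedMatrix`.
#' @return square data.frame-like matrix with indel counts in the upper
#'   triangle and substitution counts in the lower triangle.
#' @export
divergence_matrix <- function(aln) {
  n <- length(aln$ids)
  m <- matrix(NA_integer_, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pairwise_divergence(aln, i, j)
      m[i, j] <- d$indel_events
      m[j, i] <- d$substitutions
    }
  }
  m
}

#' Percent variable sites per annotated region
#'
#' For each gene (over its exons), intron and intergenic spacer of the
#' reference annotation, the percentage of variable alignment columns is
#' reported. Unlike the whole-genome site classification, a column where
#' some sequences are gapped still counts here, with '-' treated as a
#' state: a region deleted in some taxa can reach 100% variability.
#'
#' @param aln an `AlignedMatrix`.
#' @param features reference `FeatureTable`.
#' @return data.frame with `name`, `category` (`coding`/`noncoding`),
#'   `columns`, `variable`, `percent`, plus attribute `pooled` holding the
#'   pooled coding and non-coding percentages.
#' @export
region_variability <- function(aln, features) {
  mat <- aln$mat
  ref_map <- aln$column_map[[aln$reference_id]]
  # invert: reference coordinate -> alignment column
  ref_cols <- which(!is.na(ref_map))
  ref_pos <- ref_map[ref_cols]
  col_of <- integer(max(ref_pos))
  col_of[ref_pos] <- ref_cols
  bc <- .col_base_counts(mat)
  gap_state <- colSums(mat == "-") > 0L
  n_states <- colSums(bc > 0L) + as.integer(gap_state)
  col_variable <- n_states >= 2L
  f <- features$features
  has_exons <- unique(f$feature_id[f$kind == "exon"])
  with_cat <- function(sel, cat) {
    sub <- f[sel, c("name", "start", "end"), drop = FALSE]
    sub$category <- rep(cat, nrow(sub))
    sub
  }
  allf <- rbind(
    with_cat(f$kind == "exon", "coding"),
    with_cat(f$kind %in% GENE_KINDS & !f$feature_id %in% has_exons,
             "coding"),
    with_cat(f$kind %in% c("intron", "intergenic"), "noncoding"))
  if (nrow(allf) == 0L) stop("no reference features to anchor regions")
  rows <- lapply(split(allf, paste(allf$name, allf$category)), function(sub) {
    cols <- unlist(lapply(seq_len(nrow(sub)), function(r) {
      pos <- sub$start[r]:sub$end[r]
      pos <- pos[pos <= length(col_of)]
      cc <- col_of[pos]
      cc <- cc[cc > 0L]
      if (length(cc) == 0L) return(integer())
      # full column span, so insertion columns inside the region count too
      seq.int(min(cc), max(cc))
    }))
    cols <- unique(cols)
    if (length(cols) == 0L) {
      warning("region '", sub$name[1], "' absent from the alignment; skipped")
      return(NULL)
    }
    data.frame(name = sub$name[1], category = sub$category[1],
               columns = length(cols), variable = sum(col_variable[cols]),
               percent = round(100 * sum(col_variable[cols]) / length(cols),
                               2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  out <- out[order(out$category, out$name), , drop = FALSE]
  rownames(out) <- NULL
  pooled <- vapply(c("coding", "noncoding"), function(cat) {
    sub <- out[out$category == cat, , drop = FALSE]
    if (nrow(sub) == 0L) return(NA_real_)
    round(100 * sum(sub$variable) / sum(sub$columns), 2)
  }, 0)
  attr(out, "pooled") <- pooled
  out
}
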