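# Independent brute-force oracles used to validate the fast
# implementations, plus small fixture builders. The oracles share only the
# definitions with the package code, never the algorithms.

random_dna <- function(n, gc = 0.4) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

comp_chr <- function(x) chartr("ACGT", "TGCA", x)

# Quadratic longest-inverted-repeat oracle on a circular sequence: scans
# every anti-diagonal i + j = const of the match matrix
# M[i, j] = (x[i] == comp(x[j])) for maximal runs, keeping the longest
# pair of disjoint copies.
oracle_longest_ir <- function(seq, min_len) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(x)
  cx <- comp_chr(x)
  best <- 0L
  idx0 <- function(i) ((i) %% L) + 1L    # 0-based in, 1-based out
  interval_positions <- function(s0, m) (seq.int(s0, s0 + m - 1L) %% L) + 1L
  for (cc in 0L:(L - 1L)) {
    # M[i] for i in 0..L-1, partner j = (cc - i) mod L
    j <- (cc - 0:(L - 1L)) %% L
    M <- x[0:(L - 1L) + 1L] == cx[j + 1L]
    if (all(M)) next                      # degenerate palindromic circle
    a <- which(!M)[1] - 1L                # open the circle at a FALSE
    Mr <- M[((a + 0:(L - 1L)) %% L) + 1L]
    r <- rle(Mr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      m <- r$lengths[k]
      if (m < min_len || m <= best) next
      i0 <- (a + starts[k] - 1L) %% L     # copy1 start, 0-based
      # copy2 runs j0-m+1 .. j0 with j0 = (cc - i0) mod L
      j0 <- (cc - i0) %% L
      p1 <- interval_positions(i0, m)
      p2 <- interval_positions((j0 - m + 1L) %% L, m)
      if (length(intersect(p1, p2)) == 0L) best <- m
    }
  }
  best
}

# Exhaustive SSR oracle: tests every (start, unit_len) on the circle for a
# maximal perfect tandem run, reporting loci exactly as defined (leftmost
# start, floor copies, primitive motif, per-unit-length threshold).
oracle_find_ssrs <- function(seq, thresholds = DEFAULT_SSR_THRESHOLDS) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(x)
  at <- function(i) x[((i - 1L) %% L) + 1L]
  primitive <- function(m) {
    u <- nchar(m)
    for (p in seq_len(u %/% 2L)) {
      if (u %% p == 0L &&
          m == strrep(substr(m, 1L, p), u %/% p)) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (u in 1:6) {
    thr <- thresholds[u]
    for (s in 1:L) {
      if (at(s - 1L) == at(s - 1L + u)) next    # not a run start
      r <- 0L
      while (r < L && at(s + r) == at(s + r + u)) r <- r + 1L
      if (r == 0L) next
      copies <- (r + u) %/% u
      if (copies < thr) next
      motif <- paste(at(s:(s + u - 1L)), collapse = "")
      if (!grepl("^[ACGT]+$", motif) || !primitive(motif)) next
      len <- copies * u
      if (len > L) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_len = u, copies = copies, start = s,
        end = ((s + len - 2L) %% L) + 1L, length = len,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(), unit_len = integer(),
                      copies = integer(), start = integer(),
                      end = integer(), length = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_len), , drop = FALSE]
}

# Recursive minimal-pathway oracle for NG86 difference counting: explores
# every order of fixing the differing codon positions, drops paths through
# stop intermediates, and averages synonymous/nonsynonymous step counts.
oracle_pathway_counts <- function(c1, c2, code = "standard") {
  gc_id <- if (code == "standard") "1" else "11"
  aa <- Biostrings::getGeneticCode(gc_id)
  stops <- names(aa)[aa == "*"]
  paths <- list()
  walk <- function(cur, target, sd, nd) {
    if (cur == target) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd)
      return(invisible())
    }
    ch <- strsplit(cur, "", fixed = TRUE)[[1]]
    ct <- strsplit(target, "", fixed = TRUE)[[1]]
    for (p in which(ch != ct)) {
      nxt <- ch; nxt[p] <- ct[p]
      nxtc <- paste(nxt, collapse = "")
      if (nxtc %in% stops && nxtc != target) next
      syn <- aa[[cur]] == aa[[nxtc]] && aa[[cur]] != "*"
      walk(nxtc, target, sd + as.integer(syn), nd + as.integer(!syn))
    }
  }
  walk(c1, c2, 0L, 0L)
  if (length(paths) == 0L) return(NULL)   # all pathways blocked by stops
  colMeans(do.call(rbind, paths))
}

# Event-log bookkeeping oracle for pairwise indel/substitution counts:
# lays out the column space (ancestor positions plus insertion blocks)
# with its own loop and counts gap runs / mismatches per the definitions.
oracle_pair_counts <- function(anc_chars, events, id_a, id_b) {
  L <- length(anc_chars)
  state <- function(id) {
    ev <- events[events$descendant == id, , drop = FALSE]
    base <- anc_chars
    for (r in which(ev$type == "sub")) base[ev$pos[r]] <- ev$to[r]
    del <- rep(FALSE, L)
    for (r in which(ev$type == "del")) {
      del[ev$pos[r]:(ev$pos[r] + ev$length[r] - 1L)] <- TRUE
    }
    ins <- ev[ev$type == "ins", c("pos", "seq"), drop = FALSE]
    list(base = base, del = del, ins = ins)
  }
  get_row <- function(id) {
    if (id %in% events$descendant) state(id) else {
      list(base = anc_chars, del = rep(FALSE, L),
           ins = data.frame(pos = integer(), seq = character()))
    }
  }
  a <- get_row(id_a); b <- get_row(id_b)
  # build the two rows over the shared column space position by position
  ca <- vector("list", L); cb <- vector("list", L)
  ins_pos <- unique(c(a$ins$pos, b$ins$pos))
  for (pos in seq_len(L)) {
    pa <- if (a$del[pos]) "-" else a$base[pos]
    pb <- if (b$del[pos]) "-" else b$base[pos]
    if (pos %in% ins_pos) {
      for (who in c("a", "b")) {
        st <- if (who == "a") a else b
        blk <- st$ins$seq[st$ins$pos == pos]
        if (length(blk) == 1L) {
          n <- nchar(blk)
          chars <- strsplit(blk, "", fixed = TRUE)[[1]]
          if (who == "a") {
            pa <- c(pa, chars); pb <- c(pb, rep("-", n))
          } else {
            pb <- c(pb, chars); pa <- c(pa, rep("-", n))
          }
        }
      }
    }
    ca[[pos]] <- pa; cb[[pos]] <- pb
  }
  ra <- unlist(ca); rb <- unlist(cb)
  keep <- !(ra == "-" & rb == "-")
  ra <- ra[keep]; rb <- rb[keep]
  runs <- function(v) sum(rle(v == "-")$values)
  list(indels = runs(ra) + runs(rb),
       subs = sum(ra != "-" & rb != "-" & ra != rb))
}

# small canonical test plastome with genes and SSRs
small_synth <- function(seed = 1L) {
  generate_plastome(plastome_spec(lsc_len = 30000L, ir_len = 8000L,
                                  ssc_len = 1200L, seed = seed))
}

# in-frame random CDS without stop codons
.random_cds <- function(n_codons, seed = 1) {
  set.seed(seed)
  codons <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(codons, codons, paste0), codons,
                                paste0))
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE)),
        collapse = "")
}

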