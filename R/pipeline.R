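# End-to-end orchestration: quadripartite structure -> SSR scan ->
# alignment divergence -> codon rates, emitting diff-able TSV report
# tables (UTF-8, '.' decimal) and a run manifest.

#' Assemble and validate a pipeline run configuration
#'
#' @param fasta character vector of genome FASTA paths (each may hold
#'   several records).
#' @param gff named character vector of GFF3 paths, keyed by genome id.
#' @param reference id of the genome anchoring reference-based statistics.
#' @param alignment optional path to the whole-genome multiple alignment
#'   (aligned FASTA, produced externally e.g. by MAFFT). The pipeline never
#'   computes alignments itself; stages that need one are skipped with an
#'   error if it is missing.
#' @param out_dir output directory for report tables.
#' @param ssr_thresholds minimum SSR copies per unit length 1-6.
#' @param window,step sliding-window length and step in columns.
#' @param min_ir_len minimum inverted-repeat length.
#' @param dn_max,ds_max,ds_min dN/dS extreme-value filters.
#' @param seed integer seed recorded in the manifest.
#' @return a validated `RunConfig` list.
#' @export
run_config <- function(fasta, gff = NULL, reference = NULL,
                       alignment = NULL, out_dir = "plastidcomp_out",
                       ssr_thresholds = DEFAULT_SSR_THRESHOLDS,
                       window = 600L, step = 200L, min_ir_len = 1000L,
                       dn_max = 0.5, ds_max = 5, ds_min = 0.0005,
                       seed = 1L) {
  stopifnot(length(fasta) >= 1L, all(ssr_thresholds > 0L),
            window >= step, step >= 1L, min_ir_len >= 100L)
  structure(list(fasta = fasta, gff = gff, reference = reference,
                 alignment = alignment, out_dir = out_dir,
                 ssr_thresholds = as.integer(ssr_thresholds),
                 window = as.integer(window), step = as.integer(step),
                 min_ir_len = as.integer(min_ir_len), dn_max = dn_max,
                 ds_max = ds_max, ds_min = ds_min,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_config()]; relative paths are resolved against the file's
#'   directory.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    out <- ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
    if (!is.null(names(p))) names(out) <- names(p)
    out
  }
  run_config(
    fasta = resolve(unlist(y$fasta)),
    gff = resolve(unlist(y$gff)),
    reference = y$reference,
    alignment = resolve(y$alignment),
    out_dir = if (is.null(y$out_dir)) "plastidcomp_out" else y$out_dir,
    ssr_thresholds = if (is.null(y$ssr_thresholds)) DEFAULT_SSR_THRESHOLDS
                     else unlist(y$ssr_thresholds),
    window = if (is.null(y$window)) 600L else y$window,
    step = if (is.null(y$step)) 200L else y$step,
    min_ir_len = if (is.null(y$min_ir_len)) 1000L else y$min_ir_len,
    dn_max = if (is.null(y$dn_max)) 0.5 else y$dn_max,
    ds_max = if (is.null(y$ds_max)) 5 else y$ds_max,
    ds_min = if (is.null(y$ds_min)) 0.0005 else y$ds_min,
    seed = if (is.null(y$seed)) 1L else y$seed)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Map feature coordinates into canonical-rotation coordinates
#'
#' @param ft `FeatureTable` in input coordinates.
#' @param partition the partition detected on the same (untransformed)
#'   genome.
#' @param genome the canonical genome the result should attach to.
#' @return `FeatureTable` in canonical coordinates (wrapping intervals
#'   split; strands flipped when the canonicalization flipped the strand).
#' @export
transform_features <- function(ft, partition, genome) {
  L <- partition$genome_length
  off <- partition$rotation_offset
  f <- ft$features[!ft$features$kind %in% c("intron", "intergenic"), ,
                   drop = FALSE]
  rows <- empty_features_df()
  for (r in seq_len(nrow(f))) {
    s <- f$start[r]; e <- f$end[r]
    if (partition$strand_flipped) {
      s2 <- circ_pos((L - e + 1L) - off, L)
      e2 <- circ_pos((L - s + 1L) - off, L)
      strand <- if (f$strand[r] == "+") "-" else "+"
    } else {
      s2 <- circ_pos(s - off, L)
      e2 <- circ_pos(e - off, L)
      strand <- f$strand[r]
    }
    pieces <- split_wrap(s2, e2, L)
    for (k in seq_len(nrow(pieces))) {
      rows <- rbind(rows, data.frame(
        feature_id = f$feature_id[r], name = f$name[r], kind = f$kind[r],
        strand = strand, start = as.integer(pieces[k, "start"]),
        end = as.integer(pieces[k, "end"]),
        part = if (nrow(pieces) > 1L) k else f$part[r],
        pseudo = f$pseudo[r], stringsAsFactors = FALSE))
    }
  }
  feature_table(genome, rows)
}

#' Run the full comparative-plastome analysis
#'
#' Executes structure detection, SSR scanning, alignment divergence and
#' codon-rate stages, writing one TSV per report table into
#' `config$out_dir`. A stage failure aborts the run with the stage name;
#' tables already written are preserved.
#'
#' @param config a `RunConfig` from [run_config()] or [read_run_config()].
#' @return invisibly, a list with all computed objects (`genomes`,
#'   `partitions`, `features`, `structure_table`, `ssr`, `divergence`,
#'   `dnds`, `junctions`, `manifest`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  genomes <- stage("read", {
    gl <- list()
    for (p in config$fasta) gl <- c(gl, read_fasta(p))
    gl
  })
  ids <- names(genomes)
  reference <- if (is.null(config$reference)) ids[1] else config$reference
  if (!reference %in% ids) {
    stop("configuration error: reference '", reference,
         "' is not among the genome ids (", paste(ids, collapse = ", "), ")")
  }

  partitions <- list(); features <- list()
  structure_rows <- list()
  stage("quadripartite", {
    for (id in ids) {
      part <- detect_quadripartite(genomes[[id]],
                                   min_ir_len = config$min_ir_len)
      can <- canonical_rotation(genomes[[id]], part)
      ft_raw <- if (!is.null(config$gff) && id %in% names(config$gff)) {
        read_features(config$gff[[id]], genomes[[id]])
      } else {
        feature_table(genomes[[id]], empty_features_df())
      }
      ft <- transform_features(ft_raw, part, can$genome)
      genomes[[id]] <- can$genome
      partitions[[id]] <- can$partition
      features[[id]] <- ft
      g <- can$genome; pp <- can$partition
      structure_rows[[id]] <- data.frame(
        genome = id, size_bp = g$length, lsc_bp = pp$lsc_len,
        ssc_bp = pp$ssc_len, ir_bp = pp$irb_len,
        gc_pct = round(100 * gc_content(g), 1),
        gc_lsc_pct = round(100 * gc_content(g, 1L, pp$jlb - 1L), 1),
        gc_ssc_pct = round(100 * gc_content(g, pp$jsb, pp$jsa - 1L), 1),
        gc_ir_pct = round(100 * gc_content(g, pp$jlb, pp$jsb - 1L), 1),
        jlb = pp$jlb, jsb = pp$jsb, jsa = pp$jsa, jla = pp$jla,
        stringsAsFactors = FALSE)
    }
  })
  structure_table <- do.call(rbind, structure_rows)
  rownames(structure_table) <- NULL
  write_tsv(structure_table, file.path(config$out_dir, "structure.tsv"))

  junctions <- stage("junctions", {
    do.call(rbind, lapply(ids, function(id) {
      cbind(genome = id, junction_context(partitions[[id]], features[[id]]))
    }))
  })
  write_tsv(junctions, file.path(config$out_dir, "junction_context.tsv"))

  ssr <- stage("ssr", {
    loci <- do.call(rbind, lapply(ids, function(id) {
      l <- find_ssrs(genomes[[id]], thresholds = config$ssr_thresholds)
      classify_ssrs(l, partitions[[id]], features[[id]])
    }))
    list(loci = loci, summary = ssr_summary(loci, partitions))
  })
  write_tsv(ssr$loci, file.path(config$out_dir, "ssr_loci.tsv"))
  write_tsv(ssr$summary$by_region,
            file.path(config$out_dir, "ssr_by_region.tsv"))
  write_tsv(ssr$summary$by_unit,
            file.path(config$out_dir, "ssr_by_unit.tsv"))
  write_tsv(ssr$summary$density,
            file.path(config$out_dir, "ssr_density.tsv"))

  divergence <- NULL
  if (is.null(config$alignment)) {
    message("no alignment configured: divergence stage skipped ",
            "(supply 'alignment' to enable it)")
  } else {
    divergence <- stage("divergence", {
      aln <- read_alignment(config$alignment, reference_id = reference)
      sites <- classify_sites(aln, partition = partitions[[reference]])
      div <- nucleotide_diversity(aln)
      win <- sliding_windows(aln, window = config$window,
                             step = config$step)
      hv <- hypervariable_regions(win, aln = aln,
                                  features = features[[reference]])
      dm <- divergence_matrix(aln)
      rv <- region_variability(aln, features[[reference]])
      list(alignment = aln, sites = sites, diversity = div, windows = win,
           hypervariable = hv, pairwise = dm, region_variability = rv)
    })
    site_tab <- with(divergence$sites, data.frame(
      region = c(divergence$sites$by_region$region, "all"),
      sites = c(divergence$sites$by_region$columns, total_columns),
      variable = c(divergence$sites$by_region$variable, variable_sites),
      informative = c(divergence$sites$by_region$informative,
                      parsimony_informative_sites)))
    write_tsv(site_tab, file.path(config$out_dir, "site_classes.tsv"))
    write_tsv(data.frame(pi = divergence$diversity$pi,
                         theta = divergence$diversity$theta,
                         n = divergence$diversity$n,
                         gap_free_sites = divergence$diversity$L,
                         segregating = divergence$diversity$S),
              file.path(config$out_dir, "diversity.tsv"))
    write_tsv(divergence$windows, file.path(config$out_dir, "windows.tsv"))
    write_tsv(divergence$hypervariable,
              file.path(config$out_dir, "hypervariable_regions.tsv"))
    pm <- as.data.frame(divergence$pairwise)
    pm <- cbind(genome = rownames(pm), pm)
    write_tsv(pm, file.path(config$out_dir, "indel_substitution.tsv"))
    write_tsv(divergence$region_variability,
              file.path(config$out_dir, "region_variability.tsv"))
  }

  dnds <- NULL
  has_genes <- any(vapply(features, function(ft) {
    any(ft$features$kind == "gene")
  }, TRUE))
  if (has_genes && length(ids) >= 2L) {
    dnds <- stage("codon_rates", {
      ca <- build_codon_alignment(genomes, features)
      tab <- dnds_matrix(ca, dn_max = config$dn_max,
                         ds_max = config$ds_max, ds_min = config$ds_min)
      list(codon_alignment = ca, table = tab,
           matrix = format_dnds_matrix(tab))
    })
    write_tsv(dnds$table, file.path(config$out_dir, "dnds_pairs.tsv"))
    fm <- as.data.frame(dnds$matrix)
    fm <- cbind(genome = rownames(fm), fm)
    write_tsv(fm, file.path(config$out_dir, "dnds_matrix.tsv"))
  }

  manifest <- data.frame(
    key = c("package", "version", "r_version", "reference", "seed",
            "ssr_thresholds", "window", "step", "min_ir_len",
            "dnds_filters", "genomes"),
    value = c("plastidcomp",
              as.character(utils::packageVersion("plastidcomp")),
              paste(R.version$major, R.version$minor, sep = "."),
              reference, config$seed,
              paste(config$ssr_thresholds, collapse = ","),
              config$window, config$step, config$min_ir_len,
              sprintf("dN>%g,dS>%g,dS<%g", config$dn_max, config$ds_max,
                      config$ds_min),
              paste(ids, collapse = ",")),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))

  invisible(list(genomes = genomes, partitions = partitions,
                 features = features, structure_table = structure_table,
                 ssr = ssr, divergence = divergence, dnds = dnds,
                 junctions = junctions, manifest = manifest))
}
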