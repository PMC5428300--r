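#' Pipeline configuration
#'
#' @param genbank_paths character vector of GenBank files, one per genome.
#' @param alignment_path whole-genome aligned FASTA (taxon names must match
#'   the GenBank-derived labels).
#' @param primers_path primer table TSV (see [read_primers()]); defaults to
#'   the shipped table.
#' @param markers named list; each element `c(fwd = , rev = )` gives the
#'   primer names (rows of the primer table) delimiting one marker.
#' @param reference_taxon taxon whose annotation is projected onto the
#'   alignment (default: first genome).
#' @param denominator_mode passed to [pairwise_difference_matrix()].
#' @param bootstrap_reps bootstrap replicates for the trees.
#' @param seed RNG seed, recorded in every output header.
#' @param collapse_threshold bootstrap percent below which branches are
#'   collapsed in the `*_collapsed.nwk` outputs.
#' @param top_n_noncoding how many non-coding regions to keep in the ranking.
#' @param min_ir_len minimum inverted-repeat length for structure detection.
#' @param column_mask optional integer vector of alignment columns to drop
#'   before tree building (e.g. externally identified inversion columns).
#' @param out_dir output directory.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(genbank_paths, alignment_path,
                            primers_path = NULL,
                            markers = list(
                              "trnH-psbA" = c(fwd = "trnHf_05",
                                              rev = "psbA3_f"),
                              "rbcL" = c(fwd = "rbcLa-F", rev = "rbcLa-R")),
                            reference_taxon = NULL,
                            denominator_mode = "alignment_length",
                            bootstrap_reps = 200L, seed = 42L,
                            collapse_threshold = 50,
                            top_n_noncoding = 25L,
                            min_ir_len = 10000L,
                            column_mask = integer(),
                            out_dir = "superbarcode_out") {
  structure(list(genbank_paths = genbank_paths,
                 alignment_path = alignment_path,
                 primers_path = primers_path, markers = markers,
                 reference_taxon = reference_taxon,
                 denominator_mode = denominator_mode,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed),
                 collapse_threshold = collapse_threshold,
                 top_n_noncoding = as.integer(top_n_noncoding),
                 min_ir_len = as.integer(min_ir_len),
                 column_mask = column_mask,
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv_commented <- function(df, path, seed, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# superbarcode %s | seed %d",
                       as.character(utils::packageVersion("superbarcode")),
                       seed), paste0("# ", extra)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Table-2-style matrix: counts below the diagonal, percents above
diff_matrix_table <- function(dm) {
  n <- length(dm$taxa)
  out <- matrix("", n, n, dimnames = list(dm$taxa, dm$taxa))
  out[lower.tri(out)] <- dm$counts[lower.tri(dm$counts)]
  out[upper.tri(out)] <- sprintf("%.2f%%", dm$percents[upper.tri(dm$percents)])
  data.frame(taxon = dm$taxa, out, check.names = FALSE)
}

# columns of the alignment covered by IRb and by tRNA/rRNA genes of the
# reference annotation: the standard filter before whole-plastome trees
phylogeny_filter_columns <- function(aln, record) {
  map <- coordinate_map(aln, record$taxon)
  drop <- integer()
  if (!is.null(record$partition)) {
    irb <- record$partition$irb
    L <- nchar(record$sequence)
    pos <- if (irb[2L] >= irb[1L]) irb[1L]:irb[2L]
           else c(irb[1L]:L, 1L:irb[2L])
    drop <- c(drop, map$col_of_pos[pos])
  }
  f <- record$features
  f <- f[f$kind %in% c("tRNA", "rRNA") & !f$spans_origin, , drop = FALSE]
  for (i in seq_len(nrow(f)))
    drop <- c(drop, map$col_of_pos[f$start[i]:f$end[i]])
  unique(drop)
}

#' Run the full super-barcoding pipeline
#'
#' Orchestrates: genome stats (with IR detection), the pairwise difference
#' matrix, coding and non-coding region rankings from the reference
#' annotation, in-silico PCR plus per-marker discriminability reports, and
#' bootstrapped neighbor-joining trees from the filtered whole-genome
#' alignment (single IR copy, tRNA/rRNA genes removed, optional extra
#' column mask) and from each marker. All outputs are TSV/Newick/FASTA files
#' under `config$out_dir` plus a JSON run manifest with input checksums;
#' reruns with identical inputs and seed are byte-identical (timestamps
#' only in the manifest).
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("superbarcode")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   inputs = list(), outputs = character(), status = "FAILED")
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  fail <- function(stage, e) {
    manifest$status <<- "FAILED"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    finish()
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    fail(name, e))

  # -- inputs ---------------------------------------------------------------
  stage("inputs", {
    paths <- c(config$genbank_paths, config$alignment_path,
               config$primers_path)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    manifest$inputs <- as.list(tools::md5sum(paths))
  })

  records <- stage("genome_io", {
    recs <- lapply(config$genbank_paths, read_genbank)
    for (i in seq_along(recs))
      recs[[i]]$partition <- detect_inverted_repeats(recs[[i]],
                                                     config$min_ir_len)
    names(recs) <- vapply(recs, `[[`, character(1), "taxon")
    tab <- genome_stats_table(recs)
    write_tsv_commented(tab[, c("taxon", "length_bp", "gc_percent",
                                "n_genes_total", "n_unique_protein_coding",
                                "n_trna", "n_rrna_total")],
                        file.path(out, "stats.tsv"), config$seed)
    recs
  })
  manifest$outputs <- c(manifest$outputs, "stats.tsv")

  aln <- stage("alignment", {
    a <- read_alignment(config$alignment_path)
    if (!setequal(a$taxa, names(records)))
      stop("alignment taxa do not match the GenBank records")
    a
  })

  dm <- stage("distances", {
    d <- pairwise_difference_matrix(aln, mode = config$denominator_mode)
    write_tsv_commented(diff_matrix_table(d), file.path(out, "table2.tsv"),
                        config$seed,
                        sprintf("denominator: %s", config$denominator_mode))
    d
  })
  manifest$outputs <- c(manifest$outputs, "table2.tsv")

  ref <- config$reference_taxon %||% names(records)[1L]
  stage("regions", {
    rec <- records[[ref]]
    map <- coordinate_map(aln, ref)
    Gred_ok <- function(f) !f$spans_origin
    f <- rec$features
    if (!is.null(rec$partition)) {
      irb <- rec$partition$irb
      f <- f[!arc_contains(irb[1L], irb[2L], f$start,
                           nchar(rec$sequence)), , drop = FALSE]
    }
    coding <- f[f$kind == "protein_coding" & Gred_ok(f), , drop = FALSE]
    gene_regions <- setNames(lapply(seq_len(nrow(coding)), function(i)
      project_interval(map, start = coding$start[i], end = coding$end[i])),
      coding$name)
    cstats <- rank_regions(region_stats_table(aln, gene_regions))
    write_tsv_commented(cstats, file.path(out, "coding_regions.tsv"),
                        config$seed,
                        sprintf("reference annotation: %s", ref))
    ig <- list_intergenic_regions(rec)
    ig <- ig[ig$end >= ig$start, , drop = FALSE]  # skip wrap-around spacer
    sp_regions <- setNames(lapply(seq_len(nrow(ig)), function(i)
      project_interval(map, start = ig$start[i], end = ig$end[i])),
      ig$region)
    nstats <- rank_regions(region_stats_table(aln, sp_regions),
                           config$top_n_noncoding)
    write_tsv_commented(nstats, file.path(out, "noncoding_regions.tsv"),
                        config$seed,
                        sprintf("reference annotation: %s", ref))
  })
  manifest$outputs <- c(manifest$outputs, "coding_regions.tsv",
                        "noncoding_regions.tsv")

  marker_alns <- stage("markers", {
    primers <- if (is.null(config$primers_path)) read_primers()
               else read_primers(config$primers_path)
    getp <- function(nm) {
      i <- match(nm, primers$name)
      if (is.na(i)) stop("primer not in table: ", nm)
      primers$sequence[i]
    }
    m_alns <- list()
    for (mk in names(config$markers)) {
      fwd <- getp(config$markers[[mk]][["fwd"]])
      rev <- getp(config$markers[[mk]][["rev"]])
      amps <- do.call(rbind, lapply(records, function(r)
        head(in_silico_pcr(r, fwd, rev, marker_name = mk), 1L)))
      if (is.null(amps) || nrow(amps) < 2L) {
        warning("marker ", mk, ": fewer than 2 amplicons; skipped")
        next
      }
      write_fasta(setNames(amps$sequence,
                           sprintf("%s|%s|%d-%d|%d", amps$taxon, mk,
                                   amps$start, amps$end, amps$length_bp)),
                  file.path(out, sprintf("amplicons_%s.fasta", mk)))
      rep <- marker_snp_matrix(amps, taxa = names(records), marker_name = mk)
      snp_df <- data.frame(taxon = rep$taxa, rep$pairwise_snps,
                           check.names = FALSE)
      write_tsv_commented(snp_df,
                          file.path(out, sprintf("marker_%s_snps.tsv", mk)),
                          config$seed)
      write_tsv_commented(
        if (nrow(rep$unresolved_pairs)) rep$unresolved_pairs
        else data.frame(taxon1 = character(), taxon2 = character()),
        file.path(out, sprintf("marker_%s_unresolved.tsv", mk)), config$seed)
      m_alns[[mk]] <- align_small(setNames(amps$sequence, amps$taxon))
    }
    m_alns
  })
  manifest$outputs <- c(manifest$outputs,
                        as.vector(outer(c("amplicons_", "marker_"),
                                        names(marker_alns), paste0)))

  stage("trees", {
    if (length(aln$taxa) < 3L) {
      warning("fewer than 3 taxa: tree stage skipped")
    } else {
      drop <- unique(c(phylogeny_filter_columns(aln, records[[ref]]),
                       config$column_mask))
      flt <- mask_columns(aln, drop)
      build <- function(a, stem) {
        if (length(a$taxa) >= 4L) {
          tr <- bootstrap_support(a, n_reps = config$bootstrap_reps,
                                  seed = config$seed,
                                  mode = config$denominator_mode)
          write_tree_file(tr, file.path(out, paste0(stem, ".nwk")))
          write_tree_file(collapse_low_support(tr,
                                               config$collapse_threshold),
                          file.path(out, paste0(stem, "_collapsed.nwk")))
        } else {
          tr <- nj_tree(pairwise_difference_matrix(a,
                                                   config$denominator_mode))
          write_tree_file(tr, file.path(out, paste0(stem, ".nwk")))
        }
      }
      build(flt, "tree_plastome")
      for (mk in names(marker_alns))
        build(marker_alns[[mk]],
              paste0("tree_", gsub("[^A-Za-z0-9]", "_", mk)))
    }
  })

  manifest$outputs <- list.files(out)
  manifest$status <- "OK"
  finish()
  invisible(manifest)
}
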