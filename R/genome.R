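# position arithmetic on a circle: 1-based position of p on a genome of length L
wrap_pos <- function(p, L) ((p - 1L) %% L) + 1L

# length of the closed interval (start, end) on a circle of length L
arc_length <- function(start, end, L) {
  if (end >= start) end - start + 1L else L - start + 1L + end
}

# does the closed (possibly wrapping) arc contain position p?
arc_contains <- function(start, end, p, L) {
  if (end >= start) p >= start & p <= end else p >= start | p <= end
}

arcs_overlap <- function(a, b, L) {
  arc_contains(a[1], a[2], b[1], L) || arc_contains(a[1], a[2], b[2], L) ||
    arc_contains(b[1], b[2], a[1], L)
}

# substring on a circular sequence, wrapping the origin when end < start
circular_substr <- function(sequence, start, end) {
  L <- nchar(sequence)
  if (end >= start) substring(sequence, start, end)
  else paste0(substring(sequence, start, L), substring(sequence, 1L, end))
}

#' Detect the quadripartite (LSC/IRa/SSC/IRb) plastome structure
#'
#' Finds the maximal-length pair of disjoint intervals whose sequences are
#' exact reverse complements of each other (the inverted repeat), by hashed
#' seed-and-extend over 2-bit packed k-mers. Ties on repeat length are broken
#' by the smallest start coordinate. The two single-copy regions are the arcs
#' between the repeat copies: the longer is LSC, the shorter SSC; IRa is the
#' copy that immediately follows the LSC in circular order. On circular
#' records the search is rotation-invariant (performed on the doubled
#' sequence with coordinates reduced modulo the genome length).
#'
#' @param record a [genome_record()].
#' @param min_len minimum repeat length in bp to accept (>= 1000).
#' @return an object of class `quadripartite`: a list with closed 1-based
#'   intervals `lsc`, `ira`, `ssc`, `irb` (a wrapping interval has
#'   `end < start`) and `ir_length`; or `NULL` (with a message) when no
#'   reverse-complement repeat of at least `min_len` bp exists.
#' @export
detect_inverted_repeats <- function(record, min_len = 10000L) {
  stopifnot(inherits(record, "genome_record"), min_len >= 1000L)
  s <- record$sequence
  L <- nchar(s)
  search_seq <- if (record$circular) paste0(s, s) else s
  cand <- revcomp_repeats_cpp(search_seq, as.integer(min_len))
  if (nrow(cand)) {
    keep <- matrix(integer(), 0, 3)
    seen <- character()
    for (r in seq_len(nrow(cand))) {
      len <- min(cand[r, 3L], L)
      s1 <- wrap_pos(cand[r, 1L], L)
      s2 <- wrap_pos(cand[r, 2L], L)
      if (s1 == s2) next
      if (s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp }
      a <- c(s1, wrap_pos(s1 + len - 1L, L))
      b <- c(s2, wrap_pos(s2 + len - 1L, L))
      if (arcs_overlap(a, b, L)) next
      key <- paste(s1, s2, len)
      if (key %in% seen) next
      seen <- c(seen, key)
      keep <- rbind(keep, c(s1, s2, len))
    }
    cand <- keep
  }
  if (!nrow(cand)) {
    message(sprintf("no inverted repeat of >= %d bp found in %s",
                    min_len, record$taxon))
    return(NULL)
  }
  cand <- cand[order(-cand[, 3L], cand[, 1L], cand[, 2L]), , drop = FALSE]
  len <- unname(cand[1L, 3L])
  a_start <- unname(cand[1L, 1L]); b_start <- unname(cand[1L, 2L])
  a <- c(a_start, wrap_pos(a_start + len - 1L, L))
  b <- c(b_start, wrap_pos(b_start + len - 1L, L))

  gap_ab <- c(wrap_pos(a[2L] + 1L, L), wrap_pos(b[1L] - 1L, L)) # after a, before b
  gap_ba <- c(wrap_pos(b[2L] + 1L, L), wrap_pos(a[1L] - 1L, L)) # after b, before a
  len_ab <- arc_length(gap_ab[1L], gap_ab[2L], L)
  len_ba <- arc_length(gap_ba[1L], gap_ba[2L], L)
  if (len_ab + len_ba + 2L * len != L)
    stop("internal error: quadripartite intervals do not tile the genome")
  if (len_ba >= len_ab) {
    lsc <- gap_ba; ssc <- gap_ab; ira <- a; irb <- b
  } else {
    lsc <- gap_ab; ssc <- gap_ba; ira <- b; irb <- a
  }
  structure(list(lsc = lsc, ira = ira, ssc = ssc, irb = irb,
                 ir_length = as.integer(len),
                 lsc_length = max(len_ab, len_ba),
                 ssc_length = min(len_ab, len_ba)),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf("<quadripartite> LSC %d bp | IR %d bp x2 | SSC %d bp\n",
              x$lsc_length, x$ir_length, x$ssc_length))
  invisible(x)
}

#' Summary statistics for an annotated genome
#'
#' Gene counts are taken from the feature table; "unique" counts collapse
#' IR-duplicated copies by gene name (a gene counts as duplicated only when a
#' second full copy is annotated). G+C content excludes N from both numerator
#' and denominator and is rounded to one decimal.
#'
#' @param record a [genome_record()].
#' @return a one-row data.frame with columns `taxon`, `length_bp`,
#'   `gc_percent`, `n_genes_total`, `n_unique_protein_coding`, `n_trna`,
#'   `n_unique_trna`, `n_rrna_total`, `n_unique_rrna`, `n_intron_genes`.
#' @export
genome_stats <- function(record) {
  stopifnot(inherits(record, "genome_record"))
  chars <- str_chars(record$sequence)
  n_gc <- sum(chars %in% c("G", "C"))
  n_acgt <- sum(chars != "N")
  gc <- if (n_acgt) round_fixed(100 * n_gc / n_acgt, 1L) else NA_real_
  f <- record$features
  genic <- f[f$kind %in% c("protein_coding", "tRNA", "rRNA"), , drop = FALSE]
  data.frame(
    taxon = record$taxon,
    length_bp = nchar(record$sequence),
    gc_percent = gc,
    n_genes_total = nrow(genic),
    n_unique_protein_coding =
      length(unique(genic$name[genic$kind == "protein_coding"])),
    n_trna = sum(genic$kind == "tRNA"),
    n_unique_trna = length(unique(genic$name[genic$kind == "tRNA"])),
    n_rrna_total = sum(genic$kind == "rRNA"),
    n_unique_rrna = length(unique(genic$name[genic$kind == "rRNA"])),
    n_intron_genes = length(unique(genic$name[genic$intron_count > 0L])))
}

#' Tabulate genome statistics for several records
#' @param records list of `genome_record`s.
#' @param path optional output TSV path; when given the table is written with
#'   columns `taxon`, `length_bp`, `gc_percent`, `n_genes_total`,
#'   `n_unique_protein_coding`, `n_trna`, `n_rrna_total`.
#' @return the full stats data.frame (one row per genome), invisibly when
#'   `path` is given.
#' @export
genome_stats_table <- function(records, path = NULL) {
  tab <- do.call(rbind, lapply(records, genome_stats))
  if (!is.null(path)) {
    out <- tab[, c("taxon", "length_bp", "gc_percent", "n_genes_total",
                   "n_unique_protein_coding", "n_trna", "n_rrna_total")]
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Extract the sequence of a named feature
#'
#' Minus-strand features are returned reverse-complemented; origin-spanning
#' features are concatenated across the origin. When the gene is annotated
#' more than once (e.g. duplicated in the inverted repeat) all copies are
#' returned.
#'
#' @param record a [genome_record()].
#' @param feature_name gene symbol to look up (exact match).
#' @return a character vector of one sequence per annotated copy.
#' @export
extract_feature_sequence <- function(record, feature_name) {
  f <- record$features
  hit <- which(f$name == feature_name)
  if (!length(hit)) {
    near <- unique(agrep(feature_name, f$name, max.distance = 0.25,
                         value = TRUE, ignore.case = TRUE))
    stop(sprintf("no feature named '%s'%s", feature_name,
                 if (length(near))
                   paste0("; close matches: ", paste(head(near, 5L), collapse = ", "))
                 else ""))
  }
  out <- vapply(hit, function(i) {
    seq <- circular_substr(record$sequence, f$start[i], f$end[i])
    if (f$strand[i] == "-") revcomp(seq) else seq
  }, character(1))
  names(out) <- paste0(feature_name, if (length(out) > 1L)
    paste0("_copy", seq_along(out)) else "")
  out
}
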