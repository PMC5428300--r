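#' Validate a primer sequence
#' @param sequence IUPAC DNA string (degenerate codes allowed).
#' @param name primer name (used in error messages).
#' @return the uppercased sequence, invisibly on success.
#' @export
validate_primer <- function(sequence, name = "primer") {
  sequence <- toupper(sequence)
  if (!nchar(sequence)) stop(name, ": empty primer sequence")
  bad <- setdiff(unique(str_chars(sequence)), IUPAC_LETTERS)
  if (length(bad))
    stop(sprintf("%s: non-IUPAC character(s) in primer: %s", name,
                 paste(bad, collapse = ", ")))
  invisible(sequence)
}

#' Read a primer table
#'
#' Expects a TSV with columns `name`, `sequence`, `orientation`
#' (forward/reverse) and optionally `marker`. The package ships a default
#' table (`system.file("extdata", "primers.tsv", package = "superbarcode")`)
#' with widely used plant-barcoding primer pairs; sequences there are
#' taken from the published primer literature and can be overridden by
#' supplying your own file.
#'
#' @param path TSV path; defaults to the shipped table.
#' @return a data.frame of validated primers.
#' @export
read_primers <- function(path = system.file("extdata", "primers.tsv",
                                            package = "superbarcode")) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("name", "sequence", "orientation")
  if (!all(req %in% names(tab)))
    stop("primer table must have columns: ", paste(req, collapse = ", "))
  tab$sequence <- toupper(tab$sequence)
  for (i in seq_len(nrow(tab))) validate_primer(tab$sequence[i], tab$name[i])
  if (!all(tab$orientation %in% c("forward", "reverse")))
    stop("primer orientation must be 'forward' or 'reverse'")
  tab
}

# candidate start positions of a primer on a template string, allowing up to
# max_mm mismatches under IUPAC-aware compatibility (degenerate primer codes
# match any compatible base; template N matches only primer N), with an
# exact-match clamp of `clamp` bases at one end. Returns a data.frame of
# start positions and mismatch counts.
primer_sites <- function(template, primer, max_mm, clamp,
                         clamp_side = c("right", "left")) {
  clamp_side <- match.arg(clamp_side)
  p <- nchar(primer)
  if (nchar(template) < p) return(data.frame(start = integer(), mm = integer()))
  hits <- Biostrings::matchPattern(primer, Biostrings::DNAString(template),
                                   max.mismatch = max_mm, fixed = "subject")
  starts <- Biostrings::start(hits)
  if (!length(starts)) return(data.frame(start = integer(), mm = integer()))
  pc <- str_chars(primer)
  clamp_idx <- if (clamp_side == "right") (p - clamp + 1L):p else seq_len(clamp)
  keep <- logical(length(starts))
  mm <- integer(length(starts))
  for (k in seq_along(starts)) {
    tc <- str_chars(substring(template, starts[k], starts[k] + p - 1L))
    compat <- iupac_compatible(pc, tc)
    mm[k] <- sum(!compat)
    keep[k] <- mm[k] <= max_mm && all(compat[clamp_idx])
  }
  data.frame(start = starts[keep], mm = mm[keep])
}

# one orientation of the PCR search on a (possibly doubled) template
pcr_one_strand <- function(template, L, circular, fwd_seq, rev_seq,
                           max_mismatches, max_product, clamp) {
  t2 <- if (circular) paste0(template, template) else template
  rc_rev <- revcomp(rev_seq)
  f <- primer_sites(t2, fwd_seq, max_mismatches, clamp, clamp_side = "right")
  f <- f[f$start <= L, , drop = FALSE]
  if (!nrow(f)) return(NULL)
  r <- primer_sites(t2, rc_rev, max_mismatches, clamp, clamp_side = "left")
  if (!nrow(r)) return(NULL)
  lf <- nchar(fwd_seq); lr <- nchar(rc_rev)
  out <- list()
  for (i in seq_len(nrow(f))) {
    s <- f$start[i]
    for (j in seq_len(nrow(r))) {
      r_end <- r$start[j] + lr - 1L
      plen <- r_end - s + 1L
      if (r$start[j] < s + lf) next
      if (plen > max_product) next
      if (circular && plen > L) next
      if (!circular && r_end > L) next
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = r_end, length_bp = plen,
        sequence = substring(t2, s, r_end),
        fwd_mismatches = f$mm[i], rev_mismatches = r$mm[j])
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' In-silico PCR on an annotated genome
#'
#' Locates all sites where the forward primer matches one strand and the
#' reverse primer matches the opposite strand downstream within
#' `max_product` bp, allowing up to `max_mismatches` per primer under
#' IUPAC-aware base compatibility; the `clamp` 3'-terminal bases of each
#' primer must match exactly (polymerase extension requires a matched 3'
#' end). The amplicon spans from the first base of the forward primer site
#' to the last base of the reverse primer site, inclusive (primer-inclusive
#' product lengths). Circular templates are searched across the origin.
#'
#' @param record a [genome_record()] (or a plain DNA string).
#' @param fwd,rev primer sequences (IUPAC codes allowed).
#' @param marker_name label recorded on the amplicons.
#' @param max_mismatches maximum mismatches per primer (default 3).
#' @param max_product maximum product length in bp (default 5000).
#' @param clamp number of exact-match 3'-terminal bases (default 3).
#' @return a data.frame of amplicons ordered by start: `taxon`, `marker`,
#'   `start`, `end` (1-based closed, on the forward strand; `end < start`
#'   for products spanning the origin), `strand` (the strand the forward
#'   primer annealed to), `length_bp`, `sequence` (in primer orientation),
#'   `fwd_mismatches`, `rev_mismatches`. Empty (zero rows) when no site is
#'   found.
#' @export
in_silico_pcr <- function(record, fwd, rev, marker_name = "marker",
                          max_mismatches = 3L, max_product = 5000L,
                          clamp = 3L) {
  if (is.character(record)) record <- genome_record("template", record,
                                                    circular = FALSE)
  fwd <- validate_primer(fwd, "forward primer")
  rev <- validate_primer(rev, "reverse primer")
  s <- record$sequence
  L <- nchar(s)
  empty <- data.frame(taxon = character(), marker = character(),
                      start = integer(), end = integer(), strand = character(),
                      length_bp = integer(), sequence = character(),
                      fwd_mismatches = integer(), rev_mismatches = integer())

  plus <- pcr_one_strand(s, L, record$circular, fwd, rev,
                         max_mismatches, max_product, clamp)
  if (!is.null(plus)) {
    plus$strand <- "+"
    plus$start_genome <- wrap_pos(plus$start, L)
    plus$end_genome <- wrap_pos(plus$end, L)
  }
  rs <- revcomp(s)
  minus <- pcr_one_strand(rs, L, record$circular, fwd, rev,
                          max_mismatches, max_product, clamp)
  if (!is.null(minus)) {
    minus$strand <- "-"
    # map [start, end] on the reverse strand back to forward coordinates;
    # the amplicon's forward-strand arc runs from L-end+1 to L-start+1
    minus$start_genome <- wrap_pos(L - wrap_pos(minus$end, L) + 1L, L)
    minus$end_genome <- wrap_pos(L - wrap_pos(minus$start, L) + 1L, L)
  }
  res <- rbind(plus, minus)
  if (is.null(res) || !nrow(res)) return(empty)
  out <- data.frame(taxon = record$taxon, marker = marker_name,
                    start = res$start_genome, end = res$end_genome,
                    strand = res$strand, length_bp = res$length_bp,
                    sequence = res$sequence,
                    fwd_mismatches = res$fwd_mismatches,
                    rev_mismatches = res$rev_mismatches)
  out <- out[!duplicated(out[, c("start", "end", "strand")]), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intergenic regions of an annotated genome
#'
#' For each pair of adjacent features (by start coordinate, optionally after
#' dropping the IRb copy of duplicated genes) with a nonzero gap between
#' them, emits the spacer interval named `"upstream -> downstream"` in
#' genome order. On circular records the wrap-around spacer between the last
#' and first feature is included.
#'
#' @param record a [genome_record()] with at least 2 features.
#' @param dedupe_ir when `TRUE` (default) and a quadripartite partition is
#'   attached, features starting inside IRb are dropped first, so only one
#'   IR copy contributes.
#' @return a data.frame: `region`, `upstream`, `downstream`, `start`, `end`,
#'   `length_bp` (closed 1-based; `end < start` marks a wrap-around spacer).
#' @export
list_intergenic_regions <- function(record, dedupe_ir = TRUE) {
  f <- record$features
  f <- f[f$kind != "other", , drop = FALSE]
  L <- nchar(record$sequence)
  if (dedupe_ir && !is.null(record$partition)) {
    irb <- record$partition$irb
    f <- f[!arc_contains(irb[1L], irb[2L], f$start, L), , drop = FALSE]
  }
  if (nrow(f) < 2L)
    return(data.frame(region = character(), upstream = character(),
                      downstream = character(), start = integer(),
                      end = integer(), length_bp = integer()))
  f <- f[order(f$start), , drop = FALSE]
  n <- nrow(f)
  out <- list()
  last_pair <- if (record$circular) n else n - 1L
  for (i in seq_len(last_pair)) {
    j <- if (i == n) 1L else i + 1L
    gap_start <- wrap_pos(f$end[i] + 1L, L)
    gap_end <- wrap_pos(f$start[j] - 1L, L)
    glen <- if (i == n) {
      if (f$start[j] > f$end[i]) f$start[j] - f$end[i] - 1L
      else L - f$end[i] + f$start[j] - 1L
    } else f$start[j] - f$end[i] - 1L
    if (glen <= 0L) next
    out[[length(out) + 1L]] <- data.frame(
      region = paste(f$name[i], "->", f$name[j]),
      upstream = f$name[i], downstream = f$name[j],
      start = gap_start, end = gap_end, length_bp = glen)
  }
  if (!length(out))
    return(data.frame(region = character(), upstream = character(),
                      downstream = character(), start = integer(),
                      end = integer(), length_bp = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-marker SNP matrix and species discriminability
#'
#' Aligns one amplicon per taxon with [align_small()] and counts pairwise
#' SNPs with [pairwise_difference_matrix()] semantics (gap and N columns
#' excluded). Taxa without an amplicon are reported as amplification
#' failures and excluded with a warning.
#'
#' @param amplicons named character vector of amplicon sequences (one per
#'   taxon), or an amplicon data.frame from [in_silico_pcr()] rows bound
#'   over several genomes.
#' @param taxa optional full taxon set; members missing from `amplicons`
#'   are flagged as amplification failures.
#' @param marker_name marker label.
#' @param ... scoring parameters passed to [align_small()].
#' @return an object of class `marker_report`: list with `markers`, `taxa`,
#'   symmetric integer `pairwise_snps`, `unresolved_pairs` (data.frame of
#'   taxon pairs with zero diagnostic SNPs), `amplicon_lengths`, `failed`.
#' @export
marker_snp_matrix <- function(amplicons, taxa = NULL,
                              marker_name = "marker", ...) {
  if (is.data.frame(amplicons)) {
    if (anyDuplicated(amplicons$taxon))
      stop("need exactly one amplicon per taxon; got duplicates for: ",
           paste(unique(amplicons$taxon[duplicated(amplicons$taxon)]),
                 collapse = ", "))
    amplicons <- setNames(amplicons$sequence, amplicons$taxon)
  }
  failed <- character()
  if (!is.null(taxa)) {
    failed <- setdiff(taxa, names(amplicons))
    if (length(failed))
      warning("amplification failure for: ", paste(failed, collapse = ", "),
              " (excluded from the matrix)")
  }
  if (length(amplicons) < 2L) stop("need amplicons for at least 2 taxa")
  aln <- align_small(amplicons, ...)
  dm <- pairwise_difference_matrix(aln, mode = "alignment_length")
  marker_report(marker_name, dm$taxa, dm$counts,
                amplicon_lengths = nchar(amplicons), failed = failed)
}

marker_report <- function(markers, taxa, snps, amplicon_lengths = NULL,
                          failed = character()) {
  stopifnot(isSymmetric(unname(snps)), all(diag(snps) == 0L))
  pairs <- which(upper.tri(snps) & snps == 0L, arr.ind = TRUE)
  unresolved <- data.frame(taxon1 = taxa[pairs[, 1L]],
                           taxon2 = taxa[pairs[, 2L]])
  structure(list(markers = markers, taxa = taxa, pairwise_snps = snps,
                 unresolved_pairs = unresolved,
                 amplicon_lengths = amplicon_lengths, failed = failed),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("<marker_report> %s: %d taxa, SNPs %d-%d, %d unresolved pair(s)\n",
              paste(x$markers, collapse = "+"), length(x$taxa),
              min(x$pairwise_snps[upper.tri(x$pairwise_snps)]),
              max(x$pairwise_snps), nrow(x$unresolved_pairs)))
  invisible(x)
}

#' Combine marker reports
#'
#' Sums the pairwise SNP matrices elementwise over the same taxon set;
#' a pair stays unresolved only when every combined marker leaves it
#' unresolved (zero summed SNPs).
#'
#' @param ... `marker_report` objects (or one list of them).
#' @return a combined `marker_report`.
#' @export
combine_markers <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "marker_report"))
    reports <- reports[[1L]]
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "marker_report")))
  taxa <- reports[[1L]]$taxa
  for (r in reports[-1L]) {
    if (!setequal(r$taxa, taxa))
      stop("marker reports cover different taxon sets")
  }
  snps <- matrix(0L, length(taxa), length(taxa),
                 dimnames = list(taxa, taxa))
  for (r in reports) snps <- snps + r$pairwise_snps[taxa, taxa]
  marker_report(unlist(lapply(reports, `[[`, "markers")), taxa, snps)
}
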