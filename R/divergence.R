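#' Pairwise base-difference matrix over an alignment
#'
#' For each pair of rows, counts the columns where both taxa carry an
#' unambiguous residue (A/C/G/T) and the residues differ; columns with a gap
#' or N in either row never contribute. Percentages divide by the full
#' alignment length (`"alignment_length"`, the default, which matches the
#' scale of published plastome difference tables) or by the per-pair count
#' of columns where both rows are unambiguous (`"pairwise_ungapped"`).
#'
#' @param x an `msa` (or character matrix).
#' @param mode denominator mode.
#' @return an object of class `diff_matrix`: list with `taxa`, symmetric
#'   integer `counts`, `percents` (rounded to 2 decimals), `denominator`
#'   (scalar or per-pair matrix) and `denominator_mode`.
#' @export
pairwise_difference_matrix <- function(x, mode = c("alignment_length",
                                                   "pairwise_ungapped")) {
  mode <- match.arg(mode)
  mat <- if (inherits(x, "msa")) msa_matrix(x) else x
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 taxa")
  taxa <- rownames(mat) %||% paste0("seq", seq_len(n))
  ok <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  counts <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  denom <- matrix(NA_integer_, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      d <- sum(both & (mat[i, ] != mat[j, ]))
      counts[i, j] <- counts[j, i] <- as.integer(d)
      denom[i, j] <- denom[j, i] <- sum(both)
    }
  }
  diag(denom) <- 0L
  if (mode == "alignment_length") {
    percents <- round_fixed(100 * counts / ncol(mat), 2L)
    denominator <- ncol(mat)
  } else {
    percents <- matrix(0, n, n, dimnames = list(taxa, taxa))
    off <- upper.tri(denom) | lower.tri(denom)
    percents[off] <- round_fixed(100 * counts[off] / denom[off], 2L)
    denominator <- denom
  }
  structure(list(taxa = taxa, counts = counts, percents = percents,
                 denominator = denominator, denominator_mode = mode),
            class = "diff_matrix")
}

#' @export
print.diff_matrix <- function(x, ...) {
  cat(sprintf("<diff_matrix> %d taxa, %d-%d differences (denominator: %s)\n",
              length(x$taxa), min(x$counts[upper.tri(x$counts)]),
              max(x$counts), x$denominator_mode))
  print(x$counts)
  invisible(x)
}

#' Count indel events in an alignment region
#'
#' An indel event is a maximal run of consecutive columns sharing an
#' identical gap pattern (the same nonempty subset of rows gapped); adjacent
#' runs with different gap patterns count as distinct events.
#'
#' @param x an `msa` (or character matrix).
#' @param region optional closed column interval `c(start, end)`.
#' @return integer number of indel events.
#' @export
count_indel_events <- function(x, region = NULL) {
  mat <- if (inherits(x, "msa")) msa_matrix(x) else x
  if (!is.null(region)) {
    if (region[1L] < 1L || region[2L] > ncol(mat) || region[1L] > region[2L])
      stop("region out of range")
    mat <- mat[, region[1L]:region[2L], drop = FALSE]
  }
  gap <- mat == "-"
  if (!any(gap)) return(0L)
  n <- nrow(mat)
  # encode each column's gap pattern as a number (0 = no gaps)
  if (n <= 50L) {
    pattern <- as.vector(2^(seq_len(n) - 1L) %*% gap)
  } else {
    pattern <- apply(gap, 2L, function(g) paste(which(g), collapse = ","))
  }
  r <- rle(pattern)
  sum(r$values != if (is.numeric(r$values)) 0 else "")
}

#' Divergence summary for one alignment region
#'
#' @param x an `msa`.
#' @param region closed column interval `c(start, end)`.
#' @param name region label (gene symbol or `"geneA -> geneB"`).
#' @return a one-row data.frame: `region`, `length_bp` (alignment length of
#'   the region), `variable_sites`, `indel_events`, `pid_percent` (percent
#'   of columns identical across all rows, gaps counting as non-identical,
#'   rounded to 1 decimal).
#' @export
region_stats <- function(x, region, name = "region") {
  if (region[1L] < 1L || region[2L] > x$length || region[1L] > region[2L])
    stop(sprintf("empty or out-of-range region [%s, %s]",
                 region[1L], region[2L]))
  sub <- msa_slice(x, region)
  cc <- classify_columns(sub)
  len <- sub$length
  data.frame(region = name,
             length_bp = len,
             variable_sites = sum(cc$variable),
             indel_events = count_indel_events(sub),
             pid_percent = round_fixed(100 * sum(cc$identical) / len, 1L))
}

#' Divergence summaries for a set of named regions
#' @param x an `msa`.
#' @param regions named list of closed column intervals.
#' @return a data.frame with one row per region.
#' @export
region_stats_table <- function(x, regions) {
  stopifnot(length(regions) > 0L, !is.null(names(regions)))
  do.call(rbind, lapply(names(regions), function(nm)
    region_stats(x, regions[[nm]], nm)))
}

#' Rank regions by divergence
#'
#' Orders most-divergent first: ascending percent-identical sites, ties
#' broken by more variable sites, then by region name.
#'
#' @param stats a data.frame as returned by [region_stats_table()].
#' @param top_n number of regions to return.
#' @return the top `top_n` rows, most divergent first.
#' @export
rank_regions <- function(stats, top_n = nrow(stats)) {
  if (!nrow(stats)) stop("empty region table")
  if (top_n <= 0L) stop("top_n must be positive")
  ord <- order(stats$pid_percent, -stats$variable_sites, stats$region)
  out <- stats[ord, , drop = FALSE][seq_len(min(top_n, nrow(stats))), ,
                                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count gene regions whose alignments are identical across all taxa
#'
#' A region counts as identical when it has zero variable sites and zero
#' indel events.
#'
#' @param x an `msa`.
#' @param gene_regions named list of closed column intervals.
#' @return integer count.
#' @export
count_identical_gene_alignments <- function(x, gene_regions) {
  stats <- region_stats_table(x, gene_regions)
  sum(stats$variable_sites == 0L & stats$indel_events == 0L)
}
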