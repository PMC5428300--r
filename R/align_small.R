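# shared k-mer count between two sequences (guide-order similarity)
kmer_similarity <- function(a, b, k = 6L) {
  ka <- substring(a, seq_len(max(nchar(a) - k + 1L, 0L)),
                  seq_len(max(nchar(a) - k + 1L, 0L)) + k - 1L)
  kb <- substring(b, seq_len(max(nchar(b) - k + 1L, 0L)),
                  seq_len(max(nchar(b) - k + 1L, 0L)) + k - 1L)
  ta <- table(ka)
  tb <- table(kb)
  shared <- intersect(names(ta), names(tb))
  sum(pmin(ta[shared], tb[shared]))
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment of two sequences. A gap of length g
#' costs `gap_open + g * gap_extend`; N never counts as a match. Traceback
#' ties are resolved deterministically (substitution preferred over a gap in
#' the second sequence, preferred over a gap in the first).
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return a list with gapped strings `a`, `b` and the optimal `score`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -2,
                       gap_open = -5, gap_extend = -1) {
  if (!nchar(a) || !nchar(b)) stop("cannot align an empty sequence")
  nw_align_cpp(toupper(a), toupper(b), match, mismatch, gap_open, gap_extend)
}

# merge a new pairwise alignment (center_pair vs new_pair) into the master
# alignment, whose rows include the (gapped) center: "once a gap, always a
# gap". Returns the master rows (char vectors) plus the new row appended.
merge_into_master <- function(master, center_row, center_pair, new_pair) {
  mc <- master[[center_row]]
  pc <- str_chars(center_pair)
  pn <- str_chars(new_pair)
  n_master <- length(mc)
  n_pair <- length(pc)
  # output column source: >0 = master column, 0 = new insertion column
  src_master <- integer(0)
  src_pair <- integer(0)
  i <- 1L; j <- 1L
  while (i <= n_master || j <= n_pair) {
    if (i <= n_master && mc[i] == "-") {
      src_master <- c(src_master, i); src_pair <- c(src_pair, 0L); i <- i + 1L
    } else if (j <= n_pair && pc[j] == "-") {
      src_master <- c(src_master, 0L); src_pair <- c(src_pair, j); j <- j + 1L
    } else {
      # both are the same residue of the center sequence
      src_master <- c(src_master, i); src_pair <- c(src_pair, j)
      i <- i + 1L; j <- j + 1L
    }
  }
  out <- lapply(master, function(row) {
    r <- rep("-", length(src_master))
    r[src_master > 0L] <- row[src_master[src_master > 0L]]
    r
  })
  new_row <- rep("-", length(src_pair))
  new_row[src_pair > 0L] <- pn[src_pair[src_pair > 0L]]
  out[[length(out) + 1L]] <- new_row
  out
}

#' Multiple alignment of a small set of sequences
#'
#' Center-star progressive alignment for marker-scale inputs (each sequence
#' at most 10 kb): the center is the sequence with the largest total shared
#' k-mer count, the remaining sequences are merged in decreasing k-mer
#' similarity to the center (ties by input order), each via an affine-gap
#' pairwise alignment against the ungapped center, with gaps propagated into
#' the growing master alignment ("once a gap, always a gap"). Deterministic
#' given inputs and scores. This replaces an external MSA tool only at
#' marker scale; genome-scale alignments remain an input to the package.
#'
#' @param seqs named character vector of >= 2 DNA sequences.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return an [msa()] with rows in input order; the summed pairwise
#'   alignment scores against the center are attached as `attr(, "score")`
#'   (for two sequences this is the optimal pairwise score).
#' @export
align_small <- function(seqs, match = 1, mismatch = -2,
                        gap_open = -5, gap_extend = -1) {
  if (length(seqs) < 2L) stop("align_small needs at least 2 sequences")
  if (any(!nchar(seqs))) stop("cannot align an empty sequence")
  if (any(nchar(seqs) > 10000L))
    stop("align_small is for marker-scale sequences (<= 10 kb)")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  n <- length(seqs)

  if (n == 2L) {
    al <- align_pair(seqs[[1L]], seqs[[2L]], match, mismatch,
                     gap_open, gap_extend)
    out <- msa(setNames(c(al$a, al$b), names(seqs)))
    attr(out, "score") <- al$score
    return(out)
  }

  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sim[i, j] <- sim[j, i] <- kmer_similarity(seqs[[i]], seqs[[j]])
    }
  }
  center <- which.max(rowSums(sim))
  others <- setdiff(seq_len(n), center)
  others <- others[order(-sim[center, others], others)]

  master <- list(str_chars(seqs[[center]]))
  order_added <- center
  total_score <- 0
  for (k in others) {
    al <- align_pair(seqs[[center]], seqs[[k]], match, mismatch,
                     gap_open, gap_extend)
    total_score <- total_score + al$score
    master <- merge_into_master(master, 1L, al$a, al$b)
    order_added <- c(order_added, k)
  }
  rows <- vapply(master, paste, character(1), collapse = "")
  names(rows) <- names(seqs)[order_added]
  out <- msa(rows[names(seqs)])  # restore input order
  attr(out, "score") <- total_score
  out
}
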