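#' Construct a multiple sequence alignment object
#'
#' @param rows named character vector of equal-length gapped sequences over
#'   `{A,C,G,T,N,-}` (uppercased on ingest).
#' @return an object of class `msa` with elements `taxa`, `rows`, `length`.
#' @export
msa <- function(rows) {
  if (is.null(names(rows)) || any(names(rows) == ""))
    names(rows) <- paste0("seq", seq_along(rows))
  if (length(rows) < 2L)
    stop("an alignment needs at least 2 sequences (got ",
         length(rows), ")")
  rows <- toupper(rows)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- names(rows)[lens != lens[1L]][1L]
    stop(sprintf("ragged alignment: row '%s' has %d columns, expected %d",
                 bad, nchar(rows[bad]), lens[1L]))
  }
  chars <- unique(str_chars(paste(rows, collapse = "")))
  extra <- setdiff(chars, c("A", "C", "G", "T", "N", "-"))
  if (length(extra)) {
    amb <- intersect(extra, IUPAC_LETTERS)
    if (length(setdiff(extra, amb)))
      stop("alignment contains non-nucleotide characters: ",
           paste(setdiff(extra, amb), collapse = ", "))
    warning("ambiguous bases (", paste(amb, collapse = ","),
            ") normalised to N")
    rows <- vapply(rows, function(r)
      chartr(paste(amb, collapse = ""),
             strrep("N", length(amb)), r), character(1))
  }
  structure(list(taxa = names(rows), rows = rows, length = lens[[1L]]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d taxa x %s columns\n", length(x$taxa),
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Read an aligned FASTA file
#' @param path aligned-FASTA path (>= 2 rows of equal length).
#' @return an [msa()] with taxa in file order.
#' @export
read_alignment <- function(path) msa(read_fasta(path))

#' Write an alignment to aligned FASTA
#' @param x an `msa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) write_fasta(x$rows, path)

# character matrix view (taxa x columns); cached on the object by callers
msa_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$rows, "", fixed = TRUE))
  rownames(m) <- x$taxa
  m
}

#' Remove gaps from one alignment row
#' @param x an `msa`.
#' @param taxon taxon label.
#' @return the ungapped sequence string.
#' @export
degap <- function(x, taxon) gsub("-", "", x$rows[[taxon]], fixed = TRUE)

# per-column base counts used by several operations
column_profile <- function(mat) {
  list(A = colSums(mat == "A"), C = colSums(mat == "C"),
       G = colSums(mat == "G"), T = colSums(mat == "T"),
       N = colSums(mat == "N"), gap = colSums(mat == "-"),
       n = nrow(mat))
}

#' Classify alignment columns
#'
#' Every column gets a primary state with precedence
#' `variable > gap_containing > ambiguous > invariant`:
#' *variable* means at least two distinct unambiguous residues (A/C/G/T)
#' occur in the column (N never creates variability); *gap_containing* means
#' at least one `-`; *ambiguous* means no variability and no gap but at least
#' one N. A column is *identical* only when all rows carry the same
#' unambiguous residue (no gaps, no N) — the basis of the percent-identical
#' statistic. A column may simultaneously be variable and contain gaps; the
#' logical columns of the result record each attribute independently of the
#' primary state.
#'
#' @param x an `msa` (or a character matrix).
#' @return a data.frame with one row per column: `index`, `state`,
#'   `variable`, `gap_containing`, `ambiguous`, `identical`; the count of
#'   each primary state is attached as `attr(, "summary")`.
#' @export
classify_columns <- function(x) {
  mat <- if (inherits(x, "msa")) msa_matrix(x) else x
  p <- column_profile(mat)
  n_states <- (p$A > 0) + (p$C > 0) + (p$G > 0) + (p$T > 0)
  variable <- n_states >= 2L
  gapc <- p$gap > 0L
  hasN <- p$N > 0L
  identical <- pmax(p$A, p$C, p$G, p$T) == p$n
  state <- rep("invariant", ncol(mat))
  state[hasN & !gapc & !variable] <- "ambiguous"
  state[gapc & !variable] <- "gap_containing"
  state[variable] <- "variable"
  out <- data.frame(index = seq_len(ncol(mat)), state = state,
                    variable = variable, gap_containing = gapc,
                    ambiguous = hasN, identical = identical)
  attr(out, "summary") <- c(
    invariant = sum(state == "invariant"),
    variable = sum(state == "variable"),
    gap_containing = sum(state == "gap_containing"),
    ambiguous = sum(state == "ambiguous"),
    identical = sum(identical))
  out
}

#' Column <-> ungapped coordinate map for one alignment row
#'
#' @param x an `msa`.
#' @param taxon taxon label.
#' @return a list with `col_of_pos` (for each ungapped position, its
#'   alignment column) and `pos_of_col` (for each column, the ungapped
#'   position, `NA` at gaps); both 1-based.
#' @export
coordinate_map <- function(x, taxon) {
  if (!taxon %in% x$taxa) stop("unknown taxon: ", taxon)
  chars <- str_chars(x$rows[[taxon]])
  nongap <- chars != "-"
  pos_of_col <- ifelse(nongap, cumsum(nongap), NA_integer_)
  list(col_of_pos = which(nongap), pos_of_col = as.integer(pos_of_col))
}

#' Project an ungapped interval onto alignment columns
#'
#' Maps a closed 1-based interval on a taxon's ungapped sequence to the
#' smallest column window containing all its residues; gap columns of other
#' taxa inside the window are retained.
#'
#' @param map a [coordinate_map()] (or an `msa`, in which case `taxon` is
#'   required and the map is computed).
#' @param taxon taxon label (when `map` is an `msa`).
#' @param start,end closed 1-based interval on the ungapped sequence.
#' @return integer vector `c(start_col, end_col)` (closed).
#' @export
project_interval <- function(map, taxon = NULL, start, end) {
  if (inherits(map, "msa")) map <- coordinate_map(map, taxon)
  np <- length(map$col_of_pos)
  if (start < 1L || end > np || start > end)
    stop(sprintf("interval [%d, %d] out of range for ungapped length %d",
                 start, end, np))
  c(map$col_of_pos[start], map$col_of_pos[end])
}

#' Subset alignment columns
#' @param x an `msa`.
#' @param cols integer vector of columns to keep (or a closed `c(start,end)`
#'   pair when `as_range = TRUE`).
#' @param as_range interpret `cols` as a closed interval.
#' @return an `msa` over the selected columns.
#' @export
msa_slice <- function(x, cols, as_range = length(cols) == 2L) {
  if (as_range) {
    if (cols[1L] < 1L || cols[2L] > x$length || cols[1L] > cols[2L])
      stop(sprintf("column interval [%d, %d] out of range (length %d)",
                   cols[1L], cols[2L], x$length))
    rows <- substring(x$rows, cols[1L], cols[2L])
    names(rows) <- x$taxa
    return(msa(rows))
  }
  mat <- msa_matrix(x)[, cols, drop = FALSE]
  msa(setNames(apply(mat, 1L, paste, collapse = ""), x$taxa))
}

#' Drop a set of columns from an alignment
#' @param x an `msa`.
#' @param drop integer vector of column indices to remove.
#' @return an `msa` without the given columns.
#' @export
mask_columns <- function(x, drop) {
  if (!length(drop)) return(x)
  drop <- unique(as.integer(drop))
  if (any(drop < 1L | drop > x$length)) stop("mask columns out of range")
  msa_slice(x, setdiff(seq_len(x$length), drop), as_range = FALSE)
}
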