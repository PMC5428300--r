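#' @useDynLib superbarcode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rgeom rmultinom rpois runif setNames
#' @importFrom utils read.delim write.table head combn
NULL

# IUPAC nucleotide codes -> set of unambiguous bases each code stands for
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

# complement table covering the full degenerate alphabet plus gap
COMP_FROM <- "ACGTRYSWKMBDHVN-"
COMP_TO   <- "TGCAYRSWMKVHDBN-"

#' Reverse complement of a DNA string
#'
#' Handles the full 15-letter IUPAC alphabet plus gaps; case is preserved
#' as uppercase (inputs are normalised to uppercase elsewhere on ingest).
#'
#' @param x a single DNA string.
#' @return the reverse complement as a single string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr(COMP_FROM, COMP_TO, toupper(x))
  intToUtf8(rev(utf8ToInt(comp)))
}

# reverse complement of a character vector of single bases
revcomp_chars <- function(v) {
  rev(chartr(COMP_FROM, COMP_TO, paste(v, collapse = "")) |>
        strsplit("") |> unlist(use.names = FALSE))
}

# split one string into a character vector of single characters
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# TRUE where template base (A/C/G/T/N) is compatible with the IUPAC primer
# code: the template base must be one of the bases the code stands for.
# A template N is compatible only with a primer N (conservative).
iupac_compatible <- function(primer_chars, template_chars) {
  ok <- logical(length(primer_chars))
  for (i in seq_along(primer_chars)) {
    set <- IUPAC_SETS[[primer_chars[i]]]
    ok[i] <- if (template_chars[i] == "N") primer_chars[i] == "N"
             else template_chars[i] %in% set
  }
  ok
}

# normalise a raw sequence string: uppercase; IUPAC ambiguity codes other
# than N become N (with a warning); anything unrecognised is an error.
normalize_sequence <- function(x, what = "sequence") {
  x <- toupper(x)
  chars <- str_chars(x)
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    amb <- chars[bad] %in% IUPAC_LETTERS
    if (any(!amb)) {
      stop(sprintf("%s contains non-nucleotide characters: %s", what,
                   paste(unique(chars[bad][!amb]), collapse = ", ")))
    }
    warning(sprintf("%s: %d ambiguous base(s) (%s) normalised to N", what,
                    sum(bad), paste(unique(chars[bad]), collapse = ",")))
    chars[bad] <- "N"
    x <- paste(chars, collapse = "")
  }
  x
}

# fixed-decimal rounding helper (round half away from zero, like printed tables)
round_fixed <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
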