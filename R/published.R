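#' Published pairwise difference counts for the nine Echinacea plastomes
#'
#' Returns the published whole-plastome pairwise base-difference counts
#' among the nine Echinacea species as a symmetric integer matrix, shipped
#' with the package as a plain-text table. The corresponding percentages in
#' the source table are on the scale of the 151,913 bp alignment, so
#' `echinacea_difference_counts() / 151913` gives p-distances suitable for
#' [nj_tree()].
#'
#' @return symmetric integer matrix with species epithets as dimnames.
#' @export
echinacea_difference_counts <- function() {
  path <- system.file("extdata", "echinacea_plastome_differences.tsv",
                      package = "superbarcode")
  tab <- read.delim(path, comment.char = "#", row.names = 1L,
                    check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "integer"
  stopifnot(isSymmetric(unname(m)), all(diag(m) == 0L))
  m
}
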