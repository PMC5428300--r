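# Independent oracles and fixture builders used across the test files.

# naive per-column recount of pairwise differences: deliberately simple and
# independent of the package implementation
naive_diff_count <- function(mat) {
  n <- nrow(mat)
  counts <- matrix(0L, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- 0L
      for (col in seq_len(ncol(mat))) {
        a <- mat[i, col]; b <- mat[j, col]
        if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T") &&
            a != b) d <- d + 1L
      }
      counts[i, j] <- counts[j, i] <- d
    }
  }
  counts
}

# random gapped alignment as an msa
random_alignment <- function(n_taxa, n_cols, gap_prob = 0.05,
                             n_prob = 0.02) {
  states <- c("A", "C", "G", "T")
  rows <- replicate(n_taxa, {
    r <- sample(states, n_cols, replace = TRUE)
    r[runif(n_cols) < gap_prob] <- "-"
    r[runif(n_cols) < n_prob] <- "N"
    paste(r, collapse = "")
  })
  names(rows) <- paste0("t", seq_len(n_taxa))
  msa(rows)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# plain three-matrix dynamic program in R (independent of the C++ code)
brute_force_score_dp <- function(a, b, match = 1, mismatch = -2,
                                 open = -5, extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- open + i * extend
  for (j in seq_len(m)) Y[1, j + 1] <- open + j * extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + open + extend,
                             X[i, j + 1] + extend,
                             Y[i, j + 1] + open + extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + open + extend,
                             Y[i + 1, j] + extend,
                             X[i + 1, j] + open + extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive enumeration of all global alignments for tiny sequences:
# the strongest form of the oracle (exponential; keep inputs <= ~8 bp)
enumerate_align_score <- function(a, b, match = 1, mismatch = -2,
                                  open = -5, extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  score_alignment <- function(pa, pb) {
    s <- 0
    run_a <- FALSE; run_b <- FALSE
    for (k in seq_along(pa)) {
      if (pa[k] == "-") {
        s <- s + extend + if (run_a) 0 else open
        run_a <- TRUE; run_b <- FALSE
      } else if (pb[k] == "-") {
        s <- s + extend + if (run_b) 0 else open
        run_b <- TRUE; run_a <- FALSE
      } else {
        s <- s + if (pa[k] == pb[k] && pa[k] != "N") match else mismatch
        run_a <- FALSE; run_b <- FALSE
      }
    }
    s
  }
  best <- -Inf
  walk <- function(i, j, pa, pb) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_alignment(pa, pb))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      walk(i + 1, j + 1, c(pa, av[i]), c(pb, bv[j]))
    if (i <= length(av)) walk(i + 1, j, c(pa, av[i]), c(pb, "-"))
    if (j <= length(bv)) walk(i, j + 1, c(pa, "-"), c(pb, bv[j]))
  }
  walk(1, 1, character(), character())
  best
}

# minimal GenBank flat-file text built in code
make_genbank_text <- function(sequence, organism = "Testus plantus",
                              circular = TRUE, features = NULL) {
  len <- nchar(sequence)
  lines <- c(
    sprintf("LOCUS       TEST%06d %d bp    DNA     %s PLN 01-JAN-2020",
            len, len, if (circular) "circular" else "linear"),
    "DEFINITION  test record.",
    "SOURCE      test",
    sprintf("  ORGANISM  %s", organism),
    "FEATURES             Location/Qualifiers")
  if (!is.null(features)) lines <- c(lines, features)
  lines <- c(lines, "ORIGIN")
  for (s in seq(1, len, by = 60)) {
    chunk <- substring(sequence, s, min(s + 59, len))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s,
                              paste(tolower(groups), collapse = " ")))
  }
  c(lines, "//")
}

# small fast simulation configuration shared by several test files
small_sim_config <- function(seed, ...) {
  sim_config(genome_length = 60000L, ir_length = 12000L, ssc_length = 8000L,
             seed = seed, ...)
}
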