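#' Construct an annotated plastome record
#'
#' The central container of the package: one (usually circular) chloroplast
#' genome with its gene annotation and, once detected, its quadripartite
#' LSC/IRa/SSC/IRb partition. All coordinates are 1-based closed intervals
#' on the forward strand, the native GenBank convention.
#'
#' @param taxon taxon label.
#' @param sequence DNA string; uppercased, ambiguity codes other than N
#'   normalised to N with a warning.
#' @param circular logical; circular records allow origin-spanning features
#'   and rotation-invariant repeat search.
#' @param features a data.frame with columns `name`, `kind` (one of
#'   `"protein_coding"`, `"tRNA"`, `"rRNA"`, `"other"`), `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `intron_count`, and logical `spans_origin`.
#'   Origin-spanning features have `end < start`.
#' @param partition optional quadripartite partition as returned by
#'   [detect_inverted_repeats()].
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(taxon, sequence, circular = TRUE,
                          features = empty_features(), partition = NULL) {
  sequence <- normalize_sequence(sequence, what = sprintf("sequence of %s", taxon))
  len <- nchar(sequence)
  if (len == 0L) stop("sequence must be non-empty")
  features <- as.data.frame(features)
  req <- c("name", "kind", "start", "end", "strand", "intron_count")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols))
    stop("features table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"spans_origin" %in% names(features))
    features$spans_origin <- features$end < features$start
  if (nrow(features)) {
    bad <- features$start < 1 | features$end < 1 |
      features$start > len | features$end > len
    if (any(bad)) {
      stop(sprintf("feature '%s' has coordinates outside [1, %d]",
                   features$name[which(bad)[1L]], len))
    }
    if (any(features$end < features$start & !features$spans_origin)) {
      i <- which(features$end < features$start & !features$spans_origin)[1L]
      stop(sprintf("feature '%s' has end < start but is not flagged origin-spanning",
                   features$name[i]))
    }
    if (any(features$spans_origin) && !circular)
      stop("origin-spanning features require a circular record")
    key <- paste(features$name, features$start, features$end, features$strand)
    if (anyDuplicated(key))
      stop("duplicate feature (same name, start, end, strand): ",
           features$name[which(duplicated(key))[1L]])
    stopifnot(all(features$kind %in% c("protein_coding", "tRNA", "rRNA", "other")),
              all(features$strand %in% c("+", "-")),
              all(features$intron_count >= 0))
  }
  structure(list(taxon = taxon, sequence = sequence, circular = circular,
                 features = features, partition = partition),
            class = "genome_record")
}

empty_features <- function() {
  data.frame(name = character(), kind = character(), start = integer(),
             end = integer(), strand = character(), intron_count = integer(),
             spans_origin = logical())
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, %d features%s\n",
              x$taxon, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features),
              if (is.null(x$partition)) "" else
                sprintf(", IR %d bp", x$partition$ir_length)))
  invisible(x)
}

#' Feature length in bp, origin-spanning aware
#' @param record a `genome_record`.
#' @param i feature row index (vectorised).
#' @return integer vector of lengths.
#' @export
feature_length <- function(record, i = seq_len(nrow(record$features))) {
  f <- record$features[i, , drop = FALSE]
  len <- nchar(record$sequence)
  ifelse(f$spans_origin, len - f$start + 1L + f$end, f$end - f$start + 1L)
}

# ---- GenBank flat-file parsing ------------------------------------------

# parse a GenBank location string into segments + strand
parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("^order\\(", loc)) loc <- sub("^order\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  segs <- lapply(parts, function(p) {
    p <- trimws(p)
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else {
      se <- rep(as.integer(p), 2L)
    }
    se
  })
  list(segments = segs, strand = strand)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Parses the LOCUS line (length, circular/linear), ORGANISM, the FEATURES
#' table (`CDS`, `tRNA`, `rRNA`, and `gene` keys) and the ORIGIN sequence
#' block. CDS features map to kind `"protein_coding"`; `gene` features whose
#' name is not covered by a CDS/tRNA/rRNA feature are kept with kind
#' `"other"`. Multi-segment `join()` locations contribute
#' `intron_count = segments - 1`; on circular records a final/first segment
#' pair that wraps the origin is treated as one origin-spanning exon.
#'
#' @param path path to a `.gb`/`.gbk` file containing one record.
#' @param taxon_label optional override for the ORGANISM-derived label.
#' @return a [genome_record()].
#' @export
read_genbank <- function(path, taxon_label = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)

  circular <- any(grepl("^LOCUS .*circular", lines[1L], ignore.case = TRUE))
  organism <- NA_character_
  org_i <- grep("^ {0,12}ORGANISM", lines)
  if (length(org_i))
    organism <- trimws(sub("^ *ORGANISM *", "", lines[org_i[1L]]))

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  if (!length(origin_start))
    stop("GenBank record has no ORIGIN sequence block: ", path)

  # sequence block
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1L] else length(lines) + 1L
  seq_lines <- lines[(origin_start[1L] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("GenBank ORIGIN block contains no sequence: ", path)

  feats <- empty_features()
  if (length(feat_start) && feat_start[1L] < origin_start[1L]) {
    block <- lines[(feat_start[1L] + 1L):(origin_start[1L] - 1L)]
    # feature keys start at column 6; qualifier/continuation lines at column 22
    is_key <- grepl("^ {5}\\S", block)
    idx <- which(is_key)
    recs <- list()
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      key <- sub("^ {5}(\\S+).*", "\\1", block[from])
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      body <- paste(trimws(substring(block[from:to], 22L)), collapse = "\n")
      first <- trimws(substring(block[from], 22L))
      cont <- character()
      j <- from + 1L
      while (j <= to && !grepl("^ {21}/", block[j])) {
        cont <- c(cont, trimws(block[j])); j <- j + 1L
      }
      locstr <- paste0(first, paste(cont, collapse = ""))
      # qualifiers
      quals <- regmatches(body, gregexpr('/(gene|product|label)="?[^"\n/]+"?', body))[[1L]]
      getq <- function(q) {
        hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('"', "", sub(paste0("^/", q, "="), "", hit[1L]))
      }
      nm <- getq("gene")
      if (is.na(nm)) nm <- getq("label")
      if (is.na(nm)) nm <- getq("product")
      if (is.na(nm)) nm <- sprintf("%s_%d", key, k)
      loc <- parse_location(locstr)
      segs <- loc$segments
      starts <- vapply(segs, `[`, integer(1), 1L)
      ends <- vapply(segs, `[`, integer(1), 2L)
      spans_origin <- FALSE
      n_seg <- length(segs)
      if (circular && n_seg >= 2L &&
          ends[n_seg] < starts[1L]) {
        # join wrapping the origin: treated as one contiguous exon
        spans_origin <- TRUE
        n_seg <- n_seg - 1L
      }
      recs[[length(recs) + 1L]] <- data.frame(
        name = nm,
        kind = switch(key, CDS = "protein_coding", tRNA = "tRNA",
                      rRNA = "rRNA", gene = "other"),
        start = starts[1L], end = ends[length(ends)],
        strand = loc$strand, intron_count = n_seg - 1L,
        spans_origin = spans_origin)
    }
    if (length(recs)) {
      feats <- do.call(rbind, recs)
      # a bare 'gene' entry duplicating a typed feature by name is redundant
      typed <- feats$name[feats$kind != "other"]
      feats <- feats[!(feats$kind == "other" & feats$name %in% typed), ,
                     drop = FALSE]
      feats <- feats[!duplicated(paste(feats$name, feats$start, feats$end,
                                       feats$strand)), , drop = FALSE]
      rownames(feats) <- NULL
    }
  }

  len <- nchar(sequence)
  if (nrow(feats) && any(feats$start > len | feats$end > len)) {
    i <- which(feats$start > len | feats$end > len)[1L]
    stop(sprintf("feature '%s' (%d..%d) exceeds sequence length %d in %s",
                 feats$name[i], feats$start[i], feats$end[i], len, path))
  }

  genome_record(taxon = taxon_label %||% organism %||% basename(path),
                sequence = sequence, circular = circular, features = feats)
}

#' Write a genome record as a minimal GenBank flat file
#'
#' Emits LOCUS/ORGANISM headers, the feature table (CDS/tRNA/rRNA keys with
#' `/gene=` qualifiers) and the ORIGIN block; sufficient for round-tripping
#' through [read_genbank()].
#'
#' @param record a `genome_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  len <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     gsub("\\s+", "_", record$taxon), len,
                     if (record$circular) "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s chloroplast genome.", record$taxon), con)
  writeLines(c("SOURCE      synthetic",
               sprintf("  ORGANISM  %s", record$taxon),
               "FEATURES             Location/Qualifiers"), con)
  if (nrow(record$features)) {
    f <- record$features
    for (i in seq_len(nrow(f))) {
      key <- switch(f$kind[i], protein_coding = "CDS", tRNA = "tRNA",
                    rRNA = "rRNA", other = "gene")
      loc <- if (f$spans_origin[i])
        sprintf("join(%d..%d,1..%d)", f$start[i], len, f$end[i])
      else sprintf("%d..%d", f$start[i], f$end[i])
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", key, loc), con)
      writeLines(sprintf('                     /gene="%s"', f$name[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  starts <- seq(1L, len, by = 60L)
  for (s in starts) {
    chunk <- substring(record$sequence, s, min(s + 59L, len))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, paste(tolower(groups), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

# ---- FASTA I/O (Biostrings-backed) --------------------------------------

#' Read sequences from a FASTA file
#' @param path FASTA file (may contain `-` gap characters).
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
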