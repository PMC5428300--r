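#' Simulation configuration
#'
#' Defaults emulate a set of nine congeneric plastomes: ~152 kb circular
#' genomes with quadripartite structure (two 25 kb inverted repeats, 18 kb
#' SSC), pairwise divergence between 0.1% and 0.6%, protein-coding/tRNA/rRNA
#' annotation with the rRNA operon duplicated in the IR, substitution rates
#' elevated in intergenic spacers, short geometric-length indels restricted
#' to single-copy spacers, and two barcode markers delimited by conserved
#' primer-binding sites (a trnH-psbA-style spacer marker of ~500 bp and an
#' rbcL-style coding marker of ~599 bp).
#'
#' @param n_taxa number of leaves (default 9).
#' @param genome_length total root genome length in bp (default 152,000).
#' @param ir_length inverted repeat length (default 25,000).
#' @param ssc_length small single-copy length (default 18,000).
#' @param divergence range of expected pairwise substitution fraction,
#'   genome-wide (default 0.001-0.006).
#' @param gc root G+C fraction (default 0.375).
#' @param intergenic_multiplier substitution-rate multiplier for spacers
#'   relative to genes (default 4; multipliers are normalised to mean 1 over
#'   the genome so the divergence range is genome-wide).
#' @param spacer_multipliers optional named numeric vector of extra rate
#'   multipliers for individual spacers (names as in the layout, e.g.
#'   `"geneA -> geneB"`).
#' @param indels_per_branch expected indel events on a branch of average
#'   length (default 2; scaled linearly with branch length).
#' @param indel_mean_length mean of the geometric indel-length distribution
#'   (default 6 bp, capped at 30).
#' @param tree optional Newick string for the generating tree (tip labels
#'   must equal `taxon_labels`); when `NULL` a random topology with
#'   deterministic ultrametric join depths spanning the divergence range is
#'   drawn.
#' @param taxon_labels leaf names.
#' @param seed RNG seed used by [simulate_genomes()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 9L,
                       genome_length = 152000L,
                       ir_length = 25000L,
                       ssc_length = 18000L,
                       divergence = c(0.001, 0.006),
                       gc = 0.375,
                       intergenic_multiplier = 4,
                       spacer_multipliers = NULL,
                       indels_per_branch = 2,
                       indel_mean_length = 6,
                       tree = NULL,
                       taxon_labels = sprintf("sp%02d", seq_len(n_taxa)),
                       seed = 1L) {
  stopifnot(n_taxa >= 2L, genome_length > 2L * ir_length + ssc_length,
            length(divergence) == 2L, all(divergence >= 0),
            divergence[1L] <= divergence[2L], divergence[2L] <= 0.05,
            intergenic_multiplier >= 0, indels_per_branch >= 0,
            indel_mean_length >= 1, length(taxon_labels) == n_taxa)
  structure(list(n_taxa = as.integer(n_taxa),
                 genome_length = as.integer(genome_length),
                 ir_length = as.integer(ir_length),
                 ssc_length = as.integer(ssc_length),
                 divergence = divergence, gc = gc,
                 intergenic_multiplier = intergenic_multiplier,
                 spacer_multipliers = spacer_multipliers,
                 indels_per_branch = indels_per_branch,
                 indel_mean_length = indel_mean_length,
                 tree = tree, taxon_labels = taxon_labels,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# published universal barcoding primers planted by the simulator
SIM_MARKERS <- list(
  list(name = "trnH-psbA", fwd = "CGCGCATGGTGGATTCACAATCC",   # trnHf_05
       rev = "GTTATGCATGAACGTAATGCTC"),                        # psbA3_f
  list(name = "rbcL", fwd = "ATGTCACCACAAACAGAGACTAAAGC",      # rbcLa-F
       rev = "GTAAAATCAAGTCCACCRCG")                           # rbcLa-R
)

# deterministic root genome layout: features and spacers in root coordinates
# (genome order LSC | IRa | SSC | IRb; the reduced genome is LSC+IRa+SSC)
build_layout <- function(config) {
  G <- config$genome_length
  ir <- config$ir_length
  ssc <- config$ssc_length
  lsc <- G - 2L * ir - ssc
  feats <- list(); spacers <- list()
  add_feat <- function(name, kind, start, end, strand, introns = 0L)
    feats[[length(feats) + 1L]] <<- data.frame(
      name = name, kind = kind, start = start, end = end, strand = strand,
      intron_count = introns, spans_origin = FALSE)
  add_spacer <- function(up, down, start, end, region = "sc")
    if (end >= start) spacers[[length(spacers) + 1L]] <<- data.frame(
      name = paste(up, "->", down), start = start, end = end, region = region)

  glen <- c(900L, 420L, 1500L, 660L, 282L, 1200L, 534L)
  slen <- c(150L, 220L, 310L, 180L, 420L, 260L)

  fill_sc <- function(pos, limit, prefix, prev_gene, start_idx, region) {
    gi <- start_idx
    repeat {
      gl <- glen[(gi - 1L) %% length(glen) + 1L]
      sl <- slen[(gi - 1L) %% length(slen) + 1L]
      if (pos + gl + sl > limit) break
      nm <- if (gi %% 6L == 0L) sprintf("trn%s%02d", prefix, gi)
            else sprintf("gene%s%03d", prefix, gi)
      kind <- if (gi %% 6L == 0L) "tRNA" else "protein_coding"
      gl2 <- if (kind == "tRNA") 72L else gl
      add_feat(nm, kind, pos, pos + gl2 - 1L,
               if (gi %% 2L) "+" else "-",
               introns = if (gi %% 7L == 0L) 1L else 0L)
      add_spacer(nm, "", pos + gl2, pos + gl2 + sl - 1L, region)
      pos <- pos + gl2 + sl
      gi <- gi + 1L
    }
    list(pos = pos, gi = gi)
  }

  # --- LSC: leading spacer, trnH, trnH->psbA spacer, psbA, rbcL, filler ---
  pos <- 121L  # [1,120] leading spacer (from the wrap-around gene)
  add_feat("trnH", "tRNA", pos, pos + 73L, "-")
  trnH_start <- pos
  pos <- pos + 74L
  add_spacer("trnH", "psbA", pos, pos + 429L, "lsc")
  pos <- pos + 430L
  add_feat("psbA", "protein_coding", pos, pos + 1061L, "+")
  psbA_start <- pos
  pos <- pos + 1062L
  add_spacer("psbA", "rbcL", pos, pos + 199L, "lsc")
  pos <- pos + 200L
  add_feat("rbcL", "protein_coding", pos, pos + 1427L, "+")
  rbcL_start <- pos
  pos <- pos + 1428L
  add_spacer("rbcL", "", pos, pos + 249L, "lsc")
  pos <- pos + 250L
  res <- fill_sc(pos, lsc - 60L, "L", "rbcL", 1L, "lsc")
  add_spacer("lsc_end", "ira", res$pos, lsc, "boundary")

  # --- IRa: rRNA operon + tRNAs + one duplicated protein gene ------------
  ira0 <- lsc  # offset base; IRa spans [lsc+1, lsc+ir]
  ir_plan <- list(
    list("spacer", 300L), list("rrn16", "rRNA", 1491L, "+"),
    list("spacer", 200L), list("trnI", "tRNA", 72L, "+"),
    list("spacer", 150L), list("rrn23", "rRNA", 2810L, "+"),
    list("spacer", 120L), list("rrn4.5", "rRNA", 103L, "+"),
    list("spacer", 80L), list("rrn5", "rRNA", 121L, "+"),
    list("spacer", 200L), list("trnA", "tRNA", 73L, "-"),
    list("spacer", 100L), list("ycf2", "protein_coding", 2000L, "+"))
  p <- ira0 + 1L
  prev <- "ira_start"
  ira_feats <- list()
  for (item in ir_plan) {
    if (item[[1L]] == "spacer") {
      add_spacer(prev, "", p, p + item[[2L]] - 1L, "ira")
      p <- p + item[[2L]]
    } else {
      add_feat(item[[1L]], item[[2L]], p, p + item[[3L]] - 1L, item[[4L]])
      ira_feats[[length(ira_feats) + 1L]] <-
        list(name = item[[1L]], kind = item[[2L]], start = p,
             end = p + item[[3L]] - 1L, strand = item[[4L]])
      prev <- item[[1L]]
      p <- p + item[[3L]]
    }
  }
  add_spacer(prev, "ira_end", p, ira0 + ir, "ira")

  # --- SSC ----------------------------------------------------------------
  ssc0 <- lsc + ir
  pos <- ssc0 + 1L
  add_spacer("ira", "ndhF", pos, pos + 179L, "ssc")
  pos <- pos + 180L
  add_feat("ndhF", "protein_coding", pos, pos + 2231L, "-")
  pos <- pos + 2232L
  add_spacer("ndhF", "ycf1", pos, pos + 299L, "ssc")
  pos <- pos + 300L
  add_feat("ycf1", "protein_coding", pos, pos + 4999L, "+")
  pos <- pos + 5000L
  add_spacer("ycf1", "", pos, pos + 199L, "ssc")
  pos <- pos + 200L
  res <- fill_sc(pos, ssc0 + ssc - 60L, "S", "ycf1", 1L, "ssc")
  add_spacer("ssc_end", "irb", res$pos, ssc0 + ssc, "boundary")

  # --- IRb: mirrored copies of the IRa features ---------------------------
  irb0 <- ssc0 + ssc   # IRb spans [irb0+1, G]
  for (ft in ira_feats) {
    off_s <- ft$start - ira0; off_e <- ft$end - ira0  # 1-based offsets in IRa
    add_feat(ft$name, ft$kind, irb0 + ir - off_e + 1L, irb0 + ir - off_s + 1L,
             if (ft$strand == "+") "-" else "+")
  }

  features <- do.call(rbind, feats)
  spacers <- do.call(rbind, spacers)
  # resolve spacer names left open during filling
  blank <- spacers$name == "" | grepl("-> $", spacers$name)
  if (any(blank)) {
    up <- sub(" ->.*$", "", spacers$name[blank])
    nxt <- vapply(which(blank), function(i) {
      after <- features$name[features$start > spacers$end[i]]
      if (length(after)) after[1L] else "end"
    }, character(1))
    spacers$name[blank] <- paste(up, "->", nxt)
  }
  list(lsc = lsc, ir = ir, ssc = ssc, G = G, Gred = lsc + ir + ssc,
       ira = c(ira0 + 1L, ira0 + ir),
       features = features, spacers = spacers,
       trnH_start = trnH_start, psbA_start = psbA_start,
       rbcL_start = rbcL_start)
}

# resolve a degenerate primer to one compatible unambiguous sequence
# (first base of each IUPAC set: deterministic)
resolve_primer <- function(seq) {
  paste(vapply(str_chars(seq), function(c) IUPAC_SETS[[c]][1L],
               character(1)), collapse = "")
}

# random rooted ultrametric tree: random topology, deterministic join depths
# evenly spaced in [dmin/2, dmax/2] so pairwise path lengths span the range
random_ultrametric_tree <- function(labels, dmin, dmax) {
  n <- length(labels)
  frag <- labels
  depth <- rep(0, n)
  for (k in seq_len(n - 1L)) {
    t_k <- if (n == 2L) dmax / 2 else
      dmin / 2 + (k - 1L) * (dmax - dmin) / 2 / (n - 2L)
    pick <- sample.int(length(frag), 2L)
    i <- min(pick); j <- max(pick)
    frag[i] <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], t_k - depth[i],
                       frag[j], t_k - depth[j])
    depth[i] <- t_k
    frag <- frag[-j]; depth <- depth[-j]
  }
  ape::read.tree(text = paste0(frag, ";"))
}

#' Simulate a set of annotated plastomes with known truth
#'
#' Builds a quadripartite root genome with gene annotation and planted
#' primer-binding sites, draws (or accepts) a generating tree, and evolves
#' the sequence down the tree: per-site substitutions uniform over the three
#' alternative bases, rates elevated in intergenic spacers (multipliers
#' normalised to genome-wide mean 1), geometric-length indels restricted to
#' single-copy spacers, primer sites held invariant, and the IRb kept an
#' exact reverse complement of IRa throughout (IR mutations appear in both
#' copies). Because every event is tracked in root coordinates, the emitted
#' whole-genome alignment is exact, and the truth difference matrix is
#' computed from the final aligned sequences (so substitution collisions are
#' resolved exactly).
#'
#' @param config a [sim_config()].
#' @return a list of class `plastome_sim`: `records` (list of
#'   [genome_record()]s), `msa` (the true whole-genome alignment), `truth`
#'   (generating tree, exact pairwise difference counts, indel event log,
#'   marker/primer coordinates, root layout, column map), `config`.
#' @export
simulate_genomes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- build_layout(config)
  Gred <- lay$Gred
  BASES <- c("A", "C", "G", "T")

  # root sequence over the reduced genome (LSC+IRa+SSC)
  gc <- config$gc
  root <- sample(BASES, Gred, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  # plant primer-binding sites inside the flanking genes of each marker
  markers <- list()
  plant <- function(start, seq) {
    chars <- str_chars(seq)
    root[start:(start + length(chars) - 1L)] <<- chars
    c(start, start + length(chars) - 1L)
  }
  m1 <- SIM_MARKERS[[1L]]  # spacer marker inside trnH..psbA
  f1 <- plant(lay$trnH_start + 40L, resolve_primer(m1$fwd))
  r1_end <- lay$trnH_start + 40L + 499L - 1L
  r1 <- plant(r1_end - nchar(m1$rev) + 1L, revcomp(resolve_primer(m1$rev)))
  markers[["trnH-psbA"]] <- list(name = "trnH-psbA", fwd = m1$fwd,
                                 rev = m1$rev, fwd_site = f1, rev_site = r1,
                                 span = c(f1[1L], r1[2L]))
  m2 <- SIM_MARKERS[[2L]]  # coding marker inside rbcL
  f2 <- plant(lay$rbcL_start, resolve_primer(m2$fwd))
  r2_end <- lay$rbcL_start + 599L - 1L
  r2 <- plant(r2_end - nchar(m2$rev) + 1L, revcomp(resolve_primer(m2$rev)))
  markers[["rbcL"]] <- list(name = "rbcL", fwd = m2$fwd, rev = m2$rev,
                            fwd_site = f2, rev_site = r2,
                            span = c(f2[1L], r2[2L]))

  # per-site substitution-rate multipliers on the reduced genome
  mult <- rep(1, Gred)
  for (i in seq_len(nrow(lay$spacers))) {
    sp <- lay$spacers[i, ]
    m <- config$intergenic_multiplier
    extra <- config$spacer_multipliers
    if (!is.null(extra) && sp$name %in% names(extra))
      m <- m * extra[[sp$name]]
    mult[sp$start:sp$end] <- m
  }
  for (mk in markers) {
    mult[mk$fwd_site[1L]:mk$fwd_site[2L]] <- 0
    mult[mk$rev_site[1L]:mk$rev_site[2L]] <- 0
  }
  ira <- lay$ira
  norm <- (sum(mult) + sum(mult[ira[1L]:ira[2L]])) / lay$G
  mult <- mult / norm

  # indel-eligible spacers: single-copy regions only (IR stays indel-free)
  elig <- lay$spacers[lay$spacers$region %in% c("lsc", "ssc"), , drop = FALSE]
  elig <- elig[elig$end - elig$start + 1L >= 40L, , drop = FALSE]
  for (mk in markers) {
    sites <- rbind(mk$fwd_site, mk$rev_site)
    for (r in seq_len(nrow(sites))) {
      if (config$indels_per_branch > 0 &&
          any(elig$start <= sites[r, 2L] & elig$end >= sites[r, 1L]))
        stop("config error: indels possible inside a primer-binding site")
    }
  }

  # generating tree
  if (!is.null(config$tree)) {
    tree <- ape::read.tree(text = config$tree)
    if (!setequal(tree$tip.label, config$taxon_labels))
      stop("config tree tips do not match taxon_labels")
    if (is.null(tree$edge.length))
      stop("config tree needs branch lengths")
  } else {
    tree <- random_ultrametric_tree(config$taxon_labels,
                                    config$divergence[1L],
                                    config$divergence[2L])
  }
  mean_bl <- mean(tree$edge.length)

  # evolve down the tree, logging indel events in root coordinates
  events <- list()            # global event log
  del_iv <- matrix(numeric(), 0L, 2L)
  ins_anchor <- integer()
  leaf_seq <- list(); leaf_ev <- list()
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  mutate <- function(b) {
    idx <- match(b, BASES)
    BASES[((idx - 1L + sample.int(3L, length(b), replace = TRUE)) %% 4L) + 1L]
  }
  draw_events <- function(bl) {
    lambda <- if (config$indels_per_branch <= 0 || mean_bl <= 0) 0
              else config$indels_per_branch * bl / mean_bl
    n_ev <- rpois(1L, lambda)
    ids <- integer()
    for (e in seq_len(n_ev)) {
      placed <- FALSE
      for (try in seq_len(50L)) {
        type <- sample(c("ins", "del"), 1L)
        len <- min(1L + rgeom(1L, 1 / config$indel_mean_length), 30L)
        sp <- elig[sample.int(nrow(elig), 1L,
                              prob = elig$end - elig$start + 1L), ]
        if (type == "del") {
          if (sp$end - sp$start - 1L < len) next
          start <- sp$start + sample.int(sp$end - sp$start - len, 1L)
          iv <- c(start, start + len - 1L)
          if (nrow(del_iv) && any(del_iv[, 1L] <= iv[2L] &
                                  del_iv[, 2L] >= iv[1L])) next
          if (length(ins_anchor) && any(ins_anchor >= iv[1L] - 1L &
                                        ins_anchor <= iv[2L])) next
          del_iv <<- rbind(del_iv, iv)
          events[[length(events) + 1L]] <<- list(
            id = length(events) + 1L, type = "del", start = iv[1L],
            length = len, spacer = sp$name, content = NULL)
        } else {
          anchor <- sp$start + sample.int(sp$end - sp$start, 1L) - 1L
          if (anchor %in% ins_anchor) next
          if (nrow(del_iv) && any(del_iv[, 1L] <= anchor + 1L &
                                  del_iv[, 2L] >= anchor)) next
          ins_anchor <<- c(ins_anchor, anchor)
          events[[length(events) + 1L]] <<- list(
            id = length(events) + 1L, type = "ins", start = anchor,
            length = len, spacer = sp$name,
            content = sample(BASES, len, replace = TRUE,
                             prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                      (1 - gc) / 2)))
        }
        ids <- c(ids, length(events))
        placed <- TRUE
        break
      }
      if (!placed) warning("indel event skipped: no free position found")
    }
    ids
  }
  evolve <- function(node, seq, ev) {
    for (edge_i in kids[[as.character(node)]]) {
      child <- tree$edge[edge_i, 2L]
      bl <- tree$edge.length[edge_i]
      s2 <- seq
      hits <- which(runif(Gred) < bl * mult)
      if (length(hits)) s2[hits] <- mutate(s2[hits])
      ev2 <- c(ev, draw_events(bl))
      if (child <= ntip) {
        leaf_seq[[tree$tip.label[child]]] <<- s2
        leaf_ev[[tree$tip.label[child]]] <<- ev2
      } else {
        evolve(child, s2, ev2)
      }
    }
  }
  evolve(ntip + 1L, root, integer())

  # ---- assemble the exact alignment --------------------------------------
  ins_ev <- Filter(function(e) e$type == "ins", events)
  ins_len_at <- integer(Gred)
  for (e in ins_ev) ins_len_at[e$start] <- e$length
  col_of_base <- seq_len(Gred) + c(0L, cumsum(ins_len_at)[-Gred])
  Lred <- Gred + sum(ins_len_at)
  ir <- lay$ir
  col_of_base_full <- c(col_of_base, Lred + seq_len(ir))
  taxa <- tree$tip.label
  rows <- list()
  for (tx in taxa) {
    row <- rep("-", Lred)
    row[col_of_base] <- leaf_seq[[tx]]
    for (eid in leaf_ev[[tx]]) {
      e <- events[[eid]]
      if (e$type == "del") {
        row[col_of_base[e$start:(e$start + e$length - 1L)]] <- "-"
      } else {
        row[col_of_base[e$start] + seq_len(e$length)] <- e$content
      }
    }
    irb_chars <- revcomp_chars(leaf_seq[[tx]][ira[1L]:ira[2L]])
    rows[[tx]] <- c(row, irb_chars)
  }
  aln <- msa(vapply(rows, paste, character(1), collapse = ""))

  # truth difference counts straight from the aligned rows
  n <- length(taxa)
  counts <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- rows[[i]]; b <- rows[[j]]
      both <- a != "-" & b != "-"
      counts[i, j] <- counts[j, i] <- sum(both & a != b)
    }
  }

  # leaf genome records with per-leaf coordinates
  records <- list()
  marker_spans <- list()
  for (tx in taxa) {
    row <- rows[[tx]]
    cum <- cumsum(row != "-")
    map_coord <- function(r) cum[col_of_base_full[r]]
    f <- lay$features
    f2 <- f
    f2$start <- vapply(f$start, map_coord, numeric(1))
    f2$end <- vapply(f$end, map_coord, numeric(1))
    records[[tx]] <- genome_record(tx, paste(row[row != "-"], collapse = ""),
                                   circular = TRUE, features = f2)
    marker_spans[[tx]] <- lapply(markers, function(mk)
      c(map_coord(mk$span[1L]), map_coord(mk$span[2L])))
  }

  indel_log <- if (length(events)) data.frame(
    id = vapply(events, `[[`, integer(1), "id"),
    type = vapply(events, `[[`, character(1), "type"),
    start = vapply(events, `[[`, numeric(1), "start"),
    length = vapply(events, `[[`, numeric(1), "length"),
    spacer = vapply(events, `[[`, character(1), "spacer"),
    taxa = vapply(seq_along(events), function(i)
      paste(taxa[vapply(taxa, function(tx) i %in% leaf_ev[[tx]],
                        logical(1))], collapse = ","), character(1))
  ) else data.frame(id = integer(), type = character(), start = numeric(),
                    length = numeric(), spacer = character(),
                    taxa = character())

  truth <- list(tree = tree, counts = counts, indels = indel_log,
                markers = markers, marker_spans = marker_spans,
                layout = lay, col_of_base = col_of_base_full,
                seed = config$seed)
  structure(list(records = records, msa = aln, truth = truth,
                 config = config), class = "plastome_sim")
}

#' @export
print.plastome_sim <- function(x, ...) {
  cat(sprintf("<plastome_sim> %d taxa, %s bp genomes, alignment %s cols, %d indel event(s), seed %d\n",
              length(x$records),
              format(nchar(x$records[[1L]]$sequence), big.mark = ","),
              format(x$msa$length, big.mark = ","),
              nrow(x$truth$indels), x$truth$seed))
  invisible(x)
}

#' Alignment columns of a root-coordinate interval
#' @param sim a `plastome_sim`.
#' @param start,end closed interval in root genome coordinates.
#' @return closed column interval `c(start_col, end_col)`.
#' @export
region_columns <- function(sim, start, end) {
  c(sim$truth$col_of_base[start], sim$truth$col_of_base[end])
}

#' Named gene regions of a simulation, as column intervals
#' @param sim a `plastome_sim`.
#' @param kinds feature kinds to keep.
#' @param dedupe_ir drop the IRb copies (default TRUE).
#' @return named list of closed column intervals.
#' @export
sim_gene_regions <- function(sim, kinds = "protein_coding",
                             dedupe_ir = TRUE) {
  f <- sim$truth$layout$features
  f <- f[f$kind %in% kinds, , drop = FALSE]
  if (dedupe_ir) f <- f[f$start <= sim$truth$layout$Gred, , drop = FALSE]
  setNames(lapply(seq_len(nrow(f)), function(i)
    region_columns(sim, f$start[i], f$end[i])), f$name)
}

#' Named intergenic spacer regions of a simulation, as column intervals
#' @param sim a `plastome_sim`.
#' @param single_copy_only keep only LSC/SSC spacers (default TRUE).
#' @return named list of closed column intervals.
#' @export
sim_spacer_regions <- function(sim, single_copy_only = TRUE) {
  sp <- sim$truth$layout$spacers
  if (single_copy_only)
    sp <- sp[sp$region %in% c("lsc", "ssc"), , drop = FALSE]
  setNames(lapply(seq_len(nrow(sp)), function(i)
    region_columns(sim, sp$start[i], sp$end[i])), sp$name)
}

#' Extract the true marker sequences of a simulated data set
#'
#' @param sim a `plastome_sim`.
#' @param marker_name one of the simulated marker names.
#' @return a list: `sequences` (named per-taxon amplicon strings, spanning
#'   forward primer start to reverse primer end on each leaf genome),
#'   `lengths`, `snps` (exact pairwise difference counts inside the marker
#'   columns), `columns` (the marker's alignment column interval).
#' @export
simulate_marker_set <- function(sim, marker_name) {
  mk <- sim$truth$markers[[marker_name]]
  if (is.null(mk)) stop("unknown marker: ", marker_name, "; available: ",
                        paste(names(sim$truth$markers), collapse = ", "))
  seqs <- vapply(names(sim$records), function(tx) {
    span <- sim$truth$marker_spans[[tx]][[marker_name]]
    substring(sim$records[[tx]]$sequence, span[1L], span[2L])
  }, character(1))
  cols <- region_columns(sim, mk$span[1L], mk$span[2L])
  sub <- msa_slice(sim$msa, cols)
  dm <- pairwise_difference_matrix(sub)
  list(sequences = seqs, lengths = nchar(seqs), snps = dm$counts,
       columns = cols)
}

#' Write a simulated data set to disk
#'
#' Emits one GenBank file per genome, an ungapped multi-FASTA, the true
#' whole-genome alignment as aligned FASTA, and a truth JSON (generating
#' tree, pairwise difference counts, indel log, seed).
#'
#' @param sim a `plastome_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in sim$records)
    write_genbank(rec, file.path(dir, paste0(rec$taxon, ".gb")))
  write_fasta(vapply(sim$records, `[[`, character(1), "sequence") |>
                setNames(names(sim$records)),
              file.path(dir, "genomes.fasta"))
  write_alignment(sim$msa, file.path(dir, "alignment.fasta"))
  truth <- list(tree = ape::write.tree(sim$truth$tree),
                counts = sim$truth$counts,
                indels = sim$truth$indels,
                seed = sim$truth$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
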