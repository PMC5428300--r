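test_that("zero-rate simulation yields identical genomes", {
  cfg <- small_sim_config(seed = 71, divergence = c(0, 0),
                          indels_per_branch = 0)
  sim <- simulate_genomes(cfg)
  seqs <- vapply(sim$records, `[[`, character(1), "sequence")
  expect_equal(length(unique(seqs)), 1L)
  dm <- pairwise_difference_matrix(sim$msa)
  expect_true(all(dm$counts == 0L))
  expect_true(all(sim$truth$counts == 0L))
  # and the markers are identical too
  ms <- simulate_marker_set(sim, "trnH-psbA")
  expect_equal(length(unique(ms$sequences)), 1L)
})

test_that("the computed difference matrix equals the logged truth exactly", {
  for (seed in c(72, 73)) {
    sim <- simulate_genomes(small_sim_config(seed = seed))
    dm <- pairwise_difference_matrix(sim$msa)
    expect_identical(unname(dm$counts), unname(sim$truth$counts))
  }
})

test_that("the IRb is the exact reverse complement of IRa at every leaf", {
  sim <- simulate_genomes(small_sim_config(seed = 74))
  ir <- sim$config$ir_length
  for (rec in sim$records) {
    part <- detect_inverted_repeats(rec, min_len = 10000)
    expect_equal(part$ir_length, ir)
    L <- nchar(rec$sequence)
    irb <- substring(rec$sequence, L - ir + 1L, L)
    ira <- substring(rec$sequence, part$ira[1], part$ira[2])
    expect_identical(revcomp(irb), ira)
  }
})

test_that("identical config and seed reproduce bit-identical output", {
  s1 <- simulate_genomes(small_sim_config(seed = 75))
  s2 <- simulate_genomes(small_sim_config(seed = 75))
  expect_identical(vapply(s1$records, `[[`, character(1), "sequence"),
                   vapply(s2$records, `[[`, character(1), "sequence"))
  expect_identical(s1$msa$rows, s2$msa$rows)
  expect_identical(ape::write.tree(s1$truth$tree),
                   ape::write.tree(s2$truth$tree))
  s3 <- simulate_genomes(small_sim_config(seed = 76))
  expect_false(identical(s1$msa$rows, s3$msa$rows))
})

test_that("alignment rows degap to the emitted genome sequences", {
  sim <- simulate_genomes(small_sim_config(seed = 77))
  for (tx in names(sim$records))
    expect_identical(degap(sim$msa, tx), sim$records[[tx]]$sequence)
})

test_that("a rate-boosted spacer ranks first among non-coding regions", {
  cfg <- small_sim_config(seed = 78,
                          spacer_multipliers = c("ndhF -> ycf1" = 10))
  sim <- simulate_genomes(cfg)
  st <- region_stats_table(sim$msa, sim_spacer_regions(sim))
  expect_equal(rank_regions(st, 1)$region, "ndhF -> ycf1")
})

test_that("marker truth accounts for every planted indel in the span", {
  cfg <- small_sim_config(seed = 79, indels_per_branch = 6)
  sim <- simulate_genomes(cfg)
  ms <- simulate_marker_set(sim, "trnH-psbA")
  log <- sim$truth$indels
  in_span <- log[log$spacer == "trnH -> psbA", , drop = FALSE]
  for (tx in names(sim$records)) {
    carried <- in_span[vapply(strsplit(in_span$taxa, ","), function(v)
      tx %in% v, logical(1)), , drop = FALSE]
    net <- sum(ifelse(carried$type == "ins", 1, -1) * carried$length)
    expect_equal(unname(ms$lengths[tx]), 499L + as.integer(net), info = tx)
  }
})

test_that("planted primer sites are invariant and amplify in every taxon", {
  sim <- simulate_genomes(small_sim_config(seed = 80, indels_per_branch = 4))
  for (mk in sim$truth$markers) {
    for (tx in names(sim$records)) {
      amp <- in_silico_pcr(sim$records[[tx]], mk$fwd, mk$rev,
                           marker_name = mk$name)
      expect_equal(nrow(amp), 1L, info = paste(mk$name, tx))
      expect_equal(amp$fwd_mismatches + amp$rev_mismatches, 0L)
      span <- sim$truth$marker_spans[[tx]][[mk$name]]
      expect_equal(c(amp$start, amp$end), span,
                   info = paste(mk$name, tx))
    }
  }
})

test_that("gene annotations track indel-shifted coordinates", {
  sim <- simulate_genomes(small_sim_config(seed = 81, indels_per_branch = 5))
  # extract each leaf's copy of a gene and compare with the alignment slice
  cols <- sim_gene_regions(sim)[["ycf1"]]
  sub <- msa_slice(sim$msa, cols)
  for (tx in names(sim$records)) {
    from_rec <- extract_feature_sequence(sim$records[[tx]], "ycf1")
    # ycf1 is annotated on + in the simulator layout; single copy in SSC
    expect_identical(unname(from_rec[1]), degap(sub, tx), info = tx)
  }
})

test_that("simulations write readable GenBank, FASTA and truth files", {
  sim <- simulate_genomes(small_sim_config(seed = 82, n_taxa = 3))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  gb <- list.files(dir, pattern = "\\.gb$", full.names = TRUE)
  expect_length(gb, 3L)
  rec <- read_genbank(gb[1])
  tx <- rec$taxon
  expect_identical(rec$sequence, sim$records[[tx]]$sequence)
  aln <- read_alignment(file.path(dir, "alignment.fasta"))
  expect_identical(aln$rows, sim$msa$rows)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 82L)
  expect_equal(unname(as.matrix(truth$counts)),
               unname(sim$truth$counts))
})
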