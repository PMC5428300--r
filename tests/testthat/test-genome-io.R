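test_that("GenBank parsing maps features, kinds and organism correctly", {
  seq <- random_dna(400)
  feats <- c(
    "     gene            10..120",
    '                     /gene="psbX"',
    "     CDS             10..120",
    '                     /gene="psbX"',
    "     tRNA            complement(150..220)",
    '                     /gene="trnQ"')
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(make_genbank_text(seq, features = feats), path)
  rec <- read_genbank(path)

  expect_s3_class(rec, "genome_record")
  expect_equal(rec$taxon, "Testus plantus")
  expect_true(rec$circular)
  expect_equal(rec$sequence, seq)
  expect_equal(nrow(rec$features), 2L)  # bare gene entry folded into CDS
  expect_setequal(rec$features$kind, c("protein_coding", "tRNA"))
  trnq <- rec$features[rec$features$name == "trnQ", ]
  expect_equal(trnq$strand, "-")
  expect_equal(c(trnq$start, trnq$end), c(150L, 220L))
})

test_that("GenBank parsing handles introns and origin-spanning joins", {
  seq <- random_dna(300)
  feats <- c(
    "     CDS             join(10..50,80..130)",
    '                     /gene="clpP"',
    "     CDS             join(280..300,1..30)",
    '                     /gene="wrapper"')
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(make_genbank_text(seq, features = feats), path)
  rec <- read_genbank(path)
  clpP <- rec$features[rec$features$name == "clpP", ]
  expect_equal(clpP$intron_count, 1L)
  wrap <- rec$features[rec$features$name == "wrapper", ]
  expect_true(wrap$spans_origin)
  expect_equal(c(wrap$start, wrap$end), c(280L, 30L))
})

test_that("invalid GenBank records are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".gb")
  # coordinates exceeding the sequence
  writeLines(make_genbank_text(random_dna(100), features = c(
    "     CDS             50..150",
    '                     /gene="tooLong"')), path)
  expect_error(read_genbank(path), "tooLong")

  # no ORIGIN block
  writeLines(c("LOCUS       X 100 bp DNA linear PLN", "//"), path)
  expect_error(read_genbank(path), "ORIGIN")
})

test_that("sequences round-trip through GenBank and FASTA", {
  sim <- simulate_genomes(small_sim_config(seed = 3, n_taxa = 2))
  rec <- sim$records[[1]]
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  rec2 <- read_genbank(gb)
  expect_identical(rec2$sequence, rec$sequence)
  expect_identical(rec2$features$name, rec$features$name)
  expect_identical(rec2$features$start, as.integer(rec$features$start))

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(g = rec$sequence), fa)
  expect_identical(unname(read_fasta(fa)), rec$sequence)
})

test_that("ambiguity codes other than N are normalised with a warning", {
  expect_warning(rec <- genome_record("t", "ACGTRYACGT"), "normalised to N")
  expect_equal(rec$sequence, "ACGTNNACGT")
  expect_error(genome_record("t", "ACGT!!"), "non-nucleotide")
})

test_that("inverted repeat detection recovers a planted L+R+S+revcomp(R) structure", {
  set.seed(11)
  Lp <- random_dna(9000); R <- random_dna(2500); S <- random_dna(1500)
  s <- strsplit(paste0(Lp, R, S, revcomp(R)), "")[[1]]
  # barrier bases so chance matches cannot extend the planted repeat:
  # both sides of each repeat boundary get the same (non-complementary) base
  s[c(1, 9000, 11501, 13000)] <- "A"
  g <- genome_record("t", paste(s, collapse = ""), circular = TRUE)
  part <- detect_inverted_repeats(g, min_len = 1000)
  expect_equal(part$ir_length, 2500L)
  expect_equal(part$ira, c(9001L, 11500L))
  expect_equal(part$irb, c(13001L, 15500L))
  expect_equal(part$lsc_length, 9000L)
  expect_equal(part$ssc_length, 1500L)
  # the defining invariant: the two intervals are exact reverse complements
  expect_identical(
    revcomp(substring(g$sequence, part$irb[1], part$irb[2])),
    substring(g$sequence, part$ira[1], part$ira[2]))
})

test_that("inverted repeat detection is rotation-invariant on circular records", {
  set.seed(12)
  Lp <- random_dna(6000); R <- random_dna(2000); S <- random_dna(1200)
  s <- paste0(Lp, R, S, revcomp(R))
  part0 <- detect_inverted_repeats(genome_record("t", s), min_len = 1000)
  for (shift in c(500L, 4000L, 9500L)) {
    rot <- paste0(substring(s, shift + 1, nchar(s)), substring(s, 1, shift))
    part <- detect_inverted_repeats(genome_record("t", rot), min_len = 1000)
    expect_equal(part$ir_length, part0$ir_length)
    expect_equal(part$lsc_length, part0$lsc_length)
    expect_equal(part$ssc_length, part0$ssc_length)
  }
})

test_that("absence of a long inverted repeat is signalled, not an error", {
  set.seed(13)
  g <- genome_record("t", random_dna(10000), circular = FALSE)
  expect_message(part <- detect_inverted_repeats(g, min_len = 1000),
                 "no inverted repeat")
  expect_null(part)
})

test_that("genome statistics count genes and IR duplicates as annotated", {
  rec <- genome_record("t", "ATGC", circular = FALSE)
  st <- genome_stats(rec)
  expect_equal(st$length_bp, 4L)
  expect_equal(st$gc_percent, 50.0)
  expect_equal(st$n_genes_total, 0L)

  # 5 planted genes, 2 of them duplicated copies (same name twice)
  f <- data.frame(
    name = c("g1", "g2", "g2", "rrn5", "rrn5"),
    kind = c("protein_coding", "protein_coding", "protein_coding",
             "rRNA", "rRNA"),
    start = c(1, 20, 60, 100, 140), end = c(10, 40, 80, 120, 160),
    strand = c("+", "+", "-", "+", "-"), intron_count = c(1L, 0L, 0L, 0L, 0L))
  rec <- genome_record("t", random_dna(200), circular = FALSE, features = f)
  st <- genome_stats(rec)
  expect_equal(st$n_genes_total, 5L)
  expect_equal(st$n_unique_protein_coding, 2L)
  expect_equal(st$n_rrna_total, 2L)
  expect_equal(st$n_unique_rrna, 1L)
  expect_equal(st$n_intron_genes, 1L)

  # permutation invariance in feature order
  st2 <- genome_stats(genome_record("t", rec$sequence, circular = FALSE,
                                    features = f[sample(5), ]))
  expect_equal(st2[, -1], st[, -1])

  # N excluded from the GC computation
  expect_equal(genome_stats(genome_record("t", "GGNN",
                                          circular = FALSE))$gc_percent, 100)
})

test_that("feature sequences honour strand, origin spanning and duplication", {
  set.seed(14)
  s <- random_dna(500)
  f <- data.frame(
    name = c("fwd", "rev", "wrap", "dup", "dup"),
    kind = "protein_coding",
    start = c(11, 101, 480, 200, 300), end = c(40, 160, 30, 220, 320),
    strand = c("+", "-", "+", "+", "+"), intron_count = 0L,
    spans_origin = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  rec <- genome_record("t", s, circular = TRUE, features = f)
  expect_equal(unname(extract_feature_sequence(rec, "fwd")),
               substring(s, 11, 40))
  expect_equal(unname(extract_feature_sequence(rec, "rev")),
               revcomp(substring(s, 101, 160)))
  wrap <- extract_feature_sequence(rec, "wrap")
  expect_equal(unname(nchar(wrap)), 500 - 480 + 1 + 30)
  expect_equal(unname(wrap), paste0(substring(s, 480, 500),
                                    substring(s, 1, 30)))
  expect_length(extract_feature_sequence(rec, "dup"), 2L)
  expect_error(extract_feature_sequence(rec, "nosuchgene"), "no feature")
  expect_error(extract_feature_sequence(rec, "fwx"), "fwd")
})
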