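FWD <- "ATGTCACCACAAACAGAGACTAAAGC"   # 26 nt
REV <- "GTAAAATCAAGTCCACCRCG"         # 20 nt, one degenerate position

# linear template with the primer pair planted at known coordinates;
# rev_at gives the last base of the reverse-primer footprint
make_template <- function(len, fwd_at, rev_end, fwd = FWD, rev = REV,
                          resolve_r = "A", seed = 1) {
  set.seed(seed)
  ch <- strsplit(random_dna(len), "")[[1]]
  fseq <- strsplit(fwd, "")[[1]]
  ch[fwd_at:(fwd_at + length(fseq) - 1)] <- fseq
  rseq <- strsplit(revcomp(sub("R", resolve_r, rev)), "")[[1]]
  ch[(rev_end - length(rseq) + 1):rev_end] <- rseq
  paste(ch, collapse = "")
}

test_that("primer validation enforces the IUPAC alphabet", {
  expect_silent(validate_primer("ACGTRYSWKMBDHVN"))
  expect_error(validate_primer("ACGTX"), "non-IUPAC")
  expect_error(validate_primer(""), "empty")
  expect_error(in_silico_pcr(random_dna(100), "ACZT", "ACGT"), "non-IUPAC")
})

test_that("planted primer sites are recovered at exact coordinates", {
  tmpl <- make_template(2000, fwd_at = 101, rev_end = 700)
  rec <- genome_record("t", tmpl, circular = FALSE)
  amp <- in_silico_pcr(rec, FWD, REV, marker_name = "rbcL")
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 101L)
  expect_equal(amp$end, 700L)
  expect_equal(amp$length_bp, 600L)
  expect_equal(amp$strand, "+")
  expect_equal(amp$fwd_mismatches, 0L)
  expect_equal(amp$rev_mismatches, 0L)
  expect_equal(amp$sequence, substring(tmpl, 101, 700))
})

test_that("degenerate primer positions match any compatible base", {
  # R in the reverse primer must bind sites carrying either A or G
  for (base in c("A", "G")) {
    tmpl <- make_template(1500, fwd_at = 51, rev_end = 650, resolve_r = base)
    amp <- in_silico_pcr(genome_record("t", tmpl, circular = FALSE),
                         FWD, REV)
    expect_equal(amp$rev_mismatches, 0L, info = base)
  }
  # a mismatch at an internal (non-clamp) reverse-primer position is
  # tolerated and counted
  tmpl <- make_template(1500, fwd_at = 51, rev_end = 650)
  ch <- strsplit(tmpl, "")[[1]]
  ch[640] <- setdiff(c("A", "C", "G", "T"), ch[640])[1]
  amp <- in_silico_pcr(genome_record("t", paste(ch, collapse = ""),
                                     circular = FALSE), FWD, REV)
  expect_equal(amp$rev_mismatches, 1L)
})

test_that("the 3'-clamp vetoes mismatches at primer ends", {
  tmpl <- make_template(1500, fwd_at = 51, rev_end = 650)
  ch <- strsplit(tmpl, "")[[1]]
  # corrupt the last base of the forward footprint (the primer's 3' end)
  pos <- 51 + nchar(FWD) - 1
  ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
  amp <- in_silico_pcr(genome_record("t", paste(ch, collapse = ""),
                                     circular = FALSE), FWD, REV,
                       max_mismatches = 3)
  expect_equal(nrow(amp), 0L)
})

test_that("internal mismatches are tolerated up to the configured maximum", {
  tmpl <- make_template(1500, fwd_at = 51, rev_end = 650)
  ch <- strsplit(tmpl, "")[[1]]
  for (off in c(3, 8)) # two internal positions of the forward footprint
    ch[51 + off] <- setdiff(c("A", "C", "G", "T"), ch[51 + off])[1]
  rec <- genome_record("t", paste(ch, collapse = ""), circular = FALSE)
  amp <- in_silico_pcr(rec, FWD, REV, max_mismatches = 3)
  expect_equal(amp$fwd_mismatches, 2L)
  expect_equal(nrow(in_silico_pcr(rec, FWD, REV, max_mismatches = 1)), 0L)
})

test_that("circular templates amplify across the origin", {
  tmpl <- make_template(3000, fwd_at = 2701, rev_end = 2999)
  # rotate so the product spans the origin: product occupied 2701..2999,
  # shift by 2800 puts the forward site at the end and the tail at the start
  rot <- paste0(substring(tmpl, 2801, 3000), substring(tmpl, 1, 2800))
  rec <- genome_record("t", rot, circular = TRUE)
  amp <- in_silico_pcr(rec, FWD, REV)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length_bp, 299L)
  expect_lt(amp$end, amp$start)  # wraps the origin
  expect_equal(amp$start, 2901L)
  expect_equal(amp$end, 199L)
  # the linear version of the same template yields the identical product
  amp_lin <- in_silico_pcr(genome_record("t", tmpl, circular = FALSE),
                           FWD, REV)
  expect_equal(amp$sequence, amp_lin$sequence)
})

test_that("markers on the reverse strand are found and reported forward", {
  tmpl <- make_template(2000, fwd_at = 101, rev_end = 700)
  flip <- revcomp(tmpl)
  amp <- in_silico_pcr(genome_record("t", flip, circular = FALSE), FWD, REV)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$strand, "-")
  expect_equal(amp$sequence, substring(tmpl, 101, 700))
  expect_equal(c(amp$start, amp$end), c(2000 - 700 + 1, 2000 - 101 + 1))
})

test_that("re-amplifying an amplicon returns the full amplicon (idempotence)", {
  tmpl <- make_template(2000, fwd_at = 101, rev_end = 700)
  amp <- in_silico_pcr(genome_record("t", tmpl, circular = FALSE), FWD, REV)
  amp2 <- in_silico_pcr(genome_record("t", amp$sequence, circular = FALSE),
                        FWD, REV)
  expect_equal(nrow(amp2), 1L)
  expect_equal(c(amp2$start, amp2$end), c(1L, amp$length_bp))
  expect_identical(amp2$sequence, amp$sequence)
})

test_that("no binding site yields an empty result, not an error", {
  set.seed(5)
  amp <- in_silico_pcr(genome_record("t", random_dna(2000),
                                     circular = FALSE), FWD, REV)
  expect_s3_class(amp, "data.frame")
  expect_equal(nrow(amp), 0L)
})

test_that("intergenic regions are named and located from the annotation", {
  f <- data.frame(
    name = c("gA", "gB", "gC"), kind = "protein_coding",
    start = c(11, 61, 200), end = c(40, 120, 260),
    strand = "+", intron_count = 0L)
  rec <- genome_record("t", random_dna(300), circular = TRUE, features = f)
  ig <- list_intergenic_regions(rec)
  expect_equal(nrow(ig), 3L)  # circular: includes the wrap-around spacer
  expect_equal(ig$region[1:2], c("gA -> gB", "gB -> gC"))
  expect_equal(c(ig$start[1], ig$end[1]), c(41L, 60L))
  expect_equal(ig$length_bp[3], 300L - 260L + 11L - 1L)  # gC -> gA wraps

  rec$circular <- FALSE
  expect_equal(nrow(list_intergenic_regions(rec)), 2L)

  # abutting genes produce no region
  f2 <- data.frame(name = c("x", "y"), kind = "protein_coding",
                   start = c(1, 51), end = c(50, 100), strand = "+",
                   intron_count = 0L)
  rec2 <- genome_record("t", random_dna(100), circular = FALSE,
                        features = f2)
  expect_equal(nrow(list_intergenic_regions(rec2)), 0L)
})

test_that("marker SNP matrices count planted substitutions exactly", {
  set.seed(41)
  base <- random_dna(400)
  seqs <- setNames(rep(base, 4), paste0("t", 1:4))
  # plant exactly 4 substitutions between t1 and t2; t3/t4 stay identical
  ch <- strsplit(base, "")[[1]]
  for (p in c(50, 150, 250, 350))
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  seqs[["t2"]] <- paste(ch, collapse = "")
  rep <- marker_snp_matrix(seqs, marker_name = "m1")
  expect_equal(rep$pairwise_snps["t1", "t2"], 4L)
  expect_equal(rep$pairwise_snps["t3", "t4"], 0L)
  expect_true(any(rep$unresolved_pairs$taxon1 == "t3" &
                  rep$unresolved_pairs$taxon2 == "t4"))

  # identical amplicons: all pairs unresolved
  rep0 <- marker_snp_matrix(setNames(rep(base, 3), paste0("s", 1:3)))
  expect_true(all(rep0$pairwise_snps == 0L))
  expect_equal(nrow(rep0$unresolved_pairs), 3L)
})

test_that("missing amplicons are flagged as amplification failures", {
  set.seed(42)
  seqs <- setNames(replicate(3, random_dna(300)), paste0("t", 1:3))
  expect_warning(rep <- marker_snp_matrix(seqs, taxa = paste0("t", 1:5)),
                 "amplification failure")
  expect_setequal(rep$failed, c("t4", "t5"))
  expect_equal(dim(rep$pairwise_snps), c(3L, 3L))
})

test_that("combining markers is commutative, associative and complementary", {
  taxa <- paste0("t", 1:4)
  mk <- function(pairs) {
    m <- matrix(0L, 4, 4, dimnames = list(taxa, taxa))
    for (p in pairs) { m[p[1], p[2]] <- m[p[2], p[1]] <- p[3] }
    m
  }
  # marker A resolves (1,2); marker B resolves everything A misses
  rA <- superbarcode:::marker_report("mA", taxa, mk(list(c(1, 2, 3L))))
  rB <- superbarcode:::marker_report("mB", taxa,
    mk(list(c(1, 3, 2L), c(1, 4, 1L), c(2, 3, 2L), c(2, 4, 2L),
            c(3, 4, 5L))))
  comb <- combine_markers(rA, rB)
  expect_equal(nrow(comb$unresolved_pairs), 0L)
  expect_equal(comb$pairwise_snps, rA$pairwise_snps + rB$pairwise_snps)
  # commutative and associative on the SNP matrix
  expect_equal(combine_markers(rB, rA)$pairwise_snps, comb$pairwise_snps)
  expect_equal(
    combine_markers(combine_markers(rA, rB), rA)$pairwise_snps,
    combine_markers(rA, combine_markers(rB, rA))$pairwise_snps)
  # combining with an all-zero twin changes nothing
  zero <- superbarcode:::marker_report("z", taxa, mk(list()))
  expect_equal(combine_markers(rA, zero)$pairwise_snps, rA$pairwise_snps)
  expect_equal(combine_markers(rA, zero)$unresolved_pairs,
               rA$unresolved_pairs)
  # mismatched taxon sets are rejected
  rC <- superbarcode:::marker_report("mC", paste0("u", 1:4), mk(list()))
  expect_error(combine_markers(rA, rC), "different taxon sets")
})

test_that("marker SNPs never exceed whole-genome differences for a pair", {
  sim <- simulate_genomes(small_sim_config(seed = 51))
  dm <- pairwise_difference_matrix(sim$msa)
  for (mk in names(sim$truth$markers)) {
    ms <- simulate_marker_set(sim, mk)
    expect_true(all(ms$snps <= dm$counts[rownames(ms$snps),
                                         colnames(ms$snps)]))
  }
})
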