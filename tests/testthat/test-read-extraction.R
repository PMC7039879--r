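make_read <- function(rna, dna, barcode = "ACGTAC", pad_to = 150,
                      reverse = FALSE) {
  ol <- radicl_oligos()
  core <- paste0(rna, ol$adapter_top, dna, ol$linker_upper, barcode)
  pad <- paste(rep("A", pad_to - nchar(core)), collapse = "")
  s <- paste0(core, pad)
  if (reverse) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))) else s
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("locate_adapter finds the unique best placement per orientation", {
  set.seed(1)
  an <- small_anatomy()
  rna <- rand_seq(27); dna <- rand_seq(27)
  fwd <- make_read(rna, dna)
  loc <- locate_adapter(fwd, an)
  expect_equal(loc$status, "found")
  expect_equal(loc$orientation, "forward")
  expect_equal(loc$offset, 28L)  # 1-based; 27-nt RNA flank precedes it

  rev <- make_read(rna, dna, reverse = TRUE)
  locr <- locate_adapter(rev, an)
  expect_equal(locr$orientation, "reverse")
  # symmetric placement: adapter occupies the same bases after revcomp
  expect_equal(150L - (locr$offset + 49L) + 1L, 28L)

  # two adapter copies tie at distance 0: ambiguous
  double <- paste0(substr(fwd, 1, 50), radicl_oligos()$adapter_top,
                   radicl_oligos()$adapter_top)
  expect_equal(locate_adapter(double, an)$status, "ambiguous")
})

test_that("random reads essentially never contain an adapter placement", {
  set.seed(2)
  an <- small_anatomy()
  reads <- vapply(seq_len(10000), function(i) rand_seq(150), "")
  loc <- locate_adapter(reads, an, max_mismatches = 2)
  expect_lte(sum(loc$status != "none"), 1L)
})

test_that("extraction round-trips error-free simulated reads exactly", {
  sim <- small_sim()
  rec <- small_records()
  expect_equal(nrow(rec), nrow(sim$truth))
  acc <- rec[rec$rejection_reason == "", ]
  expect_equal(nrow(acc), nrow(sim$truth))  # clean reads: all accepted
  tr <- sim$truth[match(acc$read_id, sim$truth$read_id), ]
  expect_equal(acc$barcode, tr$barcode)
  expect_equal(acc$reverse, tr$reverse)
  fx <- small_sim()$fixture
  rna_true <- with(tr, mapply(function(cn, s, e) as.character(
    Biostrings::subseq(fx$genome_seq[[cn]], s + 1, e)),
    rna_chrom, rna_start, rna_end, USE.NAMES = FALSE))
  minus <- tr$rna_strand == "-"
  rna_true[minus] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rna_true[minus])))
  not_rrna <- !tr$rrna_contaminant
  expect_equal(acc$rna_seq[not_rrna], rna_true[not_rrna])
})

test_that("rejection reasons cover short flanks and bad barcodes", {
  set.seed(3)
  an <- small_anatomy()
  short <- make_read(rand_seq(24), rand_seq(27))
  expect_equal(extract_tags(short, an)$rejection_reason, "short_flank")

  # flank of 28+: only the adapter-proximal 27 bases are kept
  long_read <- make_read(rand_seq(30), rand_seq(27), pad_to = 153)
  rec <- extract_tags(substr(long_read, 1, 153), an)
  expect_equal(rec$rejection_reason, "")
  expect_equal(nchar(rec$rna_seq), 27L)

  bc2 <- "AATTAC"  # distance 2 from ACGTAC, >= 4 from the others
  expect_equal(extract_tags(make_read(rand_seq(27), rand_seq(27),
                                      barcode = bc2), an)$rejection_reason,
               "bad_barcode")
  bc1 <- "CCGTAC"  # distance 1: corrected to the whitelist entry
  rec1 <- extract_tags(make_read(rand_seq(27), rand_seq(27), barcode = bc1),
                       an)
  expect_equal(rec1$rejection_reason, "")
  expect_equal(rec1$barcode, "ACGTAC")

  expect_equal(extract_tags(rand_seq(150), an)$rejection_reason,
               "no_adapter")
})

test_that("DNA tag lengths are resolved against the linker", {
  set.seed(4)
  an <- small_anatomy()
  for (L in 25:27) {
    rec <- extract_tags(make_read(rand_seq(26), rand_seq(L)), an)
    expect_equal(nchar(rec$dna_seq), L)
  }
})

test_that("rRNA k-mer screen flags both strands and spares random tags", {
  set.seed(5)
  rrna <- rand_seq(5000)
  tag <- substr(rrna, 101, 127)
  expect_true(filter_rrna(tag, rrna))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tag)))
  expect_true(filter_rrna(rc, rrna))
  random_tags <- vapply(seq_len(10000), function(i) rand_seq(27), "")
  expect_lte(sum(filter_rrna(random_tags, rrna)), 1L)
  expect_error(filter_rrna("ACGT", rrna), "k exceeds")
})

test_that("dedup keeps one record per distinct triple, first occurrence", {
  rec <- data.frame(read_id = c("a", "b", "c"),
                    rna_seq = "AAA", dna_seq = "CCC", barcode = "ACGTAC",
                    stringsAsFactors = FALSE)
  expect_equal(dedup_pairs(rec)$read_id, "a")
  rec$dna_seq <- c("CCC", "CCG", "CCC")
  expect_equal(dedup_pairs(rec)$read_id, c("a", "b"))
  rec$dna_seq <- "CCC"; rec$barcode <- c("ACGTAC", "TGCAGT", "ACGTAC")
  expect_equal(dedup_pairs(rec)$read_id, c("a", "b"))

  # brute-force set oracle on random records + idempotence
  set.seed(6)
  n <- 500
  big <- data.frame(
    read_id = as.character(seq_len(n)),
    rna_seq = sample(c("AA", "AC", "AG"), n, TRUE),
    dna_seq = sample(c("TT", "TC"), n, TRUE),
    barcode = sample(c("ACGTAC", "TGCAGT"), n, TRUE),
    stringsAsFactors = FALSE)
  dd <- dedup_pairs(big)
  oracle <- length(unique(paste(big$rna_seq, big$dna_seq, big$barcode)))
  expect_equal(nrow(dd), oracle)
  expect_identical(dedup_pairs(dd), dd)
})

test_that("tag trimming truncates from the 5' end and validates L", {
  rec <- data.frame(rna_seq = "ACGTACGTACGTACGTACGTACGTACG",
                    dna_seq = "TTTTACGTACGTACGTACGTACGTACG",
                    stringsAsFactors = FALSE)
  tt <- trim_tags(rec, 20)
  expect_equal(tt$rna_seq, substr(rec$rna_seq, 1, 20))
  expect_equal(tt$dna_seq, substr(rec$dna_seq, 1, 20))
  expect_identical(trim_tags(rec, 27), rec)
  expect_error(trim_tags(rec, 28), "exceeds")
})

test_that("extraction stays robust at 1 percent per-base error", {
  cfg <- sim_config(seed = 21, n_contacts = 3000, dup_rate = 0,
                    rrna_rate = 0, seq_error_rate = 0.01)
  sim <- simulate_library(cfg)
  rec <- extract_tags(sim$reads, read_anatomy(cfg$barcodes))
  acc <- rec[rec$rejection_reason == "", ]
  expect_gte(nrow(acc) / nrow(sim$truth), 0.9)
  tr <- sim$truth[match(acc$read_id, sim$truth$read_id), ]
  # zero RNA/DNA swaps: orientation call always matches the truth
  expect_equal(sum(acc$reverse != tr$reverse), 0L)
})
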