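pairs_df <- function(n, rna_chrom = "chr1", rna_center = 0,
                     dna_chrom = "chr1", dna_center = 0, ...) {
  df <- data.frame(read_id = sprintf("r%04d", seq_len(n)),
                   rna_chrom = rna_chrom, rna_center = rna_center,
                   dna_chrom = dna_chrom, dna_center = dna_center,
                   stringsAsFactors = FALSE, ...)
  class(df) <- c("contact_pairs", "data.frame")
  df
}

test_that("replicate correlation uses complete observations", {
  t1 <- data.frame(rna = c("a", "b", "c"), bin = "x", count = c(1, 5, 9))
  expect_equal(replicate_correlation(list(t1, t1))$r, 1)
  t2 <- t1; t2$count <- 2 * t1$count
  expect_equal(replicate_correlation(list(t1, t2))$r, 1)
  # a unit absent from one table is excluded from the comparison
  t3 <- rbind(t1, data.frame(rna = "d", bin = "x", count = 100))
  rc <- replicate_correlation(list(A = t3, B = t1))
  expect_equal(rc$n, 3L)
  expect_error(replicate_correlation(list(t1)), "two")

  set.seed(40)
  n <- 2000
  ta <- data.frame(rna = as.character(1:n), bin = "x",
                   count = stats::rpois(n, 10) + 1)
  tb <- data.frame(rna = as.character(1:n), bin = "x",
                   count = stats::rpois(n, 10) + 1)
  expect_lt(abs(replicate_correlation(list(ta, tb))$r), 3 / sqrt(n))
})

test_that("expression correlation applies RPK and TPM thresholds", {
  counts <- c(g1 = 500, g2 = 100, g3 = 1)
  lengths <- c(g1 = 2000, g2 = 1000, g3 = 2000)
  # RPK: 500 / 2 kb = 250
  tpm <- c(g1 = 250, g2 = 100, g3 = 10)
  ec <- expression_correlation(counts, lengths, tpm)
  expect_equal(ec$n, 2L)  # g3 has RPK 0.5 < 1
  expect_equal(ec$table$rpk[ec$table$gene_id == "g1"], 250)
  expect_equal(ec$r_squared, 1, tolerance = 1e-12)
  expect_error(expression_correlation(c(g1 = 0.1), c(g1 = 2000),
                                      c(g1 = 5)), "threshold")
})

test_that("distance decay orders expression quartiles by decay rate", {
  genes <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                      start = 0, end = 1000, strand = "+",
                      stringsAsFactors = FALSE)
  expression <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  # low-expression genes decay faster (alpha 2) than high (alpha 0.8)
  set.seed(41)
  mk <- function(gid, alpha, n = 4000) {
    d <- decay_distance(n, alpha, 1000, 1e6)
    p <- pairs_df(n, rna_center = 500, dna_center = 1000 + d)
    p$rna_gene <- gid
    p
  }
  alphas <- c(2, 1.6, 1.2, 0.8)
  pp <- do.call(rbind, Map(mk, paste0("g", 1:4), alphas))
  class(pp) <- c("contact_pairs", "data.frame")
  dd <- distance_decay(pp, genes, expression)
  expect_equal(rownames(dd$curves), c("I", "II", "III", "IV"))
  expect_equal(unname(rowSums(dd$curves)), rep(1, 4), tolerance = 1e-9)
  # mean log distance increases from quartile I to IV
  expect_true(all(diff(dd$mean_log10) > 0))

  # all pairs at distance zero collapse into the first bin
  p0 <- pairs_df(10, rna_center = 500, dna_center = 500)
  p0$rna_gene <- "g1"
  dd0 <- distance_decay(p0, genes, expression)
  expect_equal(unname(dd0$curves["I", 1]), 1)
})

test_that("fraction below threshold is the nascent proxy", {
  p <- pairs_df(2, rna_center = c(0, 0), dna_center = c(500, 2000))
  fb <- fraction_below(p, 1000)
  expect_equal(fb$overall, 0.5)
  expect_equal(fb$cis, 0.5)
  pt <- pairs_df(3, dna_chrom = "chr2")
  expect_equal(fraction_below(pt)$overall, 0)
  # the fold-reduction usage pattern between two conditions
  p2 <- pairs_df(4, rna_center = 0, dna_center = c(1, 2, 3, 2000))
  expect_equal(fraction_below(p2)$overall / fb$overall, 1.5)
})

test_that("metaprofile window arithmetic and flatness behave", {
  genome <- genome_build("chr1", 100000)
  regions <- data.frame(chrom = "chr1", start = 31000, end = 34000)
  # window = region +/- its width; a region too close to the edge drops
  set.seed(42)
  pos <- sample(0:99999, 30000, replace = TRUE)
  mp <- meta_profile(rep("chr1", length(pos)), pos, regions, genome)
  expect_equal(mp$n_bins, 300L)
  expect_equal(mp$n_regions, 1L)
  edge <- data.frame(chrom = "chr1", start = 1000, end = 4000)
  expect_error(meta_profile("chr1", 5, edge, genome), "usable")

  # uniform coverage: nearly flat; aggregate over many regions
  regions2 <- data.frame(chrom = "chr1",
                         start = seq(5000, 80000, by = 5000))
  regions2$end <- regions2$start + 3000
  mp2 <- meta_profile(rep("chr1", length(pos)), pos, regions2, genome)
  prof <- mp2$profile
  se <- apply(mp2$per_region, 2, stats::sd) / sqrt(mp2$n_regions)
  frac_flat <- mean(abs(prof - mean(prof)) < 3 * pmax(se, 1e-9))
  expect_gte(frac_flat, 0.99)

  # signal confined to the region elevates only the central bins
  inside <- sample(31000:33999, 5000, replace = TRUE)
  mp3 <- meta_profile(rep("chr1", length(inside)), inside, regions, genome)
  expect_true(all(mp3$profile[c(1:100, 201:300)] == 0))
  expect_gt(mean(mp3$profile[101:200]), 0)
})

test_that("inside/outside TAD profiles separate confined signal", {
  genome <- genome_build("chr1", 200000)
  tads <- data.frame(chrom = "chr1", start = c(60000, 120000),
                     end = c(90000, 150000))
  set.seed(43)
  # RNAs inside TAD 1 contact only their own TAD; outside RNAs uniform
  n <- 4000
  rna_in <- sample(60000:89999, n, TRUE)
  dna_in <- sample(60000:89999, n, TRUE)
  rna_out <- sample(0:49999, n, TRUE)
  dna_out <- sample(0:199999, n, TRUE)
  p <- pairs_df(2 * n, rna_center = c(rna_in, rna_out),
                dna_center = c(dna_in, dna_out))
  io <- inside_outside_profile(p, tads, genome)
  ci <- mean(io$inside$profile[101:200])
  fi <- mean(io$inside$profile[c(1:100, 201:300)])
  expect_gt(ci, 5 * max(fi, 1e-9))
  co <- mean(io$outside$profile[101:200])
  fo <- mean(io$outside$profile[c(1:100, 201:300)])
  expect_lt(co, 2 * fo)
  expect_error(inside_outside_profile(p, tads[0, ], genome), "TADs")

  # boundary convention: a center at TAD start is inside (half-open)
  pb <- pairs_df(1, rna_center = 60000, dna_center = 70000)
  iob <- inside_outside_profile(pb, tads[1, , drop = FALSE], genome)
  expect_gt(sum(iob$inside$profile), 0)
  expect_equal(sum(iob$outside$profile), 0)
})

test_that("peak density profiles normalise to the window baseline", {
  set.seed(44)
  peaks <- data.frame(chrom = "chr1",
                      start = seq(20000, 80000, by = 10000) - 250)
  peaks$end <- peaks$start + 500
  pos <- sample(0:99999, 50000, replace = TRUE)
  pd <- peak_density_profile(rep("chr1", length(pos)), pos, peaks)
  expect_equal(length(pd$density), 10001L)
  expect_equal(mean(pd$density), 1, tolerance = 1e-9)
  expect_lt(stats::sd(pd$density), 2)

  centers <- fragment_center(peaks$start, peaks$end)
  pd2 <- peak_density_profile(rep("chr1", nrow(peaks)), centers, peaks)
  expect_equal(which.max(pd2$density), 5001L)  # spike at offset 0
})

test_that("repeat interval proportions follow the stated formula", {
  fam <- c(rep("LINE", 100), rep("NR", 200))
  cls <- factor(c(rep("long", 10), rep("local", 90),
                  rep("long", 10), rep("local", 190)),
                levels = c("local", "short", "medium", "long",
                           "extreme", "trans"))
  p <- pairs_df(300)
  p$repeat_family <- fam
  p$distance_class <- cls
  rp <- repeat_interval_proportions(p)
  expect_equal(unname(rp$percent["LINE", "long"]), 10)
  expect_equal(unname(rp$percent["NR", "long"]), 5)
  expect_equal(unname(rowSums(rp$percent)), rep(100, 2), tolerance = 1e-9)

  # identical replicate-level proportions give t = 0, p = 1
  p$rep <- rep(c("r1", "r2"), 150)
  rp2 <- repeat_interval_proportions(p, replicate = p$rep)
  row <- rp2$tests[rp2$tests$interval == "long" &
                     rp2$tests$family == "LINE", ]
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)

  # planted long-range-only family tests significantly above NR
  set.seed(45)
  n <- 1200
  fam3 <- rep(c("LINE", "NR"), each = n / 2)
  cls3 <- factor(ifelse(fam3 == "LINE",
                        ifelse(stats::runif(n) < 0.8, "long", "local"),
                        ifelse(stats::runif(n) < 0.1, "long", "local")),
                 levels = levels(cls))
  p3 <- pairs_df(n)
  p3$repeat_family <- fam3; p3$distance_class <- cls3
  p3$rep <- sample(c("r1", "r2", "r3"), n, TRUE)
  rp3 <- repeat_interval_proportions(p3, replicate = p3$rep)
  row3 <- rp3$tests[rp3$tests$interval == "long" &
                      rp3$tests$family == "LINE", ]
  expect_gt(row3$t, 0)
  expect_lt(row3$p, 0.05)

  p$self_interaction <- TRUE
  expect_error(repeat_interval_proportions(p), "self-interactions")
})

test_that("jaccard distance and capture difference match definitions", {
  a <- list(g = c("b1", "b2", "b3")); attr(a, "width") <- 5000
  b <- list(g = c("b2", "b3", "b4")); attr(b, "width") <- 5000
  same <- jaccard_vs_capture(a, a, c(g = 10), c(g = 10))
  expect_equal(same$jaccard_distance, 0)
  expect_equal(same$capture_diff_pct, 0)
  disj <- list(g = c("b7", "b8")); attr(disj, "width") <- 5000
  expect_equal(jaccard_vs_capture(a, disj, c(g = 1),
                                  c(g = 1))$jaccard_distance, 1)
  jc <- jaccard_vs_capture(a, b, c(g = 80), c(g = 100))
  expect_equal(jc$jaccard_distance, 0.5)
  expect_equal(jc$capture_diff_pct, 20)
  empty <- list(g = character(0)); attr(empty, "width") <- 5000
  both0 <- jaccard_vs_capture(empty, empty, c(g = 0), c(g = 0))
  expect_equal(both0$jaccard_distance, 0)
  expect_equal(both0$capture_diff_pct, 0)
  attr(b, "width") <- 25000
  expect_error(jaccard_vs_capture(a, b, c(g = 1), c(g = 1)), "scheme")
})

test_that("promoter log2 ratios use CPM with pseudocount", {
  genome <- genome_build("chr1", 1e6)
  genes <- data.frame(gene_id = "g", chrom = "chr1", tss = 50000,
                      stringsAsFactors = FALSE)
  pw <- promoter_windows(genes, 2000, genome)
  pa <- pairs_df(1000, dna_center = 50000)
  pr <- promoter_log2ratio(pa, pa, pw)
  expect_equal(pr$log2_ratio, 0)
  # A with twice B's per-promoter rate at equal library size
  pb <- pairs_df(1000, dna_center = c(rep(50000, 500),
                                      rep(900000, 500)))
  pr2 <- promoter_log2ratio(pa, pb, pw)
  expect_equal(pr2$log2_ratio,
               log2((1e6 / 1e3 * 1000 + 1) / (1e6 / 1e3 * 500 + 1)))
})

test_that("unique target counts come from the significant set", {
  p <- fake_pairs(c("G", "G", "H"),
                  c("chr1:0-25000", "chr1:25000-50000", "chr1:0-25000"))
  m <- aggregate_matrix(p)
  u <- unique_targets(m)
  expect_equal(unname(u["G"]), 2L)
  expect_false("missing" %in% names(u))
})

test_that("compartment segregation fractions behave at the extremes", {
  comp <- data.frame(chrom = "chr1",
                     start = seq(0, 90000, by = 10000),
                     end = seq(10000, 100000, by = 10000),
                     name = rep_len(c("A", "B"), 10),
                     stringsAsFactors = FALSE)
  pA <- pairs_df(50, rna_center = 5000, dna_center = 25000)
  expect_equal(compartment_segregation(pA, comp)$fraction_same, 1)

  set.seed(46)
  n <- 5000
  pr <- pairs_df(n, rna_center = sample(0:99999, n, TRUE),
                 dna_center = sample(0:99999, n, TRUE))
  fs <- compartment_segregation(pr, comp)$fraction_same
  expect_lt(abs(fs - 0.5), 3 * sqrt(0.25 / n))

  # strictly local pairs in alternating compartments stay together
  pl <- pairs_df(n, rna_center = sample(0:99899, n, TRUE))
  pl$dna_center <- pl$rna_center + sample(0:100, n, TRUE)
  expect_gt(compartment_segregation(pl, comp)$fraction_same, 0.98)

  # unlabelled bins are excluded and counted
  px <- pairs_df(3, rna_chrom = "chrUn")
  seg <- suppressWarnings(compartment_segregation(px, comp))
  expect_equal(seg$n_unlabelled, 3L)
})

test_that("shared interaction sets report union percentages", {
  a <- data.frame(rna = c("r1", "r2"), bin = c("b1", "b2"))
  expect_equal(shared_trans(a, a)$pct_union, 100)
  b <- data.frame(rna = c("r3", "r4"), bin = c("b3", "b4"))
  expect_equal(shared_trans(a, b)$pct_union, 0)
  c2 <- data.frame(rna = c("r1", "r3"), bin = c("b1", "b3"))
  st <- shared_trans(a, c2)
  expect_equal(st$shared, 1L)
  expect_equal(st$pct_union, 100 / 3, tolerance = 1e-9)
  a$distance_class <- c("trans", "local")
  c2$distance_class <- c("trans", "trans")
  stc <- shared_trans(a, c2)
  tr <- stc$by_class[stc$by_class$distance_class == "trans", ]
  expect_equal(tr$shared, 1L)
  expect_equal(tr$pct_union, 50)
})

test_that("top-K overlap ranks by score with deterministic ties", {
  s <- stats::setNames(10:1, letters[1:10])
  expect_equal(top_k_overlap(s, s, k = 10)$both, 10L)
  rev_s <- stats::setNames(1:10, letters[1:10])
  expect_equal(top_k_overlap(s, rev_s, k = 5)$both, 0L)
  # ties at the boundary break by gene id
  tied <- stats::setNames(c(5, 5, 5, 1), c("d", "b", "c", "a"))
  expect_equal(top_k_overlap(tied, tied, k = 2)$both, 2L)
  o1 <- top_k_overlap(tied, tied, k = 2)
  o2 <- top_k_overlap(tied[c(3, 1, 2, 4)], tied, k = 2)
  expect_equal(o1, o2)
  # k caps at the list length
  expect_equal(top_k_overlap(s, s, k = 99)$k_a, 10L)
})

test_that("dominant labels per bin pair use the fixed tie orders", {
  rg <- factor(c("intron", "intron", "intron", "exon"),
               levels = c("exon", "intron", "intergenic"))
  cl <- factor(rep("protein_coding", 4),
               levels = c("protein_coding", "long_ncRNA", "ncRNA", "other"))
  p <- pairs_df(4)
  p$rna_bin <- "chr1:0-25000"; p$dna_bin <- "chr1:25000-50000"
  p$rna_region <- rg; p$rna_class <- cl
  p$distance_class <- factor(rep("short", 4),
                             levels = c("local", "short", "medium", "long",
                                        "extreme", "trans"))
  dm <- dominant_class_matrix(p)
  expect_equal(dm$matrix$region, "intron")
  expect_equal(dm$matrix$n, 4L)

  # 2-2 tie resolves to exon (the earlier label in the fixed order)
  p$rna_region <- factor(c("exon", "exon", "intron", "intron"),
                         levels = levels(rg))
  expect_equal(dominant_class_matrix(p)$matrix$region, "exon")

  p1 <- p[1, ]
  class(p1) <- class(p)
  expect_equal(dominant_class_matrix(p1)$matrix$region, "exon")
  expect_equal(unname(rowSums(dominant_class_matrix(p)$by_distance_region)["short"]),
               1, tolerance = 1e-12)
})
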