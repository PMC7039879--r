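# Synthetic RADICL-seq data: a small genome with annotation and structural
# features, a ground-truth contact set with configurable cis distance decay,
# and 150-nt chimeric reads with the full construct anatomy
# (RNA tag | 50-nt bridge adapter | DNA tag | sequencing linker | barcode).

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substrings of a genome (DNAStringSet), 0-based half-open coordinates
genome_seqs <- function(genome_seq, chrom, start, end) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    i <- chrom == cn
    out[i] <- as.character(Biostrings::Views(genome_seq[[cn]],
                                             start = start[i] + 1L,
                                             end = end[i]))
  }
  out
}

#' Configuration for the synthetic RADICL-seq generator
#'
#' Defines the fixture genome, annotation, and the contact/read model:
#' cis contacts decay with genomic distance as \eqn{P(d) \propto (d +
#' d0)^{-\alpha}}, a fraction of contacts are nascent-like (< 1 kb from the
#' source gene) or trans (different chromosome), selected (RNA, bin) pairs
#' can be enriched by a fold factor, and reads carry PCR duplicates,
#' rRNA-contaminant RNA tags, and per-base substitution errors.
#'
#' @param seed Integer seed; the generator is fully deterministic given
#'   (seed, config).
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes,exons_per_gene Gene count (split across chromosomes) and
#'   exons per gene.
#' @param biotype_mix Named fractions over the four biotype groups.
#' @param n_contacts Number of true RNA-DNA contacts to sample.
#' @param cis_decay_alpha,d0 Decay exponent and offset (bp) of the cis
#'   distance distribution.
#' @param frac_trans,frac_nascent Fractions of trans and of nascent-like
#'   (< 1 kb) contacts.
#' @param enriched Optional data.frame(gene_id, chrom, bin, fold): target
#'   bins (per-chromosome index at \code{bin_width}) receiving fold times
#'   the background bin mass for that RNA, renormalised.
#' @param dup_rate Fraction of emitted reads that are exact PCR duplicates.
#' @param rrna_rate Fraction of reads whose RNA tag is an rRNA-unit
#'   substring.
#' @param seq_error_rate Per-base substitution probability.
#' @param barcodes Whitelist of 6-nt library barcodes.
#' @param tag_len_range EcoP15I tag length range, default c(25, 27).
#' @param read_length Read length (default 150).
#' @param bin_width Bin width used for enrichment targets (default 25000).
#' @param expr_meanlog,expr_sdlog Log-normal expression-weight parameters.
#' @param repeat_length,repeat_copies Planted identical repeat: segment
#'   length and number of copies (>= 2 exercises multi-mapping; 1 plants a
#'   single, uniquely mappable copy).
#' @param n_repeats,n_peaks,n_blacklist Numbers of annotated repeat
#'   intervals, peaks, and blacklist intervals.
#' @param rrna_length Length of the synthetic rRNA repeating unit.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 500000L,
                       n_genes = 40L, exons_per_gene = 3L,
                       biotype_mix = c(protein_coding = 0.55,
                                       long_ncRNA = 0.20,
                                       ncRNA = 0.15, other = 0.10),
                       n_contacts = 10000L,
                       cis_decay_alpha = 1.2, d0 = 1000,
                       frac_trans = 0.10, frac_nascent = 0.15,
                       enriched = NULL,
                       dup_rate = 0.10, rrna_rate = 0.05,
                       seq_error_rate = 0.001,
                       barcodes = c("ACGTAC", "TGCAGT", "GATCGA", "CTAGCT"),
                       tag_len_range = c(25L, 27L),
                       read_length = 150L,
                       bin_width = 25000,
                       expr_meanlog = 1, expr_sdlog = 1,
                       repeat_length = 500L, repeat_copies = 2L,
                       n_repeats = 8L, n_peaks = 30L, n_blacklist = 2L,
                       rrna_length = 5000L) {
  fracs <- c(frac_trans = frac_trans, frac_nascent = frac_nascent,
             dup_rate = dup_rate, rrna_rate = rrna_rate,
             seq_error_rate = seq_error_rate)
  if (any(fracs < 0 | fracs > 1))
    stop("all rate/fraction parameters must lie in [0, 1]")
  if (frac_trans + frac_nascent > 1)
    stop("frac_trans + frac_nascent must not exceed 1")
  if (frac_trans > 0 && n_chroms < 2L)
    stop("trans contacts require at least two chromosomes")
  if (!is.null(enriched)) {
    stopifnot(is.data.frame(enriched),
              all(c("gene_id", "chrom", "bin", "fold") %in% names(enriched)),
              all(enriched$fold >= 1))
  }
  stopifnot(length(tag_len_range) == 2L, tag_len_range[1] >= 1,
            tag_len_range[1] <= tag_len_range[2],
            all(nchar(barcodes) == 6L), !anyDuplicated(barcodes),
            abs(sum(biotype_mix) - 1) < 1e-8)
  ol <- radicl_oligos()
  capacity <- 2L * tag_len_range[2] + nchar(ol$adapter_top) +
    nchar(ol$linker_upper) + 6L
  if (capacity > read_length)
    stop("tag_len_range exceeds read capacity: construct needs ", capacity,
         " nt but read_length is ", read_length)
  cfg <- as.list(environment())
  cfg$fracs <- NULL
  cfg$ol <- NULL
  cfg$capacity <- NULL
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_chroms, "x",
      format(x$chrom_length, big.mark = ","), "bp |", x$n_genes, "genes |",
      format(x$n_contacts, big.mark = ","), "contacts\n")
  invisible(x)
}

#' Build a synthetic genome fixture
#'
#' Generates a random genome with non-overlapping genes (exon/intron
#' structure, four biotype groups, log-normal expression weights),
#' non-overlapping TADs, alternating A/B compartments, annotated repeat
#' intervals including a planted multi-copy identical segment, peaks, a
#' blacklist, and a synthetic rRNA repeating unit. Deterministic under
#' \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Optional directory; when given, the fixture is also written
#'   to disk (FASTA, GTF, BED, chrom.sizes, expression table).
#' @return An object of class \code{radicl_fixture}.
#' @export
build_fixture <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fx <- with_seed(config$seed, build_fixture_impl(config))
  if (!is.null(dir)) write_fixture(fx, dir)
  fx
}

build_fixture_impl <- function(config) {
  L <- config$chrom_length
  chroms <- paste0("chr", seq_len(config$n_chroms))
  seqs <- Biostrings::DNAStringSet(vapply(chroms, function(x) random_dna(L), ""))
  names(seqs) <- chroms
  genome <- genome_build(chroms, rep(L, config$n_chroms))

  # genes in the first 70% of each chromosome; repeats planted in the tail
  gene_chrom <- chroms[rep_len(seq_along(chroms), config$n_genes)]
  genes <- NULL; exons <- NULL
  for (cn in chroms) {
    n_here <- sum(gene_chrom == cn)
    if (n_here == 0L) next
    lens <- sample(2000:8000, n_here, replace = TRUE)
    gaps <- sample(500:3000, n_here, replace = TRUE)
    starts <- cumsum(gaps + c(0, lens[-n_here]))
    if (any(starts + lens > 0.7 * L))
      stop("infeasible packing: too many genes for chromosome length")
    ids <- sprintf("G%s.%03d", sub("chr", "", cn), seq_len(n_here))
    genes <- rbind(genes, data.frame(
      gene_id = ids, chrom = cn, start = starts, end = starts + lens,
      strand = sample(c("+", "-"), n_here, replace = TRUE),
      stringsAsFactors = FALSE))
    for (i in seq_len(n_here)) {
      # alternate exon/intron blocks of jittered equal width
      k <- config$exons_per_gene
      nb <- 2L * k - 1L
      w <- lens[i] * (0.5 + stats::runif(nb)) ; w <- w / sum(w) * lens[i]
      bnd <- starts[i] + c(0, round(cumsum(w)))
      bnd[nb + 1L] <- starts[i] + lens[i]
      ex_i <- seq(1L, nb, by = 2L)
      exons <- rbind(exons, data.frame(
        gene_id = ids[i], chrom = cn,
        start = bnd[ex_i], end = bnd[ex_i + 1L],
        strand = genes$strand[nrow(genes) - n_here + i],
        stringsAsFactors = FALSE))
    }
  }
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  mix <- config$biotype_mix
  type_of <- c(protein_coding = "protein_coding", long_ncRNA = "lincRNA",
               ncRNA = "snRNA", other = "TEC")
  grp <- sample(names(mix), nrow(genes), replace = TRUE, prob = mix)
  genes$gene_type <- unname(type_of[grp])
  genes$gene_name <- sub("^G", "Gene", genes$gene_id)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  expression <- stats::setNames(
    stats::rlnorm(nrow(genes), config$expr_meanlog, config$expr_sdlog),
    genes$gene_id)

  # planted identical repeat copies in the gene-free tail of chromosome 1
  rep_seq <- random_dna(config$repeat_length)
  tail_lo <- ceiling(0.75 * L)
  rep_starts <- round(seq(tail_lo, L - config$repeat_length - 100,
                          length.out = max(config$repeat_copies, 1L)))
  repeats <- NULL
  for (j in seq_len(config$repeat_copies)) {
    s <- rep_starts[j]
    seqs[[chroms[1]]] <- Biostrings::replaceAt(
      seqs[[chroms[1]]],
      IRanges::IRanges(s + 1L, s + config$repeat_length),
      Biostrings::DNAString(rep_seq))
    repeats <- rbind(repeats, data.frame(
      chrom = chroms[1], start = s, end = s + config$repeat_length,
      name = "LINE", strand = "+", stringsAsFactors = FALSE))
  }
  fams <- c("SINE", "LINE", "LTR", "snRNA")
  if (config$n_repeats > 0L) {
    rl <- sample(200:600, config$n_repeats, replace = TRUE)
    rc <- sample(chroms, config$n_repeats, replace = TRUE)
    rs <- floor(stats::runif(config$n_repeats) * (L - rl))
    repeats <- rbind(repeats, data.frame(
      chrom = rc, start = rs, end = rs + rl,
      name = sample(fams, config$n_repeats, replace = TRUE),
      strand = sample(c("+", "-"), config$n_repeats, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  planted <- repeats[seq_len(config$repeat_copies), , drop = FALSE]
  repeats <- repeats[order(repeats$chrom, repeats$start), ]
  rownames(repeats) <- NULL

  # TADs: non-overlapping 50-100 kb domains with small gaps
  tads <- NULL
  for (cn in chroms) {
    pos <- 0
    while (pos + 100000 < L) {
      w <- sample(50000:100000, 1L)
      g <- sample(0:5000, 1L)
      if (pos + w > L) break
      tads <- rbind(tads, data.frame(chrom = cn, start = pos, end = pos + w,
                                     stringsAsFactors = FALSE))
      pos <- pos + w + g
    }
  }
  tads$name <- sprintf("TAD%03d", seq_len(nrow(tads)))

  # A/B compartments: alternating 100-kb blocks, 25-kb aligned
  comp <- NULL
  for (cn in chroms) {
    starts <- seq(0, L - 1, by = 100000)
    comp <- rbind(comp, data.frame(
      chrom = cn, start = starts, end = pmin(starts + 100000, L),
      name = rep_len(c("A", "B"), length(starts)),
      stringsAsFactors = FALSE))
  }

  pl <- sample(500:2000, config$n_peaks, replace = TRUE)
  pc <- sample(chroms, config$n_peaks, replace = TRUE)
  ps <- floor(stats::runif(config$n_peaks) * (L - pl))
  peaks <- data.frame(chrom = pc, start = ps, end = ps + pl,
                      name = sprintf("peak%03d", seq_len(config$n_peaks)),
                      stringsAsFactors = FALSE)

  bs <- floor(stats::runif(config$n_blacklist) * (L - 10000))
  blacklist <- data.frame(
    chrom = sample(chroms, config$n_blacklist, replace = TRUE),
    start = bs, end = bs + sample(5000:10000, config$n_blacklist, TRUE),
    stringsAsFactors = FALSE)

  structure(list(config = config, genome = genome, genome_seq = seqs,
                 rrna = random_dna(config$rrna_length),
                 genes = genes, exons = exons, expression = expression,
                 tads = tads, repeats = repeats, planted_repeats = planted,
                 peaks = peaks,
                 blacklist = blacklist, compartments = comp),
            class = "radicl_fixture")
}

#' @export
print.radicl_fixture <- function(x, ...) {
  cat("radicl_fixture:", length(x$genome$chrom_names), "chromosomes,",
      nrow(x$genes), "genes,", nrow(x$tads), "TADs,",
      nrow(x$repeats), "repeat intervals\n")
  invisible(x)
}

#' Write a fixture to disk
#'
#' @param fixture A \code{radicl_fixture}.
#' @param dir Output directory (created if absent).
#' @return Named vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(fixture$genome_seq, p("genome.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(rRNA_unit = fixture$rrna)), p("rrna.fa"))
  write_gtf(fixture$genes, fixture$exons, p("genes.gtf"))
  write_bed(fixture$tads, p("tads.bed"))
  write_bed(fixture$repeats, p("repeats.bed"))
  write_bed(fixture$peaks, p("peaks.bed"))
  write_bed(fixture$blacklist, p("blacklist.bed"))
  write_bed(fixture$compartments, p("compartments.bed"))
  write_chrom_sizes(fixture$genome, p("chrom.sizes"))
  utils::write.table(
    data.frame(gene_id = names(fixture$expression),
               expression = unname(fixture$expression)),
    p("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stats::setNames(
    p(c("genome.fa", "rrna.fa", "genes.gtf", "tads.bed", "repeats.bed",
        "peaks.bed", "blacklist.bed", "compartments.bed", "chrom.sizes",
        "expression.tsv")),
    c("genome", "rrna", "gtf", "tads", "repeats", "peaks", "blacklist",
      "compartments", "chrom_sizes", "expression")))
}

#' Truncated power-law distance sampler and CDF
#'
#' Cis contact distances follow \eqn{P(d) \propto (d + d0)^{-\alpha}} on
#' \code{[1, dmax]} (continuous, rounded to integer bp).
#'
#' @param n Number of draws.
#' @param alpha Decay exponent (>= 0).
#' @param d0 Offset in bp (> 0).
#' @param dmax Upper truncation in bp.
#' @return \code{decay_distance} returns integer distances;
#'   \code{decay_cdf} the CDF evaluated at \code{d}.
#' @export
decay_distance <- function(n, alpha, d0, dmax) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    d <- (1 + d0) * exp(u * log((dmax + d0) / (1 + d0))) - d0
  } else {
    a <- (1 + d0)^(1 - alpha)
    b <- (dmax + d0)^(1 - alpha)
    d <- (a + u * (b - a))^(1 / (1 - alpha)) - d0
  }
  pmax(1L, pmin(as.integer(round(d)), as.integer(dmax)))
}

#' @rdname decay_distance
#' @param d Distances at which to evaluate the CDF.
#' @export
decay_cdf <- function(d, alpha, d0, dmax) {
  d <- pmax(pmin(d, dmax), 1)
  if (abs(alpha - 1) < 1e-12) {
    log((d + d0) / (1 + d0)) / log((dmax + d0) / (1 + d0))
  } else {
    a <- (1 + d0)^(1 - alpha)
    b <- (dmax + d0)^(1 - alpha)
    ((d + d0)^(1 - alpha) - a) / (b - a)
  }
}

#' Sample ground-truth RNA-DNA contacts
#'
#' Per contact, the source gene is drawn from the fixture's expression
#' weights; the RNA tag is a 25-27 nt interval within the gene on its
#' strand; the DNA position is drawn from the mixture {nascent < 1 kb,
#' cis power-law decay, trans uniform}. For RNAs listed in
#' \code{config$enriched}, DNA bins are drawn from the discretised
#' background bin mass with the target bin multiplied by its fold factor
#' and renormalised.
#'
#' @param fixture A \code{radicl_fixture}.
#' @param n Number of contacts (default \code{config$n_contacts}).
#' @param seed Seed (default \code{config$seed + 1}).
#' @return data.frame of truth contacts: contact id, gene, RNA tag interval
#'   and strand, DNA tag interval.
#' @export
sample_contacts <- function(fixture, n = NULL, seed = NULL) {
  stopifnot(inherits(fixture, "radicl_fixture"))
  cfg <- fixture$config
  if (is.null(n)) n <- cfg$n_contacts
  if (is.null(seed)) seed <- cfg$seed + 1L
  with_seed(seed, sample_contacts_impl(fixture, n))
}

sample_contacts_impl <- function(fixture, n) {
  cfg <- fixture$config
  genes <- fixture$genes
  L <- cfg$chrom_length
  gi <- sample(nrow(genes), n, replace = TRUE,
               prob = fixture$expression[genes$gene_id])
  g <- genes[gi, ]
  tlr <- cfg$tag_len_range
  rna_len <- sample(seq(tlr[1], tlr[2]), n, replace = TRUE)
  rna_start <- g$start + floor(stats::runif(n) * (g$end - g$start - rna_len + 1))
  rna_end <- rna_start + rna_len
  rna_center <- fragment_center(rna_start, rna_end)

  u <- stats::runif(n)
  mode <- ifelse(u < cfg$frac_trans, "trans",
                 ifelse(u < cfg$frac_trans + cfg$frac_nascent,
                        "nascent", "cis"))
  dna_chrom <- g$chrom
  dna_center <- numeric(n)

  enr <- cfg$enriched
  is_enr <- if (is.null(enr)) rep(FALSE, n) else g$gene_id %in% enr$gene_id

  i <- mode == "trans" & !is_enr
  if (any(i)) {
    pick_other <- function(cn) sample(setdiff(fixture$genome$chrom_names, cn), 1L)
    dna_chrom[i] <- vapply(g$chrom[i], pick_other, "")
    dna_center[i] <- floor(stats::runif(sum(i)) * L)
  }
  left <- rna_center
  right <- L - 1 - rna_center
  i <- mode == "nascent" & !is_enr
  if (any(i)) {
    d <- sample(0:999, sum(i), replace = TRUE)
    dna_center[i] <- place_at_distance(rna_center[i], d, left[i], right[i])
  }
  i <- mode == "cis" & !is_enr
  if (any(i)) {
    dmax <- pmax(left[i], right[i])
    d <- decay_distance(sum(i), cfg$cis_decay_alpha, cfg$d0, max(dmax))
    d <- pmin(d, dmax)
    dna_center[i] <- place_at_distance(rna_center[i], d, left[i], right[i])
  }
  if (any(is_enr)) {
    scheme <- make_bins(fixture$genome, cfg$bin_width)
    bt <- bin_table(scheme)
    for (gid in unique(g$gene_id[is_enr])) {
      sel <- which(is_enr & g$gene_id == gid)
      w <- enriched_bin_weights(fixture, gid, bt)
      bi <- sample(nrow(bt), length(sel), replace = TRUE, prob = w)
      dna_chrom[sel] <- bt$chrom[bi]
      dna_center[sel] <- bt$start[bi] +
        floor(stats::runif(length(sel)) * (bt$end[bi] - bt$start[bi]))
    }
  }
  dna_len <- sample(seq(tlr[1], tlr[2]), n, replace = TRUE)
  dna_start <- pmax(0, pmin(dna_center - floor((dna_len - 1) / 2),
                            L - dna_len))
  data.frame(contact_id = sprintf("read%06d", seq_len(n)),
             gene_id = g$gene_id,
             rna_chrom = g$chrom, rna_start = rna_start, rna_end = rna_end,
             rna_strand = g$strand,
             dna_chrom = dna_chrom, dna_start = dna_start,
             dna_end = dna_start + dna_len,
             stringsAsFactors = FALSE, row.names = NULL)
}

place_at_distance <- function(center, d, left, right) {
  ok_minus <- d <= left
  ok_plus <- d <= right
  sign <- ifelse(ok_minus & ok_plus,
                 ifelse(stats::runif(length(d)) < 0.5, -1, 1),
                 ifelse(ok_plus, 1, -1))
  center + sign * d
}

# discretised background bin mass for an enriched RNA: nascent mass to the
# gene-center bin, cis mass ~ (|bin center - gene center| + d0)^-alpha,
# trans mass uniform over other chromosomes; enriched bins scaled by fold
enriched_bin_weights <- function(fixture, gene_id, bt) {
  cfg <- fixture$config
  g <- fixture$genes[fixture$genes$gene_id == gene_id, ]
  gc <- fragment_center(g$start, g$end)
  w <- numeric(nrow(bt))
  cis <- bt$chrom == g$chrom
  bc <- (bt$start + bt$end) / 2
  wc <- (abs(bc[cis] - gc) + cfg$d0)^(-cfg$cis_decay_alpha) *
    (bt$end[cis] - bt$start[cis])
  p_cis <- 1 - cfg$frac_trans - cfg$frac_nascent
  w[cis] <- wc / sum(wc) * p_cis
  if (cfg$frac_nascent > 0) {
    home <- cis & bt$start <= gc & gc < bt$end
    w[home] <- w[home] + cfg$frac_nascent
  }
  if (any(!cis) && cfg$frac_trans > 0) {
    wt <- bt$end[!cis] - bt$start[!cis]
    w[!cis] <- wt / sum(wt) * cfg$frac_trans
  }
  enr <- cfg$enriched[cfg$enriched$gene_id == gene_id, , drop = FALSE]
  for (j in seq_len(nrow(enr))) {
    hit <- bt$chrom == enr$chrom[j] & bt$bin == enr$bin[j]
    w[hit] <- w[hit] * enr$fold[j]
  }
  w / sum(w)
}

#' Synthesize chimeric RADICL-seq reads from truth contacts
#'
#' Each 150-nt read is assembled as RNA tag (transcript sense), 50-nt
#' bridge-adapter top strand, DNA tag, sequencing-linker stub, 6-nt
#' barcode, and random padding; with probability 0.5 the whole construct
#' is reverse-complemented (opposite sequencing direction). rRNA
#' contaminants replace the RNA tag with an rRNA-unit substring; per-base
#' substitution errors are applied; PCR duplicates are appended as exact
#' copies.
#'
#' @param contacts Truth contacts from \code{\link{sample_contacts}}.
#' @param fixture The \code{radicl_fixture} the contacts were sampled on.
#' @param seed Seed (default \code{config$seed + 2}).
#' @return List with \code{reads} (read_id, seq) and \code{truth} (per
#'   read: contact fields plus barcode, construct orientation, duplicate
#'   and rRNA-contaminant flags).
#' @export
synthesize_reads <- function(contacts, fixture, seed = NULL) {
  stopifnot(inherits(fixture, "radicl_fixture"))
  cfg <- fixture$config
  if (is.null(seed)) seed <- cfg$seed + 2L
  with_seed(seed, synthesize_reads_impl(contacts, fixture))
}

synthesize_reads_impl <- function(contacts, fixture) {
  cfg <- fixture$config
  ol <- radicl_oligos()
  n <- nrow(contacts)
  rna_seq <- genome_seqs(fixture$genome_seq, contacts$rna_chrom,
                         contacts$rna_start, contacts$rna_end)
  minus <- contacts$rna_strand == "-"
  rna_seq[minus] <- revcomp(rna_seq[minus])
  dna_seq <- genome_seqs(fixture$genome_seq, contacts$dna_chrom,
                         contacts$dna_start, contacts$dna_end)

  is_rrna <- stats::runif(n) < cfg$rrna_rate
  if (any(is_rrna)) {
    len <- nchar(rna_seq[is_rrna])
    pos <- floor(stats::runif(sum(is_rrna)) * (cfg$rrna_length - len)) + 1L
    rna_seq[is_rrna] <- substring(fixture$rrna, pos, pos + len - 1L)
  }
  barcode <- sample(cfg$barcodes, n, replace = TRUE)
  core <- paste0(rna_seq, ol$adapter_top, dna_seq, ol$linker_upper, barcode)
  pad_n <- cfg$read_length - nchar(core)
  pad <- vapply(pad_n, random_dna, "")
  reads <- paste0(core, pad)
  reverse <- stats::runif(n) < 0.5
  reads[reverse] <- revcomp(reads[reverse])
  reads <- apply_substitutions(reads, cfg$seq_error_rate)

  truth <- cbind(contacts,
                 data.frame(read_id = contacts$contact_id,
                            barcode = barcode, reverse = reverse,
                            rrna_contaminant = is_rrna,
                            duplicate = FALSE,
                            orig_id = NA_character_,
                            stringsAsFactors = FALSE))
  if (cfg$dup_rate > 0) {
    n_dup <- round(n * cfg$dup_rate / (1 - cfg$dup_rate))
    src <- sample(n, n_dup, replace = TRUE)
    dup_truth <- truth[src, ]
    dup_truth$read_id <- sprintf("dup%06d", seq_len(n_dup))
    dup_truth$duplicate <- TRUE
    dup_truth$orig_id <- truth$read_id[src]
    truth <- rbind(truth, dup_truth)
    reads <- c(reads, reads[src])
  }
  rownames(truth) <- NULL
  list(reads = data.frame(read_id = truth$read_id, seq = reads,
                          stringsAsFactors = FALSE),
       truth = truth)
}

apply_substitutions <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Simulate a complete RADICL-seq library
#'
#' Convenience wrapper: \code{\link{build_fixture}},
#' \code{\link{sample_contacts}}, \code{\link{synthesize_reads}}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Optional output directory; when given, fixture files and a
#'   FASTQ are written.
#' @return List with \code{fixture}, \code{contacts}, \code{reads},
#'   \code{truth} (and \code{paths} when written).
#' @export
simulate_library <- function(config, dir = NULL) {
  fixture <- build_fixture(config, dir = dir)
  contacts <- sample_contacts(fixture)
  rd <- synthesize_reads(contacts, fixture)
  out <- list(fixture = fixture, contacts = contacts,
              reads = rd$reads, truth = rd$truth)
  if (!is.null(dir)) {
    fq <- file.path(dir, "reads.fastq")
    write_fastq(rd$reads$read_id, rd$reads$seq, fq)
    utils::write.table(rd$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- c(fastq = fq, truth = file.path(dir, "truth.tsv"))
  }
  out
}
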