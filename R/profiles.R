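# Downstream summaries of RNA-chromatin interaction sets: replicate
# reproducibility, expression correlation, distance decay by expression
# quartile, TAD metaprofiles, peak density profiles, repeat enrichment,
# and cross-sample comparisons.

#' Pairwise Pearson correlation between replicate count tables
#'
#' Correlation is computed on the counts of complete observations: (RNA,
#' bin) units observed (count > 0) in every table.
#'
#' @param tables Named list (>= 2) of count data.frames with rna, bin,
#'   count columns.
#' @return data.frame of table pairs with Pearson r and the number of
#'   complete units.
#' @export
replicate_correlation <- function(tables) {
  if (length(tables) < 2L) stop("need at least two count tables")
  if (is.null(names(tables)))
    names(tables) <- paste0("rep", seq_along(tables))
  keys <- lapply(tables, function(t) paste0(t$rna, "\r", t$bin))
  common <- Reduce(intersect, keys)
  counts <- vapply(seq_along(tables), function(i)
    tables[[i]]$count[match(common, keys[[i]])], numeric(length(common)))
  cmb <- utils::combn(length(tables), 2L)
  data.frame(a = names(tables)[cmb[1L, ]], b = names(tables)[cmb[2L, ]],
             r = apply(cmb, 2L, function(ij)
               stats::cor(counts[, ij[1L]], counts[, ij[2L]])),
             n = length(common), stringsAsFactors = FALSE)
}

#' Squared correlation between interaction counts and expression
#'
#' Interaction counts are normalised to reads per kilobase (RPK) of the
#' gene; genes with RPK >= threshold and TPM >= threshold are retained and
#' the squared Pearson correlation of the log10 values is returned.
#'
#' @param counts Named per-gene interaction counts.
#' @param lengths Named gene lengths in bp.
#' @param tpm Named expression values (TPM).
#' @param threshold Lower threshold applied to both RPK and TPM
#'   (default 1).
#' @return List with r_squared, n genes retained, and the merged table.
#' @export
expression_correlation <- function(counts, lengths, tpm, threshold = 1) {
  genes <- intersect(names(counts), names(tpm))
  rpk <- counts[genes] / (lengths[genes] / 1000)
  keep <- rpk >= threshold & tpm[genes] >= threshold
  if (!any(keep)) stop("no genes pass the RPK/TPM threshold")
  r <- stats::cor(log10(rpk[keep]), log10(tpm[genes][keep]))
  list(r_squared = unname(r^2), n = sum(keep),
       table = data.frame(gene_id = genes[keep], rpk = unname(rpk[keep]),
                          tpm = unname(tpm[genes][keep]),
                          stringsAsFactors = FALSE))
}

#' Distance from DNA tag centers to their source gene
#'
#' Linear distance from the DNA tag center to the nearest edge of the
#' RNA's gene span; 0 inside the gene body; NA for trans pairs.
#' @noRd
gene_edge_distance <- function(pairs, genes) {
  gidx <- match(pairs$rna_gene, genes$gene_id)
  d <- pmax(genes$start[gidx] - pairs$dna_center,
            pairs$dna_center - (genes$end[gidx] - 1), 0)
  d[pairs$dna_chrom != genes$chrom[gidx]] <- NA
  d
}

#' Contact distance decay by expression quartile
#'
#' Splits genic transcripts into expression quartiles (I lowest, IV
#' highest), measures the distance from each cis DNA tag center to the
#' nearest gene-span edge (0 inside the gene), aggregates counts in
#' log-spaced distance bins, and normalises each quartile's curve to sum
#' to 1.
#'
#' @param pairs Annotated pairs (rna_gene column required).
#' @param genes Gene table.
#' @param expression Named per-gene expression values.
#' @param n_quartiles Number of expression groups (default 4).
#' @param n_dist_bins Number of log-spaced distance bins (default 20).
#' @return List: \code{curves} (quartile x bin matrix of normalised
#'   fractions), \code{breaks}, and \code{mean_log10} per quartile (mean
#'   log10 distance of non-zero-distance contacts, a decay-rate summary).
#' @export
distance_decay <- function(pairs, genes, expression, n_quartiles = 4L,
                           n_dist_bins = 20L) {
  keep <- !is.na(pairs$rna_gene) & pairs$rna_gene %in% names(expression)
  p <- pairs[keep, , drop = FALSE]
  d <- gene_edge_distance(p, genes)
  cis <- !is.na(d)
  p <- p[cis, , drop = FALSE]; d <- d[cis]
  expr <- expression[p$rna_gene]
  qs <- stats::quantile(expression, probs = seq(0, 1,
                                                length.out = n_quartiles + 1L))
  quart <- cut(expr, breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
  quart <- factor(utils::as.roman(quart), levels = utils::as.roman(
    seq_len(max(quart, na.rm = TRUE))))
  dmax <- max(d, 1)
  breaks <- c(-0.5, 0.5, exp(seq(log(1), log(dmax + 1),
                                 length.out = n_dist_bins))[-1])
  breaks[length(breaks)] <- dmax + 1
  db <- cut(d, breaks = breaks, include.lowest = TRUE)
  m <- table(quart, db)
  curves <- sweep(m, 1L, pmax(rowSums(m), 1L), "/")
  mean_log10 <- tapply(d, quart, function(x)
    if (any(x > 0)) mean(log10(x[x > 0])) else NA_real_)
  list(curves = unclass(curves), breaks = breaks,
       mean_log10 = mean_log10)
}

#' Fraction of interactions below a distance threshold
#'
#' The nascent-transcription proxy: the fraction of RNA-DNA pairs whose
#' tags lie within d bp (default 1 kb) on the same chromosome, reported
#' against all pairs and against cis pairs only.
#'
#' @param pairs A \code{contact_pairs} data.frame.
#' @param d Distance threshold in bp (default 1000).
#' @return List with \code{overall} and \code{cis} fractions.
#' @export
fraction_below <- function(pairs, d = 1000) {
  cis <- pairs$rna_chrom == pairs$dna_chrom
  close <- cis & abs(pairs$rna_center - pairs$dna_center) < d
  list(overall = if (nrow(pairs)) sum(close) / nrow(pairs) else 0,
       cis = if (any(cis)) sum(close) / sum(cis) else 0)
}

#' Metaprofile of tag coverage over regions
#'
#' Each region is extended by its own width on both sides, the resulting
#' window divided into \code{n_bins} position bins (the region proper
#' occupying the central third, bins 101-200 of 300), per-bin counts are
#' scaled to a per-bp rate, and rates are averaged across regions.
#' Regions whose extended window leaves the chromosome are dropped.
#'
#' @param chrom,pos Tag center coordinates (0-based).
#' @param regions Region table (chrom, start, end).
#' @param genome A \code{genome_build} (for boundary checks).
#' @param n_bins Number of position bins (default 300).
#' @return Object of class \code{meta_profile}: mean per-bp rate per bin,
#'   number of regions aggregated, number dropped.
#' @export
meta_profile <- function(chrom, pos, regions, genome, n_bins = 300L) {
  w <- regions$end - regions$start
  lo <- regions$start - w
  hi <- regions$end + w
  usable <- lo >= 0 & hi <= chrom_length(genome, regions$chrom)
  if (!any(usable)) stop("no usable regions after extension")
  reg <- regions[usable, , drop = FALSE]
  lo <- lo[usable]; hi <- hi[usable]
  acc <- matrix(0, nrow = sum(usable), ncol = n_bins)
  for (i in seq_len(nrow(reg))) {
    sel <- chrom == reg$chrom[i] & pos >= lo[i] & pos < hi[i]
    bw <- (hi[i] - lo[i]) / n_bins
    if (any(sel)) {
      b <- pmin(floor((pos[sel] - lo[i]) / bw), n_bins - 1L) + 1L
      acc[i, ] <- tabulate(b, nbins = n_bins) / bw
    }
  }
  structure(list(profile = colMeans(acc), n_regions = nrow(reg),
                 n_dropped = sum(!usable), n_bins = n_bins,
                 per_region = acc),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile:", x$n_bins, "bins over", x$n_regions, "regions (",
      x$n_dropped, "dropped ); central mean",
      signif(mean(central_bins(x)), 4), "vs flank mean",
      signif(mean(flank_bins(x)), 4), "\n")
  invisible(x)
}

#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(seq_len(x$n_bins), x$profile, type = "l",
                 xlab = "position bin", ylab = "mean tag rate (per bp)", ...)
  graphics::abline(v = c(x$n_bins / 3, 2 * x$n_bins / 3), lty = 2)
  invisible(x)
}

central_bins <- function(mp) {
  k <- mp$n_bins / 3
  mp$profile[(k + 1):(2 * k)]
}
flank_bins <- function(mp) {
  k <- mp$n_bins / 3
  mp$profile[c(1:k, (2 * k + 1):mp$n_bins)]
}

#' DNA-tag metaprofiles split by RNA origin relative to each TAD
#'
#' On a TAD-by-TAD basis, pairs are split by whether the RNA tag center
#' lies inside the TAD (half-open interval) or outside it, and the DNA
#' tag centers of each split are aggregated into a TAD metaprofile.
#'
#' @param pairs A \code{contact_pairs} data.frame.
#' @param tads TAD table (chrom, start, end).
#' @param genome A \code{genome_build}.
#' @param n_bins Number of position bins (default 300).
#' @return List with \code{inside} and \code{outside}
#'   \code{meta_profile}s.
#' @export
inside_outside_profile <- function(pairs, tads, genome, n_bins = 300L) {
  if (is.null(tads) || nrow(tads) == 0L) stop("no TADs supplied")
  w <- tads$end - tads$start
  usable <- tads$start - w >= 0 &
    tads$end + w <= chrom_length(genome, tads$chrom)
  if (!any(usable)) stop("no usable TADs after extension")
  reg <- tads[usable, , drop = FALSE]
  acc_in <- acc_out <- matrix(0, nrow = nrow(reg), ncol = n_bins)
  for (i in seq_len(nrow(reg))) {
    lo <- reg$start[i] - (reg$end[i] - reg$start[i])
    hi <- reg$end[i] + (reg$end[i] - reg$start[i])
    bw <- (hi - lo) / n_bins
    inside <- pairs$rna_chrom == reg$chrom[i] &
      pairs$rna_center >= reg$start[i] & pairs$rna_center < reg$end[i]
    in_win <- pairs$dna_chrom == reg$chrom[i] &
      pairs$dna_center >= lo & pairs$dna_center < hi
    for (side in c("in", "out")) {
      sel <- in_win & (if (side == "in") inside else !inside)
      if (any(sel)) {
        b <- pmin(floor((pairs$dna_center[sel] - lo) / bw), n_bins - 1L) + 1L
        v <- tabulate(b, nbins = n_bins) / bw
        if (side == "in") acc_in[i, ] <- v else acc_out[i, ] <- v
      }
    }
  }
  mk <- function(acc) structure(
    list(profile = colMeans(acc), n_regions = nrow(reg),
         n_dropped = sum(!usable), n_bins = n_bins, per_region = acc),
    class = "meta_profile")
  list(inside = mk(acc_in), outside = mk(acc_out))
}

#' Tag density profile around peaks
#'
#' Aggregates tag centers by offset from peak centers within a +/-
#' half_window bp window (1-bp resolution) and divides by the mean over
#' the window to align baselines; optionally also profiles a matched set
#' of random regions.
#'
#' @param chrom,pos Tag center coordinates.
#' @param peaks Peak table (chrom, start, end).
#' @param half_window Half-window in bp (default 5000).
#' @param genome Optional \code{genome_build}; when supplied together
#'   with \code{random_baseline = TRUE}, a matched random peak set is
#'   profiled as control.
#' @param random_baseline Also compute a random-region baseline.
#' @param baseline \code{"window"} (default) divides by the mean over the
#'   whole window; \code{"edges"} divides by the mean of the outermost 10
#'   percent of offsets.
#' @return List: \code{offset} (-half_window..half_window),
#'   \code{density} (normalised), optionally \code{random_density}.
#' @export
peak_density_profile <- function(chrom, pos, peaks, half_window = 5000L,
                                 genome = NULL, random_baseline = FALSE,
                                 baseline = c("window", "edges")) {
  baseline <- match.arg(baseline)
  profile_for <- function(pk) {
    pc <- fragment_center(pk$start, pk$end)
    counts <- numeric(2L * half_window + 1L)
    for (i in seq_len(nrow(pk))) {
      sel <- chrom == pk$chrom[i] & abs(pos - pc[i]) <= half_window
      if (any(sel)) {
        off <- pos[sel] - pc[i] + half_window + 1L
        counts <- counts + tabulate(off, nbins = 2L * half_window + 1L)
      }
    }
    base <- if (baseline == "window") mean(counts) else {
      k <- max(1L, round(0.05 * length(counts)))
      mean(counts[c(seq_len(k), length(counts) - seq_len(k) + 1L)])
    }
    if (base == 0) counts else counts / base
  }
  out <- list(offset = seq(-half_window, half_window),
              density = profile_for(peaks))
  if (random_baseline) {
    if (is.null(genome)) stop("random baseline requires a genome_build")
    wlen <- peaks$end - peaks$start
    rchrom <- sample(genome$chrom_names, nrow(peaks), replace = TRUE)
    rstart <- floor(stats::runif(nrow(peaks)) *
                      (chrom_length(genome, rchrom) - wlen))
    out$random_density <- profile_for(
      data.frame(chrom = rchrom, start = rstart, end = rstart + wlen))
  }
  out
}

#' Repeat-family interaction percentages by distance interval
#'
#' For each repeat family (including \code{"NR"}, RNA tags on no repeat),
#' the number of significant interactions in each RNA-DNA distance
#' interval is divided by the family's total RNA tag count. With a
#' replicate column, each family is compared against NR per interval by a
#' two-sided equal-variance Student's t test on the replicate-level
#' proportions. Self-interactions must be removed beforehand.
#'
#' @param pairs Annotated pairs with \code{repeat_family} and
#'   \code{distance_class} columns (pre-filtered to significant,
#'   non-self interactions).
#' @param replicate Optional factor of replicate labels per pair.
#' @return List: \code{percent} (family x interval percentage matrix),
#'   \code{totals} (per-family tag counts), and \code{tests} (per
#'   interval and family, t statistic and p value vs NR) when replicates
#'   are given.
#' @export
repeat_interval_proportions <- function(pairs, replicate = NULL) {
  stopifnot(!is.null(pairs$repeat_family), !is.null(pairs$distance_class))
  if (any(pairs$self_interaction %||% FALSE))
    stop("remove self-interactions before computing repeat proportions")
  fam <- pairs$repeat_family
  tot <- table(fam)
  empty <- names(tot)[tot == 0L]
  m <- table(fam, pairs$distance_class)
  percent <- sweep(m, 1L, as.numeric(tot[rownames(m)]), "/") * 100
  out <- list(percent = unclass(percent),
              totals = as.integer(tot), excluded = empty)
  names(out$totals) <- names(tot)
  if (!is.null(replicate)) {
    if (!"NR" %in% fam) stop("no NR (non-repeat) tags to compare against")
    reps <- sort(unique(replicate))
    prop <- function(f, cl, r) {
      i <- replicate == r & fam == f
      if (!any(i)) return(NA_real_)
      sum(pairs$distance_class[i] == cl) / sum(i) * 100
    }
    classes <- levels(pairs$distance_class)
    fams <- setdiff(rownames(m), "NR")
    tests <- do.call(rbind, lapply(classes, function(cl) {
      do.call(rbind, lapply(fams, function(f) {
        x <- vapply(reps, function(r) prop(f, cl, r), 0)
        y <- vapply(reps, function(r) prop("NR", cl, r), 0)
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2L || length(y) < 2L)
          return(data.frame(interval = cl, family = f, t = NA_real_,
                            p = NA_real_))
        if (stats::sd(c(x - mean(x), y - mean(y))) == 0)
          return(data.frame(interval = cl, family = f, t = 0, p = 1))
        tt <- stats::t.test(x, y, var.equal = TRUE)
        data.frame(interval = cl, family = f, t = unname(tt$statistic),
                   p = tt$p.value, stringsAsFactors = FALSE)
      }))
    }))
    out$tests <- tests
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary DNA-binding profiles on 5-kb bins
#'
#' Per gene, a binary vector over 5-kb genome bins: 1 where at least one
#' DNA tag of that RNA falls in the bin.
#'
#' @param pairs Annotated pairs (rna_gene required).
#' @param scheme A 5-kb \code{\link{make_bins}} scheme.
#' @return Named list of character vectors of occupied bin keys, with the
#'   scheme width attached as attribute \code{"width"}.
#' @export
binding_profile <- function(pairs, scheme) {
  keep <- !is.na(pairs$rna_gene)
  key <- bin_key(scheme, pairs$dna_chrom[keep], pairs$dna_center[keep])
  out <- lapply(split(key, pairs$rna_gene[keep]), unique)
  attr(out, "width") <- scheme$width
  out
}

#' Jaccard binding distance and capture-rate difference per gene
#'
#' Compares two conditions: the Jaccard distance J = 1 - |A int B| / |A
#' un B| between each gene's binary 5-kb binding profiles (0 when both
#' are empty), and the difference in normalised counts as a percentage of
#' the maximum in either condition (0 when both are zero).
#'
#' @param binding_a,binding_b \code{\link{binding_profile}} outputs on
#'   the same bin scheme.
#' @param counts_a,counts_b Named per-gene normalised counts.
#' @return data.frame: gene_id, jaccard_distance, capture_diff_pct.
#' @export
jaccard_vs_capture <- function(binding_a, binding_b, counts_a, counts_b) {
  if (!identical(attr(binding_a, "width"), attr(binding_b, "width")))
    stop("binding profiles use different bin schemes")
  genes <- union(names(binding_a), names(binding_b))
  jd <- vapply(genes, function(g) {
    a <- binding_a[[g]] %||% character(0)
    b <- binding_b[[g]] %||% character(0)
    u <- length(union(a, b))
    if (u == 0L) 0 else 1 - length(intersect(a, b)) / u
  }, 0)
  ca <- counts_a[genes]; cb <- counts_b[genes]
  ca[is.na(ca)] <- 0; cb[is.na(cb)] <- 0
  mx <- pmax(ca, cb)
  diff_pct <- ifelse(mx == 0, 0, abs(ca - cb) / mx * 100)
  data.frame(gene_id = genes, jaccard_distance = unname(jd),
             capture_diff_pct = unname(diff_pct),
             stringsAsFactors = FALSE)
}

#' Promoter-level log2 ratio of normalised DNA tag counts
#'
#' Counts DNA tag centers in +/- flank promoter windows per gene,
#' normalises each library to counts per million, and returns log2 of
#' the ratio with a pseudocount of 1 on the normalised counts.
#'
#' @param pairs_a,pairs_b \code{contact_pairs} of the two conditions.
#' @param promoters Promoter windows from \code{\link{promoter_windows}}.
#' @return data.frame: gene_id, cpm_a, cpm_b, log2_ratio.
#' @export
promoter_log2ratio <- function(pairs_a, pairs_b, promoters) {
  count_in <- function(pairs) {
    q <- point_granges(pairs$dna_chrom, pairs$dna_center)
    ov <- quiet_overlaps(q, df_granges(promoters))
    tab <- table(factor(S4Vectors::subjectHits(ov),
                        levels = seq_len(nrow(promoters))))
    as.numeric(tab)
  }
  ka <- normalize_cpm(count_in(pairs_a), nrow(pairs_a))
  kb <- normalize_cpm(count_in(pairs_b), nrow(pairs_b))
  data.frame(gene_id = promoters$gene_id, cpm_a = ka, cpm_b = kb,
             log2_ratio = log2((ka + 1) / (kb + 1)),
             stringsAsFactors = FALSE)
}

#' Unique genomic targets per RNA
#'
#' Number of distinct contacted bins per RNA in a contact matrix or in
#' the significant set of a \code{radicl_sig}.
#'
#' @param x A \code{contact_matrix} or \code{radicl_sig}.
#' @return Named integer vector, one entry per represented RNA.
#' @export
unique_targets <- function(x) {
  if (inherits(x, "radicl_sig")) {
    tab <- sig_table(x)
    u <- tapply(tab$bin, tab$rna, function(b) length(unique(b)))
    stats::setNames(as.integer(u), names(u))
  } else if (inherits(x, "contact_matrix")) {
    x$U
  } else stop("x must be a contact_matrix or radicl_sig")
}

#' Same-compartment fraction of interactions
#'
#' Labels RNA and DNA bins with A/B compartments and returns the fraction
#' of pairs whose two bins carry the same label; unlabelled bins are
#' excluded and counted.
#'
#' @param pairs A \code{contact_pairs} data.frame.
#' @param compartments Interval table (chrom, start, end, name = A/B).
#' @param by Optional column name of \code{pairs} (e.g. "rna_class") for
#'   a per-group breakdown.
#' @return List: \code{fraction_same}, \code{n_used},
#'   \code{n_unlabelled}, and \code{by_group} when requested.
#' @export
compartment_segregation <- function(pairs, compartments, by = NULL) {
  lab <- function(chrom, pos) {
    q <- point_granges(chrom, pos)
    ov <- quiet_overlaps(q, df_granges(compartments))
    out <- rep(NA_character_, length(chrom))
    out[S4Vectors::queryHits(ov)] <-
      compartments$name[S4Vectors::subjectHits(ov)]
    out
  }
  la <- lab(pairs$rna_chrom, pairs$rna_center)
  lb <- lab(pairs$dna_chrom, pairs$dna_center)
  ok <- !is.na(la) & !is.na(lb)
  res <- list(fraction_same = if (any(ok)) mean(la[ok] == lb[ok]) else NA_real_,
              n_used = sum(ok), n_unlabelled = sum(!ok))
  if (!is.null(by)) {
    g <- pairs[[by]][ok]
    res$by_group <- tapply(la[ok] == lb[ok], g, mean)
  }
  res
}

#' Shared interactions between two significant sets
#'
#' Intersection of (RNA, DNA bin) keys between two significant sets, as a
#' count and as a percentage of the union, overall and per distance
#' category.
#'
#' @param sig_a,sig_b data.frames with rna and bin columns (e.g.
#'   \code{\link{sig_table}} output), optionally with a distance_class
#'   column for the per-category breakdown.
#' @return List: \code{shared}, \code{pct_union}, and \code{by_class}
#'   data.frame when distance classes are present.
#' @export
shared_trans <- function(sig_a, sig_b) {
  key <- function(s) paste0(s$rna, "\r", s$bin)
  ka <- unique(key(sig_a)); kb <- unique(key(sig_b))
  shared <- length(intersect(ka, kb))
  un <- length(union(ka, kb))
  out <- list(shared = shared,
              pct_union = if (un) 100 * shared / un else 0)
  if (!is.null(sig_a$distance_class) && !is.null(sig_b$distance_class)) {
    cls <- union(unique(as.character(sig_a$distance_class)),
                 unique(as.character(sig_b$distance_class)))
    out$by_class <- do.call(rbind, lapply(cls, function(cl) {
      a <- unique(key(sig_a[sig_a$distance_class == cl, , drop = FALSE]))
      b <- unique(key(sig_b[sig_b$distance_class == cl, , drop = FALSE]))
      s <- length(intersect(a, b)); u <- length(union(a, b))
      data.frame(distance_class = cl, shared = s,
                 pct_union = if (u) 100 * s / u else 0,
                 stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Overlap of the top-K ranked genes of two datasets
#'
#' Genes are ranked by score (descending), ties at the boundary broken by
#' gene id; returns the intersection size and Venn counts of the two
#' top-K sets.
#'
#' @param scores_a,scores_b Named numeric vectors (e.g. normalised
#'   counts).
#' @param k Number of top genes (default 10000, capped at list length).
#' @return List: k used per list, \code{both}, \code{only_a},
#'   \code{only_b}.
#' @export
top_k_overlap <- function(scores_a, scores_b, k = 10000L) {
  top <- function(s) {
    ord <- order(-s, names(s))
    names(s)[ord][seq_len(min(k, length(s)))]
  }
  ta <- top(scores_a); tb <- top(scores_b)
  list(k_a = length(ta), k_b = length(tb),
       both = length(intersect(ta, tb)),
       only_a = length(setdiff(ta, tb)),
       only_b = length(setdiff(tb, ta)))
}

#' Dominant RNA region and class per bin pair
#'
#' For every (RNA source 25-kb bin, DNA 25-kb bin) combination, the
#' most-represented RNA region and RNA class; ties broken by the fixed
#' orders exon < intron < intergenic and protein_coding < long_ncRNA <
#' ncRNA < other. A companion table summarises label proportions per
#' distance class.
#'
#' @param pairs Annotated pairs (rna_region and rna_class columns).
#' @return List: \code{matrix} (per bin pair: dominant region and class,
#'   n), \code{by_distance_region} and \code{by_distance_class}
#'   proportion tables.
#' @export
dominant_class_matrix <- function(pairs) {
  stopifnot(!is.null(pairs$rna_region), !is.null(pairs$rna_class))
  keyv <- paste0(pairs$rna_bin, "\r", pairs$dna_bin)
  dominant <- function(f) {
    lv <- levels(f)
    vapply(split(as.integer(f), keyv), function(ix) {
      cnt <- tabulate(ix, nbins = length(lv))
      lv[which.max(cnt)]  # which.max takes the first (highest-priority) tie
    }, "")
  }
  dom_r <- dominant(pairs$rna_region)
  cls <- pairs$rna_class
  cls_int <- as.integer(cls); cls_int[is.na(cls_int)] <- length(levels(cls)) + 1L
  lv2 <- c(levels(cls), "unassigned")
  clsf <- factor(lv2[cls_int], levels = lv2)
  dom_c <- dominant(clsf)
  keys <- names(dom_r)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  mat <- data.frame(rna_bin = vapply(parts, `[`, "", 1L),
                    dna_bin = vapply(parts, `[`, "", 2L),
                    region = dom_r, class = dom_c[keys],
                    n = as.integer(table(keyv)[keys]),
                    stringsAsFactors = FALSE, row.names = NULL)
  prop_tab <- function(f) {
    t <- table(pairs$distance_class, f)
    sweep(t, 1L, pmax(rowSums(t), 1L), "/")
  }
  list(matrix = mat,
       by_distance_region = unclass(prop_tab(pairs$rna_region)),
       by_distance_class = unclass(prop_tab(clsf)))
}
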