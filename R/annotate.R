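# Center-point annotation of tags: gene assignment (stranded for RNA,
# strand-blind for DNA), exon/intron/intergenic classification, biotype
# groups, repeat-family intersection, self-interaction flags, promoters.

df_granges <- function(df, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(strand)) "*" else strand)
}

point_granges <- function(chrom, pos, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = rep_len(chrom, length(pos)),
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L),
    strand = if (is.null(strand)) "*" else rep_len(strand, length(pos)))
}

#' Assign tag centers to genes
#'
#' A tag belongs to the gene whose span contains its center; for RNA tags
#' the tag strand must match the gene strand (\code{stranded = TRUE}),
#' while DNA tags are assigned strand-blind. Ties between overlapping
#' genes are broken by smallest span, then lexicographic gene id.
#'
#' @param chrom,pos Center coordinates (0-based).
#' @param strand Tag strands, or NULL for strand-blind assignment.
#' @param genes Gene table (gene_id, chrom, start, end, strand).
#' @param stranded Require strand match (default TRUE when strand given).
#' @return Character vector of gene ids; NA for intergenic centers.
#' @export
assign_gene <- function(chrom, pos, strand = NULL, genes,
                        stranded = !is.null(strand)) {
  q <- point_granges(chrom, pos, if (stranded) strand else NULL)
  s <- df_granges(genes, if (stranded) genes$strand else NULL)
  ov <- quiet_overlaps(q, s, ignore.strand = !stranded)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  out <- rep(NA_character_, length(pos))
  if (length(qh)) {
    span <- genes$end[sh] - genes$start[sh]
    ord <- order(qh, span, genes$gene_id[sh])
    keep <- !duplicated(qh[ord])
    out[qh[ord][keep]] <- genes$gene_id[sh[ord][keep]]
  }
  out
}

#' Classify tag centers as exon, intron or intergenic
#'
#' A center assigned to a gene is exonic if it falls in any exon of that
#' gene (union of exons across isoforms), intronic otherwise; unassigned
#' centers are intergenic.
#'
#' @param chrom,pos Center coordinates (0-based).
#' @param gene_id Gene assignment from \code{\link{assign_gene}} (NA =
#'   intergenic).
#' @param exons Exon table (gene_id, chrom, start, end).
#' @return Factor with levels exon, intron, intergenic.
#' @export
classify_region <- function(chrom, pos, gene_id, exons) {
  chrom <- rep_len(chrom, length(pos))
  out <- ifelse(is.na(gene_id), "intergenic", "intron")
  genic <- which(!is.na(gene_id))
  if (length(genic)) {
    q <- point_granges(chrom[genic], pos[genic])
    s <- df_granges(exons)
    ov <- quiet_overlaps(q, s, ignore.strand = TRUE)
    hit_gene <- exons$gene_id[S4Vectors::subjectHits(ov)]
    same <- hit_gene == gene_id[genic][S4Vectors::queryHits(ov)]
    out[genic[unique(S4Vectors::queryHits(ov)[same])]] <- "exon"
  }
  factor(out, levels = c("exon", "intron", "intergenic"))
}

biotype_levels <- c("protein_coding", "long_ncRNA", "ncRNA", "other")

.long_nc_types <- c("lincRNA", "lncRNA", "antisense", "processed_transcript",
                    "sense_intronic", "sense_overlapping",
                    "3prime_overlapping_ncRNA",
                    "bidirectional_promoter_lncRNA", "macro_lncRNA",
                    "non_coding")
.small_nc_types <- c("miRNA", "snRNA", "snoRNA", "rRNA", "misc_RNA",
                     "scaRNA", "sRNA", "scRNA", "ribozyme", "vaultRNA",
                     "Mt_tRNA", "Mt_rRNA", "tRNA")
.known_other_regex <- "^TEC$|pseudogene|^IG_|^TR_"

#' Collapse gene biotypes into four groups
#'
#' Maps annotation biotype strings onto the four RADICL-seq groups:
#' protein_coding, long_ncRNA (GENCODE long-noncoding biotypes), ncRNA
#' (Rfam/miRBase-style small-RNA biotypes), and other (everything else).
#' Strings outside the known tables map to other with a warning.
#'
#' @param biotype Character vector of biotype strings.
#' @return Factor with levels protein_coding, long_ncRNA, ncRNA, other.
#' @export
biotype_group <- function(biotype) {
  out <- rep("other", length(biotype))
  out[biotype == "protein_coding"] <- "protein_coding"
  out[biotype %in% .long_nc_types] <- "long_ncRNA"
  out[biotype %in% .small_nc_types] <- "ncRNA"
  known <- biotype == "protein_coding" | biotype %in% .long_nc_types |
    biotype %in% .small_nc_types | grepl(.known_other_regex, biotype)
  if (any(!known))
    warning("unknown biotype(s) mapped to 'other': ",
            paste(unique(biotype[!known]), collapse = ", "))
  factor(out, levels = biotype_levels)
}

#' Intersect tag centers with repeat intervals
#'
#' Strand-aware center-in-interval test against a repeat annotation with
#' family labels; centers outside every repeat get \code{"NR"} (not
#' repeat-mapped). Ties between overlapping repeats are broken by smallest
#' interval, then input order.
#'
#' @param chrom,pos,strand Tag center coordinates and strand.
#' @param repeats Repeat table (chrom, start, end, name = family, strand).
#' @param stranded Require strand match (default TRUE).
#' @return Character vector of family labels, \code{"NR"} if none.
#' @export
intersect_repeats <- function(chrom, pos, strand, repeats, stranded = TRUE) {
  q <- point_granges(chrom, pos, if (stranded) strand else NULL)
  s <- df_granges(repeats, if (stranded) repeats$strand else NULL)
  ov <- quiet_overlaps(q, s, ignore.strand = !stranded)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  out <- rep("NR", length(pos))
  if (length(qh)) {
    width <- repeats$end[sh] - repeats$start[sh]
    ord <- order(qh, width, sh)
    keep <- !duplicated(qh[ord])
    out[qh[ord][keep]] <- repeats$name[sh[ord][keep]]
  }
  out
}

#' Flag self-interactions
#'
#' A pair is a self-interaction when its RNA and DNA tags are assigned to
#' the same gene id (the DNA assignment being strand-blind).
#'
#' @param rna_gene,dna_gene Gene ids (NA = intergenic).
#' @return Logical vector.
#' @export
is_self_interaction <- function(rna_gene, dna_gene) {
  !is.na(rna_gene) & !is.na(dna_gene) & rna_gene == dna_gene
}

#' Promoter windows around TSSs
#'
#' \code{[TSS - flank, TSS + flank)} per gene, clipped to chromosome
#' bounds. The TSS is the 5' end of the gene span respecting strand.
#'
#' @param genes Gene table with gene_id, chrom, tss columns.
#' @param flank Half-window in bp (default 2000).
#' @param genome A \code{genome_build} used for clipping.
#' @return data.frame gene_id, chrom, start, end.
#' @export
promoter_windows <- function(genes, flank = 2000L, genome) {
  len <- chrom_length(genome, genes$chrom)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, genes$tss - flank),
             end = pmin(len, genes$tss + flank),
             stringsAsFactors = FALSE)
}

#' Annotate contact pairs with gene, region, biotype and repeat labels
#'
#' Adds per-pair columns: rna_gene (stranded center assignment),
#' rna_region (exon/intron/intergenic), rna_class (biotype group),
#' dna_gene (strand-blind), self_interaction, and repeat_family when a
#' repeat table is supplied.
#'
#' @param pairs A \code{contact_pairs} data.frame.
#' @param genes,exons Gene-model tables (see \code{\link{read_gene_models}}).
#' @param repeats Optional repeat table (chrom, start, end, name, strand).
#' @return The annotated pairs data.frame.
#' @export
annotate_pairs <- function(pairs, genes, exons, repeats = NULL) {
  pairs$rna_gene <- assign_gene(pairs$rna_chrom, pairs$rna_center,
                                pairs$rna_strand, genes)
  pairs$rna_region <- classify_region(pairs$rna_chrom, pairs$rna_center,
                                      pairs$rna_gene, exons)
  type_of <- stats::setNames(genes$gene_type, genes$gene_id)
  grp <- rep(NA_character_, nrow(pairs))
  genic <- !is.na(pairs$rna_gene)
  if (any(genic))
    grp[genic] <- as.character(biotype_group(type_of[pairs$rna_gene[genic]]))
  pairs$rna_class <- factor(grp, levels = biotype_levels)
  pairs$dna_gene <- assign_gene(pairs$dna_chrom, pairs$dna_center,
                                strand = NULL, genes)
  pairs$self_interaction <- is_self_interaction(pairs$rna_gene,
                                                pairs$dna_gene)
  if (!is.null(repeats))
    pairs$repeat_family <- intersect_repeats(pairs$rna_chrom,
                                             pairs$rna_center,
                                             pairs$rna_strand, repeats)
  pairs
}

# findOverlaps with the harmless "sequence levels not in the other object"
# warning silenced: queries routinely touch chromosomes absent from an
# annotation track (and vice versa), which is an expected no-overlap case
quiet_overlaps <- function(query, subject, ...) {
  withCallingHandlers(
    GenomicRanges::findOverlaps(query, subject, ...),
    warning = function(w) {
      if (grepl("sequence levels", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}
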