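# File I/O helpers. All on-disk interval formats follow their native
# conventions (BED 0-based half-open, GTF 1-based closed); in-memory tables
# are 0-based half-open throughout.

#' Read a BED3/BED6 file
#'
#' @param path BED file path.
#' @return data.frame with chrom, start, end and, when present, name,
#'   score, strand. Coordinates 0-based half-open.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$name)) df$name <- as.character(md$name)
  if (!is.null(md$score)) df$score <- md$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- ifelse(st == "*", ".", st)
  df
}

#' Write intervals as BED3/BED6
#'
#' @param df data.frame with chrom, start, end and optionally name, score,
#'   strand (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  stopifnot(all(cols %in% names(df)))
  out <- df[, cols, drop = FALSE]
  if (!is.null(df$name) || !is.null(df$strand)) {
    out$name <- if (is.null(df$name)) "." else df$name
    out$score <- if (is.null(df$score)) 0 else df$score
    out$strand <- if (is.null(df$strand)) "." else df$strand
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Tab-separated file: chromosome name, length.
#' @return A \code{genome_build}.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  genome_build(df$chrom, df$length)
}

#' @noRd
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(genome$chrom_names, unname(genome$chrom_lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# FASTQ writer (Phred+33, constant quality); reads are plain character
# vectors so the simulator stays free of large intermediate objects.
write_fastq <- function(ids, seqs, path, quality_char = "I") {
  stopifnot(length(ids) == length(seqs), nchar(quality_char) == 1L)
  qual <- vapply(nchar(seqs), function(n)
    paste(rep(quality_char, n), collapse = ""), "")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  invisible(path)
}

#' Read a FASTQ file into id and sequence vectors
#'
#' @param path FASTQ path (uncompressed or gzip).
#' @return data.frame with read_id and seq.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x), stringsAsFactors = FALSE)
}

# GENCODE-like GTF writer for simulated annotation (gene/transcript/exon
# records with gene_id, gene_name, gene_type attributes; 1-based closed).
write_gtf <- function(genes, exons, path) {
  attr_str <- function(id, name, type)
    sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";', id, name, type)
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    a <- attr_str(g$gene_id, g$gene_name, g$gene_type)
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, g$start + 1L, g$end, g$strand, a),
      sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s transcript_id \"%s.t1\";",
              g$chrom, g$start + 1L, g$end, g$strand, a, g$gene_id),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s transcript_id \"%s.t1\";",
              ex$chrom, ex$start + 1L, ex$end, ex$strand, a, g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GENCODE-style GTF
#'
#' Parses gene and exon features (gene_id, gene_name, gene_type attributes)
#' into the gene-model tables used by the annotation functions. Coordinates
#' are converted to 0-based half-open.
#'
#' @param path GTF file path.
#' @return List with \code{genes} (gene_id, gene_name, gene_type, chrom,
#'   start, end, strand, tss) and \code{exons} (gene_id, chrom, start, end,
#'   strand) data.frames.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  md <- S4Vectors::mcols(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(md$type),
                   gene_id = as.character(md$gene_id),
                   stringsAsFactors = FALSE)
  df$gene_name <- if (!is.null(md$gene_name))
    as.character(md$gene_name) else df$gene_id
  df$gene_type <- if (!is.null(md$gene_type))
    as.character(md$gene_type) else if (!is.null(md$gene_biotype))
    as.character(md$gene_biotype) else NA_character_
  genes <- df[df$type == "gene",
              c("gene_id", "gene_name", "gene_type", "chrom",
                "start", "end", "strand")]
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  exons <- df[df$type == "exon",
              c("gene_id", "chrom", "start", "end", "strand")]
  rownames(genes) <- rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Write or read a tag-pair table
#'
#' Tab-separated table of paired aligned tags, the interchange format
#' between an external aligner and \code{\link{import_aligned_pairs}}.
#' Columns: read_id, rna_chrom, rna_start, rna_end, rna_strand, rna_mapq,
#' dna_chrom, dna_start, dna_end, dna_mapq (0-based half-open).
#'
#' @param df Pairs data.frame.
#' @param path File path.
#' @export
write_pairs_table <- function(df, path) {
  cols <- c("read_id", "rna_chrom", "rna_start", "rna_end", "rna_strand",
            "rna_mapq", "dna_chrom", "dna_start", "dna_end", "dna_mapq")
  stopifnot(all(cols %in% names(df)))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
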