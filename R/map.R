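# Exact tag mapping on fixture genomes (deterministic stand-in for an
# external aligner), pairing of RNA and DNA tags by read id, and import of
# externally aligned tag pairs.

#' Map tags to a genome by exact search
#'
#' Searches each tag on both strands of the genome. A unique exact hit is
#' reported with MAPQ 37 (the uniqueness convention of BWA used downstream);
#' two or more hits give MAPQ 0 (multi-mapping, first hit reported); no hit
#' leaves the tag unmapped. For RNA tags the reported strand is the strand
#' whose sequence matches the tag in sense.
#'
#' @param tags Character vector of tag sequences (may be named by read id).
#' @param genome_seq A \link[Biostrings]{DNAStringSet} genome.
#' @return data.frame: tag index/name, chrom, start, end (0-based
#'   half-open), strand, mapq, n_hits; unmapped tags have NA coordinates
#'   and mapq NA.
#' @export
exact_map <- function(tags, genome_seq) {
  n <- length(tags)
  ids <- if (!is.null(names(tags))) names(tags) else as.character(seq_len(n))
  hits_chrom <- rep(NA_character_, n)
  hits_start <- rep(NA_integer_, n)
  hits_strand <- rep(NA_character_, n)
  n_hits <- integer(n)
  lens <- nchar(tags)

  record <- function(idx, chrom, start, strand) {
    first <- n_hits[idx] == 0L
    hits_chrom[idx[first]] <<- chrom
    hits_start[idx[first]] <<- start[first]
    hits_strand[idx[first]] <<- strand
    n_hits[idx] <<- n_hits[idx] + 1L
  }
  scan <- function(patterns, idx, strand) {
    # patterns all of equal width here
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns))
    for (cn in names(genome_seq)) {
      m <- Biostrings::matchPDict(pd, genome_seq[[cn]])
      st <- Biostrings::startIndex(m)
      cnt <- lengths(st)
      for (i in which(cnt > 0L)) {
        for (s in st[[i]]) record(idx[i], cn, s - 1L, strand)
      }
    }
  }
  for (L in sort(unique(lens))) {
    sel <- which(lens == L)
    scan(tags[sel], sel, "+")
    scan(revcomp(tags[sel]), sel, "-")
  }
  mapq <- ifelse(n_hits == 1L, 37L, ifelse(n_hits >= 2L, 0L, NA_integer_))
  data.frame(read_id = ids, chrom = hits_chrom, start = hits_start,
             end = hits_start + lens, strand = hits_strand,
             mapq = mapq, n_hits = n_hits, stringsAsFactors = FALSE)
}

#' Pair mapped RNA and DNA tags by read id
#'
#' Joins RNA-tag and DNA-tag alignments on read id, applies the uniqueness
#' filter (both tags must reach \code{mapq_min}), and derives centers, bin
#' keys and distance classes.
#'
#' @param rna,dna Alignment data.frames from \code{\link{exact_map}} or
#'   equivalent (read_id, chrom, start, end, strand, mapq).
#' @param scheme A \code{\link{make_bins}} scheme.
#' @param mapq_min Minimum MAPQ for both tags (default 37, unique hits).
#' @return A contact-pairs data.frame (class \code{contact_pairs}) with
#'   per-tag coordinates, centers, bin keys and distance_class. Drop
#'   counts are attached as attribute \code{"drops"}.
#' @export
pair_tags <- function(rna, dna, scheme, mapq_min = 37L) {
  m <- merge(rna, dna, by = "read_id", suffixes = c("_rna", "_dna"))
  pairs <- data.frame(read_id = m$read_id,
                      rna_chrom = m$chrom_rna, rna_start = m$start_rna,
                      rna_end = m$end_rna, rna_strand = m$strand_rna,
                      rna_mapq = m$mapq_rna,
                      dna_chrom = m$chrom_dna, dna_start = m$start_dna,
                      dna_end = m$end_dna, dna_mapq = m$mapq_dna,
                      stringsAsFactors = FALSE)
  finish_pairs(pairs, scheme, mapq_min)
}

finish_pairs <- function(pairs, scheme, mapq_min) {
  n0 <- nrow(pairs)
  unmapped <- is.na(pairs$rna_mapq) | is.na(pairs$dna_mapq)
  pairs <- pairs[!unmapped, , drop = FALSE]
  low <- pairs$rna_mapq < mapq_min | pairs$dna_mapq < mapq_min
  pairs <- pairs[!low, , drop = FALSE]
  pairs$rna_center <- fragment_center(pairs$rna_start, pairs$rna_end)
  pairs$dna_center <- fragment_center(pairs$dna_start, pairs$dna_end)
  pairs$rna_bin <- bin_key(scheme, pairs$rna_chrom, pairs$rna_center)
  pairs$dna_bin <- bin_key(scheme, pairs$dna_chrom, pairs$dna_center)
  pairs$distance_class <- classify_distance(pairs$rna_chrom, pairs$dna_chrom,
                                            pairs$rna_center, pairs$dna_center)
  rownames(pairs) <- NULL
  attr(pairs, "drops") <- c(input = n0, unmapped = sum(unmapped),
                            low_mapq = sum(low), kept = nrow(pairs))
  class(pairs) <- c("contact_pairs", "data.frame")
  pairs
}

#' Import externally aligned tag pairs
#'
#' Reads the tab-separated pairs table produced by an external aligner
#' workflow (columns read_id, rna_chrom, rna_start, rna_end, rna_strand,
#' rna_mapq, dna_chrom, dna_start, dna_end, dna_mapq; 0-based half-open),
#' applies the MAPQ uniqueness filter, and derives centers, bins, and
#' distance classes.
#'
#' @param path Pairs table path.
#' @param scheme A \code{\link{make_bins}} scheme.
#' @param mapq_min Minimum MAPQ for both tags (default 37).
#' @return A \code{contact_pairs} data.frame; see \code{\link{pair_tags}}.
#' @export
import_aligned_pairs <- function(path, scheme, mapq_min = 37L) {
  cols <- c("read_id", "rna_chrom", "rna_start", "rna_end", "rna_strand",
            "rna_mapq", "dna_chrom", "dna_start", "dna_end", "dna_mapq")
  lines <- readLines(path)
  if (length(lines) == 0L || (length(lines) == 1L && lines == "")) {
    warning("empty pairs table: ", path)
    df <- stats::setNames(
      data.frame(matrix(character(0), 0, length(cols))), cols)
    df$rna_mapq <- df$dna_mapq <- integer(0)
    df$rna_start <- df$rna_end <- df$dna_start <- df$dna_end <- numeric(0)
    return(finish_pairs(df, scheme, mapq_min))
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (!all(cols %in% header))
    stop("line 1: missing columns: ",
         paste(setdiff(cols, header), collapse = ", "))
  body <- lines[-1L]
  if (length(body) == 0L) {
    warning("empty pairs table: ", path)
    df <- as.data.frame(matrix(character(0), 0L, length(cols)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    for (cc in c("rna_start", "rna_end", "dna_start", "dna_end",
                 "rna_mapq", "dna_mapq")) df[[cc]] <- numeric(0)
    return(finish_pairs(df, scheme, mapq_min))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header)))
    stop("line ", which(nf != length(header))[1L] + 1L,
         ": expected ", length(header), " fields, found ",
         nf[nf != length(header)][1L])
  mat <- do.call(rbind, parts)
  colnames(mat) <- header
  df <- as.data.frame(mat[, cols, drop = FALSE], stringsAsFactors = FALSE)
  for (cc in c("rna_start", "rna_end", "dna_start", "dna_end",
               "rna_mapq", "dna_mapq")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stop("line ", which(is.na(v))[1L] + 1L, ": non-numeric ", cc)
    df[[cc]] <- v
  }
  if (nrow(df) == 0L) warning("empty pairs table: ", path)
  finish_pairs(df, scheme, mapq_min)
}
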