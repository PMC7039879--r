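#' Genome build from chromosome lengths
#'
#' A minimal description of a genome assembly: ordered chromosome names and
#' lengths. All package coordinates are 0-based, half-open (BED convention).
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Integer vector of chromosome lengths in bp (> 0).
#' @return An object of class \code{genome_build}.
#' @export
genome_build <- function(chrom_names, chrom_lengths) {
  stopifnot(length(chrom_names) == length(chrom_lengths),
            !anyDuplicated(chrom_names), all(chrom_lengths > 0))
  structure(list(chrom_names = as.character(chrom_names),
                 chrom_lengths = stats::setNames(as.numeric(chrom_lengths),
                                                 chrom_names)),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", length(x$chrom_names), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp\n")
  invisible(x)
}

#' Genome build from a FASTA file or DNAStringSet
#'
#' @param x Path to a FASTA file, or a \link[Biostrings]{DNAStringSet}.
#' @return A \code{genome_build}.
#' @export
genome_build_from_fasta <- function(x) {
  if (is.character(x)) x <- Biostrings::readDNAStringSet(x)
  genome_build(names(x), Biostrings::width(x))
}

chrom_length <- function(genome, chrom) {
  len <- genome$chrom_lengths[chrom]
  if (anyNA(len)) stop("unknown chromosome: ",
                       paste(unique(chrom[is.na(len)]), collapse = ", "))
  unname(len)
}

#' Tile a genome into fixed-width bins
#'
#' Tiles each chromosome with non-overlapping bins of \code{width} bp
#' (default 25 kb, the resolution used for RADICL-seq contact matrices);
#' the last bin of each chromosome is truncated at the chromosome end.
#' Bins are indexed 0..n-1 per chromosome and named \code{"chrom:start-end"}.
#'
#' @param genome A \code{genome_build}.
#' @param width Bin width in bp (> 0).
#' @return An object of class \code{bin_scheme}.
#' @examples
#' g <- genome_build("chr1", 60000)
#' bin_table(make_bins(g, 25000))
#' @export
make_bins <- function(genome, width = 25000) {
  stopifnot(inherits(genome, "genome_build"))
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("bin width must be a positive number")
  n_bins <- ceiling(genome$chrom_lengths / width)
  structure(list(genome = genome, width = as.numeric(width),
                 n_bins = n_bins),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("bin_scheme: width", format(x$width, big.mark = ","), "bp,",
      sum(x$n_bins), "bins over", length(x$n_bins), "chromosomes\n")
  invisible(x)
}

#' All bins of a scheme as a table
#'
#' @param scheme A \code{bin_scheme}.
#' @return data.frame with chrom, start, end (0-based half-open), bin index
#'   (per chromosome) and key \code{"chrom:start-end"}.
#' @export
bin_table <- function(scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  g <- scheme$genome
  chrom <- rep(g$chrom_names, scheme$n_bins[g$chrom_names])
  idx <- unlist(lapply(g$chrom_names,
                       function(cn) seq_len(scheme$n_bins[cn]) - 1L),
                use.names = FALSE)
  start <- idx * scheme$width
  end <- pmin(start + scheme$width, chrom_length(g, chrom))
  data.frame(chrom = chrom, start = start, end = end, bin = idx,
             key = paste0(chrom, ":", formatC(start, format = "d"), "-",
                          formatC(end, format = "d")),
             stringsAsFactors = FALSE)
}

#' Assign genomic positions to bins
#'
#' @param scheme A \code{bin_scheme}.
#' @param chrom Chromosome of each position.
#' @param pos 0-based position(s), within the chromosome.
#' @return Integer bin index per chromosome (\code{floor(pos / width)}).
#' @export
assign_bin <- function(scheme, chrom, pos) {
  stopifnot(inherits(scheme, "bin_scheme"))
  len <- chrom_length(scheme$genome, chrom)
  if (any(pos < 0 | pos >= len))
    stop("position outside chromosome bounds")
  as.integer(floor(pos / scheme$width))
}

#' Bin key ("chrom:start-end") for genomic positions
#'
#' @inheritParams assign_bin
#' @return Character vector of bin keys.
#' @export
bin_key <- function(scheme, chrom, pos) {
  if (length(pos) == 0L) return(character(0))
  idx <- assign_bin(scheme, chrom, pos)
  start <- idx * scheme$width
  end <- pmin(start + scheme$width, chrom_length(scheme$genome, chrom))
  paste0(chrom, ":", formatC(start, format = "d"), "-",
         formatC(end, format = "d"))
}

#' Parse bin keys back into intervals
#'
#' @param key Character vector of \code{"chrom:start-end"} keys.
#' @return data.frame with chrom, start, end.
#' @export
parse_bin_key <- function(key) {
  m <- regmatches(key, regexec("^(.+):([0-9]+)-([0-9]+)$", key))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed bin key: ", key[bad][1L])
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.numeric(vapply(m, `[`, "", 3L)),
             end = as.numeric(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Center of a genomic fragment
#'
#' Single-nucleotide center used to assign tags to features and bins:
#' \code{start + floor((length - 1) / 2)}; for even lengths the base left of
#' the midpoint is used.
#'
#' @param start,end 0-based half-open fragment coordinates.
#' @return 0-based center position(s).
#' @examples
#' fragment_center(100, 127)  # 113
#' @export
fragment_center <- function(start, end) {
  stopifnot(all(end > start), all(start >= 0))
  floor(start + (end - start - 1) / 2)
}

distance_class_levels <- c("local", "short", "medium", "long", "extreme", "trans")

#' Classify RNA-DNA interaction distance
#'
#' Maps center-to-center genomic distance to the six RADICL-seq distance
#' classes: local (<= 10 kb), short (> 10, <= 100 kb), medium (> 100 kb,
#' <= 1 Mb), long (> 1, <= 10 Mb), extreme (> 10 Mb), and trans
#' (different chromosomes).
#'
#' @param rna_chrom,dna_chrom Chromosomes of the RNA and DNA tag.
#' @param rna_center,dna_center Tag center positions (see
#'   \code{\link{fragment_center}}).
#' @return Factor with levels local, short, medium, long, extreme, trans.
#' @export
classify_distance <- function(rna_chrom, dna_chrom, rna_center, dna_center) {
  n <- max(length(rna_chrom), length(dna_chrom),
           length(rna_center), length(dna_center))
  rna_chrom <- rep_len(rna_chrom, n); dna_chrom <- rep_len(dna_chrom, n)
  d <- abs(rep_len(rna_center, n) - rep_len(dna_center, n))
  cls <- ifelse(rna_chrom != dna_chrom, "trans",
         ifelse(d <= 1e4, "local",
         ifelse(d <= 1e5, "short",
         ifelse(d <= 1e6, "medium",
         ifelse(d <= 1e7, "long", "extreme")))))
  factor(cls, levels = distance_class_levels)
}

#' Counts per million normalisation
#'
#' @param counts Numeric vector of per-feature counts.
#' @param library_size Total pair count of the library (> 0).
#' @return \code{counts * 1e6 / library_size}.
#' @export
normalize_cpm <- function(counts, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1L ||
      library_size <= 0)
    stop("library_size must be a single positive number")
  counts * 1e6 / library_size
}
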