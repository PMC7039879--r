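#' Oligonucleotide sequences of the RADICL-seq construct
#'
#' Returns the fixed sequences that define the RADICL-seq library anatomy:
#' the 50-nt bridge adapter (upper and lower strands), the Y-shaped
#' sequencing linker strands, and the library PCR primers. The bridge
#' adapter carries an EcoP15I recognition site (CAGCAG) at each end, one
#' per strand, so that digestion releases 25-27 nt RNA and DNA tags on
#' either side of the adapter. The Index RV primer template encodes the
#' 6-nt multiplexing barcode as a run of \code{B} placeholders.
#'
#' @return Named list of character scalars: \code{adapter_top},
#'   \code{adapter_bottom}, \code{linker_upper}, \code{linker_lower},
#'   \code{hairpin}, \code{universal_fw}, \code{index_rv}.
#' @examples
#' nchar(radicl_oligos()$adapter_top)  # 50
#' @export
radicl_oligos <- function() {
  list(
    adapter_top    = "CTGCTGCTCCTTCCCTTTCCCCTTTTGGTCCGACGGTCCAAGTCAGCAGT",
    adapter_bottom = "CTGCTGACTTGGACCGTCGGACC",
    linker_upper   = "GATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT",
    linker_lower   = "CTCGGCATTCCTGCTGAACCGCTCTTCCGATCT",
    hairpin        = "GGCCCTCCAAAAGGAGGGCA",
    universal_fw   = "AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT",
    index_rv       = "CAAGCAGAAGACGGCATACGAGATBBBBBBCTCGGCATTCCTGCTGAACCGCTCTTCCGATCT"
  )
}

#' Count EcoP15I recognition sites on either strand
#'
#' EcoP15I recognises CAGCAG and cleaves 25-27 nt downstream of the site.
#' Sites are counted on the given sequence and on its reverse complement
#' (equivalently, occurrences of CAGCAG and CTGCTG on the given strand).
#'
#' @param seq A character scalar DNA sequence.
#' @return Integer number of recognition sites over both strands.
#' @examples
#' ecop15i_sites(radicl_oligos()$adapter_top)  # 2, one per adapter end
#' @export
ecop15i_sites <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- Biostrings::DNAString(toupper(seq))
  fwd <- Biostrings::countPattern("CAGCAG", s)
  rev <- Biostrings::countPattern("CAGCAG", Biostrings::reverseComplement(s))
  as.integer(fwd + rev)
}

#' Barcode placeholder length in a primer template
#'
#' Parses a primer template in which the multiplexing barcode is written as
#' a run of \code{B} (IUPAC "not A") placeholder bases, and returns the
#' length of that run.
#'
#' @param primer Character scalar primer template.
#' @return Integer length of the (single) barcode placeholder run.
#' @examples
#' barcode_placeholder_length(radicl_oligos()$index_rv)  # 6
#' @export
barcode_placeholder_length <- function(primer) {
  stopifnot(is.character(primer), length(primer) == 1L)
  runs <- regmatches(primer, gregexpr("B+", primer))[[1]]
  if (length(runs) == 0L) stop("no barcode placeholder (run of 'B') in primer")
  if (length(runs) > 1L) stop("multiple 'B' runs in primer; template ambiguous")
  nchar(runs)
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# vectorised Hamming distance between equal-length strings and one pattern;
# positions missing from a (truncated) string count as mismatches
str_hamming <- function(strings, pattern) {
  np <- nchar(pattern)
  d <- np - pmin(nchar(strings), np)
  for (i in seq_len(np)) {
    ci <- substr(strings, i, i)
    d <- d + (ci != substr(pattern, i, i) & ci != "")
  }
  d
}
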