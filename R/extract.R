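# Deconvolution of chimeric reads: locate the 50-nt bridge adapter by
# Hamming scan in both orientations, orient the read, and split it into
# RNA tag (upstream flank, transcript sense), DNA tag (downstream flank,
# length resolved against the sequencing-linker stub), and 6-nt barcode.

#' Read anatomy of the RADICL-seq construct
#'
#' Bundles the adapter and linker sequences, EcoP15I tag-length window,
#' barcode whitelist and mismatch tolerances shared by the simulator and
#' the extractor.
#'
#' @param barcodes Character vector of 6-nt whitelist barcodes.
#' @param tag_len_range Accepted tag lengths, default c(25, 27); flanks of
#'   28+ nt keep only the adapter-proximal 27 bases.
#' @param max_adapter_mismatches Maximum Hamming distance for an adapter
#'   placement (default 2).
#' @param max_barcode_mismatches Maximum Hamming distance for barcode
#'   whitelist matching (default 1).
#' @return Object of class \code{read_anatomy}.
#' @export
read_anatomy <- function(barcodes,
                         tag_len_range = c(25L, 27L),
                         max_adapter_mismatches = 2L,
                         max_barcode_mismatches = 1L) {
  ol <- radicl_oligos()
  stopifnot(nchar(ol$adapter_top) == 50L,
            ecop15i_sites(ol$adapter_top) == 2L,
            all(nchar(barcodes) == 6L))
  structure(list(adapter_top = ol$adapter_top,
                 adapter_bottom = ol$adapter_bottom,
                 linker = ol$linker_upper,
                 barcode_length = 6L,
                 barcodes = barcodes,
                 tag_len_range = as.integer(tag_len_range),
                 max_adapter_mismatches = as.integer(max_adapter_mismatches),
                 max_barcode_mismatches = as.integer(max_barcode_mismatches)),
            class = "read_anatomy")
}

#' Locate the bridge adapter in reads
#'
#' Best Hamming-distance placement of the adapter top strand and of its
#' reverse complement. A read is assigned the unique best placement with
#' distance at most \code{max_mismatches}; two placements tying at the
#' best distance make the read ambiguous.
#'
#' @param seqs Character vector of read sequences.
#' @param anatomy A \code{\link{read_anatomy}}.
#' @param max_mismatches Override of the anatomy's adapter tolerance.
#' @return data.frame with status (\code{found}, \code{none},
#'   \code{ambiguous}), orientation (\code{forward}/\code{reverse}) and
#'   1-based placement offset in the read as sequenced.
#' @export
locate_adapter <- function(seqs, anatomy,
                           max_mismatches = anatomy$max_adapter_mismatches) {
  adapter <- Biostrings::DNAString(anatomy$adapter_top)
  rc_adapter <- Biostrings::reverseComplement(adapter)
  dss <- Biostrings::DNAStringSet(seqs)
  mf <- Biostrings::vmatchPattern(adapter, dss, max.mismatch = max_mismatches)
  mr <- Biostrings::vmatchPattern(rc_adapter, dss, max.mismatch = max_mismatches)
  sf <- Biostrings::startIndex(mf)
  sr <- Biostrings::startIndex(mr)
  nf <- lengths(sf); nr <- lengths(sr)
  n <- length(seqs)
  status <- rep("none", n)
  orientation <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)
  first_or_na <- function(x) if (length(x)) x[[1L]] else NA_integer_
  one <- nf + nr == 1L
  status[one] <- "found"
  orientation[one] <- ifelse(nf[one] == 1L, "forward", "reverse")
  offset[one] <- ifelse(nf[one] == 1L,
                        vapply(sf[one], first_or_na, 1L),
                        vapply(sr[one], first_or_na, 1L))
  for (i in which(nf + nr > 1L)) {
    cand_start <- c(sf[[i]], sr[[i]])
    cand_orient <- rep(c("forward", "reverse"), c(nf[i], nr[i]))
    mm <- c(if (nf[i]) Biostrings::neditStartingAt(adapter, dss[[i]],
                                                   starting.at = sf[[i]]),
            if (nr[i]) Biostrings::neditStartingAt(rc_adapter, dss[[i]],
                                                   starting.at = sr[[i]]))
    best <- which(mm == min(mm))
    if (length(best) > 1L) {
      status[i] <- "ambiguous"
    } else {
      status[i] <- "found"
      orientation[i] <- cand_orient[best]
      offset[i] <- cand_start[best]
    }
  }
  data.frame(status = status, orientation = orientation, offset = offset,
             stringsAsFactors = FALSE)
}

#' Extract RNA tag, DNA tag and barcode from chimeric reads
#'
#' Reads with the adapter in reverse orientation are reverse-complemented
#' first, so the upstream flank is always the RNA tag in transcript sense
#' and the downstream flank the DNA tag. The DNA-tag length (25-27 nt) is
#' resolved by matching the sequencing-linker stub at the three candidate
#' positions; the barcode is read immediately after the linker and matched
#' to the whitelist. Failures are recorded per read in
#' \code{rejection_reason} (\code{no_adapter}, \code{ambiguous_adapter},
#' \code{short_flank}, \code{bad_barcode}); accepted records have an empty
#' reason.
#'
#' @param reads data.frame(read_id, seq) or character vector of sequences.
#' @param anatomy A \code{\link{read_anatomy}}.
#' @return data.frame: read_id, rna_seq, dna_seq, barcode (whitelist-
#'   corrected), reverse (TRUE if the construct was sequenced in reverse),
#'   rejection_reason.
#' @export
extract_tags <- function(reads, anatomy) {
  if (is.character(reads))
    reads <- data.frame(read_id = paste0("read", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  seqs <- reads$seq
  n <- length(seqs)
  loc <- locate_adapter(seqs, anatomy)
  reason <- ifelse(loc$status == "none", "no_adapter",
                   ifelse(loc$status == "ambiguous", "ambiguous_adapter", ""))
  rna <- dna <- barcode <- rep(NA_character_, n)
  reverse <- loc$orientation == "reverse"

  ok <- which(reason == "")
  if (length(ok)) {
    s <- seqs[ok]
    o <- loc$offset[ok]
    rev_i <- reverse[ok]
    if (any(rev_i)) {
      rl <- nchar(s[rev_i])
      s[rev_i] <- revcomp(s[rev_i])
      o[rev_i] <- rl - (o[rev_i] + 49L) + 1L
    }
    tmax <- anatomy$tag_len_range[2]
    tmin <- anatomy$tag_len_range[1]
    flank <- o - 1L
    short <- flank < tmin
    rna_ok <- substr(s, pmax(1L, o - tmax), o - 1L)

    e <- o + 49L  # adapter end (1-based, inclusive)
    lk <- anatomy$linker
    lk_len <- nchar(lk)
    cand <- seq(tmin, tmax)
    scores <- sapply(cand, function(L)
      str_hamming(substr(s, e + L + 1L, e + L + lk_len), lk))
    if (length(ok) == 1L) scores <- matrix(scores, nrow = 1L)
    # invalidate candidates whose DNA tag would run past the read end
    for (j in seq_along(cand))
      scores[nchar(s) < e + cand[j], j] <- Inf
    # best linker placement; ties resolved toward the longer tag
    best_j <- max.col(-scores, ties.method = "last")
    no_fit <- !is.finite(scores[cbind(seq_along(best_j), best_j)])
    dlen <- cand[best_j]
    dna_ok <- substr(s, e + 1L, e + dlen)
    bc_start <- e + dlen + lk_len + 1L
    bc_raw <- substr(s, bc_start, bc_start + anatomy$barcode_length - 1L)

    bc_dist <- sapply(anatomy$barcodes, function(b) str_hamming(bc_raw, b))
    if (length(ok) == 1L) bc_dist <- matrix(bc_dist, nrow = 1L)
    bc_min <- apply(bc_dist, 1L, min)
    bc_nbest <- rowSums(bc_dist == bc_min)
    bc_bad <- bc_min > anatomy$max_barcode_mismatches | bc_nbest > 1L
    bc_corr <- anatomy$barcodes[max.col(-bc_dist, ties.method = "first")]

    r <- rep("", length(ok))
    r[short | no_fit] <- "short_flank"
    r[!(short | no_fit) & bc_bad] <- "bad_barcode"
    acc <- r == ""
    reason[ok] <- r
    rna[ok][acc] <- rna_ok[acc]
    dna[ok][acc] <- dna_ok[acc]
    barcode[ok][acc] <- bc_corr[acc]
  }
  data.frame(read_id = reads$read_id, rna_seq = rna, dna_seq = dna,
             barcode = barcode, reverse = reverse,
             rejection_reason = reason, stringsAsFactors = FALSE)
}

#' Per-library extraction statistics
#'
#' @param records Output of \code{\link{extract_tags}}.
#' @param path Optional JSON output path.
#' @return Named list of counts (total, accepted, one entry per rejection
#'   reason), invisibly written as JSON when \code{path} is given.
#' @export
extraction_stats <- function(records, path = NULL) {
  reasons <- c("no_adapter", "ambiguous_adapter", "short_flank", "bad_barcode")
  out <- c(list(total = nrow(records),
                accepted = sum(records$rejection_reason == "")),
           stats::setNames(
             lapply(reasons, function(r) sum(records$rejection_reason == r)),
             reasons))
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(out)
}

#' Screen tags against an rRNA reference by exact k-mer sharing
#'
#' A tag is flagged as an rRNA contaminant if it shares at least one exact
#' k-mer with the reference on either strand.
#'
#' @param tags Character vector of tag sequences.
#' @param rrna Reference sequence (character scalar, e.g. the rDNA
#'   repeating unit).
#' @param k K-mer length, default 21; must not exceed the shortest tag.
#' @return Logical vector, TRUE for contaminants.
#' @export
filter_rrna <- function(tags, rrna, k = 21L) {
  if (any(nchar(tags) < k))
    stop("k exceeds the length of at least one tag")
  if (nchar(rrna) < k) stop("k exceeds the reference length")
  ref_kmers <- function(s) {
    starts <- seq_len(nchar(s) - k + 1L)
    substring(s, starts, starts + k - 1L)
  }
  refset <- unique(c(ref_kmers(rrna), ref_kmers(revcomp(rrna))))
  hit <- rep(FALSE, length(tags))
  for (j in seq_len(max(nchar(tags)) - k + 1L)) {
    valid <- nchar(tags) >= j + k - 1L
    hit[valid] <- hit[valid] |
      substring(tags[valid], j, j + k - 1L) %in% refset
  }
  hit
}

#' Remove PCR duplicates from extracted tag pairs
#'
#' Keeps the first occurrence of each distinct (rna_seq, dna_seq, barcode)
#' triple, in input order.
#'
#' @param records data.frame with rna_seq, dna_seq, barcode columns.
#' @return The deduplicated data.frame.
#' @export
dedup_pairs <- function(records) {
  key <- paste(records$rna_seq, records$dna_seq, records$barcode, sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trim both tags to their first L bases
#'
#' 5'-anchored truncation used to compare mappability at shorter tag
#' lengths (e.g. 20 nt, the MmeI tag length of related protocols, against
#' the native 25-27 nt EcoP15I tags).
#'
#' @param records data.frame with rna_seq and dna_seq columns.
#' @param L Target length; must not exceed the shortest tag.
#' @return Records with both tags truncated, order preserved.
#' @export
trim_tags <- function(records, L) {
  lens <- c(nchar(records$rna_seq), nchar(records$dna_seq))
  if (L > min(lens)) stop("L exceeds the shortest tag length")
  records$rna_seq <- substr(records$rna_seq, 1L, L)
  records$dna_seq <- substr(records$dna_seq, 1L, L)
  records
}
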