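# Significant RNA-chromatin interactions: sparse RNA x 25-kb-bin contact
# matrix, one-sided cumulative binomial test per (RNA, bin) with
# P = 1 / U(r) and N = N(r) taken genome-wide (cis + trans), global BH
# correction, then blacklist filtering of the significant set.

#' Aggregate contact pairs into a sparse RNA-by-bin matrix
#'
#' Counts occurrences of each (RNA feature, 25-kb DNA bin) combination.
#' The RNA feature is either the assigned gene (pairs must carry an
#' \code{rna_gene} column; intergenic pairs are dropped) or the RNA-tag
#' source bin. Per-RNA totals N(r) and unique-bin counts U(r) are computed
#' over the whole genome, cis and trans alike.
#'
#' @param pairs A \code{contact_pairs} data.frame (annotated when
#'   \code{level = "gene"}).
#' @param level \code{"gene"} or \code{"bin"} (RNA 25-kb source bin).
#' @return Object of class \code{contact_matrix}: \code{counts}
#'   data.frame (rna, bin, count), named vectors \code{N} and \code{U},
#'   and the feature level.
#' @export
aggregate_matrix <- function(pairs, level = c("gene", "bin")) {
  level <- match.arg(level)
  rna <- if (level == "gene") pairs$rna_gene else pairs$rna_bin
  if (level == "gene" && is.null(rna))
    stop("pairs lack an rna_gene column; run annotate_pairs() first")
  keep <- !is.na(rna)
  rna <- rna[keep]
  bin <- pairs$dna_bin[keep]
  if (length(rna) == 0L) {
    counts <- data.frame(rna = character(0), bin = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
  } else {
    key <- paste0(rna, "\r", bin)
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    counts <- data.frame(rna = vapply(parts, `[`, "", 1L),
                         bin = vapply(parts, `[`, "", 2L),
                         count = as.integer(tab),
                         stringsAsFactors = FALSE)
    counts <- counts[order(counts$rna, counts$bin), ]
    rownames(counts) <- NULL
  }
  N <- tapply(counts$count, counts$rna, sum)
  U <- tapply(counts$count > 0L, counts$rna, sum)
  structure(list(counts = counts,
                 N = stats::setNames(as.integer(N), names(N)),
                 U = stats::setNames(as.integer(U), names(U)),
                 level = level),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix (", x$level, " level): ", length(x$N), " RNAs, ",
      nrow(x$counts), " (rna, bin) pairs, ",
      format(sum(x$counts$count), big.mark = ","), " contacts\n", sep = "")
  invisible(x)
}

#' One-sided cumulative binomial p-value
#'
#' \eqn{p = P(X \ge k)} for \eqn{X \sim Binomial(N, P)}, the upper tail
#' used to score an (RNA, bin) count k against the RNA's genome-wide
#' contact total N at uniform bin probability P = 1/U. Computed via the
#' survival function for numerical stability.
#'
#' @param k Observed count(s), 0 <= k <= N.
#' @param N Total contacts of the RNA.
#' @param P Success probability, 0 < P <= 1.
#' @return Upper-tail p-value(s).
#' @export
binom_pvalue <- function(k, N, P) {
  if (any(k < 0 | k > N)) stop("k must satisfy 0 <= k <= N")
  if (any(P <= 0 | P > 1)) stop("P must lie in (0, 1]")
  stats::pbinom(k - 1, N, P, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR correction of a p-value vector (returned in input order).
#'
#' @param p P-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call significant RNA-chromatin interactions
#'
#' For every represented (RNA, bin) pair, tests the count k against
#' Binomial(N(r), 1/U(r)) with the one-sided cumulative binomial test,
#' adjusts all p-values jointly by Benjamini-Hochberg, calls pairs with
#' adjusted p < alpha, and then removes significant interactions whose DNA
#' bin (or, optionally, whose contributing tag centers) intersects a
#' blacklist region.
#'
#' @param matrix A \code{\link{aggregate_matrix}} result.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param blacklist Optional blacklist intervals (chrom, start, end).
#' @param blacklist_on \code{"bin"} (default): drop significant calls
#'   whose DNA-bin interval intersects the blacklist; \code{"tags"}: drop
#'   calls any of whose contributing RNA or DNA tag centers falls in the
#'   blacklist (requires \code{pairs}).
#' @param pairs The pairs the matrix was built from; only needed for
#'   \code{blacklist_on = "tags"}.
#' @return Object of class \code{radicl_sig}: per-pair table (rna, bin, k,
#'   N, P, p_value, p_adjusted, blacklisted, significant) plus summary
#'   counts.
#' @export
call_significant <- function(matrix, alpha = 0.05, blacklist = NULL,
                             blacklist_on = c("bin", "tags"),
                             pairs = NULL) {
  stopifnot(inherits(matrix, "contact_matrix"))
  blacklist_on <- match.arg(blacklist_on)
  tab <- matrix$counts
  tab$k <- tab$count
  tab$count <- NULL
  tab$N <- unname(matrix$N[tab$rna])
  tab$P <- 1 / unname(matrix$U[tab$rna])
  tab$p_value <- binom_pvalue(tab$k, tab$N, tab$P)
  tab$p_adjusted <- bh_adjust(tab$p_value)
  sig <- tab$p_adjusted < alpha
  tab$blacklisted <- rep(FALSE, nrow(tab))
  if (!is.null(blacklist) && nrow(tab) > 0L) {
    if (blacklist_on == "bin") {
      iv <- parse_bin_key(tab$bin)
      q <- df_granges(iv)
    } else {
      if (is.null(pairs))
        stop("blacklist_on = 'tags' requires the pairs data.frame")
      key <- paste0(if (matrix$level == "gene") pairs$rna_gene
                    else pairs$rna_bin, "\r", pairs$dna_bin)
      in_bl <- function(chrom, pos) {
        ov <- quiet_overlaps(point_granges(chrom, pos),
                                          df_granges(blacklist))
        seq_along(chrom) %in% S4Vectors::queryHits(ov)
      }
      hit_pair <- in_bl(pairs$rna_chrom, pairs$rna_center) |
        in_bl(pairs$dna_chrom, pairs$dna_center)
      bad_keys <- unique(key[hit_pair])
      tab$blacklisted <- paste0(tab$rna, "\r", tab$bin) %in% bad_keys
    }
    if (blacklist_on == "bin") {
      ov <- quiet_overlaps(q, df_granges(blacklist))
      tab$blacklisted <- seq_len(nrow(tab)) %in% S4Vectors::queryHits(ov)
    }
  }
  tab$significant <- sig & !tab$blacklisted
  out <- structure(list(table = tab, alpha = alpha, level = matrix$level,
                        n_tested = nrow(tab),
                        n_significant = sum(tab$significant),
                        n_blacklisted = sum(sig & tab$blacklisted)),
                   class = "radicl_sig")
  out
}

#' @export
print.radicl_sig <- function(x, ...) {
  cat("radicl_sig: ", x$n_significant, " significant of ", x$n_tested,
      " tested (rna, bin) pairs at adjusted p < ", x$alpha,
      if (x$n_blacklisted) paste0("; ", x$n_blacklisted,
                                  " removed by blacklist") else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.radicl_sig <- function(object, ...) {
  tab <- object$table
  sig <- tab[tab$significant, , drop = FALSE]
  structure(list(alpha = object$alpha, n_tested = object$n_tested,
                 n_significant = object$n_significant,
                 n_blacklisted = object$n_blacklisted,
                 n_rnas = length(unique(sig$rna)),
                 n_bins = length(unique(sig$bin))),
            class = "summary.radicl_sig")
}

#' @export
print.summary.radicl_sig <- function(x, ...) {
  cat("Significant interactions: ", x$n_significant, " / ", x$n_tested,
      " tested (alpha = ", x$alpha, ")\n",
      "  involving ", x$n_rnas, " RNAs and ", x$n_bins, " genomic bins\n",
      "  removed by blacklist: ", x$n_blacklisted, "\n", sep = "")
  invisible(x)
}

#' Significant interactions as a table
#'
#' @param sig A \code{radicl_sig} object.
#' @param significant_only Keep only significant rows (default TRUE).
#' @return data.frame of interaction records.
#' @export
sig_table <- function(sig, significant_only = TRUE) {
  tab <- sig$table
  if (significant_only) tab <- tab[tab$significant, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Export a contact matrix as sparse triplet text and MatrixMarket
#'
#' @param matrix A \code{contact_matrix}.
#' @param prefix Output path prefix; writes \code{<prefix>.triplets.tsv},
#'   \code{<prefix>.mtx}, \code{<prefix>.rows.txt},
#'   \code{<prefix>.cols.txt}.
#' @return Invisible vector of written paths.
#' @export
export_matrix <- function(matrix, prefix) {
  counts <- matrix$counts
  utils::write.table(counts, paste0(prefix, ".triplets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rnas <- sort(unique(counts$rna))
  bins <- sort(unique(counts$bin))
  m <- Matrix::sparseMatrix(i = match(counts$rna, rnas),
                            j = match(counts$bin, bins),
                            x = counts$count,
                            dims = c(length(rnas), length(bins)))
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  writeLines(rnas, paste0(prefix, ".rows.txt"))
  writeLines(bins, paste0(prefix, ".cols.txt"))
  invisible(paste0(prefix, c(".triplets.tsv", ".mtx", ".rows.txt",
                             ".cols.txt")))
}
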