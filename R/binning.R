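#' @importFrom Biostrings oligonucleotideFrequency
NULL

#' Strand-symmetric trinucleotide frequency vector
#'
#' Counts all overlapping 3-mers on the sequence and its reverse complement
#' and normalizes to frequencies; 3-mers containing N are excluded from
#' counting.  The vector is strand-symmetric by construction, so it does not
#' depend on the assembly's arbitrary choice of contig orientation.
#' Sequences shorter than 1000 nt are rejected: their composition estimate
#' is too unstable to bin on.
#'
#' @param seq nucleotide string, [Biostrings::DNAString], or
#'   [Biostrings::DNAStringSet] (vectorized).
#' @return for a single sequence, a named numeric vector of 64 frequencies
#'   summing to 1; for a set, a matrix with one row per sequence.
#' @export
trinucVector <- function(seq) {
  set <- if (methods::is(seq, "DNAStringSet")) seq
         else Biostrings::DNAStringSet(as.character(seq))
  if (any(Biostrings::width(set) < 1000L))
    mcStop("trinucleotide composition requires sequences >= 1000 nt")
  counts <- oligonucleotideFrequency(set, width = 3L) +
    oligonucleotideFrequency(Biostrings::reverseComplement(set), width = 3L)
  tot <- rowSums(counts)
  if (any(tot == 0)) mcStop("sequence contains no countable 3-mers")
  freq <- counts / tot
  if (length(set) == 1L && !methods::is(seq, "DNAStringSet"))
    freq[1L, ] else freq
}

#' Train a trinucleotide-centroid bin model
#'
#' Each bin's centroid is the length-weighted mean of the trinucleotide
#' vectors of its training contigs, renormalized to sum to 1.  The default
#' assignment threshold is the 95th percentile of the training contigs' L1
#' distance to their own centroid, computed per bin and maximized over bins.
#'
#' @param contigs a [ContigSet-class] of training contigs (>= 1000 nt each).
#' @param labels character vector of bin labels parallel to `contigs`, or a
#'   named vector keyed by contig id.
#' @param threshold `"auto"` (percentile rule) or a positive number.
#' @param quantileLevel percentile used by the auto rule.
#' @return a [BinModel-class].
#' @export
trainBinModel <- function(contigs, labels, threshold = "auto",
                          quantileLevel = 0.95) {
  ids <- contigIds(contigs)
  if (!is.null(names(labels))) labels <- unname(labels[ids])
  if (length(labels) != length(contigs) || any(is.na(labels)))
    mcStop("every training contig needs a bin label")
  lens <- Biostrings::width(contigSeqs(contigs))
  ok <- lens >= 1000L
  if (!all(ok)) {
    contigs <- contigs[which(ok)]
    labels <- labels[ok]
    lens <- lens[ok]
  }
  bins <- sort(unique(labels))
  if (length(bins) < 2L) mcStop("need training contigs for at least 2 bins")
  counts <- table(labels)
  if (any(counts < 1L)) mcStop("a bin has no valid training contigs")
  vecs <- trinucVector(contigSeqs(contigs))
  centroids <- matrix(0, nrow = length(bins), ncol = 64L,
                      dimnames = list(bins, colnames(vecs)))
  for (b in bins) {
    sel <- labels == b
    w <- lens[sel] / sum(lens[sel])
    cen <- colSums(vecs[sel, , drop = FALSE] * w)
    centroids[b, ] <- cen / sum(cen)
  }
  if (identical(threshold, "auto")) {
    perBin <- vapply(bins, function(b) {
      sel <- labels == b
      d <- rowSums(abs(vecs[sel, , drop = FALSE] -
                       rep(centroids[b, ], each = sum(sel))))
      stats::quantile(d, quantileLevel, names = FALSE)
    }, numeric(1))
    threshold <- max(perBin)
  }
  methods::new("BinModel", centroids = centroids,
               threshold = as.numeric(threshold), metric = "l1")
}

#' Classify contigs against a bin model
#'
#' Contigs shorter than `minLen` (default 2000 nt) are excluded and labeled
#' "no match".  Longer contigs are assigned to the nearest centroid under
#' the model's metric (L1 on strand-symmetrized trinucleotide frequencies);
#' contigs whose nearest-centroid distance exceeds the model threshold fall
#' in "no match" as well.  Ties break lexicographically by bin label.
#'
#' @param contigs a [ContigSet-class].
#' @param model a [BinModel-class].
#' @param minLen minimum classifiable contig length (nt).
#' @return named character vector contig_id -> bin label or "no match".
#' @export
classifyContigs <- function(contigs, model, minLen = 2000L) {
  ids <- contigIds(contigs)
  out <- stats::setNames(rep("no match", length(ids)), ids)
  lens <- Biostrings::width(contigSeqs(contigs))
  sel <- which(lens >= max(minLen, 1000L))
  if (!length(sel)) return(out)
  vecs <- trinucVector(contigSeqs(contigs)[sel])
  cen <- model@centroids
  dmat <- vapply(seq_len(nrow(cen)), function(b)
    rowSums(abs(vecs - rep(cen[b, ], each = nrow(vecs)))), numeric(nrow(vecs)))
  dmat <- matrix(dmat, nrow = nrow(vecs))
  nearest <- apply(dmat, 1L, which.min)   # ties -> first = lexicographic
  mind <- dmat[cbind(seq_len(nrow(vecs)), nearest)]
  lab <- rownames(cen)[nearest]
  lab[mind > model@threshold] <- "no match"
  out[ids[sel]] <- lab
  out
}
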