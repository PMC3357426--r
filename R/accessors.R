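#' Construct a ContigSet
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector of
#'   nucleotide sequences over A, C, G, T, N (lowercase accepted, uppercased).
#' @param depth numeric vector of positive mean assembly depths.  May be a
#'   named vector covering a subset of the contigs; contigs with no depth
#'   entry receive the conventional depth of 1.
#' @return a [ContigSet-class] object.
#' @examples
#' cs <- ContigSet(c(c1 = "ACGTACGT"), depth = c(c1 = 2))
#' contigDepth(cs)
#' @export
ContigSet <- function(seqs, depth = NULL) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- vapply(seqs, toupper, character(1))
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  ids <- names(seqs)
  if (is.null(depth)) {
    depth <- rep(1, length(seqs))
  } else if (!is.null(names(depth))) {
    depth <- unname(ifelse(is.na(depth[ids]), 1, depth[ids]))
  }
  methods::new("ContigSet", seqs = seqs, depth = as.numeric(depth))
}

#' Construct a FamilyDB
#'
#' @param aa a [Biostrings::AAStringSet] or named character vector of protein
#'   sequences (20-letter alphabet plus X).
#' @param family character vector of family labels, parallel to `aa`.
#' @return a [FamilyDB-class] object.
#' @export
FamilyDB <- function(aa, family) {
  if (!methods::is(aa, "AAStringSet"))
    aa <- Biostrings::AAStringSet(vapply(aa, toupper, character(1)))
  methods::new("FamilyDB", aa = aa, family = as.character(family))
}

# internal: profile builder keeping the perMillion invariant
makeFamilyProfile <- function(label, weightedNt, totalWeightedBases) {
  weightedNt <- weightedNt[order(names(weightedNt))]
  methods::new("FamilyProfile", label = label,
               weightedNt = weightedNt,
               perMillion = 1e6 * weightedNt / totalWeightedBases,
               totalWeightedBases = totalWeightedBases)
}

#' @rdname ContigSet-class
#' @param x object.
#' @export
setMethod("contigSeqs", "ContigSet", function(x) x@seqs)
#' @rdname ContigSet-class
#' @export
setMethod("contigDepth", "ContigSet",
          function(x) stats::setNames(x@depth, names(x@seqs)))
#' @rdname ContigSet-class
#' @export
setMethod("contigIds", "ContigSet", function(x) names(x@seqs))
#' @rdname ContigSet-class
#' @export
setMethod("length", "ContigSet", function(x) length(x@seqs))
#' @rdname ContigSet-class
#' @param i index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ContigSet", function(x, i, j, ..., drop = TRUE) {
  methods::new("ContigSet", seqs = x@seqs[i],
               depth = unname(contigDepth(x)[i]))
})
#' @rdname ContigSet-class
#' @export
setMethod("c", "ContigSet", function(x, ...) {
  rest <- list(...)
  for (y in rest)
    x <- methods::new("ContigSet",
                      seqs = c(x@seqs, contigSeqs(y)),
                      depth = c(x@depth, y@depth))
  x
})
setMethod("show", "ContigSet", function(object) {
  cat(sprintf("ContigSet: %d contigs, %s nt total, depth range [%.2g, %.2g]\n",
              length(object@seqs),
              format(sum(width(object@seqs)), big.mark = ","),
              if (length(object@depth)) min(object@depth) else NA,
              if (length(object@depth)) max(object@depth) else NA))
})

#' @rdname FamilyDB-class
#' @param x object.
#' @export
setMethod("familyLabels", "FamilyDB",
          function(x) stats::setNames(x@family, names(x@aa)))
#' @rdname FamilyDB-class
#' @export
setMethod("proteinSeqs", "FamilyDB", function(x) x@aa)
#' @rdname FamilyDB-class
#' @export
setMethod("length", "FamilyDB", function(x) length(x@aa))
setMethod("show", "FamilyDB", function(object) {
  cat(sprintf("FamilyDB: %d proteins in %d families (%s ...)\n",
              length(object@aa), length(unique(object@family)),
              paste(utils::head(sort(unique(object@family)), 5),
                    collapse = ", ")))
})

#' @rdname FamilyProfile-class
#' @param x object.
#' @export
setMethod("perMillion", "FamilyProfile", function(x) x@perMillion)
#' @rdname FamilyProfile-class
#' @export
setMethod("weightedNt", "FamilyProfile", function(x) x@weightedNt)
#' @rdname FamilyProfile-class
#' @export
setMethod("totalWeightedBases", "FamilyProfile",
          function(x) x@totalWeightedBases)
#' @rdname FamilyProfile-class
#' @export
setMethod("profileLabel", "FamilyProfile", function(x) x@label)
setMethod("show", "FamilyProfile", function(object) {
  cat(sprintf(
    "FamilyProfile '%s': %d families, %.4g depth-weighted bases\n",
    object@label, length(object@weightedNt), object@totalWeightedBases))
  top <- utils::head(sort(object@perMillion, decreasing = TRUE), 5)
  if (length(top))
    cat("  top families (nt/Mnt):",
        paste(sprintf("%s=%.1f", names(top), top), collapse = ", "), "\n")
})

#' @rdname ProfileMatrix-class
#' @param x object.
#' @export
setMethod("profileValues", "ProfileMatrix", function(x) x@values)
#' @rdname ProfileMatrix-class
#' @export
setMethod("familyClasses", "ProfileMatrix",
          function(x) stats::setNames(x@familyClass, rownames(x@values)))
setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix: %d families x %d metagenomes [%s]\n",
              nrow(object@values), ncol(object@values),
              paste(colnames(object@values), collapse = ", ")))
})

#' @rdname BinModel-class
#' @param x object.
#' @export
setMethod("binLabels", "BinModel", function(x) rownames(x@centroids))
#' @rdname BinModel-class
#' @export
setMethod("binThreshold", "BinModel", function(x) x@threshold)
setMethod("show", "BinModel", function(object) {
  cat(sprintf("BinModel (%s): %d bins [%s], threshold %.4g\n",
              object@metric, nrow(object@centroids),
              paste(rownames(object@centroids), collapse = ", "),
              object@threshold))
})
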