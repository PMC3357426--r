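#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet
NULL

#' ContigSet: assembled contigs with mean depths
#'
#' Container for the assembled contigs (or scaffolds) of one metagenome
#' together with their mean assembly depth (unitless fold-coverage).  Depth
#' acts as a proxy for the abundance of the source organism and weights every
#' downstream family total; contigs without depth information carry the
#' conventional depth of 1.
#'
#' @slot seqs a [Biostrings::DNAStringSet] over A, C, G, T, N; names are the
#'   contig identifiers and must be unique and nonempty.
#' @slot depth numeric vector of positive mean depths, parallel to `seqs`.
#' @export
setClass("ContigSet",
  representation(seqs = "DNAStringSet", depth = "numeric"))

setValidity("ContigSet", function(object) {
  ids <- names(object@seqs)
  if (length(object@seqs) && (is.null(ids) || any(!nzchar(ids))))
    return("all contigs must have nonempty identifiers")
  if (anyDuplicated(ids))
    return(sprintf("duplicate contig identifier: '%s'",
                   ids[duplicated(ids)][1L]))
  if (length(object@seqs) && any(width(object@seqs) < 1L))
    return("empty contig sequence")
  freq <- Biostrings::alphabetFrequency(object@seqs, collapse = TRUE)
  illegal <- freq[setdiff(names(freq), c("A", "C", "G", "T", "N"))]
  if (length(illegal) && sum(illegal) > 0)
    return(sprintf("illegal nucleotide character(s): %s",
                   paste(names(illegal)[illegal > 0], collapse = ", ")))
  if (length(object@depth) != length(object@seqs))
    return("depth must be parallel to seqs")
  if (length(object@depth) && (any(!is.finite(object@depth)) ||
                               any(object@depth <= 0)))
    return("contig depth must be a positive finite number")
  TRUE
})

#' FamilyDB: family-labeled protein reference database
#'
#' Protein sequences each labeled with a gene-family identifier (e.g. "GH13",
#' "GT2", "LO2"; composite labels such as "GH94/GT84" are treated as atomic
#' strings, matching how such families are tabulated).  This is the target of
#' the translated tile search, emulating the CAZy and FOLy databases.
#'
#' @slot aa a [Biostrings::AAStringSet]; names are unique protein ids.
#' @slot family character vector of family labels, parallel to `aa`.
#' @export
setClass("FamilyDB",
  representation(aa = "AAStringSet", family = "character"))

setValidity("FamilyDB", function(object) {
  if (length(object@family) != length(object@aa))
    return("family must be parallel to aa")
  if (length(object@aa) == 0L)
    return("family database must contain at least one record")
  ids <- names(object@aa)
  if (is.null(ids) || any(!nzchar(ids)))
    return("all proteins must have nonempty identifiers")
  if (anyDuplicated(ids))
    return(sprintf("duplicate protein identifier: '%s'",
                   ids[duplicated(ids)][1L]))
  if (any(is.na(object@family) | !nzchar(object@family)))
    return("every protein needs a nonempty family label")
  freq <- Biostrings::alphabetFrequency(object@aa, collapse = TRUE)
  illegal <- freq[setdiff(names(freq),
                          c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"))]
  if (length(illegal) && sum(illegal) > 0)
    return(sprintf("illegal amino-acid character(s): %s",
                   paste(names(illegal)[illegal > 0], collapse = ", ")))
  TRUE
})

#' FamilyProfile: depth-weighted family abundances of one metagenome or bin
#'
#' For every gene family, the total number of contig nucleotides attributed
#' to the family by best-hit runs, weighted by mean contig depth
#' (`weightedNt`), and the same value normalized to nucleotides per million
#' depth-weighted nucleotides (`perMillion`).
#'
#' @slot label metagenome or bin name.
#' @slot weightedNt named numeric: family -> nt x depth total.
#' @slot perMillion named numeric: family -> nt per million depth-weighted nt.
#' @slot totalWeightedBases positive real, sum over contigs of length x depth.
#' @export
setClass("FamilyProfile",
  representation(label = "character", weightedNt = "numeric",
                 perMillion = "numeric", totalWeightedBases = "numeric"))

setValidity("FamilyProfile", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a single nonempty string")
  if (length(object@totalWeightedBases) != 1L ||
      !is.finite(object@totalWeightedBases) || object@totalWeightedBases <= 0)
    return("totalWeightedBases must be a single positive number")
  if (!identical(names(object@weightedNt), names(object@perMillion)))
    return("weightedNt and perMillion must share family names")
  if (any(object@weightedNt < 0) || any(object@perMillion < 0))
    return("family totals must be nonnegative")
  pm <- 1e6 * object@weightedNt / object@totalWeightedBases
  if (length(pm) && max(abs(pm - object@perMillion)) >
      1e-6 * max(1, max(pm)))
    return("perMillion inconsistent with weightedNt / totalWeightedBases")
  TRUE
})

#' ProfileMatrix: family x metagenome per-million matrix
#'
#' Zero-filled union of the family universes of several profiles, one column
#' per metagenome (or bin), used as input to correlation-distance comparison.
#'
#' @slot values numeric matrix, rows = families, columns = labels.
#' @slot familyClass character vector parallel to rows: GH, GT, CE, PL, CBM,
#'   LO, LDA or other (majority class of composite labels, first component
#'   breaking ties).
#' @export
setClass("ProfileMatrix",
  representation(values = "matrix", familyClass = "character"))

setValidity("ProfileMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have family rownames and metagenome colnames")
  if (any(v < 0)) return("per-million values cannot be negative")
  if (length(object@familyClass) != nrow(v))
    return("familyClass must be parallel to rows")
  TRUE
})

#' BinModel: trinucleotide-composition centroid classifier
#'
#' Nearest-centroid model for composition-based contig binning.  Each
#' population bin is represented by the length-weighted mean of the
#' strand-symmetrized trinucleotide frequency vectors of its training
#' contigs; contigs farther than `threshold` from every centroid fall in the
#' "no match" class.
#'
#' @slot centroids numeric matrix, rows = bin labels, 64 columns (3-mers).
#' @slot threshold positive maximum assignment distance.
#' @slot metric distance identifier (currently "l1").
#' @export
setClass("BinModel",
  representation(centroids = "matrix", threshold = "numeric",
                 metric = "character"))

setValidity("BinModel", function(object) {
  if (nrow(object@centroids) < 2L)
    return("a bin model needs at least two bins")
  if (ncol(object@centroids) != 64L)
    return("centroids must have 64 trinucleotide columns")
  if (any(abs(rowSums(object@centroids) - 1) > 1e-9))
    return("each centroid must sum to 1")
  if (length(object@threshold) != 1L || object@threshold < 0)
    return("threshold must be a single nonnegative number")
  if (!object@metric %in% "l1")
    return(sprintf("unsupported metric '%s'", object@metric))
  TRUE
})
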