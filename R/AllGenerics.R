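#' @rdname ContigSet-class
#' @export
setGeneric("contigSeqs", function(x) standardGeneric("contigSeqs"))
#' @rdname ContigSet-class
#' @export
setGeneric("contigDepth", function(x) standardGeneric("contigDepth"))
#' @rdname ContigSet-class
#' @export
setGeneric("contigIds", function(x) standardGeneric("contigIds"))
#' @rdname FamilyDB-class
#' @export
setGeneric("familyLabels", function(x) standardGeneric("familyLabels"))
#' @rdname FamilyDB-class
#' @export
setGeneric("proteinSeqs", function(x) standardGeneric("proteinSeqs"))
#' @rdname FamilyProfile-class
#' @export
setGeneric("perMillion", function(x) standardGeneric("perMillion"))
#' @rdname FamilyProfile-class
#' @export
setGeneric("weightedNt", function(x) standardGeneric("weightedNt"))
#' @rdname FamilyProfile-class
#' @export
setGeneric("totalWeightedBases",
           function(x) standardGeneric("totalWeightedBases"))
#' @rdname FamilyProfile-class
#' @export
setGeneric("profileLabel", function(x) standardGeneric("profileLabel"))
#' @rdname ProfileMatrix-class
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname ProfileMatrix-class
#' @export
setGeneric("familyClasses", function(x) standardGeneric("familyClasses"))
#' @rdname BinModel-class
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))
#' @rdname BinModel-class
#' @export
setGeneric("binThreshold", function(x) standardGeneric("binThreshold"))
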