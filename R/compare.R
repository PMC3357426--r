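#' @importFrom stats cor hclust as.dist cmdscale cutree
#' @importFrom ape as.phylo write.tree
NULL

#' Family class of a family label
#'
#' Prefix-based classification into GH (glycoside hydrolases), GT (glycosyl
#' transferases), CE (carbohydrate esterases), PL (polysaccharide lyases),
#' CBM (carbohydrate-binding modules), LO (lignin oxidases), LDA
#' (lignin-degrading auxiliary enzymes) or "other".  Composite labels such
#' as "GH94/GT84" take the majority class of their components, with the
#' first component breaking ties (so "GH94/GT84" is GH).
#'
#' @param family character vector of family labels.
#' @return character vector of classes.
#' @export
familyClass <- function(family) {
  classOne <- function(lab) {
    comps <- strsplit(lab, "/", fixed = TRUE)[[1L]]
    cls <- sub("^(GH|GT|CE|PL|CBM|LO(?=[0-9])|LDA).*$", "\\1", comps,
               perl = TRUE)
    cls[!cls %in% c("GH", "GT", "CE", "PL", "CBM", "LO", "LDA")] <- "other"
    tab <- table(factor(cls, levels = unique(cls)))  # first-seen order
    names(tab)[which.max(tab)]                       # majority, ties -> first
  }
  vapply(family, classOne, character(1), USE.NAMES = FALSE)
}

#' Default biomass-modifying family set
#'
#' The glycoside hydrolase families known to act on the critical
#' polysaccharide bonds of hardwood (xylan, glucomannan and cellulose
#' backbones and their side chains), plus the lignin-oxidase (LO) and
#' lignin-degrading auxiliary (LDA) families.  Used as the default filter
#' for pairwise biomass-enzyme scatter comparisons.
#'
#' @return character vector of family labels (prefix match for LO/LDA).
#' @export
biomassFamilies <- function() {
  gh <- c(1, 2, 3, 5, 6, 7, 8, 9, 10, 11, 12, 26, 30, 39, 43, 44, 45, 48,
          51, 52, 54, 61, 67, 74, 113, 115, 116, 120, 124)
  c(paste0("GH", gh), paste0("LO", 1:3), paste0("LDA", 1:8))
}

# does a family label (possibly composite) belong to the biomass set?
inBiomassSet <- function(family, set = biomassFamilies()) {
  vapply(strsplit(family, "/", fixed = TRUE),
         function(comps) any(comps %in% set), logical(1))
}

#' Assemble a family x metagenome profile matrix
#'
#' Zero-fills the union of the profiles' family universes.  `filter = "GH"`
#' keeps families whose class is GH (composite labels via the majority
#' prefix rule, so "GH94/GT84" survives); `filter = "biomass"` keeps the
#' configured biomass-modifying family set (see [biomassFamilies()]).
#'
#' @param profiles list of [FamilyProfile-class] objects (>= 2).
#' @param filter `"all"`, `"GH"` or `"biomass"`.
#' @param minProfiles internal validation override.
#' @return a [ProfileMatrix-class] of per-million values.
#' @export
assembleMatrix <- function(profiles, filter = c("all", "GH", "biomass"),
                           minProfiles = 2L) {
  filter <- match.arg(filter)
  if (length(profiles) < minProfiles)
    mcStop("need at least %d profiles", minProfiles)
  labels <- vapply(profiles, profileLabel, character(1))
  if (anyDuplicated(labels))
    mcStop("duplicate profile label '%s'", labels[duplicated(labels)][1L])
  fams <- sort(unique(unlist(lapply(profiles,
                                    function(p) names(perMillion(p))))))
  m <- matrix(0, nrow = length(fams), ncol = length(profiles),
              dimnames = list(fams, labels))
  for (j in seq_along(profiles)) {
    pm <- perMillion(profiles[[j]])
    m[names(pm), j] <- pm
  }
  if (filter == "GH") {
    m <- m[familyClass(rownames(m)) == "GH", , drop = FALSE]
  } else if (filter == "biomass") {
    m <- m[inBiomassSet(rownames(m)), , drop = FALSE]
  }
  methods::new("ProfileMatrix", values = m,
               familyClass = familyClass(rownames(m)))
}

#' Spearman correlation distance between metagenomes
#'
#' d(i, j) = 1 - rho(column_i, column_j) with average ranks for ties.  A
#' column with zero variance has no defined rank correlation; its pairwise
#' distances are set to 1 (rho = 0) with a warning.
#'
#' @param matrix a [ProfileMatrix-class] or numeric matrix (rows = families,
#'   >= 3; columns = metagenomes, >= 2).
#' @return symmetric distance matrix with zero diagonal, entries in [0, 2].
#' @export
spearmanDistance <- function(matrix) {
  v <- if (methods::is(matrix, "ProfileMatrix")) profileValues(matrix)
       else matrix
  if (ncol(v) < 2L) mcStop("need at least 2 metagenome columns")
  if (nrow(v) < 3L) mcStop("need at least 3 families")
  flat <- apply(v, 2L, function(col) max(col) == min(col))
  rho <- suppressWarnings(cor(v, method = "spearman"))
  if (any(flat)) {
    warning("zero-variance column(s): ",
            paste(colnames(v)[flat], collapse = ", "),
            "; their correlations are set to 0")
    rho[flat, ] <- 0; rho[, flat] <- 0
  }
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Hierarchical clustering of a metagenome distance matrix
#'
#' Agglomerative clustering with average linkage (UPGMA) by default.  The
#' labels are put in lexicographic order before clustering so that merge
#' tie-breaking is deterministic across platforms.
#'
#' @param dist symmetric distance matrix with labels.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an object of class `hclust`.
#' @export
clusterProfiles <- function(dist, linkage = c("average", "complete",
                                              "single")) {
  linkage <- match.arg(linkage)
  ord <- order(rownames(dist))
  hclust(as.dist(dist[ord, ord]), method = linkage)
}

#' @rdname clusterProfiles
#' @param hc an `hclust` object.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @export
writeNewick <- function(hc, path = NULL) {
  tree <- as.phylo(hc)
  if (is.null(path)) write.tree(tree) else {
    write.tree(tree, file = path)
    invisible(path)
  }
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS on the double-centered squared distances.  Axes are ordered
#' by eigenvalue; each axis is flipped, if necessary, so that its first
#' nonzero coordinate is positive, making the embedding deterministic.
#'
#' @param dist symmetric distance matrix (>= 3 labels).
#' @param k embedding dimension (< number of labels).
#' @return numeric matrix labels x k.
#' @export
mdsEmbedding <- function(dist, k = 2L) {
  n <- nrow(dist)
  if (n < 3L) mcStop("MDS needs at least 3 labels")
  if (k >= n) mcStop("k must be smaller than the number of labels")
  coords <- cmdscale(as.dist(dist), k = k)
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1L], j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  coords
}

#' Pairwise biomass-enzyme scatter data
#'
#' Per-million values of two metagenomes for a filtered family set, with the
#' family class attached for plotting.  Zero-valued families are included so
#' that absences (for example the lignin-oxidase families in gut-like
#' profiles) remain visible.
#'
#' @param matrix a [ProfileMatrix-class] (assembled with `filter = "all"`).
#' @param labelA,labelB metagenome labels to compare.
#' @param filter family filter, as in [assembleMatrix()].
#' @return data.frame with columns `family`, `valueA`, `valueB`, `class`.
#' @export
pairwiseScatter <- function(matrix, labelA, labelB,
                            filter = c("biomass", "GH", "all")) {
  filter <- match.arg(filter)
  v <- profileValues(matrix)
  if (!labelA %in% colnames(v)) mcStop("unknown label '%s'", labelA)
  if (!labelB %in% colnames(v)) mcStop("unknown label '%s'", labelB)
  keep <- switch(filter,
    all = rep(TRUE, nrow(v)),
    GH = familyClass(rownames(v)) == "GH",
    biomass = inBiomassSet(rownames(v)))
  v <- v[keep, , drop = FALSE]
  data.frame(family = rownames(v), valueA = unname(v[, labelA]),
             valueB = unname(v[, labelB]),
             class = familyClass(rownames(v)), stringsAsFactors = FALSE)
}
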