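#' @importFrom IRanges IRanges reduce start end width
NULL

#' Tiling parameters
#'
#' Contigs are divided into `tileLen` nt tiles every `step` nt (defaults
#' 300/150, i.e. 300 nt tiles overlapping by 150 nt).  A final partial tile
#' is emitted only if it is at least `minTail` nt long; a contig shorter
#' than `minTail` yields a single tile covering the whole contig.
#'
#' @param tileLen,step,minTail positive/nonnegative integers (nt);
#'   `step <= tileLen`, `minTail <= tileLen`.
#' @return a validated list of class `TilingParams`.
#' @export
tilingParams <- function(tileLen = 300L, step = 150L, minTail = 150L) {
  tileLen <- as.integer(tileLen); step <- as.integer(step)
  minTail <- as.integer(minTail)
  if (tileLen < 1L || step < 1L) mcStop("tileLen and step must be positive")
  if (step > tileLen) mcStop("step must not exceed tileLen")
  if (minTail < 0L || minTail > tileLen)
    mcStop("minTail must lie in [0, tileLen]")
  structure(list(tileLen = tileLen, step = step, minTail = minTail),
            class = "TilingParams")
}

#' Divide a contig into overlapping tiles
#'
#' Tile starts are 0, step, 2*step, ...; each tile ends at
#' `min(start + tileLen, contigLen)`.  Generation stops at the first tile
#' reaching the contig end; a final partial tile shorter than `minTail` is
#' suppressed.  Coordinates are 0-based half-open.
#'
#' @param contigLen contig length in nt (>= 1).
#' @param params a [tilingParams()] list.
#' @return data.frame with columns `start`, `end`.
#' @export
tileContig <- function(contigLen, params = tilingParams()) {
  contigLen <- as.integer(contigLen)
  if (contigLen < 1L) mcStop("contig length must be >= 1")
  if (contigLen <= params$minTail)
    return(data.frame(start = 0L, end = contigLen))
  starts <- integer(0); ends <- integer(0)
  s <- 0L
  repeat {
    e <- min(s + params$tileLen, contigLen)
    if (e - s == params$tileLen || e - s >= params$minTail) {
      starts <- c(starts, s); ends <- c(ends, e)
    }
    if (s + params$tileLen >= contigLen) break
    s <- s + params$step
  }
  data.frame(start = starts, end = ends)
}

# tiles for every contig of a ContigSet, in contig order
tileContigSet <- function(contigs, params = tilingParams()) {
  ids <- contigIds(contigs)
  lens <- Biostrings::width(contigSeqs(contigs))
  out <- lapply(seq_along(ids), function(i) {
    t <- tileContig(lens[i], params)
    cbind(contigId = ids[i], t)
  })
  res <- do.call(rbind, out)
  res$contigId <- as.character(res$contigId)
  res
}

# parse "<contig>:<start>-<end>" tile ids
parseTileId <- function(queryId) {
  m <- regmatches(queryId, regexec("^(.*):([0-9]+)-([0-9]+)$", queryId))
  bad <- lengths(m) != 4L
  if (any(bad))
    mcStop("unparseable tile id '%s'", queryId[bad][1L])
  data.frame(contigId = vapply(m, `[`, "", 2L),
             tileStart = as.integer(vapply(m, `[`, "", 3L)),
             tileEnd = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Best family hit per tile
#'
#' Per tile the hit with the smallest e-value wins; ties are broken by
#' larger bit score, then lexicographically smallest family, then smallest
#' subject id.  The winning hit's aligned span is lifted from tile-local to
#' contig coordinates (`spanMode = "span"`); with `spanMode = "tile"` the
#' whole tile is attributed to the winning family instead.
#'
#' @param hits hit data.frame (already e-value filtered), tile query ids of
#'   the form `<contig>:<start>-<end>`.
#' @param spanMode `"span"` (aligned nucleotides, default) or `"tile"`.
#' @return data.frame with one row per tile that has hits: `queryId`,
#'   `contigId`, `family`, `evalue`, `bitscore`, `start`, `end` (contig
#'   coordinates, 0-based half-open).
#' @export
bestHitPerTile <- function(hits, spanMode = c("span", "tile")) {
  spanMode <- match.arg(spanMode)
  if (nrow(hits) == 0L)
    return(data.frame(queryId = character(0), contigId = character(0),
                      family = character(0), evalue = numeric(0),
                      bitscore = numeric(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  ord <- order(hits$queryId, hits$evalue, -hits$bitscore, hits$family,
               hits$subjectId, method = "radix")
  h <- hits[ord, , drop = FALSE]
  best <- h[!duplicated(h$queryId), , drop = FALSE]
  tile <- parseTileId(best$queryId)
  if (spanMode == "span") {
    start <- tile$tileStart + best$qstart
    end <- tile$tileStart + best$qend
  } else {
    start <- tile$tileStart
    end <- tile$tileEnd
  }
  data.frame(queryId = best$queryId, contigId = tile$contigId,
             family = best$family, evalue = best$evalue,
             bitscore = best$bitscore,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Collect contiguous same-family runs
#'
#' Per contig and family, the aligned spans of adjacent or overlapping tiles
#' that agree on the family are unioned into maximal disjoint intervals, so
#' each contig nucleotide is counted at most once per family (the 150 nt
#' tile overlap is never double-counted).  Runs of different families may
#' overlap each other.
#'
#' @param assignments output of [bestHitPerTile()].
#' @param contigLens named integer vector of contig lengths (for validation).
#' @return data.frame with columns `contigId`, `family`, `start`, `end`,
#'   `coveredNt`.
#' @export
collectRuns <- function(assignments, contigLens = NULL) {
  if (nrow(assignments) == 0L)
    return(data.frame(contigId = character(0), family = character(0),
                      start = integer(0), end = integer(0),
                      coveredNt = integer(0), stringsAsFactors = FALSE))
  if (!is.null(contigLens)) {
    lim <- contigLens[assignments$contigId]
    if (any(is.na(lim)) || any(assignments$start < 0) ||
        any(assignments$end > lim))
      mcStop("hit span outside its contig")
  }
  key <- paste(assignments$contigId, assignments$family, sep = "\r")
  parts <- split(assignments, key)
  out <- lapply(parts, function(p) {
    r <- reduce(IRanges(start = p$start + 1L, end = p$end))
    data.frame(contigId = p$contigId[1L], family = p$family[1L],
               start = start(r) - 1L, end = end(r),
               coveredNt = width(r), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contigId, res$family, res$start), , drop = FALSE]
}

#' Depth-weighted family totals
#'
#' Run lengths are multiplied by mean contig depth and totaled by family.
#' Contigs absent from `depths` get the conventional depth of 1.
#'
#' @param runs output of [collectRuns()].
#' @param depths named numeric vector contig_id -> depth (may be empty).
#' @return named numeric vector family -> depth-weighted nucleotide total.
#' @export
familyTotals <- function(runs, depths = numeric(0)) {
  if (nrow(runs) == 0L) return(stats::setNames(numeric(0), character(0)))
  d <- unname(depths[runs$contigId])
  d[is.na(d)] <- 1
  tot <- tapply(runs$coveredNt * d, runs$family, sum)
  stats::setNames(as.numeric(tot), names(tot))
}

#' Normalize family totals to nucleotides per million
#'
#' The denominator is the total amount of sequence data weighted by contig
#' depth: the sum over contigs of length times depth.  perMillion[f] =
#' 1e6 * weightedNt[f] / totalWeightedBases.
#'
#' @param totals named numeric vector from [familyTotals()].
#' @param contigs a [ContigSet-class] (must be nonempty).
#' @param label profile label.
#' @return a [FamilyProfile-class].
#' @export
normalizePerMillion <- function(totals, contigs, label = "metagenome") {
  if (length(contigs) == 0L) mcStop("no contigs to normalize over")
  twb <- sum(as.numeric(Biostrings::width(contigSeqs(contigs))) *
             contigDepth(contigs))
  if (twb <= 0) mcStop("total weighted bases is zero")
  makeFamilyProfile(label, totals, twb)
}

#' Whole-metagenome family profile
#'
#' Convenience composition of the pipeline: tile search (unless precomputed
#' hits are given), best hit per tile, run collection, depth weighting and
#' per-million normalization.
#'
#' @param contigs a [ContigSet-class].
#' @param db a [FamilyDB-class]; required when `hits` is `NULL`.
#' @param hits optional precomputed hit data.frame (e-value filtered).
#' @param tiling,scoring tiling and scoring parameter lists.
#' @param spanMode run-length mode, see [bestHitPerTile()].
#' @param label profile label.
#' @return a [FamilyProfile-class].
#' @export
profileMetagenome <- function(contigs, db = NULL, hits = NULL,
                              tiling = tilingParams(),
                              scoring = scoringParams(),
                              spanMode = "span", label = "metagenome") {
  if (is.null(hits)) {
    if (is.null(db)) mcStop("either hits or db must be given")
    hits <- searchContigs(contigs, db, tiling, scoring)
  }
  lens <- stats::setNames(Biostrings::width(contigSeqs(contigs)),
                          contigIds(contigs))
  runs <- collectRuns(bestHitPerTile(hits, spanMode), lens)
  normalizePerMillion(familyTotals(runs, contigDepth(contigs)),
                      contigs, label = label)
}

#' Per-bin family profiles
#'
#' Restricts the analysis to contigs of at least `minContigLen` nt (default
#' 1000), groups them by bin assignment (contigs without an assignment fall
#' in the "no match" bin) and normalizes each bin's family totals by that
#' bin's own depth-weighted base total.
#'
#' @param runs output of [collectRuns()].
#' @param contigs a [ContigSet-class].
#' @param assignment named character vector contig_id -> bin label; missing
#'   contigs are labeled "no match".
#' @param minContigLen minimum contig length in nt.
#' @param binDenominator `"bin"` (each bin's own weighted base total,
#'   default) or `"metagenome"` (shared denominator over all kept contigs).
#' @return named list of [FamilyProfile-class], one per bin present.
#' @export
binProfiles <- function(runs, contigs, assignment,
                        minContigLen = 1000L,
                        binDenominator = c("bin", "metagenome")) {
  binDenominator <- match.arg(binDenominator)
  lens <- Biostrings::width(contigSeqs(contigs))
  keep <- lens >= minContigLen
  if (!any(keep)) mcStop("no contigs of length >= %d", minContigLen)
  kept <- contigs[which(keep)]
  ids <- contigIds(kept)
  bin <- unname(assignment[ids])
  bin[is.na(bin)] <- "no match"
  depths <- contigDepth(kept)
  wb <- as.numeric(Biostrings::width(contigSeqs(kept))) * depths
  runs <- runs[runs$contigId %in% ids, , drop = FALSE]
  runBin <- stats::setNames(bin, ids)[runs$contigId]
  out <- list()
  for (b in sort(unique(bin))) {
    binTotals <- familyTotals(runs[runBin == b, , drop = FALSE], depths)
    denom <- if (binDenominator == "bin") sum(wb[bin == b]) else sum(wb)
    if (denom <= 0) mcStop("bin '%s' has zero weighted bases", b)
    out[[b]] <- makeFamilyProfile(b, binTotals, denom)
  }
  out
}

#' Rank the dominant gene families
#'
#' Orders families by decreasing abundance (ties broken lexicographically)
#' and reports the top `topN` together with their share of the grand total
#' over all families.
#'
#' @param profile a [FamilyProfile-class] or a named numeric vector of
#'   family values (counts or per-million).
#' @param topN number of families to return (>= 1).
#' @param by which slot to rank when `profile` is a FamilyProfile.
#' @return data.frame with columns `family`, `value`, `share`, ordered by
#'   decreasing `value`; `sum(share)` equals the top-`topN` fraction of the
#'   grand total.
#' @export
rankFamilies <- function(profile, topN = 22L,
                         by = c("perMillion", "weightedNt")) {
  by <- match.arg(by)
  values <- if (methods::is(profile, "FamilyProfile")) {
    if (by == "perMillion") perMillion(profile) else weightedNt(profile)
  } else profile
  if (length(values) == 0L) mcStop("empty profile")
  if (topN < 1L) mcStop("topN must be >= 1")
  ord <- order(-values, names(values), method = "radix")
  values <- values[ord]
  grand <- sum(values)
  top <- utils::head(values, topN)
  data.frame(family = names(top), value = unname(top),
             share = unname(top) / grand, stringsAsFactors = FALSE)
}
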