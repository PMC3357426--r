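#' @importFrom Biostrings translate reverseComplement subseq
#' @useDynLib MetaCAZ, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# BLOSUM62 is lazily loaded from Biostrings and cached
.mcEnv <- new.env(parent = emptyenv())

getScoreMatrix <- function(name) {
  if (is.matrix(name)) return(name)
  key <- paste0("mat_", name)
  if (is.null(.mcEnv[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .mcEnv[[key]] <- get(name, envir = e)
  }
  .mcEnv[[key]]
}

#' Scoring parameters for the translated tile search
#'
#' The e-value of a local alignment with raw score S against a database of n
#' residues, queried with a tile of m nucleotides, is computed with fixed
#' Karlin-Altschul-style constants: bitscore = (lambda * S - ln k) / ln 2 and
#' evalue = m * n * 2^(-bitscore).  Defaults are the common gapped-BLOSUM62
#' values (lambda 0.267, k 0.041, gap open -11, gap extend -1); the e-value
#' cutoff defaults to 1e-10, the threshold used throughout the profiling.
#'
#' @param matrix substitution matrix name (resolved from Biostrings) or an
#'   integer matrix with amino-acid dimnames including `*`.
#' @param gapOpen,gapExtend nonpositive integers; a gap of length g costs
#'   `gapOpen + g * gapExtend`.
#' @param lambda,k positive reals for the bit-score conversion.
#' @param evalueCutoff positive real; hits with evalue >= cutoff are dropped.
#' @return a validated list of class `ScoringParams`.
#' @export
scoringParams <- function(matrix = "BLOSUM62", gapOpen = -11L,
                          gapExtend = -1L, lambda = 0.267, k = 0.041,
                          evalueCutoff = 1e-10) {
  mat <- getScoreMatrix(matrix)
  if (!isTRUE(all.equal(mat, t(mat))))
    mcStop("substitution matrix must be symmetric")
  if (gapOpen > 0 || gapExtend > 0)
    mcStop("gap penalties must be nonpositive")
  if (lambda <= 0 || k <= 0) mcStop("lambda and k must be positive")
  if (!(evalueCutoff > 0)) mcStop("evalueCutoff must be positive")
  structure(list(matrix = mat, gapOpen = as.integer(gapOpen),
                 gapExtend = as.integer(gapExtend), lambda = lambda, k = k,
                 evalueCutoff = evalueCutoff),
            class = "ScoringParams")
}

# amino-acid character -> 0-based substitution-matrix index lookup;
# unknown letters map to X
aaEncoder <- function(mat) {
  letters <- rownames(mat)
  lut <- rep.int(match("X", letters) - 1L, 127L)
  lut[utf8ToInt(paste(letters, collapse = ""))] <- seq_along(letters) - 1L
  lut
}

encodeAA <- function(s, lut) {
  if (!nchar(s)) return(integer(0))
  lut[utf8ToInt(s)]
}

#' Six-frame translation of a nucleotide sequence
#'
#' Frames F1-F3 are the three forward-strand offsets, R1-R3 the three
#' offsets of the reverse complement.  Codons containing N translate to X;
#' stop codons are rendered as `*` and retained, since local alignments are
#' not allowed to cross them.
#'
#' @param dna a character string or [Biostrings::DNAString] of length >= 3.
#' @return named character vector of 6 peptides (F1, F2, F3, R1, R2, R3).
#' @export
sixFrameTranslate <- function(dna) {
  dna <- Biostrings::DNAString(as.character(dna))
  if (length(dna) < 3L) mcStop("sequence shorter than one codon")
  frames <- sixFrameTranslateSet(Biostrings::DNAStringSet(list(dna)))
  stats::setNames(vapply(frames, function(f) as.character(f[[1L]]),
                         character(1)),
                  c("F1", "F2", "F3", "R1", "R2", "R3"))
}

# vectorized six-frame translation of a DNAStringSet; returns a list of six
# AAStringSets (F1,F2,F3,R1,R2,R3), each parallel to the input
sixFrameTranslateSet <- function(tiles) {
  rc <- reverseComplement(tiles)
  oneFrame <- function(set, off) {
    w <- Biostrings::width(set)
    end <- off + ((w - off) %/% 3L) * 3L
    suppressWarnings(translate(subseq(set, start = pmin(off + 1L, w + 1L),
                                      end = pmax(end, off)),
                               if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  c(lapply(0:2, function(off) oneFrame(tiles, off)),
    lapply(0:2, function(off) oneFrame(rc, off)))
}

# map an aa span [a, b) in frame `frame` (1..6) back to 0-based half-open
# nucleotide coordinates on the forward strand of a tile of length L
frameSpanToNt <- function(frame, a, b, L) {
  off <- (frame - 1L) %% 3L
  if (frame <= 3L) c(off + 3L * a, off + 3L * b)
  else c(L - (off + 3L * b), L - (off + 3L * a))
}

# core search of one encoded tile against an encoded db; returns a hit
# data.frame (possibly empty).  Used by both alignTile and searchContigs.
searchEncodedTile <- function(queryId, tileLen, framesEnc, dbEnc, dbIds,
                              dbFam, nResidues, scoring, stopCode) {
  scan <- .swScanFrames(framesEnc, dbEnc, scoring$matrix,
                        scoring$gapOpen, scoring$gapExtend, stopCode)
  score <- scan[, 1L]
  bits <- (scoring$lambda * score - log(scoring$k)) / log(2)
  evalue <- as.numeric(tileLen) * nResidues * 2^(-bits)
  sel <- which(score > 0 & evalue < scoring$evalueCutoff)
  if (!length(sel)) return(emptyHitTable())
  rows <- lapply(sel, function(d) {
    f <- scan[d, 2L]
    tb <- .swTraceback(framesEnc[[f]], dbEnc[[d]], scoring$matrix,
                       scoring$gapOpen, scoring$gapExtend, stopCode)
    nt <- frameSpanToNt(f, tb$qstart, tb$qend, tileLen)
    data.frame(queryId = queryId, subjectId = dbIds[d], family = dbFam[d],
               pident = 100 * tb$matches / max(1L, tb$alnLen),
               alnLen = tb$alnLen, mismatches = tb$mismatches,
               gapOpens = tb$gapOpens,
               qstart = as.integer(nt[1L]), qend = as.integer(nt[2L]),
               sstart = tb$sstart, send = tb$send,
               evalue = evalue[d], bitscore = bits[d],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits[order(-hits$bitscore, hits$subjectId), , drop = FALSE]
}

#' Align one tile against a family database
#'
#' Smith-Waterman local alignment of all six translation frames of the tile
#' against every database record; per (tile, record) only the best local
#' alignment is kept.  Hit coordinates are reported in tile nucleotide
#' coordinates on the forward strand regardless of frame.
#'
#' @param tileSeq nucleotide string (>= 30 nt).
#' @param db a [FamilyDB-class].
#' @param scoring a [scoringParams()] list.
#' @param queryId query identifier used in the output (defaults to "tile").
#' @return hit data.frame (see [readHitTable()] for columns).
#' @export
alignTile <- function(tileSeq, db, scoring = scoringParams(),
                      queryId = "tile") {
  tileSeq <- toupper(as.character(tileSeq))
  if (nchar(tileSeq) < 30L) mcStop("tile shorter than 30 nt")
  if (length(db) == 0L) mcStop("empty family database")
  lut <- aaEncoder(scoring$matrix)
  stopCode <- match("*", rownames(scoring$matrix)) - 1L
  frames <- sixFrameTranslate(tileSeq)
  framesEnc <- lapply(frames, encodeAA, lut = lut)
  aa <- as.character(proteinSeqs(db))
  dbEnc <- lapply(aa, encodeAA, lut = lut)
  searchEncodedTile(queryId, nchar(tileSeq), framesEnc, dbEnc,
                    names(aa), unname(familyLabels(db)),
                    sum(nchar(aa)), scoring, stopCode)
}

#' Translated tile search of a whole contig set
#'
#' Divides every contig into overlapping tiles (see [tileContig()]), searches
#' each tile independently against the family database and concatenates the
#' results in contig order, tile order, then descending bit score.  Tile
#' query ids follow the pattern `<contig_id>:<start>-<end>` with 0-based
#' half-open coordinates.
#'
#' @param contigs a [ContigSet-class].
#' @param db a [FamilyDB-class].
#' @param tiling a [tilingParams()] list.
#' @param scoring a [scoringParams()] list.
#' @return hit data.frame (see [readHitTable()] for columns).
#' @export
searchContigs <- function(contigs, db, tiling = tilingParams(),
                          scoring = scoringParams()) {
  if (length(db) == 0L) mcStop("empty family database")
  tiles <- tileContigSet(contigs, tiling)
  if (nrow(tiles) == 0L) return(emptyHitTable())
  seqs <- contigSeqs(contigs)
  tileSet <- Biostrings::DNAStringSet(
    lapply(seq_len(nrow(tiles)), function(i)
      subseq(seqs[[tiles$contigId[i]]], start = tiles$start[i] + 1L,
             end = tiles$end[i])))
  frames <- sixFrameTranslateSet(tileSet)
  frameChars <- lapply(frames, as.character)
  lut <- aaEncoder(scoring$matrix)
  stopCode <- match("*", rownames(scoring$matrix)) - 1L
  aa <- as.character(proteinSeqs(db))
  dbEnc <- lapply(aa, encodeAA, lut = lut)
  dbIds <- names(aa)
  dbFam <- unname(familyLabels(db))
  nRes <- sum(nchar(aa))
  queryIds <- sprintf("%s:%d-%d", tiles$contigId, tiles$start, tiles$end)
  out <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    framesEnc <- lapply(frameChars, function(fc) encodeAA(fc[[i]], lut))
    out[[i]] <- searchEncodedTile(queryIds[i], tiles$end[i] - tiles$start[i],
                                  framesEnc, dbEnc, dbIds, dbFam, nRes,
                                  scoring, stopCode)
  }
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits
}
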