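test_that("six-frame translation follows the expected conventions", {
  expect_equal(sixFrameTranslate("ATGGCC")[["F1"]], "MA")
  expect_error(sixFrameTranslate("AT"), "codon")

  # codons with N become X; stops are retained as '*'
  fr <- sixFrameTranslate("ATGNNNTAA")
  expect_equal(fr[["F1"]], "MX*")

  # reverse-complement symmetry: forward frames of revcomp(s) equal the
  # reverse frames of s
  set.seed(42)
  for (i in 1:5) {
    s <- randomDNA(120 + i)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- sixFrameTranslate(s); b <- sixFrameTranslate(rc)
    expect_equal(unname(a[c("R1", "R2", "R3")]),
                 unname(b[c("F1", "F2", "F3")]))
  }

  # frame lengths for a 999 nt sequence
  set.seed(7)
  fr <- sixFrameTranslate(randomDNA(999))
  expect_true(all(nchar(fr) %in% c(332L, 333L)))
  expect_equal(nchar(fr[["F1"]]), 333L)
})

test_that("the built-in aligner matches the plain-R dynamic program", {
  scoring <- scoringParams()
  lut <- MetaCAZ:::aaEncoder(scoring$matrix)
  stopCode <- match("*", rownames(scoring$matrix)) - 1L
  score1 <- function(q, s) {
    MetaCAZ:::.swScanFrames(list(MetaCAZ:::encodeAA(q, lut)),
                            list(MetaCAZ:::encodeAA(s, lut)),
                            scoring$matrix, scoring$gapOpen,
                            scoring$gapExtend, stopCode)[1L, 1L]
  }
  set.seed(101)
  for (rep in 1:12) {
    qlen <- sample(10:130, 1L)
    slen <- sample(10:200, 1L)
    q <- randomPeptide(qlen)
    # half the cases share a planted common segment so high-score paths
    # (including gapped ones) are exercised, not just noise
    s <- if (rep %% 2 == 0) {
      core <- substr(q, 3, min(qlen, 3 + 40))
      mutated <- strsplit(core, "")[[1L]]
      pos <- sample(seq_along(mutated), max(1L, length(mutated) %/% 8L))
      mutated[pos] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                             length(pos), replace = TRUE)
      paste0(randomPeptide(20), paste(mutated, collapse = ""),
             randomPeptide(20))
    } else randomPeptide(slen)
    expect_equal(score1(q, s), naiveSWScore(q, s),
                 info = sprintf("case %d", rep))
    # stop codons are barriers
    qstop <- paste0(substr(q, 1, qlen %/% 2), "*",
                    substr(q, qlen %/% 2 + 1, qlen))
    expect_equal(score1(qstop, s), naiveSWScore(qstop, s))
  }

  # traceback agrees with the scan and reports a consistent local alignment
  q <- randomPeptide(60); s <- paste0(randomPeptide(10), substr(q, 11, 50))
  tb <- MetaCAZ:::.swTraceback(MetaCAZ:::encodeAA(q, lut),
                               MetaCAZ:::encodeAA(s, lut), scoring$matrix,
                               scoring$gapOpen, scoring$gapExtend, stopCode)
  expect_equal(tb$score, score1(q, s))
  expect_true(tb$qstart < tb$qend && tb$sstart < tb$send)
  expect_equal(tb$matches + tb$mismatches +
                 (tb$alnLen - (tb$qend - tb$qstart)) +
                 (tb$alnLen - (tb$send - tb$sstart)), tb$alnLen)
})

test_that("alignTile finds planted homology and controls false positives", {
  res <- buildFamilyDB(c("GH13", "GH5", "LO2"), perFamily = 2,
                       aaLenRange = c(60, 80), seed = 31)
  db <- res$db
  scoring <- scoringParams()

  # a tile containing an exact 60-aa planted segment hits its family
  member <- as.character(proteinSeqs(db)[["GH13_m1"]])
  set.seed(5)
  coding <- MetaCAZ:::reverseTranslate(substr(member, 1, 60))
  tile <- paste0(randomDNA(60), coding, randomDNA(60))
  hits <- alignTile(tile, db, scoring, queryId = "t:0-300")
  expect_true(nrow(hits) >= 1L)
  expect_equal(hits$family[1L], "GH13")
  expect_lt(hits$evalue[1L], 1e-10)
  best <- hits[hits$subjectId == "GH13_m1", ]
  expect_gte(best$qend - best$qstart, 170L)
  expect_true(best$qstart >= 55 && best$qend <= 245)

  # strand symmetry: the reverse-complement tile yields the same families
  # and e-values with mirrored coordinates
  rcTile <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tile)))
  rcHits <- alignTile(rcTile, db, scoring, queryId = "t:0-300")
  expect_equal(rcHits$family, hits$family)
  expect_equal(rcHits$evalue, hits$evalue, tolerance = 1e-12)
  expect_equal(sort(nchar(tile) - rcHits$qend), sort(hits$qstart))

  # pure background tiles produce no hits at the 1e-10 cutoff
  set.seed(77)
  false <- 0L
  for (i in 1:150) {
    h <- alignTile(randomDNA(300), db, scoring)
    false <- false + (nrow(h) > 0L)
  }
  expect_lt(false / 150, 0.01)

  # an infinite cutoff returns a superset of the 1e-10 results
  loose <- alignTile(tile, db, scoringParams(evalueCutoff = Inf))
  strictKeys <- paste(hits$subjectId, hits$qstart, hits$qend)
  looseKeys <- paste(loose$subjectId, loose$qstart, loose$qend)
  expect_true(all(strictKeys %in% looseKeys))

  expect_error(alignTile("ACGT", db), "30 nt")
})

test_that("searchContigs is the ordered concatenation of per-tile searches", {
  res <- buildFamilyDB(c("GH13", "GH5"), perFamily = 2, seed = 41)
  db <- res$db
  set.seed(8)
  member <- as.character(proteinSeqs(db)[[1L]])
  coding <- MetaCAZ:::reverseTranslate(member)
  contig <- paste0(randomDNA(400), coding, randomDNA(500 - nchar(coding)))
  cs <- ContigSet(c(c900 = substr(contig, 1, 900)))
  hits <- searchContigs(cs, db)
  tiles <- parsed <- MetaCAZ:::parseTileId(unique(hits$queryId))
  expect_true(all(parsed$tileStart %in% seq(0, 750, by = 150)))

  # a 900 nt contig has exactly 5 tiles
  expect_equal(nrow(tileContig(900L)), 5L)

  # per-tile equivalence
  for (qid in unique(hits$queryId)) {
    p <- MetaCAZ:::parseTileId(qid)
    tileSeq <- substr(contig, p$tileStart + 1L, p$tileEnd)
    solo <- alignTile(tileSeq, db, queryId = qid)
    expect_equal(hits[hits$queryId == qid, , drop = FALSE][, -1L],
                 solo[, -1L], ignore_attr = TRUE)
  }

  # round trip through the tabular format
  f <- withr::local_tempfile(fileext = ".tsv")
  writeHitTable(hits, f)
  back <- readHitTable(f)
  expect_equal(back$queryId, hits$queryId)
  expect_equal(back$family, hits$family)
  expect_equal(back$qstart, hits$qstart)
  expect_equal(back$qend, hits$qend)

  # appending residues to a db sequence never lowers its best score
  scoring <- scoringParams(evalueCutoff = Inf)
  lut <- MetaCAZ:::aaEncoder(scoring$matrix)
  stopCode <- match("*", rownames(scoring$matrix)) - 1L
  set.seed(3)
  q <- randomPeptide(50)
  s <- randomPeptide(30)
  sc <- function(subj)
    MetaCAZ:::.swScanFrames(list(MetaCAZ:::encodeAA(q, lut)),
                            list(MetaCAZ:::encodeAA(subj, lut)),
                            scoring$matrix, scoring$gapOpen,
                            scoring$gapExtend, stopCode)[1L, 1L]
  prev <- sc(s)
  for (i in 1:10) {
    s <- paste0(s, randomPeptide(5))
    cur <- sc(s)
    expect_gte(cur, prev)
    prev <- cur
  }
})
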