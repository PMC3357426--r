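test_that("tiling follows the 300/150 rule with the tail convention", {
  t900 <- tileContig(900L)
  expect_equal(t900$start, c(0L, 150L, 300L, 450L, 600L))
  expect_equal(t900$end, c(300L, 450L, 600L, 750L, 900L))

  t1000 <- tileContig(1000L)
  expect_equal(nrow(t1000), 6L)
  expect_equal(t1000$start[6L], 750L)
  expect_equal(t1000$end[6L], 1000L)

  # a contig shorter than the tail threshold yields one covering tile
  expect_equal(tileContig(80L), data.frame(start = 0L, end = 80L))

  # a sub-minTail final partial tile is suppressed
  p <- tilingParams(tileLen = 300L, step = 300L, minTail = 150L)
  t700 <- tileContig(700L, p)
  expect_equal(t700$end, c(300L, 600L))   # [600,700) is 100 nt < 150

  # coverage property: contigs >= 300 nt are covered by 1-2 tiles everywhere
  set.seed(13)
  for (len in sample(300:5000, 25)) {
    t <- tileContig(len)
    cover <- integer(len)
    for (k in seq_len(nrow(t)))
      cover[(t$start[k] + 1L):t$end[k]] <- cover[(t$start[k] + 1L):t$end[k]] + 1L
    expect_true(all(cover >= 1L & cover <= 2L), info = len)
  }

  expect_error(tilingParams(step = 400L), "exceed")
})

test_that("best hit per tile applies the documented tie-breaks", {
  mkhit <- function(fam, ev, bits, subj = "p1", qs = 10L, qe = 100L)
    data.frame(queryId = "c1:150-450", subjectId = subj, family = fam,
               pident = 90, alnLen = 30L, mismatches = 0L, gapOpens = 0L,
               qstart = qs, qend = qe, sstart = 0L, send = 30L,
               evalue = ev, bitscore = bits, stringsAsFactors = FALSE)

  b <- bestHitPerTile(rbind(mkhit("GH13", 1e-30, 100),
                            mkhit("GH3", 1e-12, 100)))
  expect_equal(b$family, "GH13")
  # span is lifted to contig coordinates
  expect_equal(b$start, 150L + 10L)
  expect_equal(b$end, 150L + 100L)

  b <- bestHitPerTile(rbind(mkhit("GH3", 1e-20, 90),
                            mkhit("GH13", 1e-20, 80)))
  expect_equal(b$family, "GH3")   # higher bitscore wins the e-value tie

  b <- bestHitPerTile(rbind(mkhit("GT2", 1e-20, 90),
                            mkhit("GH13", 1e-20, 90)))
  expect_equal(b$family, "GH13")  # full tie: lexicographic family

  b <- bestHitPerTile(rbind(mkhit("GH13", 1e-20, 90, subj = "p9"),
                            mkhit("GH13", 1e-20, 90, subj = "p2")))
  expect_equal(b$start, 160L)     # subject tie: smallest subjectId kept
  expect_equal(nrow(b), 1L)

  b <- bestHitPerTile(mkhit("GH13", 1e-20, 90), spanMode = "tile")
  expect_equal(c(b$start, b$end), c(150L, 450L))
})

test_that("run collection unions overlapping spans per family", {
  asg <- data.frame(
    queryId = c("c1:0-300", "c1:150-450"), contigId = "c1",
    family = "GH13", evalue = 1e-20, bitscore = 90,
    start = c(10L, 160L), end = c(290L, 440L), stringsAsFactors = FALSE)
  runs <- collectRuns(asg, c(c1 = 600L))
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start, 10L)
  expect_equal(runs$end, 440L)
  expect_equal(runs$coveredNt, 430L)

  # adjacent tiles with different families give one run each
  asg$family <- c("GH13", "GH3")
  runs <- collectRuns(asg, c(c1 = 600L))
  expect_equal(sort(runs$family), c("GH13", "GH3"))
  expect_equal(nrow(runs), 2L)

  expect_error(collectRuns(data.frame(
    queryId = "c1:0-300", contigId = "c1", family = "GH1", evalue = 1e-20,
    bitscore = 9, start = 100L, end = 700L), c(c1 = 600L)), "outside")

  # randomized spans: coveredNt equals a per-nucleotide marking oracle
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(5:40, 1L)
    fams <- sample(c("GH1", "GH2", "LO1"), n, replace = TRUE)
    starts <- sample(0:900, n, replace = TRUE)
    ends <- pmin(1000L, starts + sample(20:300, n, replace = TRUE))
    asg <- data.frame(queryId = sprintf("c1:%d-%d", 0, 1000),
                      contigId = "c1", family = fams, evalue = 1e-20,
                      bitscore = 50, start = starts, end = ends,
                      stringsAsFactors = FALSE)
    runs <- collectRuns(asg, c(c1 = 1000L))
    for (f in unique(fams)) {
      mask <- logical(1000L)
      for (k in which(fams == f)) mask[(starts[k] + 1L):ends[k]] <- TRUE
      expect_equal(sum(runs$coveredNt[runs$family == f]), sum(mask),
                   info = paste(rep, f))
    }
  }
})

test_that("family totals weight by depth and default missing depths to 1", {
  runs <- data.frame(contigId = c("c1", "c2"), family = "GH5",
                     start = 0L, end = c(300L, 100L),
                     coveredNt = c(300L, 100L), stringsAsFactors = FALSE)
  expect_equal(familyTotals(runs, c(c1 = 2, c2 = 1)), c(GH5 = 700))
  # absent depth table: totals are unweighted sums
  expect_equal(familyTotals(runs, numeric(0)), c(GH5 = 400))
  expect_length(familyTotals(runs[0, , drop = FALSE]), 0L)
})

test_that("per-million normalization uses depth-weighted total bases", {
  cs <- ContigSet(c(c1 = randomDNA(1000)), depth = c(c1 = 2))
  prof <- normalizePerMillion(c(GH5 = 600), cs)
  expect_equal(unname(perMillion(prof)["GH5"]), 300000)
  expect_equal(totalWeightedBases(prof), 2000)

  # duplicating every contig leaves per-million unchanged
  cs2 <- ContigSet(c(c1 = as.character(contigSeqs(cs)[[1L]]),
                     c1b = as.character(contigSeqs(cs)[[1L]])),
                   depth = c(c1 = 2, c1b = 2))
  prof2 <- normalizePerMillion(c(GH5 = 1200), cs2)
  expect_equal(perMillion(prof2), perMillion(prof))

  expect_error(normalizePerMillion(c(GH5 = 1), ContigSet(character(0))),
               "no contigs")
})

test_that("per-bin profiles use per-bin denominators and partition totals", {
  set.seed(31)
  seqs <- c(a1 = randomDNA(1500), a2 = randomDNA(2500), b1 = randomDNA(3000),
            short = randomDNA(600), stray = randomDNA(1200))
  cs <- ContigSet(seqs, depth = c(a1 = 2, a2 = 1, b1 = 3, short = 5,
                                  stray = 1))
  runs <- data.frame(
    contigId = c("a1", "a2", "b1", "short", "stray"),
    family = c("GH1", "GH1", "GH2", "GH2", "GH3"),
    start = 0L, end = 100L, coveredNt = 100L, stringsAsFactors = FALSE)
  assignment <- c(a1 = "binA", a2 = "binA", b1 = "binB", short = "binB")

  prof <- binProfiles(runs, cs, assignment, minContigLen = 1000L)
  expect_setequal(names(prof), c("binA", "binB", "no match"))
  # short contig is excluded entirely even though assigned
  expect_equal(totalWeightedBases(prof$binB), 9000)
  expect_equal(unname(weightedNt(prof$binB)["GH2"]), 300)
  expect_equal(unname(perMillion(prof$binA)["GH1"]),
               1e6 * (200 + 100) / (1500 * 2 + 2500))
  expect_equal(unname(weightedNt(prof$`no match`)["GH3"]), 100)

  # partition additivity: per-family weighted nt sums over bins match the
  # metagenome total restricted to kept contigs
  keptRuns <- runs[runs$contigId != "short", , drop = FALSE]
  total <- familyTotals(keptRuns, contigDepth(cs))
  fromBins <- Reduce(`+`, lapply(prof, function(p) {
    v <- setNames(numeric(length(total)), names(total))
    w <- weightedNt(p)
    v[names(w)] <- w
    v
  }))
  expect_equal(fromBins, total)

  # single-bin case reduces to the whole-metagenome profile on kept contigs
  oneBin <- binProfiles(keptRuns, cs,
                        setNames(rep("all", 5),
                                 c("a1", "a2", "b1", "short", "stray")))
  kept <- cs[c(1:3, 5)]
  whole <- normalizePerMillion(familyTotals(keptRuns, contigDepth(kept)),
                               kept, label = "all")
  expect_equal(perMillion(oneBin$all), perMillion(whole))
})

test_that("family ranking orders, tie-breaks and reports shares", {
  r <- rankFamilies(c(a = 5, b = 3, c = 3), topN = 2)
  expect_equal(r$family, c("a", "b"))
  expect_equal(sum(r$share), 8 / 11)

  r <- rankFamilies(c(a = 5, b = 3, c = 3), topN = 10)
  expect_equal(sum(r$share), 1)
  expect_equal(r$family, c("a", "b", "c"))

  expect_error(rankFamilies(c(a = 1), topN = 0), "topN")
  expect_error(rankFamilies(numeric(0)), "empty")
})

test_that("adding a hit-free contig dilutes every per-million value", {
  cs <- ContigSet(c(c1 = randomDNA(2000)), depth = c(c1 = 2))
  totals <- c(GH1 = 500, GH2 = 120)
  p1 <- normalizePerMillion(totals, cs)
  p2 <- normalizePerMillion(totals, c(cs, ContigSet(c(c2 = randomDNA(1000)))))
  expect_true(all(perMillion(p2) < perMillion(p1)))
})
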