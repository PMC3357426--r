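test_that("family database generation is deterministic and family-structured", {
  res <- buildFamilyDB("GH13", perFamily = 1, aaLenRange = c(100, 100),
                       seed = 7)
  expect_equal(length(res$db), 1L)
  expect_equal(unname(familyLabels(res$db)), "GH13")
  expect_equal(Biostrings::width(proteinSeqs(res$db)), 100L)

  res2 <- buildFamilyDB("GH13", perFamily = 1, aaLenRange = c(100, 100),
                        seed = 7)
  expect_identical(as.character(proteinSeqs(res$db)),
                   as.character(proteinSeqs(res2$db)))

  expect_error(buildFamilyDB("GH1", aaLenRange = c(20, 50)), ">= 30")

  # intra-family identity dominates inter-family identity (alignment-free
  # position-identity oracle on equal-length members)
  many <- buildFamilyDB(paste0("F", 1:8), perFamily = 3,
                        aaLenRange = c(80, 80), seed = 3)
  aa <- as.character(proteinSeqs(many$db))
  fam <- unname(familyLabels(many$db))
  pid <- function(a, b) mean(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])
  intra <- c(); inter <- c()
  for (i in seq_along(aa)) for (j in seq_len(i - 1L)) {
    p <- pid(aa[[i]], aa[[j]])
    if (fam[i] == fam[j]) intra <- c(intra, p) else inter <- c(inter, p)
  }
  # members are mutated at 10-20% of consensus positions, so within-family
  # identity stays above ~60%; unrelated families sit near random (~5%)
  expect_gt(min(intra), 0.5)
  expect_gt(stats::median(intra), 0.65)
  expect_lt(stats::median(inter), 0.4)
})

test_that("population genomes honor G+C targets and carry planted truth", {
  db <- buildFamilyDB(c("GH13", "LO2"), perFamily = 2, seed = 1)$db
  spec <- populationSpec("hi", gc = 0.65, genomeLen = 100000L, seed = 5)
  sim <- simulatePopulationGenome(spec, list(c("GH13", 3)), db, seed = 9)
  expect_equal(nchar(sim$seq), 100000L)
  expect_equal(nrow(sim$genes), 3L)
  expect_true(all(sim$genes$family == "GH13"))
  expect_true(all(sim$genes$start >= 0 & sim$genes$end <= 100000))
  # planted spans are pairwise disjoint
  g <- sim$genes[order(sim$genes$start), ]
  if (nrow(g) > 1L) expect_true(all(g$start[-1L] >= g$end[-nrow(g)]))

  gc <- sum(strsplit(sim$seq, "")[[1L]] %in% c("G", "C")) / nchar(sim$seq)
  expect_gt(gc, 0.62); expect_lt(gc, 0.68)

  # a planted gene on the + strand is the exact reverse-translation of a
  # family member: translating it back recovers the member's peptide
  plus <- sim$genes[sim$genes$strand == "+", ][1L, ]
  nt <- substr(sim$seq, plus$start + 1L, plus$end)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  expect_equal(aa, as.character(proteinSeqs(db)[[plus$proteinId]]))

  expect_error(
    simulatePopulationGenome(spec, list(c("XX1", 1)), db, seed = 1),
    "not in database")
  tiny <- populationSpec("t", gc = 0.5, genomeLen = 300L, seed = 1)
  expect_error(
    simulatePopulationGenome(tiny, list(c("GH13", 5)), db, seed = 1),
    "longer genome")
})

test_that("composition models separate populations beyond G+C", {
  specA <- populationSpec("a", 0.45, 50000L, seed = 1)
  specB <- populationSpec("b", 0.65, 50000L, seed = 2)
  vec <- function(spec)
    trinucVector(MetaCAZ:::.sampleMarkovSeq(20000L, spec$trans, spec$init))
  vsA <- lapply(1:5, function(i) withr::with_seed(100 + i, vec(specA)))
  vsB <- lapply(1:5, function(i) withr::with_seed(200 + i, vec(specB)))
  l1 <- function(x, y) sum(abs(x - y))
  within <- c(mapply(l1, vsA[-1], vsA[-5]), mapply(l1, vsB[-1], vsB[-5]))
  between <- as.vector(outer(seq_len(5), seq_len(5), Vectorize(
    function(i, j) l1(vsA[[i]], vsB[[j]]))))
  expect_gt(mean(between), mean(within))
})

test_that("shredding covers the genome and lifts truth exactly", {
  db <- buildFamilyDB("GH5", perFamily = 1, seed = 2)$db
  spec <- populationSpec("p", 0.5, 10000L, seed = 3)
  sim <- simulatePopulationGenome(spec, list(c("GH5", 4)), db, seed = 4)

  # fixed 2 kb contigs partition a 10 kb genome exactly
  sh <- shredToContigs(sim$seq, sim$genes,
                       lenDist = list(meanlog = log(2000), sdlog = 0,
                                      minLen = 500L), seed = 6)
  expect_equal(length(sh$contigs), 5L)
  expect_equal(sum(Biostrings::width(contigSeqs(sh$contigs))), 10000L)
  expect_equal(paste(as.character(contigSeqs(sh$contigs)), collapse = ""),
               sim$seq)
  expect_true(all(contigDepth(sh$contigs) >= 1))

  # truth spans mapped back to genome coordinates reconstruct the planted
  # spans (clipped parts reassemble)
  off <- sh$offsets
  lifted <- sh$genes
  backStart <- off$start[match(lifted$contigId, off$contigId)] + lifted$start
  backEnd <- off$start[match(lifted$contigId, off$contigId)] + lifted$end
  expect_equal(backStart, lifted$genomeStart)
  expect_equal(backEnd, lifted$genomeEnd)
  recovered <- sum(backEnd - backStart)
  expect_equal(recovered, sum(sim$genes$end - sim$genes$start))
  # contig-local spans stay inside their contigs
  w <- setNames(Biostrings::width(contigSeqs(sh$contigs)),
                contigIds(sh$contigs))
  expect_true(all(lifted$end <= w[lifted$contigId]))
})

test_that("panels honor group templates including exact lignin-family zeros", {
  db <- buildFamilyDB(c("GH13", "GH5", "GH2", "GH43", "GH9", "LO1", "LO2",
                        "LO3"), perFamily = 2, seed = 11)$db
  pops <- list(populationSpec("pA", 0.45, 150000L, seed = 1),
               populationSpec("pB", 0.60, 150000L, seed = 2))
  groups <- list(
    list(label = "free",
         template = c(GH13 = 3000, GH5 = 6000, GH2 = 2300, GH43 = 1600,
                      GH9 = 4500, LO1 = 2000, LO2 = 1200, LO3 = 2600),
         nMembers = 3L),
    list(label = "gut",
         template = c(GH13 = 6000, GH5 = 1200, GH2 = 4500, GH43 = 3000,
                      GH9 = 1600, LO1 = 0, LO2 = 0, LO3 = 0),
         nMembers = 3L))
  panel <- simulatePanel(groups, db, pops, seed = 21)
  expect_length(panel, 6L)

  for (mg in panel) {
    expect_true(all(mg$genes$family %in% unname(familyLabels(db))))
    if (mg$group == "gut")
      expect_false(any(grepl("^LO", mg$genes$family)))
    # realized planted nucleotide totals correlate with the template
    planted <- tapply(mg$genes$end - mg$genes$start, mg$genes$family, sum)
    tmpl <- mg$template[mg$template > 0]
    realized <- as.numeric(planted[names(tmpl)])
    realized[is.na(realized)] <- 0
    expect_gt(oracleSpearman(realized, as.numeric(tmpl)), 0.8)
  }

  badGroups <- list(list(label = "x", template = c(ZZ9 = 10), nMembers = 2L),
                    groups[[2L]])
  expect_error(simulatePanel(badGroups, db, pops, seed = 1),
               "not in database")
})

test_that("simulation is byte-identical under a fixed seed", {
  db <- buildFamilyDB(c("GH13", "GH5"), perFamily = 2, seed = 3)$db
  spec <- populationSpec("p", 0.55, 40000L, seed = 8)
  one <- function() {
    sim <- simulatePopulationGenome(spec, list(c("GH13", 2)), db, seed = 13)
    sh <- shredToContigs(sim$seq, sim$genes, seed = 14)
    f <- tempfile(fileext = ".fa")
    writeContigs(sh$contigs, f)
    on.exit(unlink(f))
    list(digest = unname(tools::md5sum(f)), genes = sh$genes)
  }
  a <- one(); b <- one()
  expect_identical(a$digest, b$digest)
  expect_identical(a$genes, b$genes)
})
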