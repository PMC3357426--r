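# Independent oracles and fixture builders shared across the test suite.
# These deliberately avoid the package's own code paths: the Smith-Waterman
# oracle is a plain-R dynamic program, the Spearman oracle ranks by hand and
# applies the Pearson formula, and the profiling oracle marks contig
# nucleotides one by one.

suppressPackageStartupMessages(library(Biostrings))

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# plain-R affine-gap Smith-Waterman best local score.  Stop codons in the
# query act as barriers: their rows carry H = 0 and unreachable gap states.
naiveSWScore <- function(query, subject, submat = blosum62,
                         gapOpen = -11, gapExtend = -1) {
  q <- strsplit(query, "")[[1L]]
  s <- strsplit(subject, "")[[1L]]
  n <- length(q); m <- length(s)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in query (horizontal)
  F <- matrix(NEG, n + 1, m + 1)   # gap in subject (vertical)
  best <- 0
  for (i in seq_len(n)) {
    if (q[i] == "*") next          # barrier row stays H=0, E=F=-inf
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(E[i + 1, j], H[i + 1, j] + gapOpen) + gapExtend
      F[i + 1, j + 1] <- max(F[i, j + 1], H[i, j + 1] + gapOpen) + gapExtend
      h <- max(0,
               H[i, j] + submat[q[i], s[j]],
               E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      if (h > best) best <- h
    }
  }
  best
}

# rank-by-sorting then explicit Pearson formula (average ranks for ties)
oracleSpearman <- function(x, y) {
  rk <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1L]] == v[o[i]]) j <- j + 1L
      r[o[i:j]] <- mean(i:j)
      i <- j + 1L
    }
    r
  }
  rx <- rk(x); ry <- rk(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force per-nucleotide profiling oracle: choose the best hit of each
# tile (minimum e-value, then maximum bitscore, then family, then subject),
# mark the aligned contig nucleotides in a per-family logical mask, and
# total marked nucleotides times depth over the depth-weighted base sum
oraclePerMillion <- function(hits, lens, depths) {
  marks <- list()   # [[family]][[contig]] logical vector
  for (qid in unique(hits$queryId)) {
    h <- hits[hits$queryId == qid, , drop = FALSE]
    h <- h[order(h$evalue, -h$bitscore, h$family, h$subjectId,
                 method = "radix"), , drop = FALSE]
    b <- h[1L, ]
    pos <- regmatches(qid, regexec("^(.*):([0-9]+)-([0-9]+)$", qid))[[1L]]
    contig <- pos[2L]; tileStart <- as.integer(pos[3L])
    from <- tileStart + b$qstart + 1L
    to <- tileStart + b$qend
    if (is.null(marks[[b$family]])) marks[[b$family]] <- list()
    if (is.null(marks[[b$family]][[contig]]))
      marks[[b$family]][[contig]] <- logical(lens[[contig]])
    marks[[b$family]][[contig]][from:to] <- TRUE
  }
  twb <- sum(as.numeric(lens) * depths[names(lens)])
  out <- vapply(marks, function(percontig)
    sum(vapply(names(percontig),
               function(cid) sum(percontig[[cid]]) * depths[[cid]],
               numeric(1))), numeric(1))
  1e6 * out / twb
}

# random hit table over the tiles of a contig set (no search involved)
randomHitTable <- function(lens, families, seed) {
  set.seed(seed)
  rows <- list()
  for (cid in names(lens)) {
    tiles <- tileContig(lens[[cid]])
    for (t in seq_len(nrow(tiles))) {
      if (runif(1) < 0.4) next   # tiles without hits
      tlen <- tiles$end[t] - tiles$start[t]
      nh <- sample(1:3, 1L)
      for (k in seq_len(nh)) {
        span <- sort(sample.int(tlen, 2L))
        if (span[2L] == span[1L]) span[2L] <- span[1L] + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          queryId = sprintf("%s:%d-%d", cid, tiles$start[t], tiles$end[t]),
          subjectId = sprintf("p%d", sample.int(50, 1L)),
          family = sample(families, 1L),
          pident = 90, alnLen = 30L, mismatches = 3L, gapOpens = 0L,
          qstart = span[1L] - 1L, qend = span[2L],
          sstart = 0L, send = 30L,
          evalue = 10^(-runif(1, 11, 40)), bitscore = runif(1, 50, 200),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# deterministic random DNA / peptide helpers
randomDNA <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
randomPeptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
               replace = TRUE), collapse = "")
}

# concatenate the per-population shreds of a multi-population metagenome
simulateMetagenome <- function(popSpecs, geneSpecs, db, seed) {
  contigs <- NULL; genes <- list(); pops <- character(0)
  for (i in seq_along(popSpecs)) {
    ps <- popSpecs[[i]]
    sim <- simulatePopulationGenome(ps, geneSpecs[[i]], db,
                                    seed = childSeed(seed, ps$label))
    sh <- shredToContigs(sim$seq, sim$genes,
                         seed = childSeed(seed, paste0("shred", ps$label)),
                         idPrefix = paste0(ps$label, "_c"))
    pops <- c(pops, setNames(rep(ps$label, length(sh$contigs)),
                             contigIds(sh$contigs)))
    genes[[i]] <- sh$genes
    contigs <- if (is.null(contigs)) sh$contigs else c(contigs, sh$contigs)
  }
  list(contigs = contigs, genes = do.call(rbind, genes), populations = pops)
}
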