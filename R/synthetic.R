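#' @importFrom stats rlnorm rgamma runif setNames quantile
NULL

# reproducible local RNG: runs code under set.seed(seed) and restores the
# caller's RNG state afterwards
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Derive a per-stage child seed from a global seed
#'
#' A single run seed is fanned out to independent stage seeds by hashing the
#' stage name, so each pipeline stage is reproducible in isolation.
#'
#' @param seed integer global seed.
#' @param stage stage name.
#' @return integer in [1, 2^31 - 2].
#' @export
childSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483646 + 1)
}

#' Population composition spec
#'
#' Defines one source population for the simulator: a nucleotide transition
#' model conditioned on the preceding trinucleotide (64 contexts x 4 bases)
#' whose rows all carry exactly the target G+C mass, plus a genome length.
#' The within-A/T and within-G/C splits vary randomly per context and per
#' population, giving populations genuinely distinct 3-mer structure even at
#' equal G+C -- the signal the composition binner exploits.
#'
#' @param label bin/population label.
#' @param gc target G+C fraction in [0.25, 0.75].
#' @param genomeLen genome length in nt.
#' @param seed integer seed for the per-context splits.
#' @param splitRange range of the within-pair probability splits.
#' @return a list of class `PopulationSpec` with elements `label`, `gc`,
#'   `genomeLen`, `trans` (64 x 4 row-stochastic), `init` (length 4).
#' @export
populationSpec <- function(label, gc, genomeLen, seed,
                           splitRange = c(0.2, 0.8)) {
  if (gc < 0.25 || gc > 0.75) mcStop("gc must lie in [0.25, 0.75]")
  if (genomeLen < 1) mcStop("genomeLen must be positive")
  trans <- withSeed(seed, {
    gSplit <- runif(64L, splitRange[1L], splitRange[2L])
    aSplit <- runif(64L, splitRange[1L], splitRange[2L])
    # base order A, C, G, T
    cbind((1 - gc) * aSplit, gc * gSplit, gc * (1 - gSplit),
          (1 - gc) * (1 - aSplit))
  })
  colnames(trans) <- c("A", "C", "G", "T")
  stopifnot(all(abs(rowSums(trans) - 1) < 1e-9))
  structure(list(label = label, gc = gc, genomeLen = as.integer(genomeLen),
                 trans = trans, init = c((1 - gc) / 2, gc / 2, gc / 2,
                                         (1 - gc) / 2)),
            class = "PopulationSpec")
}

#' Build a synthetic family-labeled protein database
#'
#' Stand-in for a real carbohydrate-active enzyme database: for each family
#' a random consensus peptide is drawn, and `perFamily` members are emitted,
#' each mutated at 10-20% of positions.  Members of different families are
#' unrelated random peptides, so their expected pairwise identity is far
#' below within-family identity.
#'
#' @param families character vector of family labels.
#' @param perFamily members per family (>= 1).
#' @param aaLenRange integer range of consensus lengths; minimum >= 30.
#' @param seed integer seed; identical inputs give identical databases.
#' @return list with elements `db` (a [FamilyDB-class]) and `consensus`
#'   (named character vector of per-family consensus peptides).
#' @export
buildFamilyDB <- function(families, perFamily = 2L,
                          aaLenRange = c(60L, 120L), seed = 1L) {
  if (length(families) == 0L) mcStop("families must be nonempty")
  if (perFamily < 1L) mcStop("perFamily must be >= 1")
  if (min(aaLenRange) < 30L)
    mcStop("aaLenRange minimum must be >= 30 (too short to align reliably)")
  AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  withSeed(seed, {
    seqs <- character(0); fams <- character(0); cons <- character(0)
    lenChoices <- seq.int(aaLenRange[1L], aaLenRange[2L])
    for (fam in families) {
      len <- lenChoices[sample.int(length(lenChoices), 1L)]
      consensus <- sample(AA20, len, replace = TRUE)
      cons[fam] <- paste(consensus, collapse = "")
      for (m in seq_len(perFamily)) {
        rate <- runif(1L, 0.10, 0.20)
        member <- consensus
        hit <- which(runif(len) < rate)
        for (p in hit)
          member[p] <- sample(setdiff(AA20, member[p]), 1L)
        id <- sprintf("%s_m%d", gsub("/", "-", fam, fixed = TRUE), m)
        seqs[id] <- paste(member, collapse = "")
        fams <- c(fams, fam)
      }
    }
    list(db = FamilyDB(seqs, fams), consensus = cons)
  })
}

# uniform-codon reverse translation of a peptide (no stop appended)
CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

reverseTranslate <- function(peptide) {
  aa <- strsplit(peptide, "")[[1L]]
  codons <- vapply(aa, function(a) {
    opts <- CODONS_BY_AA[[a]]
    if (is.null(opts)) mcStop("cannot reverse-translate residue '%s'", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

revcompChr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Simulate a population genome with planted family genes
#'
#' The background is drawn from the population's context-dependent
#' transition model at its target G+C.  Each planted gene is a
#' reverse-translated (uniform codon choice) family member from the
#' database, inserted on a random strand at a random position; planted
#' spans never overlap.
#'
#' @param spec a [populationSpec()].
#' @param genes list/data.frame of (family, count) pairs, e.g.
#'   `list(c("GH13", 3))` or `data.frame(family=, count=)`.
#' @param db a [FamilyDB-class].
#' @param seed integer seed.
#' @param maxTries placement retries per gene before giving up.
#' @return list with `seq` (character genome) and `genes` (data.frame with
#'   `start`, `end` 0-based half-open, `family`, `strand`, `proteinId`).
#' @export
simulatePopulationGenome <- function(spec, genes, db, seed,
                                     maxTries = 200L) {
  if (is.data.frame(genes)) {
    fams <- rep(genes$family, genes$count)
  } else {
    fams <- unlist(lapply(genes, function(g) rep(g[[1L]],
                                                 as.integer(g[[2L]]))))
  }
  dbFam <- familyLabels(db)
  unknown <- setdiff(unique(fams), dbFam)
  if (length(unknown))
    mcStop("family '%s' not in database", unknown[1L])
  aa <- as.character(proteinSeqs(db))
  withSeed(seed, {
    segs <- character(length(fams)); pids <- character(length(fams))
    for (i in seq_along(fams)) {
      members <- names(dbFam)[dbFam == fams[i]]
      pids[i] <- members[sample.int(length(members), 1L)]
      segs[i] <- reverseTranslate(aa[[pids[i]]])
    }
    if (sum(nchar(segs)) > 0.5 * spec$genomeLen)
      mcStop("planted coding length exceeds half the genome; use a longer genome")
    background <- .sampleMarkovSeq(spec$genomeLen, spec$trans, spec$init)
    placed <- matrix(integer(0), ncol = 2L)   # occupied [start, end)
    starts <- integer(length(fams)); strands <- character(length(fams))
    ord <- order(-nchar(segs))                # place long genes first
    for (i in ord) {
      w <- nchar(segs[i]); ok <- FALSE
      for (t in seq_len(maxTries)) {
        s <- sample.int(spec$genomeLen - w + 1L, 1L) - 1L
        if (!nrow(placed) ||
            all(s + w <= placed[, 1L] | s >= placed[, 2L])) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        mcStop("could not place a %d nt gene after %d tries; use a longer genome",
               w, maxTries)
      placed <- rbind(placed, c(s, s + w))
      starts[i] <- s
      strands[i] <- sample(c("+", "-"), 1L)
    }
    truth <- data.frame(start = starts, end = starts + nchar(segs),
                        family = fams, strand = strands, proteinId = pids,
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$start), , drop = FALSE]
    # rebuild in one pass: background between genes, gene segments inserted
    pieces <- character(0); pos <- 0L
    segOrd <- segs[order(starts)]
    for (i in seq_len(nrow(truth))) {
      pieces <- c(pieces, substr(background, pos + 1L, truth$start[i]))
      g <- segOrd[i]
      if (truth$strand[i] == "-") g <- revcompChr(g)
      pieces <- c(pieces, g)
      pos <- truth$end[i]
    }
    pieces <- c(pieces, substr(background, pos + 1L, spec$genomeLen))
    rownames(truth) <- NULL
    list(seq = paste(pieces, collapse = ""), genes = truth)
  })
}

#' Shred a genome into contigs with depths
#'
#' Emulates assembly output: consecutive non-overlapping windows of the
#' genome become contigs with lognormal lengths, and each contig receives a
#' gamma-distributed mean depth floored at 1.  Planted-gene coordinates are
#' lifted onto the contigs; genes split by a contig boundary are clipped and
#' both parts are retained in the truth table with their clipped spans.
#'
#' @param genomeSeq character genome sequence.
#' @param truth planted-gene data.frame from [simulatePopulationGenome()]
#'   (may be `NULL`).
#' @param lenDist list(meanlog, sdlog, minLen); `minLen >= 500`.
#' @param depthDist list(shape, scale, min).
#' @param seed integer seed.
#' @param idPrefix contig id prefix.
#' @return list with `contigs` (a [ContigSet-class]), `genes` (lifted truth
#'   with `contigId`, contig-local `start`/`end`, `clipped` flag) and
#'   `offsets` (contig -> genome interval map).
#' @export
shredToContigs <- function(genomeSeq, truth = NULL,
                           lenDist = list(meanlog = log(3000), sdlog = 0.35,
                                          minLen = 500L),
                           depthDist = list(shape = 4, scale = 1.5, min = 1),
                           seed = 1L, idPrefix = "c") {
  glen <- nchar(genomeSeq)
  if (lenDist$minLen < 500L) mcStop("minimum contig length must be >= 500")
  withSeed(seed, {
    bounds <- integer(0); pos <- 0L
    while (pos < glen) {
      w <- max(lenDist$minLen,
               as.integer(round(rlnorm(1L, lenDist$meanlog, lenDist$sdlog))))
      if (pos + w >= glen) w <- glen - pos
      bounds <- c(bounds, w)
      pos <- pos + w
    }
    # a final stub shorter than minLen is merged into the previous contig
    if (length(bounds) > 1L && bounds[length(bounds)] < lenDist$minLen) {
      bounds[length(bounds) - 1L] <- bounds[length(bounds) - 1L] +
        bounds[length(bounds)]
      bounds <- bounds[-length(bounds)]
    }
    ends <- cumsum(bounds)
    starts <- c(0L, ends[-length(ends)])
    ids <- sprintf("%s%04d", idPrefix, seq_along(starts))
    seqs <- substring(genomeSeq, starts + 1L, ends)
    depth <- pmax(depthDist$min,
                  rgamma(length(starts), shape = depthDist$shape,
                         scale = depthDist$scale))
    contigs <- ContigSet(setNames(seqs, ids), depth = depth)
    genes <- NULL
    if (!is.null(truth) && nrow(truth)) {
      rows <- list()
      for (k in seq_len(nrow(truth))) {
        gs <- truth$start[k]; ge <- truth$end[k]
        hit <- which(starts < ge & ends > gs)
        for (ci in hit) {
          s <- max(gs, starts[ci]); e <- min(ge, ends[ci])
          rows[[length(rows) + 1L]] <- data.frame(
            contigId = ids[ci], start = s - starts[ci], end = e - starts[ci],
            family = truth$family[k], strand = truth$strand[k],
            proteinId = truth$proteinId[k],
            clipped = (s > gs || e < ge),
            genomeStart = s, genomeEnd = e, stringsAsFactors = FALSE)
        }
      }
      genes <- do.call(rbind, rows)
    }
    list(contigs = contigs, genes = genes,
         offsets = data.frame(contigId = ids, start = starts, end = ends,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate a panel of metagenomes with group structure
#'
#' Each metagenome is assembled from all population genomes; per-family
#' planted gene counts are drawn so that the expected planted per-million
#' values are proportional to the member's group template, perturbed by a
#' lognormal factor with the given within-group coefficient of variation.
#' Families with template 0 (for example the lignin-oxidase families in
#' gut-like templates) receive exactly zero planted genes.
#'
#' @param groups list of groups, each `list(label =, template = named
#'   per-million numeric, nMembers =)`; `nMembers >= 2`.
#' @param db a [FamilyDB-class].
#' @param popSpecs list of [populationSpec()] objects.
#' @param withinGroupCV nonnegative real.
#' @param seed integer seed.
#' @return list of metagenomes, each `list(label, group, contigs, depths,
#'   genes, populations, template)`.
#' @export
simulatePanel <- function(groups, db, popSpecs, withinGroupCV = 0.25,
                          seed = 1L) {
  dbFams <- unique(unname(familyLabels(db)))
  for (g in groups) {
    if (g$nMembers < 2L) mcStop("each group needs >= 2 members")
    unknown <- setdiff(names(g$template), dbFams)
    if (length(unknown))
      mcStop("template family '%s' not in database", unknown[1L])
    if (any(g$template < 0)) mcStop("templates must be nonnegative")
  }
  fam2nt <- vapply(split(Biostrings::width(proteinSeqs(db)),
                         unname(familyLabels(db))), mean, numeric(1)) * 3
  totalLen <- sum(vapply(popSpecs, function(p) as.numeric(p$genomeLen),
                         numeric(1)))
  sdlog <- sqrt(log(1 + withinGroupCV^2))
  out <- list()
  for (g in groups) {
    for (m in seq_len(g$nMembers)) {
      label <- sprintf("%s_%d", g$label, m)
      mgSeed <- childSeed(seed, paste0("panel/", label))
      tmpl <- g$template
      counts <- withSeed(mgSeed, {
        noise <- rlnorm(length(tmpl), -sdlog^2 / 2, sdlog)
        target <- tmpl * noise * totalLen / 1e6           # nt per family
        cnt <- round(target / fam2nt[names(tmpl)])
        cnt[tmpl == 0 | cnt < 0] <- 0
        cnt
      })
      # distribute each family's genes over populations by genome length
      perPop <- withSeed(childSeed(seed, paste0("alloc/", label)), {
        probs <- vapply(popSpecs, function(p) p$genomeLen, numeric(1))
        probs <- probs / sum(probs)
        alloc <- lapply(seq_along(popSpecs), function(i)
          setNames(integer(length(tmpl)), names(tmpl)))
        for (f in names(tmpl)) {
          if (counts[f] == 0) next
          draw <- sample.int(length(popSpecs), counts[f], replace = TRUE,
                             prob = probs)
          tab <- tabulate(draw, nbins = length(popSpecs))
          for (i in seq_along(popSpecs)) alloc[[i]][f] <- tab[i]
        }
        alloc
      })
      allContigs <- NULL; allGenes <- list(); popOf <- character(0)
      for (i in seq_along(popSpecs)) {
        ps <- popSpecs[[i]]
        geneSpec <- data.frame(family = names(tmpl),
                               count = unname(perPop[[i]]),
                               stringsAsFactors = FALSE)
        geneSpec <- geneSpec[geneSpec$count > 0, , drop = FALSE]
        sim <- simulatePopulationGenome(
          ps, geneSpec, db,
          seed = childSeed(seed, sprintf("genome/%s/%s", label, ps$label)))
        shred <- shredToContigs(
          sim$seq, sim$genes,
          seed = childSeed(seed, sprintf("shred/%s/%s", label, ps$label)),
          idPrefix = sprintf("%s_%s_c", label, ps$label))
        popOf <- c(popOf, setNames(rep(ps$label, length(shred$contigs)),
                                   contigIds(shred$contigs)))
        allGenes[[length(allGenes) + 1L]] <- shred$genes
        allContigs <- if (is.null(allContigs)) shred$contigs
                      else c(allContigs, shred$contigs)
      }
      genes <- do.call(rbind, allGenes)
      out[[label]] <- list(label = label, group = g$label,
                           contigs = allContigs,
                           depths = contigDepth(allContigs),
                           genes = genes, populations = popOf,
                           template = tmpl)
    }
  }
  out
}
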