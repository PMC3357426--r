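#' @importFrom yaml read_yaml write_yaml
NULL

#' Default population specs emulating six separable populations
#'
#' Six populations with the G+C spread observed for the dominant bins of an
#' anaerobic wood-decay community (45.9-64.9% G+C) and per-population 3-mer
#' structure, each contributing an equal genome length.
#'
#' @param genomeLen per-population genome length (nt).
#' @param seed integer seed for the composition models.
#' @return list of [populationSpec()] objects.
#' @export
defaultPopulationSpecs <- function(genomeLen = 140000L, seed = 1L) {
  gcs <- c(binA = 0.459, binB = 0.649, binC = 0.499, binD = 0.506,
           binE = 0.553, binF = 0.541)
  lapply(names(gcs), function(b)
    populationSpec(b, gcs[[b]], genomeLen,
                   seed = childSeed(seed, paste0("pop/", b))))
}

#' Default two-group panel templates
#'
#' A "free-living-like" group whose family-abundance template includes the
#' lignin-oxidase families LO1-LO3, versus a "gut-like" group whose template
#' lacks them entirely, emulating the characteristic contrast between
#' free-living biomass-decay communities and host gut communities.
#' Glycoside hydrolase ranks also differ strongly between the two templates,
#' which is what the Spearman-distance comparison detects.
#'
#' @param nMembers metagenomes per group (>= 2).
#' @return list of group definitions for [simulatePanel()].
#' @export
defaultPanelGroups <- function(nMembers = 3L) {
  free <- c(GH5 = 4800, GH9 = 3900, GH10 = 3300, GH48 = 2700, GH13 = 2100,
            GH43 = 1800, GH67 = 1500, GH2 = 900, GH3 = 720, GH28 = 600,
            GT2 = 540, `GH94/GT84` = 360, LO1 = 1800, LO2 = 1500,
            LO3 = 2280)
  gut <- c(GH2 = 6000, GH3 = 5100, GH13 = 4200, GH43 = 3300, GH28 = 2400,
           GT2 = 2100, `GH94/GT84` = 1200, GH5 = 900, GH10 = 600,
           GH9 = 480, GH48 = 360, GH67 = 240, LO1 = 0, LO2 = 0, LO3 = 0)
  list(list(label = "free", template = free, nMembers = nMembers),
       list(label = "gut", template = gut, nMembers = nMembers))
}

# the full default configuration; every printed constant of the method
# lives here (tile 300/150, e-value 1e-10, bin-profile min length 1000,
# classification min length 2000, default depth 1 at join time)
configDefaults <- function() {
  list(
    seed = 1L,
    paths = list(contigs = NULL, depths = NULL, db = NULL, hits = NULL,
                 bins = NULL),
    simulate = list(nMembers = 3L, genomeLen = 140000L, perFamily = 2L,
                    aaLenMin = 60L, aaLenMax = 120L, withinGroupCV = 0.25),
    tiling = list(tileLen = 300L, step = 150L, minTail = 150L),
    scoring = list(matrix = "BLOSUM62", gapOpen = -11L, gapExtend = -1L,
                   lambda = 0.267, k = 0.041, evalueCutoff = 1e-10),
    binning = list(minLen = 2000L, metric = "l1", threshold = "auto",
                   trainFraction = 0.5),
    profile = list(minBinContigLen = 1000L, runLength = "span"),
    compare = list(filter = "GH", linkage = "average")
  )
}

mergeConfig <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      mcStop("unknown configuration key '%s'", full)
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]]) &&
        !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        mcStop("configuration key '%s' must be a mapping", full)
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]],
                                     c(path, key))
    } else {
      defaults[key] <- list(user[[key]])   # keeps keys with NULL values
    }
  }
  defaults
}

#' Validate a run configuration
#'
#' Reads a YAML configuration (or takes a list), injects documented
#' defaults, rejects unknown keys by name, checks invariants and that all
#' referenced input files exist.
#'
#' @param config path to a YAML file, or a (possibly partial) config list;
#'   `NULL` or an empty list yields the full default configuration.
#' @return a validated `RunConfig` list.
#' @export
validateConfig <- function(config = NULL) {
  user <- if (is.null(config)) list()
          else if (is.character(config)) read_yaml(config)
          else config
  if (is.null(user)) user <- list()
  cfg <- mergeConfig(configDefaults(), user)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) mcStop("seed must be an integer")
  tilingParams(cfg$tiling$tileLen, cfg$tiling$step, cfg$tiling$minTail)
  scoringParams(cfg$scoring$matrix, cfg$scoring$gapOpen,
                cfg$scoring$gapExtend, cfg$scoring$lambda, cfg$scoring$k,
                cfg$scoring$evalueCutoff)
  if (!cfg$profile$runLength %in% c("span", "tile"))
    mcStop("profile.runLength must be 'span' or 'tile'")
  if (!cfg$compare$filter %in% c("GH", "biomass", "all"))
    mcStop("compare.filter must be 'GH', 'biomass' or 'all'")
  if (!cfg$compare$linkage %in% c("average", "complete", "single"))
    mcStop("compare.linkage must be 'average', 'complete' or 'single'")
  for (p in names(cfg$paths)) {
    f <- cfg$paths[[p]]
    if (!is.null(f) && !file.exists(f))
      mcStop("configured file paths.%s does not exist: %s", p, f)
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' Planted-gene recovery against collected runs
#'
#' Fraction of planted coding nucleotides (on contigs of at least
#' `minContigLen` nt) covered by a run of the correct family, and the
#' weighted-nt fraction attributed to families absent from the truth.
#'
#' @param runs output of [collectRuns()].
#' @param genes lifted truth table (from [shredToContigs()]).
#' @param contigs the [ContigSet-class] searched.
#' @param minContigLen contigs shorter than this are ignored (default 300,
#'   the tile length floor).
#' @return list(recovery, spuriousFraction, plantedNt, recoveredNt).
#' @export
plantedRecovery <- function(runs, genes, contigs, minContigLen = 300L) {
  lens <- stats::setNames(Biostrings::width(contigSeqs(contigs)),
                          contigIds(contigs))
  genes <- genes[lens[genes$contigId] >= minContigLen, , drop = FALSE]
  plantedNt <- 0; recoveredNt <- 0
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    plantedNt <- plantedNt + (g$end - g$start)
    r <- runs[runs$contigId == g$contigId & runs$family == g$family, ,
              drop = FALSE]
    if (nrow(r)) {
      ov <- pmax(0L, pmin(r$end, g$end) - pmax(r$start, g$start))
      recoveredNt <- recoveredNt + sum(ov)
    }
  }
  totals <- familyTotals(runs, contigDepth(contigs))
  truthFams <- unique(genes$family)
  spurious <- sum(totals[!names(totals) %in% truthFams])
  list(recovery = if (plantedNt > 0) recoveredNt / plantedNt else NA_real_,
       spuriousFraction = if (sum(totals) > 0) spurious / sum(totals) else 0,
       plantedNt = plantedNt, recoveredNt = recoveredNt)
}

#' Run the full pipeline end to end on a synthetic panel
#'
#' simulate -> search -> profile -> bin -> compare, with a truth-evaluation
#' report.  With the default configuration this simulates a two-group panel
#' (lignin-oxidase-free "gut-like" vs "free-living-like"), profiles every
#' metagenome with the built-in translated tile search, bins the first
#' metagenome's contigs by trinucleotide composition, and compares the
#' metagenomes by Spearman correlation distance (UPGMA tree + classical
#' MDS).  Identical seed and configuration reproduce byte-identical outputs.
#'
#' @param config see [validateConfig()].
#' @param outdir optional output directory; created if needed.  Written
#'   files: resolved config echo, profile matrix, hit tables, bin
#'   assignments, distance matrix, Newick tree, MDS coordinates, scatter
#'   table and the evaluation report.
#' @param verbose log stage progress with record counts.
#' @return invisible list with profiles, matrix, distances, tree, mds,
#'   scatter, binning and report.
#' @export
runEndToEnd <- function(config = NULL, outdir = NULL, verbose = TRUE) {
  cfg <- if (inherits(config, "RunConfig")) config else validateConfig(config)
  logmsg <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  tiling <- tilingParams(cfg$tiling$tileLen, cfg$tiling$step,
                         cfg$tiling$minTail)
  scoring <- scoringParams(cfg$scoring$matrix, cfg$scoring$gapOpen,
                           cfg$scoring$gapExtend, cfg$scoring$lambda,
                           cfg$scoring$k, cfg$scoring$evalueCutoff)

  ## stage 1: simulate
  groups <- defaultPanelGroups(cfg$simulate$nMembers)
  fams <- sort(unique(unlist(lapply(groups, function(g) names(g$template)))))
  dbBuild <- buildFamilyDB(fams, perFamily = cfg$simulate$perFamily,
                           aaLenRange = c(cfg$simulate$aaLenMin,
                                          cfg$simulate$aaLenMax),
                           seed = childSeed(cfg$seed, "db"))
  db <- dbBuild$db
  popSpecs <- defaultPopulationSpecs(cfg$simulate$genomeLen,
                                     seed = childSeed(cfg$seed, "pops"))
  panel <- simulatePanel(groups, db, popSpecs,
                         withinGroupCV = cfg$simulate$withinGroupCV,
                         seed = childSeed(cfg$seed, "panel"))
  logmsg("simulate", "%d metagenomes, %d families, %d populations",
         length(panel), length(fams), length(popSpecs))

  ## stage 2+3: search and profile each metagenome
  profiles <- list(); hitTables <- list(); recov <- list()
  for (mg in panel) {
    hits <- searchContigs(mg$contigs, db, tiling, scoring)
    hitTables[[mg$label]] <- hits
    lens <- stats::setNames(Biostrings::width(contigSeqs(mg$contigs)),
                            contigIds(mg$contigs))
    runs <- collectRuns(bestHitPerTile(hits, cfg$profile$runLength), lens)
    profiles[[mg$label]] <- normalizePerMillion(
      familyTotals(runs, mg$depths), mg$contigs, label = mg$label)
    recov[[mg$label]] <- plantedRecovery(runs, mg$genes, mg$contigs)
    logmsg("search", "%s: %d hits -> %d runs, recovery %.3f",
           mg$label, nrow(hits), nrow(runs), recov[[mg$label]]$recovery)
  }

  ## stage 4: composition binning of the first metagenome
  first <- panel[[1L]]
  binEval <- withSeed(childSeed(cfg$seed, "binsplit"), {
    ids <- contigIds(first$contigs)
    lens <- Biostrings::width(contigSeqs(first$contigs))
    eligible <- which(lens >= 1000L)
    trainIdx <- sort(sample(eligible,
                            round(cfg$binning$trainFraction *
                                  length(eligible))))
    model <- trainBinModel(first$contigs[trainIdx],
                           first$populations[ids[trainIdx]],
                           threshold = cfg$binning$threshold)
    assign <- classifyContigs(first$contigs, model,
                              minLen = cfg$binning$minLen)
    heldOut <- setdiff(seq_along(ids), trainIdx)
    hoAssigned <- assign[ids[heldOut]]
    hoTruth <- first$populations[ids[heldOut]]
    scored <- hoAssigned != "no match" &
      Biostrings::width(contigSeqs(first$contigs))[heldOut] >=
        cfg$binning$minLen
    list(model = model, assignment = assign,
         accuracy = if (any(scored))
           mean(hoAssigned[scored] == hoTruth[scored]) else NA_real_,
         assignedFraction = mean(hoAssigned[
           Biostrings::width(contigSeqs(first$contigs))[heldOut] >=
             cfg$binning$minLen] != "no match"))
  })
  firstLens <- stats::setNames(Biostrings::width(contigSeqs(first$contigs)),
                               contigIds(first$contigs))
  firstRuns <- collectRuns(
    bestHitPerTile(hitTables[[first$label]], cfg$profile$runLength),
    firstLens)
  binProfs <- binProfiles(firstRuns, first$contigs, binEval$assignment,
                          minContigLen = cfg$profile$minBinContigLen)
  logmsg("bin", "accuracy %.3f, assigned fraction %.3f",
         binEval$accuracy, binEval$assignedFraction)

  ## stage 5: compare
  pmatAll <- assembleMatrix(profiles, filter = "all")
  pmatDist <- assembleMatrix(profiles, filter = cfg$compare$filter)
  dmat <- spearmanDistance(pmatDist)
  hc <- clusterProfiles(dmat, linkage = cfg$compare$linkage)
  coords <- mdsEmbedding(dmat, k = 2L)
  groupOf <- vapply(panel, function(m) m$group, character(1))
  split2 <- cutree(hc, k = 2L)[names(groupOf)]
  separated <- length(unique(paste(groupOf, split2))) ==
    length(unique(groupOf)) &&
    all(tapply(split2, groupOf, function(x) length(unique(x))) == 1L)
  gutLabels <- names(groupOf)[groupOf == "gut"]
  freeLabels <- names(groupOf)[groupOf == "free"]
  scatter <- pairwiseScatter(pmatAll, gutLabels[1L], freeLabels[1L],
                             filter = "biomass")
  report <- list(
    seed = cfg$seed,
    metagenomes = names(panel),
    groups = as.list(groupOf),
    plantedRecovery = lapply(recov, function(r) r$recovery),
    spuriousFraction = lapply(recov, function(r) r$spuriousFraction),
    binningAccuracy = binEval$accuracy,
    binningAssignedFraction = binEval$assignedFraction,
    groupSeparation = if (separated) "separated" else "mixed",
    depthTableUsed = TRUE
  )
  logmsg("compare", "group separation: %s", report$groupSeparation)

  result <- list(config = cfg, db = db, panel = panel, profiles = profiles,
                 hits = hitTables, binning = binEval,
                 binProfiles = binProfs, matrix = pmatAll,
                 distances = dmat, tree = hc, mds = coords,
                 scatter = scatter, report = report)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    cfgEcho <- unclass(cfg)
    write_yaml(cfgEcho, file.path(outdir, "config.yaml"))
    writeProfileMatrix(pmatAll, file.path(outdir, "profiles.tsv"))
    for (lab in names(hitTables))
      writeHitTable(hitTables[[lab]],
                    file.path(outdir, sprintf("hits_%s.tsv", lab)))
    write.table(data.frame(contigId = names(binEval$assignment),
                           bin = unname(binEval$assignment)),
                file.path(outdir, "bin_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeProfileMatrix(binProfs, file.path(outdir, "bin_profiles.tsv"))
    write.table(cbind(label = rownames(dmat),
                      as.data.frame(formatC(dmat, format = "f",
                                            digits = 6))),
                file.path(outdir, "distances.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeNewick(hc, file.path(outdir, "tree.nwk"))
    write.table(cbind(label = rownames(coords),
                      as.data.frame(formatC(coords, format = "f",
                                            digits = 6))),
                file.path(outdir, "mds.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(scatter, file.path(outdir, "scatter.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_yaml(report, file.path(outdir, "report.yaml"))
  }
  invisible(result)
}
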