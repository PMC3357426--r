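#' @importFrom Biostrings readBStringSet writeXStringSet
#' @importFrom utils read.delim write.table
NULL

# validation errors carry a dedicated condition class so callers can
# distinguish malformed inputs from programming errors
mcStop <- function(fmt, ..., class = "metacazValidationError") {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "metacazError")))
}

AA_LETTERS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Read a FASTA file with strict validation
#'
#' Low-level reader behind [readContigs()] and [readFamilyDB()].  Records are
#' returned in file order, sequences uppercased, and the file is rejected
#' (with a validation error) on duplicate identifiers, empty sequences, or
#' characters outside the declared alphabet (A, C, G, T, N for `dna`; the 20
#' amino acids plus X for `protein`).
#'
#' @param path file path.
#' @param alphabet `"dna"` or `"protein"`.
#' @return a data.frame with columns `id`, `description`, `seq`.
#' @export
readFasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) mcStop("file not found: %s", path)
  set <- tryCatch(readBStringSet(path),
                  error = function(e) mcStop("malformed FASTA '%s': %s",
                                             path, conditionMessage(e)))
  if (length(set) == 0L) mcStop("no records in FASTA '%s'", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    mcStop("malformed header (empty id) in '%s'", path)
  if (anyDuplicated(ids))
    mcStop("duplicate ID '%s' in '%s'", ids[duplicated(ids)][1L], path)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    mcStop("empty sequence for '%s' in '%s'", ids[!nzchar(seqs)][1L], path)
  legal <- if (alphabet == "dna") c("A", "C", "G", "T", "N") else AA_LETTERS
  chars <- unique(unlist(strsplit(seqs, "")))
  bad <- setdiff(chars, legal)
  if (length(bad))
    mcStop("illegal %s character(s) in '%s': %s", alphabet, path,
           paste(bad, collapse = ", "))
  data.frame(id = ids, description = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param ids,seqs parallel character vectors.
#' @param path output file.
#' @param descriptions optional descriptions appended after the id.
#' @export
writeFasta <- function(ids, seqs, path, descriptions = NULL) {
  headers <- ids
  if (!is.null(descriptions)) {
    has <- nzchar(descriptions)
    headers[has] <- paste(ids[has], descriptions[has])
  }
  writeLines(paste0(">", headers, "\n", seqs), path, sep = "\n")
  invisible(path)
}

#' Read contigs (and optional depth table) into a ContigSet
#'
#' @param path contig FASTA.
#' @param depthPath optional TSV of per-contig mean depths (see
#'   [readDepthTable()]); contigs absent from the table get depth 1.
#' @return a [ContigSet-class].
#' @export
readContigs <- function(path, depthPath = NULL) {
  rec <- readFasta(path, "dna")
  depth <- if (is.null(depthPath)) NULL else readDepthTable(depthPath)
  ContigSet(stats::setNames(rec$seq, rec$id), depth = depth)
}

#' @rdname readContigs
#' @param contigs a [ContigSet-class].
#' @export
writeContigs <- function(contigs, path) {
  writeFasta(contigIds(contigs), as.character(contigSeqs(contigs)), path)
}

#' Read a per-contig mean depth table
#'
#' Headerless two-column TSV (`contig_id <TAB> depth`).  A missing file is
#' treated as "no depth information": an empty map is returned and every
#' contig defaults to the conventional depth of 1 at join time.
#'
#' @param path TSV path.
#' @return named numeric vector contig_id -> depth.
#' @export
readDepthTable <- function(path) {
  if (!file.exists(path)) return(stats::setNames(numeric(0), character(0)))
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) mcStop("depth table '%s' needs two columns", path)
  tab[[1L]] <- as.character(tab[[1L]])
  depth <- suppressWarnings(as.numeric(as.character(tab[[2L]])))
  if (any(is.na(depth)))
    mcStop("non-numeric depth for contig '%s'", tab[[1L]][is.na(depth)][1L])
  if (any(depth <= 0))
    mcStop("nonpositive depth %s for contig '%s'",
           depth[depth <= 0][1L], tab[[1L]][depth <= 0][1L])
  stats::setNames(depth, tab[[1L]])
}

#' @rdname readDepthTable
#' @param depth named numeric vector.
#' @export
writeDepthTable <- function(depth, path) {
  write.table(data.frame(names(depth), formatC(depth, format = "g")),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# split "id|FAM=GH13" into protein id and family label
parseFamToken <- function(subject) {
  fam <- ifelse(grepl("\\|FAM=", subject),
                sub("^.*\\|FAM=", "", subject), NA_character_)
  list(id = sub("\\|FAM=.*$", "", subject), family = fam)
}

HIT_COLUMNS <- c("queryId", "subjectId", "family", "pident", "alnLen",
                 "mismatches", "gapOpens", "qstart", "qend",
                 "sstart", "send", "evalue", "bitscore")

#' Read a tabular translated-search hit table
#'
#' Ingests the standard 12-column tabular alignment format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bit score) so that hits produced by an external
#' aligner can replace the built-in search.  External coordinates are 1-based
#' inclusive and are converted to the package-internal 0-based half-open
#' convention on the forward tile strand.  The subject's gene family is
#' resolved through `familyMap`, or, failing that, through a `|FAM=` token in
#' the subject id; rows whose subject has no family are dropped and counted
#' in `attr(, "dropped")`.
#'
#' @param path hit TSV.
#' @param familyMap optional named character vector protein_id -> family.
#' @return data.frame of hit records (columns as in `MetaCAZ:::HIT_COLUMNS`),
#'   nucleotide `qstart`/`qend` 0-based half-open.
#' @export
readHitTable <- function(path, familyMap = NULL) {
  if (!file.exists(path)) mcStop("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    hits <- emptyHitTable()
    attr(hits, "dropped") <- 0L
    return(hits)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    mcStop("line %d of '%s': expected >= 12 tab-separated fields, got %d",
           which(nf < 12L)[1L], path, nf[nf < 12L][1L])
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (any(is.na(v)))
      mcStop("line %d of '%s': unparseable %s '%s'",
             which(is.na(v))[1L], path, what, m[is.na(v), col][1L])
    v
  }
  qs <- num(7, "qstart"); qe <- num(8, "qend")
  ss <- num(9, "sstart"); se <- num(10, "send")
  swap <- qs > qe
  tmp <- qs[swap]; qs[swap] <- qe[swap]; qe[swap] <- tmp
  tok <- parseFamToken(m[, 2])
  fam <- if (!is.null(familyMap)) unname(familyMap[tok$id]) else tok$family
  if (!is.null(familyMap)) fam[is.na(fam)] <- tok$family[is.na(fam)]
  keep <- !is.na(fam)
  dropped <- sum(!keep)
  if (dropped)
    message(sprintf("readHitTable: dropped %d rows with unknown subject family",
                    dropped))
  hits <- data.frame(
    queryId = m[keep, 1], subjectId = tok$id[keep], family = fam[keep],
    pident = num(3, "pident")[keep], alnLen = as.integer(num(4, "length"))[keep],
    mismatches = as.integer(num(5, "mismatches"))[keep],
    gapOpens = as.integer(num(6, "gapopen"))[keep],
    qstart = as.integer(qs - 1)[keep], qend = as.integer(qe)[keep],
    sstart = as.integer(ss - 1)[keep], send = as.integer(se)[keep],
    evalue = num(11, "evalue")[keep], bitscore = num(12, "bitscore")[keep],
    stringsAsFactors = FALSE)
  if (any(hits$evalue < 0)) mcStop("negative e-value in '%s'", path)
  if (any(hits$qstart >= hits$qend))
    mcStop("empty query span in '%s'", path)
  attr(hits, "dropped") <- dropped
  hits
}

emptyHitTable <- function() {
  data.frame(queryId = character(0), subjectId = character(0),
             family = character(0), pident = numeric(0),
             alnLen = integer(0), mismatches = integer(0),
             gapOpens = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), stringsAsFactors = FALSE)
}

#' @rdname readHitTable
#' @param hits hit data.frame as returned by [searchContigs()].
#' @export
writeHitTable <- function(hits, path) {
  out <- data.frame(
    hits$queryId, paste0(hits$subjectId, "|FAM=", hits$family),
    formatC(hits$pident, format = "f", digits = 1), hits$alnLen,
    hits$mismatches, hits$gapOpens,
    hits$qstart + 1L, hits$qend, hits$sstart + 1L, hits$send,
    formatC(hits$evalue, format = "e", digits = 2),
    formatC(hits$bitscore, format = "f", digits = 1))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a family-labeled protein database
#'
#' Family labels come from a `|FAM=<label>` token in each FASTA id, or from
#' an explicit `familyMap`.
#'
#' @param path protein FASTA.
#' @param familyMap optional named character vector protein_id -> family.
#' @return a [FamilyDB-class].
#' @export
readFamilyDB <- function(path, familyMap = NULL) {
  rec <- readFasta(path, "protein")
  tok <- parseFamToken(rec$id)
  fam <- tok$family
  if (!is.null(familyMap)) {
    mapped <- unname(familyMap[tok$id])
    fam[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  if (any(is.na(fam)))
    mcStop("no family label for protein '%s'", tok$id[is.na(fam)][1L])
  FamilyDB(stats::setNames(rec$seq, tok$id), fam)
}

#' @rdname readFamilyDB
#' @param db a [FamilyDB-class].
#' @export
writeFamilyDB <- function(db, path) {
  writeFasta(paste0(names(proteinSeqs(db)), "|FAM=", familyLabels(db)),
             as.character(proteinSeqs(db)), path)
}

#' Write/read a family x metagenome profile matrix
#'
#' TSV layout: rows are families sorted lexicographically, columns are
#' metagenome or bin labels, values are per-million abundances printed to two
#' decimals (absences as 0.00), mirroring the usual presentation of
#' family-distribution tables.
#'
#' @param profiles a list of [FamilyProfile-class] objects or a
#'   [ProfileMatrix-class].
#' @param path output TSV.
#' @export
writeProfileMatrix <- function(profiles, path) {
  if (methods::is(profiles, "ProfileMatrix")) {
    values <- profileValues(profiles)
  } else {
    if (length(profiles) == 0L) mcStop("no profiles to write")
    values <- profileValues(assembleMatrix(profiles, filter = "all",
                                           minProfiles = 1L))
  }
  values <- values[order(rownames(values)), , drop = FALSE]
  out <- cbind(family = rownames(values),
               as.data.frame(formatC(values, format = "f", digits = 2)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileMatrix
#' @export
readProfileMatrix <- function(path) {
  if (!file.exists(path)) mcStop("file not found: %s", path)
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  methods::new("ProfileMatrix", values = m,
               familyClass = familyClass(rownames(m)))
}
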