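#' @include AllClasses.R
NULL

#' Write detected elements as GFF3
#'
#' Emits one \code{mobile_genetic_element} record per match with fixed
#' \code{source}, \code{Name} attribute, blank score and phase, coordinates
#' 1-based inclusive, records sorted by (seqid, start), under a
#' \code{##gff-version 3} header.
#'
#' @param matches [GenomicRanges::GRanges] of detected elements.
#' @param path Output file path.
#' @param source Source column value (default \code{"L1PD"}, the conventional
#'   tag for this detection method).
#' @param type Feature type (default \code{"mobile_genetic_element"}).
#' @param name Value of the \code{Name} attribute (default \code{"LINE1"}).
#' @return The path, invisibly.
#' @export
writeGff3 <- function(matches, path, source = "L1PD",
                      type = "mobile_genetic_element", name = "LINE1") {
  stopifnot(is(matches, "GRanges"))
  gr <- granges(matches)
  mcols(gr)$source <- rep(source, length(gr))
  mcols(gr)$type <- rep(type, length(gr))
  mcols(gr)$Name <- rep(name, length(gr))
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  if (length(gr) == 0L) {
    writeLines("##gff-version 3", path)
  } else {
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Read truth/prediction intervals
#'
#' Reads GFF3 (1-based inclusive) or BED (0-based half-open) into the
#' package's internal convention (GRanges, 1-based inclusive), preserving
#' strand.  The format is inferred from the extension unless given.
#'
#' @param path Input file.
#' @param format \code{"auto"}, \code{"gff3"} or \code{"bed"}.
#' @param type Optional GFF3 feature-type filter.
#' @return A [GenomicRanges::GRanges].
#' @export
readIntervals <- function(path, format = c("auto", "gff3", "bed"),
                          type = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(readLines(path, warn = FALSE)) == 0L ||
      all(!nzchar(readLines(path, warn = FALSE))))
    return(GRanges())
  gr <- rtracklayer::import(path, format = format)
  gr <- as(gr, "GRanges")
  if (!is.null(type) && format == "gff3" && !is.null(mcols(gr)$type))
    gr <- gr[as.character(mcols(gr)$type) %in% type]
  gr
}

#' Structural GFF3 validity check
#'
#' Verifies the properties a GFF3 consumer relies on: a
#' \code{##gff-version 3} header, nine tab-delimited columns per record,
#' numeric 1-based coordinates with start <= end, legal strand and
#' dot-rendered blank score/phase.  Independent of the reading machinery in
#' [readIntervals()] so it can serve as an external check on emitted files.
#'
#' @param path GFF3 file to check.
#' @return \code{TRUE} if valid, otherwise \code{FALSE} with the offending
#'   problems in \code{attr(, "problems")}.
#' @export
validateGff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  problems <- character()
  if (length(lines) == 0L || !grepl("^##gff-version 3", lines[1L]))
    problems <- c(problems, "missing ##gff-version 3 header")
  records <- lines[!grepl("^#", lines) & nzchar(lines)]
  for (i in seq_along(records)) {
    f <- strsplit(records[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) {
      problems <- c(problems, sprintf("record %d: %d columns", i, length(f)))
      next
    }
    st <- suppressWarnings(as.numeric(f[4L]))
    en <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(st) || is.na(en) || st < 1 || st > en)
      problems <- c(problems,
                    sprintf("record %d: bad coordinates %s-%s", i, f[4L], f[5L]))
    if (!f[7L] %in% c("+", "-", ".", "?"))
      problems <- c(problems, sprintf("record %d: bad strand '%s'", i, f[7L]))
    if (!grepl("^(\\.|[0-9eE.+-]+)$", f[6L]))
      problems <- c(problems, sprintf("record %d: bad score '%s'", i, f[6L]))
    if (!f[8L] %in% c(".", "0", "1", "2"))
      problems <- c(problems, sprintf("record %d: bad phase '%s'", i, f[8L]))
  }
  if (length(problems)) {
    out <- FALSE
    attr(out, "problems") <- problems
    return(out)
  }
  TRUE
}

#' Export / import a probe set
#'
#' The probe-design/detection contract: a FASTA file with the probe sequences
#' and a tab-separated sidecar with the layout (id, region,
#' avg_offset_element, avg_offset_orf1, adjacent_distance_to_next,
#' avg_tail_length).
#'
#' @param probeset A [ProbeSet-class].
#' @param fastaPath,metaPath Output/input paths.
#' @return \code{writeProbeSet}: the paths, invisibly. \code{readProbeSet}:
#'   a [ProbeSet-class].
#' @export
writeProbeSet <- function(probeset, fastaPath, metaPath) {
  stopifnot(is(probeset, "ProbeSet"))
  writeXStringSet(probeset@probes, fastaPath)
  n <- length(probeset)
  meta <- data.frame(
    id = names(probeset@probes),
    region = probeset@region,
    avg_offset_element = probeset@offsetElement,
    avg_offset_orf1 = probeset@offsetOrf1,
    adjacent_distance_to_next = c(probeset@adjacentDistances, NA),
    avg_tail_length = probeset@avgTailLength,
    stringsAsFactors = FALSE)
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fastaPath, metaPath))
}

#' @rdname writeProbeSet
#' @export
readProbeSet <- function(fastaPath, metaPath) {
  probes <- readDNAStringSet(fastaPath)
  meta <- read.delim(metaPath, stringsAsFactors = FALSE)
  if (!all(names(probes) == meta$id))
    stop("probe FASTA and metadata ids disagree")
  ProbeSet(probes = as.character(probes), region = meta$region,
           offsetElement = meta$avg_offset_element,
           offsetOrf1 = meta$avg_offset_orf1,
           adjacentDistances = meta$adjacent_distance_to_next[-nrow(meta)],
           avgTailLength = meta$avg_tail_length[1L])
}

#' Read an aligned query set
#'
#' Aligned FASTA plus a tab-separated sidecar of ORF column ranges
#' (region_name, start_col, end_col; 1-based inclusive alignment columns).
#'
#' @param fastaPath Aligned FASTA (equal-width, gaps as \code{-}).
#' @param orfPath ORF range TSV.
#' @return An [AlignedQuerySet-class].
#' @export
readQuerySet <- function(fastaPath, orfPath) {
  aln <- readDNAStringSet(fastaPath)
  orf <- read.delim(orfPath, stringsAsFactors = FALSE)
  need <- c("region_name", "start_col", "end_col")
  if (!all(need %in% names(orf)))
    stop("ORF sidecar needs columns: ", paste(need, collapse = ", "))
  AlignedQuerySet(aln, IRanges(orf$start_col, orf$end_col,
                               names = orf$region_name))
}

#' Write a genome and its truth annotation
#'
#' Companion to the simulator: FASTA for the genome and GFF3 for the planted
#' truth (type \code{mobile_genetic_element}, the integrity class in the
#' \code{class} attribute).
#'
#' @param sim List with \code{genome} (DNAStringSet) and \code{truth}
#'   (GRanges with a \code{class} metadata column), as produced by
#'   [plantElements()].
#' @param fastaPath,gffPath Output paths.
#' @return The paths, invisibly.
#' @export
writeSimulation <- function(sim, fastaPath, gffPath) {
  writeXStringSet(sim$genome, fastaPath)
  gr <- sim$truth
  mcols(gr)$source <- "simulation"
  mcols(gr)$type <- "mobile_genetic_element"
  mcols(gr)$Name <- "LINE1"
  rtracklayer::export(gr, gffPath, format = "gff3")
  invisible(c(fastaPath, gffPath))
}
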