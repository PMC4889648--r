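#' Write simulated reads to FASTQ
#'
#' Standard 4-line FASTQ with Phred+33 qualities (all `I`, i.e. Q40, by
#' default -- the simulator has no quality model). The header line is
#' `@<id> <index1>+<index2>`, carrying the well index pair the way
#' demultiplexed Illumina headers do.
#'
#' @param reads `data.table` with columns `id`, `sequence`, `index1`,
#'   `index2` (as returned in [simulate_reads()]`$reads`).
#' @param path Output file (`.gz` suffix gzips).
#' @export
write_fastq <- function(reads, path) {
  reads <- data.table::as.data.table(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- paste0(reads$id, " ", reads$index1, "+", reads$index2)
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ of barcoded amplicon reads
#'
#' Parses the well index pair from the last whitespace-separated header
#' token of the form `INDEX1+INDEX2`; reads without one get `NA` indices
#' (they will demultiplex as `bad_index`).
#'
#' @param path FASTQ file, optionally gzipped.
#' @return `data.table` with columns `id`, `sequence`, `index1`, `index2`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  hdr <- names(x)
  toks <- strsplit(hdr, "[ \t]+")
  id <- vapply(toks, `[[`, character(1), 1L)
  pair <- vapply(toks, function(tt) {
    hit <- grep("^[ACGTN]+\\+[ACGTN]+$", tt, value = TRUE)
    if (length(hit)) hit[length(hit)] else NA_character_
  }, character(1))
  idx <- data.table::tstrsplit(pair, "+", fixed = TRUE)
  data.table::data.table(id = id, sequence = as.character(x),
                         index1 = if (length(idx)) idx[[1]] else NA_character_,
                         index2 = if (length(idx) > 1) idx[[2]] else NA_character_)
}
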