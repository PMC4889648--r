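#' Define an amplicon target (one splicing event)
#'
#' A target is the amplified region around one intron: the upstream exon
#' segment, the intron, and the downstream exon segment, all on the
#' amplicon's forward strand. The spliced isoform is `exon5 + exon3`; the
#' unspliced isoform is `exon5 + intron + exon3`. Reads are classified as
#' spliced or unspliced by exact junction-spanning matches with
#' `junction_flank_k` bases on each side of the junction (coordinates are
#' 0-based half-open; the junction sits at position `nchar(exon5)`).
#'
#' @param name Target identifier, e.g. `"fet5_intron1"`.
#' @param exon5,intron,exon3 Nucleotide strings over `{A,C,G,T}`.
#' @param junction_flank_k Integer, bases required on each side of a
#'   junction for a read to be classified (default 6).
#' @return An object of class `target_spec`.
#' @examples
#' ts <- target_spec("toy", "ACGTACGTAC", "GTAAGTTTTTACTAACTTTTAG", "GGGTTTCCCA")
#' spliced_isoform(ts)
#' @export
target_spec <- function(name, exon5, intron, exon3, junction_flank_k = 6L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  exon5 <- check_dna(exon5, "exon5")
  intron <- check_dna(intron, "intron")
  exon3 <- check_dna(exon3, "exon3")
  k <- check_number(junction_flank_k, "junction_flank_k", min = 1, integer = TRUE)
  if (min(nchar(exon5), nchar(intron), nchar(exon3)) < k)
    stop("junction_flank_k exceeds a segment length for target ", name,
         call. = FALSE)
  structure(list(name = name, exon5 = exon5, intron = intron, exon3 = exon3,
                 junction_flank_k = k),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("<target_spec> %s: exon5 %dnt | intron %dnt | exon3 %dnt (k=%d)\n",
              x$name, nchar(x$exon5), nchar(x$intron), nchar(x$exon3),
              x$junction_flank_k))
  invisible(x)
}

#' @rdname target_spec
#' @param target A `target_spec`.
#' @export
spliced_isoform <- function(target) paste0(target$exon5, target$exon3)

#' @rdname target_spec
#' @export
unspliced_isoform <- function(target)
  paste0(target$exon5, target$intron, target$exon3)

# Junction-spanning 2k-mers used for read classification.
junction_kmers <- function(target) {
  k <- target$junction_flank_k
  e5 <- target$exon5; it <- target$intron; e3 <- target$exon3
  list(
    spliced  = paste0(substr(e5, nchar(e5) - k + 1L, nchar(e5)), substr(e3, 1L, k)),
    unspliced5 = paste0(substr(e5, nchar(e5) - k + 1L, nchar(e5)), substr(it, 1L, k)),
    unspliced3 = paste0(substr(it, nchar(it) - k + 1L, nchar(it)), substr(e3, 1L, k))
  )
}

#' Built-in synthetic example targets
#'
#' Two synthetic amplicon targets mimicking the assayed fission-yeast
#' splicing events: a 45-nt intron with canonical 5' splice site (GTAAGT)
#' and branch point (TGCTAAT), and a 59-nt intron with an atypical 5'
#' splice site (GTACAA) and canonical branch point (CATTAAT). The
#' sequences themselves are synthetic (fixed, invented) -- only the intron
#' lengths and splice-site/branch motifs follow the real events.
#'
#' @return A named list of two [target_spec()] objects.
#' @export
example_targets <- function() {
  list(
    fet5_intron1 = target_spec(
      "fet5_intron1",
      exon5  = "ACCTAATGTGTTGCCCGGACCTCACACAAG",
      intron = "GTAAGTCGTGCCTATTCTACAGTTTTACTGCTAATATGCCCTCAG",
      exon3  = "ATTCCGGCTACCTCAAAAAATCCCGTGAGCGCCAACGTCT"),
    pwi1_intron2 = target_spec(
      "pwi1_intron2",
      exon5  = "GGCTGAAGCCCGTTGAATTCTATTTGCATT",
      intron = "GTACAACTGTATGCTAGCTAATAGGATAACAGCGGACGGCAACATTAATCTGGACGTAG",
      exon3  = "CATCGGGGAGCACTTTGGGGCGGTCTATGCAAACGGCGCA")
  )
}
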