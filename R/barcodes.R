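#' Generate a set of mutually distant barcodes
#'
#' Greedy rejection sampling: random candidates of the given width are
#' accepted while they keep the set's minimum pairwise Hamming distance at
#' or above `min_dist`.
#'
#' @param n Number of barcodes.
#' @param width Barcode length in nt.
#' @param min_dist Minimum pairwise Hamming distance.
#' @param seed RNG seed (local; the caller's RNG state is restored).
#' @return Character vector of `n` barcodes.
#' @export
make_barcodes <- function(n, width = 8L, min_dist = 3L, seed = 1L) {
  n <- check_number(n, "n", min = 1, integer = TRUE)
  width <- check_number(width, "width", min = min_dist, integer = TRUE)
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                    collapse = "")
      if (!length(out) || min(hamming_dist(out, cand)) >= min_dist)
        out <- c(out, cand)
      tries <- tries + 1L
      if (tries > 200L * n)
        stop("cannot find ", n, " barcodes of width ", width,
             " at min_dist ", min_dist, call. = FALSE)
    }
    out
  })
}

#' Dual-barcode demultiplexing scheme
#'
#' Holds the plate-specific barcodes (a fixed-length prefix inside the
#' insert read) and the well-specific index pairs (Illumina-style i7/i5
#' indices carried in the read header), together with the mismatch
#' tolerances used at demultiplexing. Construction fails unless every
#' barcode set is pairwise distinct with Hamming distance greater than
#' twice its mismatch tolerance, so a scheme that could assign one read to
#' two samples is rejected up front.
#'
#' @param plate_barcodes Named character vector: plate label -> barcode.
#' @param well_indices `data.frame`/`data.table` with columns `well`,
#'   `index1`, `index2`; index pairs must be unique per well.
#' @param max_mismatch_plate,max_mismatch_index Allowed mismatches when
#'   matching the plate barcode and each well index (defaults 0 and 1).
#' @return An object of class `barcode_scheme`.
#' @export
barcode_scheme <- function(plate_barcodes, well_indices,
                           max_mismatch_plate = 0L, max_mismatch_index = 1L) {
  stopifnot(is.character(plate_barcodes), !is.null(names(plate_barcodes)),
            all(nzchar(names(plate_barcodes))))
  wi <- data.table::as.data.table(well_indices)
  stopifnot(all(c("well", "index1", "index2") %in% names(wi)))
  mmp <- check_number(max_mismatch_plate, "max_mismatch_plate", min = 0, integer = TRUE)
  mmi <- check_number(max_mismatch_index, "max_mismatch_index", min = 0, integer = TRUE)
  check_set <- function(x, what, max_mm) {
    if (length(unique(nchar(x))) != 1L)
      stop(what, ": barcodes must have a single fixed length", call. = FALSE)
    ux <- unique(x)
    if (anyDuplicated(x))
      stop(what, ": duplicated barcodes", call. = FALSE)
    if (length(ux) > 1L) {
      for (i in seq_len(length(ux) - 1L)) {
        d <- hamming_dist(ux[(i + 1L):length(ux)], ux[i])
        if (min(d) <= 2L * max_mm)
          stop(what, ": pairwise Hamming distance must exceed ", 2L * max_mm,
               call. = FALSE)
      }
    }
    invisible(TRUE)
  }
  check_set(unname(plate_barcodes), "plate_barcodes", mmp)
  check_set(unique(wi$index1), "well index1 set", mmi)
  check_set(unique(wi$index2), "well index2 set", mmi)
  if (anyDuplicated(wi[, .(index1, index2)]))
    stop("well_indices: index pairs must be unique", call. = FALSE)
  if (anyDuplicated(wi$well))
    stop("well_indices: wells must be unique", call. = FALSE)
  structure(list(plate_barcodes = plate_barcodes,
                 well_indices = wi[, .(well, index1, index2)],
                 max_mismatch_plate = mmp, max_mismatch_index = mmi),
            class = "barcode_scheme")
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat(sprintf("<barcode_scheme> %d plates (len %d, mm<=%d), %d wells (mm<=%d)\n",
              length(x$plate_barcodes), nchar(x$plate_barcodes[[1L]]),
              x$max_mismatch_plate, nrow(x$well_indices), x$max_mismatch_index))
  invisible(x)
}

# 384-well labels in row-major order: A01..A24, B01, ..., P24.
well_names_384 <- function() {
  as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0)))
}

#' Default barcode scheme for a set of plates
#'
#' Builds a [barcode_scheme()] covering the given plate labels and the 384
#' standard wells, with 6-nt plate barcodes (pairwise distance >= 3) and
#' 8-nt row/column well indices (distance >= 3, Nextera-like): wells in
#' row `r`, column `c` get `index1 = column barcode c`, `index2 = row
#' barcode r`.
#'
#' @param plates Character vector of plate labels.
#' @param seed RNG seed for barcode generation.
#' @inheritParams barcode_scheme
#' @export
default_scheme <- function(plates, seed = 99L,
                           max_mismatch_plate = 0L, max_mismatch_index = 1L) {
  stopifnot(length(plates) >= 1L, !anyDuplicated(plates))
  pb <- make_barcodes(length(plates), width = 6L, min_dist = 3L, seed = seed)
  names(pb) <- plates
  col_idx <- make_barcodes(24L, width = 8L, min_dist = 3L, seed = seed + 1L)
  row_idx <- make_barcodes(16L, width = 8L, min_dist = 3L, seed = seed + 2L)
  wi <- data.table::CJ(row = 1:16, col = 1:24)
  wi[, `:=`(well = paste0(LETTERS[row], sprintf("%02d", col)),
            index1 = col_idx[col], index2 = row_idx[row])]
  barcode_scheme(pb, wi[, .(well, index1, index2)],
                 max_mismatch_plate, max_mismatch_index)
}

#' Read/write a barcode scheme as TSV
#'
#' The TSV has columns `set` (`plate` or `well`), `id` (plate label or
#' well), `index1`, `index2` (`index2` empty for plates). Mismatch
#' tolerances are not stored; pass them when reading.
#'
#' @param scheme A `barcode_scheme`.
#' @param path File path.
#' @inheritParams barcode_scheme
#' @export
write_scheme <- function(scheme, path) {
  pl <- data.table::data.table(set = "plate", id = names(scheme$plate_barcodes),
                               index1 = unname(scheme$plate_barcodes),
                               index2 = "")
  we <- data.table::data.table(set = "well", id = scheme$well_indices$well,
                               index1 = scheme$well_indices$index1,
                               index2 = scheme$well_indices$index2)
  write_tsv(rbind(pl, we), path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path, max_mismatch_plate = 0L, max_mismatch_index = 1L) {
  x <- read_tsv(path)
  pl <- x[set == "plate"]
  we <- x[set == "well"]
  barcode_scheme(stats::setNames(pl$index1, pl$id),
                 we[, .(well = id, index1, index2)],
                 max_mismatch_plate, max_mismatch_index)
}
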