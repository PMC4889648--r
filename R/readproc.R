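#' Demultiplex barcoded amplicon reads
#'
#' Assigns each read to a (plate, well): the plate from a fixed-length
#' barcode prefix of the insert sequence (within
#' `scheme$max_mismatch_plate`), the well from the header index pair (each
#' index within `scheme$max_mismatch_index` of a known index, and the
#' resulting pair present in the scheme). Reads failing either step are
#' tallied with a reason code; when a `layout` is supplied, assigned
#' positions absent from it are tallied as `not_in_layout` rather than
#' silently dropped.
#'
#' @param reads `data.table` with columns `id`, `sequence`, `index1`,
#'   `index2` (see [read_fastq()]).
#' @param scheme A [barcode_scheme()].
#' @param layout Optional layout `data.table` (`plate`, `well`,
#'   `strain_id`, `replicate`).
#' @return List: `assigned` (reads plus `plate`, `well`), `unassigned`
#'   (`id`, `reason` in `bad_plate`/`bad_index`/`not_in_layout`) and
#'   `tally` (named counts, including `total` and `assigned`).
#' @export
demultiplex <- function(reads, scheme, layout = NULL) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  reads <- data.table::as.data.table(reads)
  n <- nrow(reads)
  bc <- scheme$plate_barcodes
  bclen <- nchar(bc[[1L]])

  prefix <- substr(reads$sequence, 1L, bclen)
  plate_i <- match_with_mismatch(prefix, unname(bc), scheme$max_mismatch_plate)
  plate <- names(bc)[plate_i]

  wi <- scheme$well_indices
  i1set <- unique(wi$index1)
  i2set <- unique(wi$index2)
  mmi <- scheme$max_mismatch_index
  i1 <- i1set[match_with_mismatch(ifelse(is.na(reads$index1), "", reads$index1),
                                  i1set, mmi)]
  i2 <- i2set[match_with_mismatch(ifelse(is.na(reads$index2), "", reads$index2),
                                  i2set, mmi)]
  well <- wi$well[match(paste(i1, i2), paste(wi$index1, wi$index2))]

  reason <- rep(NA_character_, n)
  reason[is.na(plate)] <- "bad_plate"
  reason[is.na(reason) & is.na(well)] <- "bad_index"
  if (!is.null(layout)) {
    layout <- data.table::as.data.table(layout)
    known <- paste(layout$plate, layout$well)
    off <- is.na(reason) & !(paste(plate, well) %in% known)
    reason[off] <- "not_in_layout"
  }

  ok <- is.na(reason)
  assigned <- reads[ok][, `:=`(plate = plate[ok], well = well[ok])]
  unassigned <- data.table::data.table(id = reads$id[!ok], reason = reason[!ok])
  tally <- c(total = n, assigned = sum(ok),
             table(factor(reason[!ok],
                          levels = c("bad_plate", "bad_index", "not_in_layout"))))
  list(assigned = assigned, unassigned = unassigned, tally = tally)
}

#' Classify one read as spliced, unspliced or ambiguous
#'
#' Junction rule replacing alignment: with `k = junction_flank_k`, a read
#' (plate barcode already stripped) is `unspliced` if it contains an exact
#' 2k-mer spanning either exon-intron boundary, `spliced` if it contains
#' the 2k-mer spanning the exon5-exon3 junction, and `ambiguous` if
#' neither or both (read too short, entirely within one segment, or
#' contradictory). Total function; never errors on valid input.
#'
#' @param read A nucleotide string (or vector of them).
#' @param target A [target_spec()].
#' @return Character vector in `{"spliced", "unspliced", "ambiguous"}`.
#' @examples
#' ts <- example_targets()$fet5_intron1
#' classify_read(paste0(substr(ts$exon5, 25, 30), substr(ts$exon3, 1, 6)), ts)
#' @export
classify_read <- function(read, target) {
  stopifnot(inherits(target, "target_spec"))
  km <- junction_kmers(target)
  s_hit <- grepl(km$spliced, read, fixed = TRUE)
  u_hit <- grepl(km$unspliced5, read, fixed = TRUE) |
    grepl(km$unspliced3, read, fixed = TRUE)
  out <- rep("ambiguous", length(read))
  out[s_hit & !u_hit] <- "spliced"
  out[u_hit & !s_hit] <- "unspliced"
  out
}

# Is each read an exact substring of either isoform of `target`?
contained_in_target <- function(seqs, target) {
  spl <- spliced_isoform(target)
  uns <- unspliced_isoform(target)
  vapply(seqs, function(s)
    grepl(s, spl, fixed = TRUE) || grepl(s, uns, fixed = TRUE),
    logical(1), USE.NAMES = FALSE)
}

#' Count spliced and unspliced reads per sample
#'
#' Composition of [demultiplex()] and [classify_read()]: reads are
#' assigned to (plate, well), the plate barcode is stripped, and each read
#' is classified against every target. A read contributes to the sample's
#' `spliced`/`unspliced` count of the single target for which it has a
#' clear junction call; reads with a contradictory call, or with no
#' junction call but exactly contained in one target's isoforms (e.g.
#' entirely within an exon), are counted in that target's `ambiguous`
#' column; reads attributable to no target (or more than one) are tallied
#' run-level as `unresolved`. Thus, per run,
#' `assigned = sum(spliced + unspliced + ambiguous) + unresolved`.
#'
#' @inheritParams demultiplex
#' @param layout Layout `data.table` mapping `(plate, well)` to
#'   `(strain_id, replicate)`.
#' @param targets List of [target_spec()]s.
#' @return List: `counts` (one row per layout position and target --
#'   zero-filled where no reads landed -- with columns `strain_id`,
#'   `target`, `replicate`, `plate`, `well`, `spliced`, `unspliced`,
#'   `ambiguous`) and `qc` (run-level tally: total, assigned, unassigned
#'   reasons, unresolved, assigned/ambiguous fractions).
#' @export
count_isoforms <- function(reads, scheme, layout, targets) {
  layout <- data.table::as.data.table(layout)
  stopifnot(all(c("plate", "well", "strain_id", "replicate") %in% names(layout)))
  tnames <- vapply(targets, `[[`, character(1), "name")
  names(targets) <- tnames
  dmx <- demultiplex(reads, scheme, layout)
  asg <- dmx$assigned
  bclen <- nchar(scheme$plate_barcodes[[1L]])

  grid <- data.table::rbindlist(lapply(tnames, function(t)
    data.table::copy(layout)[, target := t]))
  zero <- grid[, .(strain_id, target, replicate, plate, well,
                   spliced = 0L, unspliced = 0L, ambiguous = 0L)]

  unresolved <- 0L
  if (nrow(asg)) {
    stripped <- substr(asg$sequence, bclen + 1L, nchar(asg$sequence))
    calls <- vapply(tnames, function(t) classify_read(stripped, targets[[t]]),
                    character(nrow(asg)))
    calls <- matrix(calls, nrow = nrow(asg),
                    dimnames = list(NULL, tnames))
    clear <- calls != "ambiguous"
    n_clear <- rowSums(clear)

    read_target <- rep(NA_character_, nrow(asg))
    read_class <- rep(NA_character_, nrow(asg))
    one <- n_clear == 1L
    if (any(one)) {
      tcol <- max.col(clear[one, , drop = FALSE], ties.method = "first")
      read_target[one] <- tnames[tcol]
      read_class[one] <- calls[cbind(which(one), tcol)]
    }
    # no clear call anywhere: try exact containment to attribute ambiguity
    none <- n_clear == 0L
    if (any(none)) {
      cont <- vapply(tnames, function(t)
        contained_in_target(stripped[none], targets[[t]]), logical(sum(none)))
      cont <- matrix(cont, nrow = sum(none), dimnames = list(NULL, tnames))
      uniq <- rowSums(cont) == 1L
      if (any(uniq)) {
        tcol <- max.col(cont[uniq, , drop = FALSE], ties.method = "first")
        idx <- which(none)[uniq]
        read_target[idx] <- tnames[tcol]
        read_class[idx] <- "ambiguous"
      }
    }
    unresolved <- sum(is.na(read_target))  # no target, or >1 clear targets
    keep <- !is.na(read_target)
    per <- data.table::data.table(plate = asg$plate[keep], well = asg$well[keep],
                                  target = read_target[keep],
                                  class = read_class[keep])
    agg <- per[, .(spliced = sum(class == "spliced"),
                   unspliced = sum(class == "unspliced"),
                   ambiguous = sum(class == "ambiguous")),
               by = .(plate, well, target)]
    counts <- merge(zero[, .(strain_id, target, replicate, plate, well)], agg,
                    by = c("plate", "well", "target"), all.x = TRUE)
    for (cc in c("spliced", "unspliced", "ambiguous"))
      data.table::set(counts, which(is.na(counts[[cc]])), cc, 0L)
  } else {
    counts <- zero
  }
  data.table::setorder(counts, target, plate, well)
  data.table::setcolorder(counts, c("strain_id", "target", "replicate",
                                    "plate", "well", "spliced", "unspliced",
                                    "ambiguous"))
  qc <- c(as.list(dmx$tally), list(
    unresolved = unresolved,
    assigned_fraction = if (dmx$tally[["total"]] > 0)
      dmx$tally[["assigned"]] / dmx$tally[["total"]] else NA_real_,
    ambiguous_fraction = if (dmx$tally[["assigned"]] > 0)
      sum(counts$ambiguous) / dmx$tally[["assigned"]] else NA_real_))
  list(counts = counts[], qc = qc)
}

#' Read/write layout and count tables
#'
#' Plain TSV with headers. The layout maps each physical plate position to
#' a strain and replicate; the count table is one row per (strain, target,
#' replicate) sample.
#'
#' @param x A `data.table` to write.
#' @param path File path.
#' @export
write_layout <- function(x, path) write_tsv(
  data.table::as.data.table(x)[, .(plate, well, strain_id, replicate)], path)

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- read_tsv(path)
  stopifnot(all(c("plate", "well", "strain_id", "replicate") %in% names(x)))
  if (anyDuplicated(x[, .(plate, well)]))
    stop("layout has duplicated (plate, well) positions", call. = FALSE)
  x
}

#' @rdname write_layout
#' @export
write_counts <- function(x, path) write_tsv(x, path)

#' @rdname write_layout
#' @export
read_counts <- function(path) {
  x <- read_tsv(path)
  need <- c("strain_id", "target", "replicate", "plate", "well",
            "spliced", "unspliced")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("counts file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"ambiguous" %in% names(x)) x[, ambiguous := 0L]
  if (any(x$spliced < 0 | x$unspliced < 0))
    stop("counts must be non-negative", call. = FALSE)
  x
}
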