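test_that("classify_read follows the junction rule", {
  tg <- example_targets()$fet5_intron1   # k = 6
  e5 <- tg$exon5; it <- tg$intron; e3 <- tg$exon3
  last6 <- function(s) substr(s, nchar(s) - 5L, nchar(s))
  expect_equal(classify_read(paste0(last6(e5), substr(e3, 1, 6)), tg), "spliced")
  expect_equal(classify_read(paste0(last6(e5), substr(it, 1, 6)), tg), "unspliced")
  expect_equal(classify_read(paste0(last6(it), substr(e3, 1, 6)), tg), "unspliced")
  expect_equal(classify_read(substr(e5, 1, 12), tg), "ambiguous")  # within exon5
  expect_equal(classify_read("ACGT", tg), "ambiguous")             # too short
  # both junction types present -> contradictory -> ambiguous
  both <- paste0(last6(e5), substr(it, 1, 6), last6(it), substr(e3, 1, 6),
                 last6(e5), substr(e3, 1, 6))
  expect_equal(classify_read(both, tg), "ambiguous")
  # vectorized
  expect_equal(classify_read(c(substr(e5, 1, 12), paste0(last6(e5), substr(e3, 1, 6))), tg),
               c("ambiguous", "spliced"))
})

test_that("classify_read agrees with a containment oracle on random short reads", {
  # oracle: exact-substring containment of the read in each isoform; a read
  # contained in exactly one isoform is that isoform, otherwise ambiguous.
  # classify_read may conservatively return ambiguous where the junction
  # overlap is positive but below k (documented boundary behavior).
  tg <- toy_target(k = 3L)
  spl <- spliced_isoform(tg); uns <- unspliced_isoform(tg)
  k <- tg$junction_flank_k
  withr::with_seed(101, {
    for (i in 1:300) {
      src <- sample(c(spl, uns), 1L)
      len <- sample(seq(2L * k, 15L), 1L)
      start <- sample(nchar(src) - len + 1L, 1L)
      read <- substr(src, start, start + len - 1L)
      in_s <- grepl(read, spl, fixed = TRUE)
      in_u <- grepl(read, uns, fixed = TRUE)
      oracle <- if (in_s && !in_u) "spliced" else if (in_u && !in_s)
        "unspliced" else "ambiguous"
      got <- classify_read(read, tg)
      expect_true(got == oracle || got == "ambiguous",
                  label = sprintf("read %s: got %s, oracle %s", read, got, oracle))
      if (got != oracle) {
        # disagreement only at junction overlaps below k
        end <- start + len - 1L
        j <- if (identical(src, spl)) nchar(tg$exon5) else NA_integer_
        if (identical(src, spl))
          expect_true(start > j - k + 1L || end < j + k,
                      label = sprintf("read %s spans junction with >=k flank", read))
      }
    }
  })
})

test_that("barcode_scheme rejects ambiguous barcode sets at construction", {
  wi <- data.table::data.table(well = c("A01", "A02"),
                               index1 = c("AAAAAAAA", "CCCCCCCC"),
                               index2 = c("GGGGGGGG", "GGGGGGGG"))
  # plate barcodes at Hamming distance 1 with max_mismatch 1 -> reject
  expect_error(
    barcode_scheme(c(P1 = "AAAAAA", P2 = "AAAAAC"), wi,
                   max_mismatch_plate = 1L),
    "Hamming")
  # distance fine at max_mismatch 0
  expect_s3_class(
    barcode_scheme(c(P1 = "AAAAAA", P2 = "AAAACC"), wi,
                   max_mismatch_plate = 0L),
    "barcode_scheme")
  expect_error(
    barcode_scheme(c(P1 = "AAAAAA", P2 = "AAAAAA"), wi), "duplicated")
  # index pairs must be unique
  wi_dup <- data.table::data.table(well = c("A01", "A02"),
                                   index1 = "AAAAAAAA", index2 = "GGGGGGGG")
  expect_error(barcode_scheme(c(P1 = "AAAAAA"), wi_dup), "unique")
})

test_that("demultiplex assigns exact matches and tallies failures by reason", {
  scheme <- default_scheme(c("P01.1", "P02.1"), seed = 17L)
  wi <- scheme$well_indices
  bc <- scheme$plate_barcodes
  tgt <- example_targets()$fet5_intron1
  body <- substr(spliced_isoform(tgt), 1, 40)
  flip <- function(s, i) { substr(s, i, i) <- ifelse(substr(s, i, i) == "A", "C", "A"); s }
  reads <- data.table::data.table(
    id = c("ok", "ok_mm_index", "bad_plate", "bad_pair"),
    sequence = c(paste0(bc[["P01.1"]], body),
                 paste0(bc[["P02.1"]], body),
                 paste0(flip(bc[["P01.1"]], 2L), body),   # 1 mismatch, mm_plate = 0
                 paste0(bc[["P01.1"]], body)),
    index1 = c(wi$index1[1], flip(wi$index1[5], 3L), wi$index1[1], "TTTTTTTT"),
    index2 = c(wi$index2[1], wi$index2[5], wi$index2[1], "TTTTTTTT"))
  dmx <- demultiplex(reads, scheme)
  expect_setequal(dmx$assigned$id, c("ok", "ok_mm_index"))
  expect_equal(dmx$assigned[id == "ok", well], wi$well[1])
  expect_equal(dmx$assigned[id == "ok_mm_index", well], wi$well[5])
  expect_equal(dmx$unassigned[id == "bad_plate", reason], "bad_plate")
  expect_equal(dmx$unassigned[id == "bad_pair", reason], "bad_index")
  expect_equal(unname(dmx$tally[["total"]]), 4L)
  expect_equal(unname(dmx$tally[["assigned"]]), 2L)
  # with a layout lacking P02.1/A05: not_in_layout, never silently dropped
  layout <- data.table::data.table(plate = "P01.1", well = wi$well[1],
                                   strain_id = "s1", replicate = 1L)
  dmx2 <- demultiplex(reads, scheme, layout)
  expect_equal(dmx2$unassigned[id == "ok_mm_index", reason], "not_in_layout")
})

test_that("count_isoforms round trip reproduces simulated counts exactly", {
  sim <- small_sim(depth_log_mean = log(80), depth_log_sd = 0.3, seed = 19L)
  lay <- sim$truth$layout
  scheme <- default_scheme(unique(lay$plate), seed = 23L)
  rd <- simulate_reads(sim$counts, scheme, example_targets()[1], seed = 29L)
  res <- count_isoforms(rd$reads, scheme, lay, example_targets()[1])
  a <- data.table::setorder(data.table::copy(sim$counts), plate, well)
  b <- data.table::setorder(data.table::copy(res$counts), plate, well)
  expect_equal(b$spliced, a$spliced)
  expect_equal(b$unspliced, a$unspliced)
  expect_equal(sum(b$ambiguous), 0L)
  expect_equal(res$qc$assigned_fraction, 1.0)
  # per-well totals equal the manifest
  man_tot <- rd$manifest[, .N, by = .(plate, well)]
  cnt_tot <- b[, .(n = spliced + unspliced), by = .(plate, well)]
  mm <- merge(man_tot, cnt_tot, by = c("plate", "well"))
  expect_equal(mm$N, mm$n)
})

test_that("read accounting is conserved under sequencing errors", {
  sim <- small_sim(depth_log_mean = log(60), depth_log_sd = 0.3, seed = 31L)
  lay <- sim$truth$layout
  scheme <- default_scheme(unique(lay$plate), seed = 37L)
  rd <- simulate_reads(sim$counts, scheme, example_targets()[1], seed = 41L,
                       error_rate = 0.01)
  res <- count_isoforms(rd$reads, scheme, lay, example_targets()[1])
  qc <- res$qc
  expect_equal(qc$assigned + qc$bad_plate + qc$bad_index + qc$not_in_layout,
               qc$total)
  expect_equal(sum(res$counts$spliced + res$counts$unspliced +
                     res$counts$ambiguous) + qc$unresolved,
               qc$assigned)
  expect_gt(qc$assigned_fraction, 0.8)
})

test_that("a stream of unassignable reads yields zero counts and a full tally", {
  scheme <- default_scheme("P01.1", seed = 43L)
  layout <- data.table::data.table(plate = "P01.1", well = "A01",
                                   strain_id = "s1", replicate = 1L)
  junk <- data.table::data.table(id = sprintf("j%d", 1:5),
                                 sequence = strrep("T", 60),
                                 index1 = "NNNNNNNN", index2 = "NNNNNNNN")
  res <- count_isoforms(junk, scheme, layout, example_targets()[1])
  expect_equal(sum(res$counts$spliced + res$counts$unspliced), 0L)
  expect_equal(unname(res$qc$assigned), 0L)
  expect_equal(unname(res$qc$bad_plate), 5L)
})

test_that("FASTQ round trip preserves reads, headers and indices", {
  sim <- small_sim(depth_log_mean = log(10), depth_log_sd = 0, seed = 47L)
  scheme <- default_scheme(unique(sim$truth$layout$plate), seed = 53L)
  rd <- simulate_reads(sim$counts[1:20], scheme, example_targets()[1], seed = 59L)
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(rd$reads, path)
  back <- read_fastq(path)
  expect_identical(back, rd$reads)
})

test_that("scheme and layout TSV round trips preserve content", {
  scheme <- default_scheme(c("P01.1", "P01.2"), seed = 61L)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_scheme(scheme, p1)
  back <- read_scheme(p1)
  expect_identical(back$plate_barcodes, scheme$plate_barcodes)
  expect_equal(back$well_indices, scheme$well_indices)
  lay <- make_layout(1L, 2L)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_layout(lay, p2)
  expect_equal(read_layout(p2), lay)
})
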