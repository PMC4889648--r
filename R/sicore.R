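#' Compute splice indices from a count table
#'
#' The splice index of a sample is the ratio of unspliced to spliced read
#' counts, `SI = unspliced / spliced`. With no pseudocount (the default),
#' the index is undefined when `spliced = 0` (`si = NA`,
#' `si_defined = FALSE`); `SI = 0` when `unspliced = 0` is a defined
#' value. A pseudocount, if supplied, is added to both counts.
#'
#' @param counts Count table (columns `spliced`, `unspliced`, plus sample
#'   identifiers which are carried through).
#' @param pseudocount Non-negative value added to both counts (default 0).
#' @return The input with `si` and `si_defined` columns appended.
#' @examples
#' compute_si(data.frame(spliced = c(100, 500, 0), unspliced = c(2, 0, 7)))
#' @export
compute_si <- function(counts, pseudocount = 0) {
  counts <- data.table::as.data.table(counts)
  pseudocount <- check_number(pseudocount, "pseudocount", min = 0)
  if (any(counts$spliced < 0 | counts$unspliced < 0))
    stop("counts must be non-negative", call. = FALSE)
  s <- counts$spliced + pseudocount
  u <- counts$unspliced + pseudocount
  out <- data.table::copy(counts)
  out[, si_defined := s > 0]
  out[, si := ifelse(s > 0, u / s, NA_real_)]
  out[]
}

#' Normalize splice indices by plate median
#'
#' Each 384-well plate's median splice index is taken as representative of
#' wild type, so the relative splice index is
#' `SI_rel = SI / median(SI on the same plate)`. The median is computed
#' per (plate, target, replicate) group over defined indices (even-count
#' groups use the mean of the two central values). Groups whose median is
#' 0, or with fewer than `min_defined` defined records, cannot be
#' normalized: they are flagged and their `si_rel` left undefined.
#'
#' @param si_table Output of [compute_si()] with `plate`, `target`,
#'   `replicate` columns.
#' @param min_defined Minimum defined records per group (default 8).
#' @return Input with `plate_median`, `si_rel` and `plate_flagged`
#'   columns; the per-group medians are retained for audit.
#' @export
plate_normalize <- function(si_table, min_defined = 8L) {
  x <- data.table::copy(data.table::as.data.table(si_table))
  stopifnot(all(c("plate", "target", "replicate", "si", "si_defined") %in% names(x)))
  x[, `:=`(plate_median = {
    v <- si[si_defined]
    if (length(v)) stats::median(v) else NA_real_
  }), by = .(plate, target, replicate)]
  x[, n_defined := sum(si_defined), by = .(plate, target, replicate)]
  x[, plate_flagged := is.na(plate_median) | plate_median == 0 |
      n_defined < min_defined]
  x[, si_rel := ifelse(!plate_flagged & si_defined, si / plate_median, NA_real_)]
  x[, n_defined := NULL]
  x[]
}

#' Collapse replicates into per-strain measurements with QC
#'
#' For each (strain, target): the strain statistic is the mean over
#' replicates of `log2(SI_rel)` (the filter is defined on per-replicate
#' log2 values, so the strain statistic lives on the same scale);
#' `replicate_sd` is the sample SD (n-1 denominator; for two replicates
#' `|a - b| / sqrt(2)`); `combined_reads` is the total spliced + unspliced
#' count over replicates (ambiguous reads excluded). A strain passes QC
#' iff every replicate has a defined, strictly positive `si_rel`, the
#' replicate SD is strictly below `sd_cut`, and the combined read count is
#' strictly above `reads_cut` (both inequalities strict: a combined count
#' of exactly `reads_cut` fails).
#'
#' @param norm_table Output of [plate_normalize()].
#' @param sd_cut Replicate log2 SD cutoff (default 1).
#' @param reads_cut Combined read-count cutoff (default 1000).
#' @return `data.table`: one row per (strain, target) with `log2_si_rel`,
#'   `replicate_sd`, `combined_reads`, `n_replicates`, `passes_qc` and
#'   `qc_reason` (`"ok"` or the first failed check).
#' @export
filter_replicates <- function(norm_table, sd_cut = 1, reads_cut = 1000) {
  x <- data.table::as.data.table(norm_table)
  m <- x[, {
    usable <- !is.na(si_rel) & si_rel > 0
    l2 <- log2(si_rel[usable])
    list(log2_si_rel = if (all(usable)) mean(l2) else NA_real_,
         replicate_sd = if (all(usable) && length(l2) > 1L) stats::sd(l2)
                        else if (all(usable)) NA_real_ else NA_real_,
         combined_reads = sum(spliced + unspliced),
         n_replicates = .N,
         all_defined = all(usable))
  }, by = .(strain_id, target)]
  m[, qc_reason := data.table::fcase(
    !all_defined, "undefined_si_rel",
    !is.na(replicate_sd) & replicate_sd >= sd_cut, "replicate_sd",
    combined_reads <= reads_cut, "low_reads",
    default = "ok")]
  m[, passes_qc := qc_reason == "ok"]
  m[, all_defined := NULL]
  m[]
}

#' Summarize a screen dataset per target
#'
#' Reports, per target: the median splice index and its interquartile
#' range across all samples (replicates counted separately, undefined
#' indices excluded); the replicate R-squared (squared Pearson correlation
#' of replicate 1 vs replicate 2 `log2(SI_rel)` over QC-passing strains;
#' `NA` when fewer than two replicates); and QC pass counts.
#'
#' @param norm_table Output of [plate_normalize()].
#' @param measurements Output of [filter_replicates()].
#' @return `data.table` with one row per target.
#' @export
summarize_dataset <- function(norm_table, measurements) {
  x <- data.table::as.data.table(norm_table)
  m <- data.table::as.data.table(measurements)
  out <- x[, .(median_si = stats::median(si[si_defined]),
               iqr_si = stats::IQR(si[si_defined]),
               n_samples = .N), by = target]
  r2 <- x[replicate <= 2L & !is.na(si_rel) & si_rel > 0,
          .(target, strain_id, replicate, l2 = log2(si_rel))]
  r2 <- merge(r2, m[passes_qc == TRUE, .(strain_id, target)],
              by = c("strain_id", "target"))
  r2w <- data.table::dcast(r2, target + strain_id ~ replicate, value.var = "l2")
  r2s <- if (all(c("1", "2") %in% names(r2w))) {
    r2w[!is.na(`1`) & !is.na(`2`),
        .(replicate_r2 = if (.N >= 3L) stats::cor(`1`, `2`)^2 else NA_real_),
        by = target]
  } else data.table::data.table(target = out$target, replicate_r2 = NA_real_)
  qc <- m[, .(n_strains = .N, n_pass_qc = sum(passes_qc),
              pass_rate = mean(passes_qc)), by = target]
  out <- merge(out, r2s, by = "target", all.x = TRUE)
  merge(out, qc, by = "target", all.x = TRUE)[]
}
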