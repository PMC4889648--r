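#' Fisher's exact test for hit-list overlap
#'
#' Tests whether two hit sets drawn from a common strain universe overlap
#' more than chance expects. With `k` shared hits out of `n_a` and `n_b`
#' hits in a universe of `N`, the 2x2 table is
#' `[[k, n_a - k], [n_b - k, N - n_a - n_b + k]]`; the one-sided
#' (enrichment) p-value is the hypergeometric upper tail `P(X >= k)` and
#' the two-sided p-value sums all table probabilities not exceeding the
#' observed one (the convention of `stats::fisher.test`). The sample odds
#' ratio is reported (`Inf` when a margin cell is empty).
#'
#' @param hits_a,hits_b Character vectors of hit strain ids (must be
#'   subsets of `universe`).
#' @param universe Character vector, the strains eligible to be hits
#'   (e.g. the whole deletion library).
#' @return List of class `overlap_result`: `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `odds_ratio`, `p_one_sided`, `p_two_sided`.
#' @examples
#' overlap_fisher(paste0("s", 1:57), paste0("s", c(1:14, 100:103)),
#'                paste0("s", 1:3020))
#' @export
overlap_fisher <- function(hits_a, hits_b, universe) {
  universe <- unique(as.character(universe))
  hits_a <- unique(as.character(hits_a))
  hits_b <- unique(as.character(hits_b))
  bad <- c(setdiff(hits_a, universe), setdiff(hits_b, universe))
  if (length(bad))
    stop("hits not in universe: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  N <- length(universe)
  na <- length(hits_a); nb <- length(hits_b)
  k <- length(intersect(hits_a, hits_b))
  # hypergeometric: X = |A intersect B| with A fixed, B drawn without
  # replacement from the universe
  p1 <- stats::phyper(k - 1L, na, N - na, nb, lower.tail = FALSE)
  support <- max(0L, na + nb - N):min(na, nb)
  dens <- stats::dhyper(support, na, N - na, nb)
  obs <- stats::dhyper(k, na, N - na, nb)
  p2 <- sum(dens[dens <= obs * (1 + 1e-7)])
  or <- {
    b <- na - k; c <- nb - k; d <- N - na - nb + k
    if (b == 0L || c == 0L) Inf else (k * d) / (b * c)
  }
  structure(list(n_universe = N, n_a = na, n_b = nb, n_overlap = k,
                 odds_ratio = or,
                 p_one_sided = min(p1, 1), p_two_sided = min(p2, 1)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(paste0("<overlap_result> %d/%d vs %d shared in universe of %d; ",
                     "OR = %.3g, one-sided p = %.3g, two-sided p = %.3g\n"),
              x$n_overlap, x$n_a, x$n_b, x$n_universe, x$odds_ratio,
              x$p_one_sided, x$p_two_sided))
  invisible(x)
}

#' Union of per-target hit lists
#'
#' Collects the strains called significant for at least one target into a
#' single table with per-target significance flags and direction of
#' change (sign of `log2(SI_rel)` relative to the null mean, i.e. sign of
#' the Z-score).
#'
#' @param calls_by_target Named list of [call_hits()] outputs (or a single
#'   combined table with a `target` column).
#' @return `data.table`: one row per strain in the union, with columns
#'   `sig_<target>` (logical) and `direction_<target>` (`"up"`, `"down"`
#'   or `NA`), plus `n_targets_significant`.
#' @export
hit_union <- function(calls_by_target) {
  if (data.table::is.data.table(calls_by_target) ||
      is.data.frame(calls_by_target)) {
    x <- data.table::as.data.table(calls_by_target)
    calls_by_target <- split(x, x$target)
  }
  stopifnot(is.list(calls_by_target), length(calls_by_target) > 0)
  hits <- lapply(calls_by_target, function(cc) {
    cc <- data.table::as.data.table(cc)
    cc[significant == TRUE,
       .(strain_id, sig = TRUE, direction = ifelse(z > 0, "up", "down"))]
  })
  all_ids <- sort(unique(unlist(lapply(hits, `[[`, "strain_id"))))
  out <- data.table::data.table(strain_id = all_ids)
  for (t in names(hits)) {
    h <- hits[[t]]
    out[, paste0("sig_", t) := strain_id %in% h$strain_id]
    out[, paste0("direction_", t) :=
          h$direction[match(strain_id, h$strain_id)]]
  }
  sig_cols <- grep("^sig_", names(out), value = TRUE)
  out[, n_targets_significant := rowSums(.SD), .SDcols = sig_cols]
  out[]
}

#' Run the full screen pipeline
#'
#' End-to-end orchestration of the screen analysis: counts (simulated
#' from a [simulation_config()] or supplied as a table/TSV) -> splice
#' indices -> plate-median normalization -> replicate QC -> per-target
#' depth-binned spline null -> Z/p/BH calls -> hit union and cross-target
#' overlap. All intermediate tables, the null-model dumps and a run
#' summary are returned, and written as TSV/JSON when `out_dir` is given.
#'
#' @param config A [simulation_config()] (simulate mode), or `NULL`.
#' @param counts A count table or TSV path (analysis mode), or `NULL`.
#'   Exactly one of `config`/`counts` must be supplied.
#' @param out_dir Optional output directory (created if needed).
#' @param B Number of depth bins (default 20).
#' @param alpha BH FDR level (default 0.05).
#' @param sd_cut,reads_cut QC cutoffs passed to [filter_replicates()].
#' @param universe Overlap-test universe: `"layout"` (default, all strains
#'   in the library) or `"qc_both"` (strains passing QC for every target).
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return List of class `screen_report`: `counts`, `truth` (simulate mode
#'   only), `si`, `measurements`, `summary`, `bins`, `models`, `calls`,
#'   `union`, `overlap` (for exactly two targets), `settings`.
#' @export
run_screen_pipeline <- function(config = NULL, counts = NULL, out_dir = NULL,
                                B = 20L, alpha = 0.05, sd_cut = 1,
                                reads_cut = 1000,
                                universe = c("layout", "qc_both"),
                                quiet = TRUE) {
  universe <- match.arg(universe)
  if (is.null(config) == is.null(counts))
    stop("supply exactly one of `config` (simulate mode) or `counts`",
         call. = FALSE)
  say <- function(...) if (!quiet) message("[splicescreen] ", sprintf(...))
  truth <- NULL
  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    say("simulating counts (seed %d)", config$seed)
    sim <- simulate_counts(config)
    counts <- sim$counts
    truth <- sim$truth
  } else if (is.character(counts)) {
    say("reading counts from %s", counts)
    counts <- read_counts(counts)
  } else {
    counts <- read_counts_table(counts)
  }

  say("computing splice indices for %d samples", nrow(counts))
  si <- compute_si(counts)
  si <- plate_normalize(si)
  meas <- filter_replicates(si, sd_cut = sd_cut, reads_cut = reads_cut)
  summ <- summarize_dataset(si, meas)

  tnames <- sort(unique(meas$target))
  bins <- list(); models <- list(); calls <- list()
  for (t in tnames) {
    say("fitting null model for %s", t)
    bt <- bin_by_depth(meas[target == t], B = B)
    mt <- fit_null_spline(bt, target = t)
    ct <- call_hits(score_strains(meas[target == t], mt), alpha = alpha)
    bins[[t]] <- bt; models[[t]] <- mt; calls[[t]] <- ct
  }
  union_tab <- hit_union(calls)

  overlap <- NULL
  if (length(tnames) == 2L) {
    uni <- if (universe == "layout") unique(counts$strain_id)
           else Reduce(intersect, lapply(tnames, function(t)
             meas[target == t & passes_qc == TRUE, strain_id]))
    overlap <- overlap_fisher(calls[[1L]][significant == TRUE, strain_id],
                              calls[[2L]][significant == TRUE, strain_id],
                              uni)
  }

  settings <- list(B = B, alpha = alpha, sd_cut = sd_cut,
                   reads_cut = reads_cut, universe = universe,
                   mode = if (is.null(truth)) "analyze" else "simulate",
                   seed = if (is.null(truth)) NA_integer_ else config$seed)
  report <- structure(list(counts = counts, truth = truth, si = si,
                           measurements = meas, summary = summ, bins = bins,
                           models = models, calls = calls, union = union_tab,
                           overlap = overlap, settings = settings),
                      class = "screen_report")
  if (!is.null(out_dir)) write_report(report, out_dir, say)
  report
}

read_counts_table <- function(x) {
  x <- data.table::as.data.table(x)
  need <- c("strain_id", "target", "replicate", "plate", "well",
            "spliced", "unspliced")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("counts table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"ambiguous" %in% names(x)) x[, ambiguous := 0L]
  x
}

write_report <- function(report, out_dir, say = function(...) NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv(report$counts, p("counts.tsv"))
  write_tsv(report$si, p("splice_index.tsv"))
  write_tsv(report$measurements, p("strain_measurements.tsv"))
  write_tsv(report$summary, p("summary.tsv"))
  write_tsv(data.table::rbindlist(report$bins, idcol = "target"), p("bins.tsv"))
  for (t in names(report$models))
    dump_null_model(report$models[[t]], p(sprintf("null_model_%s.json", t)))
  write_tsv(data.table::rbindlist(report$calls), p("calls.tsv"))
  write_tsv(report$union, p("hit_union.tsv"))
  if (!is.null(report$truth)) {
    write_tsv(report$truth$strains, p("truth_strains.tsv"))
    write_tsv(report$truth$layout, p("layout.tsv"))
  }
  lines <- summary_text(report)
  writeLines(lines, p("summary.txt"))
  say("report written to %s", out_dir)
  invisible(out_dir)
}

summary_text <- function(report) {
  s <- report$summary
  lines <- c("splicescreen run summary",
             sprintf("mode: %s  seed: %s  B=%d alpha=%g sd_cut=%g reads_cut=%g",
                     report$settings$mode, report$settings$seed,
                     report$settings$B, report$settings$alpha,
                     report$settings$sd_cut, report$settings$reads_cut))
  for (i in seq_len(nrow(s))) {
    t <- s$target[i]
    nhit <- sum(report$calls[[t]]$significant)
    lines <- c(lines, sprintf(
      "%s: median SI %.4g, IQR %.4g, replicate R2 %.3g, QC pass %d/%d (%.1f%%), hits %d",
      t, s$median_si[i], s$iqr_si[i], s$replicate_r2[i], s$n_pass_qc[i],
      s$n_strains[i], 100 * s$pass_rate[i], nhit))
  }
  lines <- c(lines, sprintf("hit union: %d strains", nrow(report$union)))
  if (!is.null(report$overlap)) {
    o <- report$overlap
    lines <- c(lines, sprintf(
      "overlap: %d shared of %d and %d (universe %d), one-sided Fisher p = %.3g",
      o$n_overlap, o$n_a, o$n_b, o$n_universe, o$p_one_sided))
  }
  lines
}

#' @export
print.screen_report <- function(x, ...) {
  cat(paste(summary_text(x), collapse = "\n"), "\n")
  invisible(x)
}
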