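#' Configuration for a synthetic screen
#'
#' Describes the stated world the generator draws from: an arrayed
#' deletion library on 384-well plates, grown in duplicate, assayed by
#' amplicon sequencing for one or more intron targets. Per-sample total
#' read depths are log-normal (spanning roughly two orders of magnitude at
#' the default `depth_log_sd`); per-strain true splice indices are
#' log-normal around `baseline_si`; unspliced read counts are
#' beta-binomial with intra-class correlation `overdispersion_rho`,
#' capturing replicate scatter beyond counting noise. A fraction of
#' strains is "spiked" with a true splicing defect (fold change of the
#' true splice index drawn log-uniformly from `effect_log2_range`).
#'
#' Defaults were calibrated once against the published screen's summary
#' statistics (median splice index about 0.02, interquartile range about
#' 0.01, replicate R-squared 0.2-0.4, >99% of strains passing quality
#' filters) and are fixed; see the package vignette.
#'
#' @param n_plates Number of 384-well plates (strains = 384 * n_plates).
#' @param n_replicates Biological replicates per strain (default 2).
#' @param targets List of [target_spec()]s (default [example_targets()]).
#' @param depth_log_mean,depth_log_sd Meanlog/sdlog of the log-normal
#'   per-sample total read depth (defaults `log(5000)` and 0.9).
#' @param baseline_si Median true splice index of null strains (default 0.02).
#' @param si_log_sd Strain-to-strain SD of log2 true splice index (default 0.3).
#' @param overdispersion_rho Beta-binomial intra-class correlation in
#'   `[0, 1)` (default 3e-4). Note this acts on the binomial rate, so even
#'   1e-3 is substantial when the unspliced fraction is ~2%.
#' @param spiked_fraction Fraction of strains given a true effect (default 0.02).
#' @param effect_log2_range Length-2 numeric, `[min, max]` log2 fold change
#'   of true splice index for spiked strains (default `c(2, 5)`).
#' @param effect_direction `"up"` (default; splicing defects accumulate
#'   pre-mRNA), `"down"`, or `"both"` (random sign per strain).
#' @param plate_effect_sd SD of the additive log2 plate offset applied per
#'   physical plate and target (default 0.2; exercises plate-median
#'   normalization). Set 0 to disable.
#' @param shared_spikes Logical; if `TRUE` (default) the same strains are
#'   spiked for every target, mimicking general splicing factors.
#' @param seed Integer RNG seed; all generator randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_plates = 8L, n_replicates = 2L,
                              targets = example_targets(),
                              depth_log_mean = log(5000), depth_log_sd = 0.9,
                              baseline_si = 0.02, si_log_sd = 0.3,
                              overdispersion_rho = 3e-4,
                              spiked_fraction = 0.02,
                              effect_log2_range = c(2, 5),
                              effect_direction = c("up", "down", "both"),
                              plate_effect_sd = 0.2,
                              shared_spikes = TRUE,
                              seed = 1L) {
  if (!is.list(targets) || !length(targets) ||
      !all(vapply(targets, inherits, logical(1), "target_spec")))
    stop("invalid configuration field `targets`: need a list of target_spec",
         call. = FALSE)
  if (!is.numeric(effect_log2_range) || length(effect_log2_range) != 2L ||
      effect_log2_range[1] > effect_log2_range[2])
    stop("invalid configuration field `effect_log2_range`", call. = FALSE)
  cfg <- list(
    n_plates = check_number(n_plates, "n_plates", min = 1, integer = TRUE),
    n_replicates = check_number(n_replicates, "n_replicates", min = 1, integer = TRUE),
    targets = targets,
    depth_log_mean = check_number(depth_log_mean, "depth_log_mean"),
    depth_log_sd = check_number(depth_log_sd, "depth_log_sd", min = 0),
    baseline_si = check_number(baseline_si, "baseline_si", min = 0, strict_min = TRUE),
    si_log_sd = check_number(si_log_sd, "si_log_sd", min = 0),
    overdispersion_rho = check_number(overdispersion_rho, "overdispersion_rho",
                                      min = 0, max = 1 - 1e-12),
    spiked_fraction = check_number(spiked_fraction, "spiked_fraction",
                                   min = 0, max = 1),
    effect_log2_range = as.numeric(effect_log2_range),
    effect_direction = match.arg(effect_direction),
    plate_effect_sd = check_number(plate_effect_sd, "plate_effect_sd", min = 0),
    shared_spikes = isTRUE(shared_spikes),
    seed = check_number(seed, "seed", integer = TRUE)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d plate(s) x 384 wells x %d replicate(s), ",
                     "%d target(s); baseline SI %.3g, %.0f%% spiked, seed %d\n"),
              x$n_plates, x$n_replicates, length(x$targets), x$baseline_si,
              100 * x$spiked_fraction, x$seed))
  invisible(x)
}

# Library layout: one strain per (logical plate, well); each replicate is a
# separate physical plate labelled "<plate>.<replicate>" with its own
# plate barcode and its own median normalization group.
make_layout <- function(n_plates, n_replicates) {
  wells <- well_names_384()
  lay <- data.table::CJ(plate_num = seq_len(n_plates), well = wells,
                        replicate = seq_len(n_replicates), sorted = FALSE)
  data.table::setorder(lay, plate_num, well, replicate)
  lay[, strain_id := sprintf("strain_%05d",
                             (plate_num - 1L) * 384L + match(well, wells))]
  lay[, plate := sprintf("P%02d.%d", plate_num, replicate)]
  lay[, plate_num := NULL]
  lay[, .(plate, well, strain_id, replicate)]
}

#' Simulate a screen's spliced/unspliced count table
#'
#' Draws, for every (strain, target, replicate) sample, a total read depth
#' from the configured log-normal, then an unspliced count from a
#' beta-binomial with success probability `true_si / (1 + true_si)` (after
#' applying the plate offset) and intra-class correlation
#' `overdispersion_rho`; the spliced count is the remainder. Deterministic
#' given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with elements
#'   \describe{
#'     \item{counts}{`data.table` with one row per sample: `strain_id`,
#'       `target`, `replicate`, `plate` (physical plate label), `well`,
#'       `spliced`, `unspliced`, `ambiguous` (always 0 here).}
#'     \item{truth}{`screen_truth`: `$strains` (per strain/target
#'       `true_si`, `is_spiked`, `effect_log2`), `$samples` (per-sample
#'       `total_depth`), `$layout`, `$plate_effects`, and the config.}
#'   }
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lay <- make_layout(config$n_plates, config$n_replicates)
    strains <- unique(lay$strain_id)
    n <- length(strains)
    tnames <- vapply(config$targets, `[[`, character(1), "name")

    # per-strain baseline SI (biological spread), shared across targets
    base_si <- config$baseline_si * 2^rnorm(n, 0, config$si_log_sd)

    # spiked strains and per-(strain, target) effects
    n_spiked <- round(config$spiked_fraction * n)
    spiked <- sample(strains, n_spiked)
    truth <- data.table::CJ(strain_id = strains, target = tnames, sorted = FALSE)
    truth[, is_spiked := strain_id %in% spiked]
    if (!config$shared_spikes && n_spiked > 0) {
      # independent spike sets per target (same count)
      truth[, is_spiked := strain_id %in% sample(strains, n_spiked), by = target]
    }
    truth[, effect_log2 := 0]
    nsp <- sum(truth$is_spiked)
    if (nsp > 0) {
      mag <- runif(nsp, config$effect_log2_range[1], config$effect_log2_range[2])
      sgn <- switch(config$effect_direction,
                    up = 1, down = -1,
                    both = sample(c(-1, 1), nsp, replace = TRUE))
      truth[is_spiked == TRUE, effect_log2 := mag * sgn]
      if (config$shared_spikes && length(tnames) > 1L) {
        # one effect size per strain, copied to every target
        first <- truth[target == tnames[1L], .(strain_id, effect_log2)]
        truth[, effect_log2 := first$effect_log2[match(strain_id, first$strain_id)]]
      }
    }
    truth[, true_si := base_si[match(strain_id, strains)] * 2^effect_log2]

    # per (physical plate, target) multiplicative offset on SI
    plates <- unique(lay$plate)
    pe <- data.table::CJ(plate = plates, target = tnames, sorted = FALSE)
    pe[, offset_log2 := if (config$plate_effect_sd > 0)
      rnorm(.N, 0, config$plate_effect_sd) else 0]

    samples <- data.table::rbindlist(lapply(tnames, function(t)
      data.table::copy(lay)[, target := t]))
    samples <- merge(samples, truth[, .(strain_id, target, true_si)],
                     by = c("strain_id", "target"), sort = FALSE)
    samples <- merge(samples, pe, by = c("plate", "target"), sort = FALSE)
    data.table::setorder(samples, target, plate, well)

    m <- nrow(samples)
    samples[, total_depth := pmax(1L, as.integer(round(
      rlnorm(m, config$depth_log_mean, config$depth_log_sd))))]
    samples[, si_sample := true_si * 2^offset_log2]
    samples[, pi := si_sample / (1 + si_sample)]
    rho <- config$overdispersion_rho
    p <- if (rho > 0) {
      nu <- 1 / rho - 1
      rbeta(m, samples$pi * nu, (1 - samples$pi) * nu)
    } else samples$pi
    samples[, unspliced := rbinom(m, total_depth, p)]
    samples[, spliced := total_depth - unspliced]
    samples[, ambiguous := 0L]

    counts <- samples[, .(strain_id, target, replicate, plate, well,
                          spliced, unspliced, ambiguous)]
    tr <- structure(list(
      strains = truth[, .(strain_id, target, true_si, is_spiked, effect_log2)],
      samples = samples[, .(strain_id, target, replicate, plate, well, total_depth)],
      layout = lay,
      plate_effects = pe,
      config = config), class = "screen_truth")
    list(counts = counts[], truth = tr)
  })
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf("<screen_truth> %d strains x %d target(s); %d spiked\n",
              data.table::uniqueN(x$strains$strain_id),
              data.table::uniqueN(x$strains$target),
              data.table::uniqueN(x$strains[is_spiked == TRUE, strain_id])))
  invisible(x)
}

#' Simulate barcoded amplicon reads from a count table
#'
#' Emits, for every sample row, exactly `spliced` reads drawn from the
#' spliced isoform and `unspliced` reads from the unspliced isoform. Each
#' read is the plate barcode followed by the amplicon 5' prefix, truncated
#' at `read_length` (amplicon reads start at the forward primer, so all
#' reads of a target share their start). The well index pair is carried in
#' the read header as `index1+index2`, mimicking Illumina index reads.
#'
#' @param counts Count table as produced by [simulate_counts()] (columns
#'   `plate`, `well`, `target`, `spliced`, `unspliced`).
#' @param scheme A [barcode_scheme()] covering all plates and wells used.
#' @param targets List of [target_spec()]s covering all targets used.
#' @param read_length Read length in nt including the plate barcode
#'   (default 60). Must be at least barcode length + 2k, and long enough
#'   to span the exon junction (`barcode + nchar(exon5) + k`).
#' @param seed RNG seed (read order shuffle and sequencing errors).
#' @param error_rate Per-base uniform substitution probability (default 0).
#' @return List with `reads` (`data.table`: `id`, `sequence`, `index1`,
#'   `index2`) and `manifest` (`data.table`: `read_id`, `plate`, `well`,
#'   `target`, `isoform`), the ground truth for every read.
#' @export
simulate_reads <- function(counts, scheme, targets, read_length = 60L,
                           seed = 1L, error_rate = 0) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  counts <- data.table::as.data.table(counts)
  read_length <- check_number(read_length, "read_length", min = 1, integer = TRUE)
  error_rate <- check_number(error_rate, "error_rate", min = 0, max = 1)
  tnames <- vapply(targets, `[[`, character(1), "name")
  names(targets) <- tnames
  bc <- scheme$plate_barcodes
  bclen <- nchar(bc[[1L]])
  kmax <- max(vapply(targets, `[[`, integer(1), "junction_flank_k"))
  if (read_length < bclen + 2L * kmax)
    stop("read_length must be at least plate barcode length + 2*junction_flank_k",
         call. = FALSE)
  missing_plates <- setdiff(unique(counts$plate), names(bc))
  if (length(missing_plates))
    stop("plates missing from scheme: ", paste(missing_plates, collapse = ", "),
         call. = FALSE)
  missing_targets <- setdiff(unique(counts$target), tnames)
  if (length(missing_targets))
    stop("targets unknown: ", paste(missing_targets, collapse = ", "),
         call. = FALSE)
  for (t in targets)
    if (read_length - bclen < nchar(t$exon5) + t$junction_flank_k)
      warning("reads too short to span the exon junction of target ", t$name,
              "; such reads will classify as ambiguous", call. = FALSE)

  iso_prefix <- function(iso_seq) substr(iso_seq, 1L, read_length - bclen)
  spl_prefix <- vapply(targets, function(t) iso_prefix(spliced_isoform(t)),
                       character(1))
  uns_prefix <- vapply(targets, function(t) iso_prefix(unspliced_isoform(t)),
                       character(1))

  cnt <- counts[, .(plate, well, target, spliced, unspliced)]
  long <- rbind(
    cnt[spliced > 0, .(plate, well, target, isoform = "spliced", n = spliced)],
    cnt[unspliced > 0, .(plate, well, target, isoform = "unspliced", n = unspliced)])
  if (nrow(long) == 0L) {
    empty_reads <- data.table::data.table(id = character(), sequence = character(),
                                          index1 = character(), index2 = character())
    empty_man <- data.table::data.table(read_id = character(), plate = character(),
                                        well = character(), target = character(),
                                        isoform = character())
    return(list(reads = empty_reads, manifest = empty_man))
  }
  reads <- long[rep(seq_len(.N), n)][, n := NULL]
  with_seed(seed, {
    reads <- reads[sample(.N)]
    reads[, read_id := sprintf("r%08d", seq_len(.N))]
    body <- ifelse(reads$isoform == "spliced",
                   spl_prefix[reads$target], uns_prefix[reads$target])
    seqs <- paste0(bc[reads$plate], body)
    if (error_rate > 0) seqs <- mutate_seqs(seqs, error_rate)
    wi <- scheme$well_indices
    widx <- match(reads$well, wi$well)
    if (anyNA(widx))
      stop("wells missing from scheme: ",
           paste(unique(reads$well[is.na(widx)]), collapse = ", "), call. = FALSE)
    out_reads <- data.table::data.table(id = reads$read_id, sequence = seqs,
                                        index1 = wi$index1[widx],
                                        index2 = wi$index2[widx])
    manifest <- reads[, .(read_id, plate, well, target, isoform)]
    list(reads = out_reads, manifest = manifest)
  })
}

# Uniform substitutions: each base mutates to one of the 3 other bases
# with probability `rate`. Sequences may differ in length.
mutate_seqs <- function(seqs, rate) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                  nrow = 4, byrow = TRUE)
    base_i <- match(flat[hit], c("A", "C", "G", "T"))
    flat[hit] <- alt[cbind(base_i, sample(3L, length(hit), replace = TRUE))]
  }
  grp <- rep(seq_along(seqs), lens)
  vapply(split(flat, grp), paste, character(1), collapse = "")
}

#' Simulate a mixing series of known isoform ratios
#'
#' Generates samples containing known molecular ratios of unspliced to
#' total molecules, sampled binomially at a fixed depth -- the in-silico
#' analogue of the bench validation in which defined isoform mixtures are
#' sequenced to check accuracy and linearity of ratio recovery.
#'
#' @param ratios Numeric vector of unspliced molecule fractions in `[0, 1]`.
#' @param depth Total reads per sample.
#' @param target A [target_spec()].
#' @param seed RNG seed.
#' @return `data.table` of sample counts with `true_fraction` and the
#'   implied true splice index `true_si = f / (1 - f)`.
#' @export
make_mixing_series <- function(ratios, depth, target, seed = 1L) {
  if (!is.numeric(ratios) || !length(ratios) || anyNA(ratios) ||
      any(ratios < 0 | ratios > 1))
    stop("ratios must be in [0, 1]", call. = FALSE)
  depth <- check_number(depth, "depth", min = 1, integer = TRUE)
  stopifnot(inherits(target, "target_spec"))
  with_seed(seed, {
    uns <- rbinom(length(ratios), depth, ratios)
    data.table::data.table(
      strain_id = sprintf("mix_%03d", seq_along(ratios)),
      target = target$name, replicate = 1L, plate = "MIX.1",
      well = well_names_384()[seq_along(ratios)],
      spliced = depth - uns, unspliced = uns, ambiguous = 0L,
      true_fraction = ratios,
      true_si = ifelse(ratios < 1, ratios / (1 - ratios), Inf))
  })
}
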