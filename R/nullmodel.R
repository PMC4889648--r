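#' Bin QC-passing strains by read depth
#'
#' Sorts strains by combined read count (ties broken by strain id for
#' determinism) and splits them into `B` contiguous rank-based bins of
#' near-equal size: with `n = q*B + r`, the first `r` bins get `q + 1`
#' members and the rest `q`. Each bin records the mean log10 combined
#' reads of its members (`x`), and the mean (`mu`) and sample SD (`sigma`)
#' of their `log2(SI_rel)` -- the data points through which the null
#' spline is drawn.
#'
#' @param measurements Output of [filter_replicates()] for one target;
#'   only QC-passing rows are used.
#' @param B Number of bins (default 20).
#' @return `data.table` with one row per bin: `bin_index` (0-based), `x`,
#'   `mu`, `sigma`, `n_members`, and the member depth range.
#' @export
bin_by_depth <- function(measurements, B = 20L) {
  B <- check_number(B, "B", min = 1, integer = TRUE)
  m <- data.table::as.data.table(measurements)
  m <- m[passes_qc == TRUE]
  n <- nrow(m)
  if (n < 2L * B)
    stop("need at least 2*B = ", 2L * B, " QC-passing strains to form ", B,
         " bins; lower B", call. = FALSE)
  data.table::setorder(m, combined_reads, strain_id)
  q <- n %/% B; r <- n %% B
  sizes <- rep(q, B) + (seq_len(B) <= r)
  m[, bin_index := rep(seq_len(B) - 1L, times = sizes)]
  m[, .(x = mean(log10(combined_reads)),
        mu = mean(log2_si_rel),
        sigma = stats::sd(log2_si_rel),
        n_members = .N,
        reads_min = min(combined_reads),
        reads_max = max(combined_reads)),
    by = bin_index][]
}

#' Fit the depth-dependent empirical null
#'
#' Natural cubic interpolating splines through the bin statistics give the
#' null mean and SD of `log2(SI_rel)` as smooth functions of log10 read
#' depth: `mu(x)` through the `(x, mu)` knots and `sigma(x)` through
#' `(x, sigma)`. Both pass exactly through every knot. Outside the knot
#' range the functions are clamped to the boundary knot values (cubic
#' extrapolation could drive sigma negative); `sigma` is additionally
#' floored at `sigma_floor` everywhere. Duplicate knot abscissae are
#' merged by averaging, with a warning.
#'
#' @param bins Output of [bin_by_depth()].
#' @param sigma_floor Lower bound on sigma (default 1e-6).
#' @param target Optional target label stored in the model.
#' @return An object of class `splice_null_model` with elements `knots`,
#'   `mu` and `sigma` (functions of `x = log10(combined reads)`),
#'   `x_range`, `sigma_floor`, `target`.
#' @export
fit_null_spline <- function(bins, sigma_floor = 1e-6, target = NA_character_) {
  bins <- data.table::as.data.table(bins)
  stopifnot(all(c("x", "mu", "sigma") %in% names(bins)))
  sigma_floor <- check_number(sigma_floor, "sigma_floor", min = 0)
  kn <- bins[, .(x, mu, sigma)]
  if (anyDuplicated(kn$x)) {
    warning("duplicate knot x values merged by averaging", call. = FALSE)
    kn <- kn[, .(mu = mean(mu), sigma = mean(sigma)), by = x]
  }
  data.table::setorder(kn, x)
  if (nrow(kn) < 4L)
    stop("need at least 4 bins with distinct x to fit the null spline",
         call. = FALSE)
  mu_f <- stats::splinefun(kn$x, kn$mu, method = "natural")
  sd_f <- stats::splinefun(kn$x, kn$sigma, method = "natural")
  xr <- range(kn$x)
  structure(list(
    knots = kn[],
    mu = function(x) mu_f(pmin(pmax(x, xr[1]), xr[2])),
    sigma = function(x) pmax(sd_f(pmin(pmax(x, xr[1]), xr[2])), sigma_floor),
    x_range = xr, sigma_floor = sigma_floor, target = target),
    class = "splice_null_model")
}

#' @export
print.splice_null_model <- function(x, ...) {
  cat(sprintf("<splice_null_model>%s %d knots over log10 reads [%.2f, %.2f]\n",
              if (is.na(x$target)) "" else paste0(" ", x$target),
              nrow(x$knots), x$x_range[1], x$x_range[2]))
  invisible(x)
}

#' Serialize a null model's knots and settings to JSON
#'
#' The dump contains everything needed to reproduce the interpolators
#' (knots, sigma floor, x range); [load_null_model()] rebuilds the model.
#'
#' @param model A `splice_null_model`.
#' @param path JSON file path.
#' @export
dump_null_model <- function(model, path) {
  jsonlite::write_json(list(target = model$target,
                            sigma_floor = model$sigma_floor,
                            knots = model$knots),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname dump_null_model
#' @export
load_null_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_null_spline(data.table::as.data.table(x$knots),
                  sigma_floor = x$sigma_floor,
                  target = if (is.null(x$target)) NA_character_ else x$target)
}

#' Score strains against the empirical null
#'
#' For each QC-passing strain, at `x = log10(combined_reads)`:
#' `Z = (log2(SI_rel) - mu(x)) / sigma(x)`, two-sided normal p-value
#' `p = 2 * (1 - Phi(|Z|))`, and the 95% confidence interval
#' `log2(SI_rel) +/- 2 * sigma(x)` given the read depth of that strain.
#'
#' @param measurements Output of [filter_replicates()]; rows failing QC
#'   are excluded (their reasons are retained upstream).
#' @param model A `splice_null_model` fitted on the same target.
#' @return `data.table`: `strain_id`, `target`, `log2_si_rel`,
#'   `combined_reads`, `z`, `p`, `ci_low`, `ci_high`.
#' @export
score_strains <- function(measurements, model) {
  stopifnot(inherits(model, "splice_null_model"))
  m <- data.table::as.data.table(measurements)
  m <- m[passes_qc == TRUE]
  x <- log10(m$combined_reads)
  mu <- model$mu(x)
  sg <- model$sigma(x)
  z <- (m$log2_si_rel - mu) / sg
  p <- pmin(2 * stats::pnorm(-abs(z)), 1)
  m[, .(strain_id, target, log2_si_rel, combined_reads,
        z = z, p = p,
        ci_low = log2_si_rel - 2 * sg, ci_high = log2_si_rel + 2 * sg)][]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR correction: with sorted p-values `p_(1) <= ... <=
#' p_(m)`, `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1. Input order
#' is preserved in the output.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Numeric vector of adjusted q-values, same order as `p`.
#' @export
bh_correct <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)            # largest first
  q_sorted <- cummin(m * p[o] / (m:1))        # running min from the top
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Call significant strains
#'
#' Appends BH q-values (computed across all scored strains, per target)
#' and flags strains significant iff `q < alpha` (strict: `q` exactly at
#' `alpha` is not called). The result is sorted by `q`, then decreasing
#' `|z|`.
#'
#' @param results Output of [score_strains()].
#' @param alpha FDR level (default 0.05).
#' @return `results` with `q` and `significant` columns, sorted.
#' @export
call_hits <- function(results, alpha = 0.05) {
  r <- data.table::copy(data.table::as.data.table(results))
  alpha <- check_number(alpha, "alpha", min = 0, max = 1)
  if (data.table::uniqueN(r$target) > 1L)
    r[, q := bh_correct(p), by = target]
  else
    r[, q := bh_correct(p)]
  r[, significant := q < alpha]
  r[, .abs_z := abs(z)]
  data.table::setorder(r, q, -.abs_z)
  r[, .abs_z := NULL]
  r[]
}
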