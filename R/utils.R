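#' @import data.table
#' @importFrom stats median rnorm rlnorm rbinom rbeta rbinom sd cor quantile
#'   IQR splinefun pnorm dhyper phyper runif setNames
#' @importFrom utils head tail
NULL

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Scalar checks used by the configuration constructors; `what` names the
# offending field in the error so callers can fix their config.
check_number <- function(x, what, min = -Inf, max = Inf,
                         strict_min = FALSE, integer = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_min) x > min else x >= min) && x <= max &&
    (!integer || x == round(x))
  if (!ok)
    stop(sprintf("invalid configuration field `%s`: %s", what,
                 paste(format(x), collapse = ",")), call. = FALSE)
  if (integer) as.integer(x) else as.numeric(x)
}

check_dna <- function(x, what, allow_n = FALSE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L ||
      grepl(sprintf("[^%s]", alphabet), x))
    stop(sprintf("invalid configuration field `%s`: must be a nonempty %s string",
                 what, alphabet), call. = FALSE)
  x
}

# Hamming distance between equal-length strings (vectorized over `a`;
# `b` is recycled if scalar).
hamming_dist <- function(a, b) {
  if (length(b) == 1L) b <- rep(b, length(a))
  if (length(a) == 1L) a <- rep(a, length(b))
  stopifnot(length(a) == length(b), all(nchar(a) == nchar(b)))
  am <- matrix(unlist(strsplit(a, "", fixed = TRUE)), nrow = length(a), byrow = TRUE)
  bm <- matrix(unlist(strsplit(b, "", fixed = TRUE)), nrow = length(b), byrow = TRUE)
  rowSums(am != bm)
}

# For each query, index of the unique reference within `max_mm` mismatches
# (NA if none). Queries must share the references' width.
match_with_mismatch <- function(queries, refs, max_mm) {
  hit <- match(queries, refs)            # exact matches first
  if (max_mm > 0L && anyNA(hit)) {
    todo <- unique(queries[is.na(hit)])
    todo <- todo[nchar(todo) == nchar(refs[1L])]
    if (length(todo)) {
      qm <- matrix(unlist(strsplit(todo, "", fixed = TRUE)),
                   nrow = length(todo), byrow = TRUE)
      best <- rep(NA_integer_, length(todo))
      best_d <- rep(Inf, length(todo))
      for (j in seq_along(refs)) {
        rj <- strsplit(refs[j], "", fixed = TRUE)[[1L]]
        d <- rowSums(qm != matrix(rj, nrow = nrow(qm), ncol = length(rj),
                                  byrow = TRUE))
        upd <- d < best_d
        best[upd] <- j
        best_d[upd] <- d[upd]
      }
      best[best_d > max_mm] <- NA_integer_
      hit[is.na(hit)] <- best[match(queries[is.na(hit)], todo)]
    }
  }
  hit
}

# Sample-median convention used throughout: stats::median (mean of the two
# central order statistics for even n).
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                    data.table = TRUE)
}
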