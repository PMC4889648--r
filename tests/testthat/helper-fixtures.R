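# Shared fixtures, built in code at test time.

# A minimal target with hand-checkable junctions (k = 3).
toy_target <- function(k = 3L) {
  target_spec("toy",
              exon5  = "AACCGGTTAC",
              intron = "GTATGCCTAG",
              exon3  = "CTTGAGCATG",
              junction_flank_k = k)
}

# Small simulated screen; single target unless stated.
small_sim <- function(n_plates = 1L, seed = 42L, ...) {
  simulate_counts(simulation_config(n_plates = n_plates, seed = seed,
                                    targets = example_targets()[1], ...))
}

# Measurements table built directly (bypassing the generator) for null-model
# unit tests: all rows QC-passing.
fake_measurements <- function(n, log2_si_rel, combined_reads,
                              target = "t1") {
  data.table::data.table(
    strain_id = sprintf("s%05d", seq_len(n)), target = target,
    log2_si_rel = log2_si_rel, replicate_sd = 0,
    combined_reads = as.integer(combined_reads), n_replicates = 2L,
    qc_reason = "ok", passes_qc = TRUE)
}

# Brute-force BH step-up: literal definition, independent of bh_correct.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(pmin(m * p[o[js]] / js, 1))
  }
  q
}

# Brute-force hypergeometric overlap test by enumeration of all possible
# overlap counts (for small universes).
overlap_oracle <- function(k, na, nb, N) {
  support <- max(0L, na + nb - N):min(na, nb)
  dens <- exp(lchoose(na, support) + lchoose(N - na, nb - support) -
                lchoose(N, nb))
  obs <- dens[match(k, support)]
  list(p_one_sided = sum(dens[support >= k]),
       p_two_sided = sum(dens[dens <= obs * (1 + 1e-7)]))
}
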