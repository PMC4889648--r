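test_that("bin_by_depth forms near-equal rank-based bins", {
  m <- fake_measurements(3000L, rnorm(3000), sample(1001:100000, 3000, TRUE))
  b <- bin_by_depth(m, B = 20L)
  expect_equal(nrow(b), 20L)
  expect_true(all(b$n_members == 150L))      # 3000 / 20 exactly
  expect_equal(b$bin_index, 0:19)
  # remainder rule: n = 101, B = 20 -> one bin of 6, nineteen of 5
  m2 <- fake_measurements(101L, rnorm(101), sample(1001:50000, 101))
  b2 <- bin_by_depth(m2, B = 20L)
  expect_equal(sort(b2$n_members, decreasing = TRUE), c(6L, rep(5L, 19L)))
  # bins partition by depth rank: x strictly increasing
  expect_true(all(diff(b$x) > 0))
  expect_true(all(diff(b2$reads_min) >= 0))
  # constant response -> mu = c, sigma = 0 in every bin
  m3 <- fake_measurements(100L, rep(0.7, 100), sample(1001:9999, 100))
  b3 <- bin_by_depth(m3, B = 10L)
  expect_equal(b3$mu, rep(0.7, 10L))
  expect_equal(b3$sigma, rep(0, 10L))
  # too few strains
  expect_error(bin_by_depth(fake_measurements(30L, rnorm(30), 1:30 + 1000L),
                            B = 20L), "lower B")
})

test_that("fit_null_spline interpolates knots exactly and clamps outside", {
  bins <- data.table::data.table(x = c(2, 2.5, 3, 3.7, 4.4, 5),
                                 mu = c(0.1, -0.05, 0.02, 0, 0.03, -0.01),
                                 sigma = c(0.9, 0.6, 0.4, 0.3, 0.22, 0.2))
  mod <- fit_null_spline(bins)
  expect_equal(mod$mu(bins$x), bins$mu)
  expect_equal(mod$sigma(bins$x), bins$sigma)
  # clamped extrapolation: boundary knot values
  expect_equal(mod$mu(0), bins$mu[1])
  expect_equal(mod$mu(10), bins$mu[6])
  expect_equal(mod$sigma(10), bins$sigma[6])
  # collinear knots -> natural cubic spline is the straight line
  lin <- data.table::data.table(x = 1:6, mu = 2 * (1:6) + 1, sigma = 1:6 / 10)
  lmod <- fit_null_spline(lin)
  expect_equal(lmod$mu(c(1.5, 3.25, 5.5)), 2 * c(1.5, 3.25, 5.5) + 1)
  # sigma floor
  fl <- data.table::data.table(x = 1:5, mu = 0, sigma = c(0.5, 0.2, 0, 0.2, 0.5))
  fmod <- fit_null_spline(fl, sigma_floor = 1e-6)
  expect_true(all(fmod$sigma(seq(1, 5, 0.05)) >= 1e-6))
  # duplicate knot x merged with warning; too few knots errors
  dup <- data.table::data.table(x = c(1, 1, 2, 3, 4), mu = c(0, 1, 0, 0, 0),
                                sigma = 0.5)
  expect_warning(dmod <- fit_null_spline(dup), "duplicate")
  expect_equal(dmod$mu(1), 0.5)
  suppressWarnings(expect_error(fit_null_spline(dup[x < 3]), "4 bins"))
})

test_that("null model JSON dump round trips", {
  m <- fake_measurements(200L, rnorm(200, 0, 0.3),
                         as.integer(10^runif(200, 3.1, 5)))
  mod <- fit_null_spline(bin_by_depth(m, B = 10L), target = "t1")
  path <- withr::local_tempfile(fileext = ".json")
  dump_null_model(mod, path)
  back <- load_null_model(path)
  xs <- seq(mod$x_range[1] - 1, mod$x_range[2] + 1, length.out = 50)
  expect_equal(back$mu(xs), mod$mu(xs))
  expect_equal(back$sigma(xs), mod$sigma(xs))
  expect_equal(back$target, "t1")
})

test_that("score_strains computes Z, two-sided p and 2-sigma intervals", {
  bins <- data.table::data.table(x = seq(3, 5, length.out = 5),
                                 mu = 0.5, sigma = 0.25)
  mod <- fit_null_spline(bins)
  m <- fake_measurements(3L, c(1.0, 0.5, 0.5 + 1.959964 * 0.25),
                         c(10000L, 10000L, 10000L))
  sc <- score_strains(m, mod)
  expect_equal(sc$z[1], 2.0)                     # (1.0 - 0.5) / 0.25
  expect_equal(sc$z[2], 0)
  expect_equal(sc$p[2], 1)
  expect_equal(sc$ci_low, sc$log2_si_rel - 0.5)  # 2 * sigma = 0.5
  expect_equal(sc$ci_high, sc$log2_si_rel + 0.5)
  expect_equal(sc$p[3], 0.05, tolerance = 1e-6)  # |Z| = 1.959964 -> p = 0.05
  # QC-failing strains are excluded
  m_bad <- data.table::copy(m)[1, passes_qc := FALSE]
  expect_equal(nrow(score_strains(m_bad, mod)), 2L)
})

test_that("|Z| is monotone in the departure from the null mean at fixed depth", {
  bins <- data.table::data.table(x = seq(3, 5, length.out = 6),
                                 mu = c(0, 0.1, -0.1, 0.05, 0, 0.02),
                                 sigma = c(0.8, 0.5, 0.4, 0.3, 0.25, 0.2))
  mod <- fit_null_spline(bins)
  for (reads in c(1500L, 8000L, 60000L)) {
    dep <- seq(0, 3, length.out = 25)
    mu_here <- mod$mu(log10(reads))
    m <- fake_measurements(length(dep), mu_here + dep, rep(reads, length(dep)))
    z <- score_strains(m, mod)$z
    expect_true(all(diff(abs(z)) > 0))
  }
})

test_that("bh_correct implements the step-up rule", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(0.3), 0.3)
  expect_equal(bh_correct(numeric(0)), numeric(0))
  expect_error(bh_correct(c(0.5, 0)), "0, 1")
  expect_error(bh_correct(c(0.5, 1.2)), "0, 1")
  # order preserved, q >= p, q <= 1
  withr::with_seed(7, {
    p <- runif(50)
    q <- bh_correct(p)
    expect_true(all(q >= p) && all(q <= 1))
    expect_equal(bh_correct(p), stats::p.adjust(p, "BH"))
    expect_equal(q, bh_oracle(p))
  })
})

test_that("call_hits uses a strict q < alpha threshold and sorts by q", {
  r <- data.table::data.table(strain_id = c("a", "b", "c"), target = "t",
                              log2_si_rel = c(2, 1, 0), combined_reads = 2000L,
                              z = c(4, 2, 0.1),
                              p = c(0.01, 0.05, 0.9),
                              ci_low = 0, ci_high = 1)
  # single p = 0.05: q = 0.05 exactly -> NOT significant
  single <- call_hits(r[2], alpha = 0.05)
  expect_equal(single$q, 0.05)
  expect_false(single$significant)
  expect_true(call_hits(r[2][, p := 0.049], alpha = 0.05)$significant)
  out <- call_hits(r, alpha = 0.05)
  expect_equal(out$strain_id, c("a", "b", "c"))  # sorted by q then |z|
  expect_true(all(diff(out$q) >= 0))
})

test_that("fitted sigma(x) tracks a known depth-dependent null within 15%", {
  # generating model: log2(SI_rel) ~ N(0, s(d)) with s(d) the binomial
  # delta-method sd at unspliced fraction pi; depths span 1e2..1e5
  pi0 <- 0.02
  withr::with_seed(11, {
    n <- 3000L
    d <- as.integer(round(10^runif(n, 2, 5)))
    s_true <- 1 / (log(2) * sqrt(d * pi0 * (1 - pi0)))
    m <- fake_measurements(n, rnorm(n, 0, s_true), d)
    mod <- fit_null_spline(bin_by_depth(m, B = 20L))
    at_knots <- mod$knots$x
    s_pred <- 1 / (log(2) * sqrt(10^at_knots * pi0 * (1 - pi0)))
    expect_true(all(abs(mod$sigma(at_knots) / s_pred - 1) < 0.15))
  })
})

test_that("realized FDR stays below 0.1 with 5% spiked strains", {
  fdr <- numeric(10)
  for (s in 1:10) {
    cfg <- simulation_config(n_plates = 4L, spiked_fraction = 0.05,
                             targets = example_targets()[1], seed = 600L + s)
    sim <- simulate_counts(cfg)
    meas <- filter_replicates(plate_normalize(compute_si(sim$counts)))
    calls <- call_hits(score_strains(meas,
                                     fit_null_spline(bin_by_depth(meas, B = 20L))))
    calls <- merge(calls, sim$truth$strains, by = c("strain_id", "target"))
    hits <- calls[significant == TRUE]
    fdr[s] <- if (nrow(hits)) mean(!hits$is_spiked) else 0
  }
  expect_lte(mean(fdr), 0.1)
})

test_that("p-values are uniform when data come from the fitted model family", {
  # scoring data simulated from a known (mu, sigma) must give uniform p
  withr::with_seed(13, {
    n <- 2000L
    d <- as.integer(round(10^runif(n, 3.1, 5)))
    s_true <- 1 / (log(2) * sqrt(d * 0.02 * 0.98))
    m <- fake_measurements(n, rnorm(n, 0, s_true), d)
    mod <- fit_null_spline(bin_by_depth(m, B = 20L))
    p <- score_strains(m, mod)$p
    expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
  })
})
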