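test_that("segment scores follow the z-score arithmetic exactly", {
  # numerator vanishes when the native energy equals the null mean
  expect_equal(segment_score(-8, c(-7, -8, -9))$s, 0)
  # direct arithmetic: mean -8, sample sd 1, s = -2
  sc <- segment_score(-10, c(-7, -8, -9))
  expect_equal(sc$s, -2)
  expect_equal(sc$null_mean, -8)
  expect_equal(sc$null_sd, 1)
  expect_equal(sc$n_null, 3L)
  expect_false(sc$degenerate)

  expect_error(segment_score(-10, numeric()), "non-empty")

  deg <- segment_score(-5, c(-3, -3, -3))
  expect_equal(deg$s, 0)
  expect_true(deg$degenerate)
})

test_that("segment scores are invariant under affine energy rescaling", {
  set.seed(21)
  for (k in 1:25) {
    nulls <- rnorm(20, -30, 4)
    e <- rnorm(1, -35, 4)
    a <- runif(1, 0.5, 3); b <- runif(1, -10, 10)
    expect_equal(segment_score(a * e + b, a * nulls + b)$s,
                 segment_score(e, nulls)$s, tolerance = 1e-12)
  }
})

test_that("a homopolymer scans to all-zero energies with degenerate nulls", {
  prof <- scan_windows(seq_record("polyA", strrep("A", 120)),
                       window_spec(sizes = 50L), n_null = 5, seed = 1)
  expect_equal(nrow(prof), 120 - 50 + 1)
  expect_true(all(prof$e_mfe == 0))
  expect_true(all(prof$g_ensemble == 0))
  expect_true(all(prof$s_mfe == 0))
  expect_true(all(prof$degenerate))
})

test_that("scans are deterministic given the seed", {
  set.seed(31); s <- random_rna(90)
  a <- scan_windows(s, window_spec(sizes = c(30L, 40L)), n_null = 10,
                    seed = 5)
  b <- scan_windows(s, window_spec(sizes = c(30L, 40L)), n_null = 10,
                    seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("the scan matches a naive window-by-window re-implementation", {
  set.seed(41)
  res <- random_rna(120)
  size <- 34L
  n_null <- 6L
  seed <- 9L
  cfg <- fold_config()
  prof <- scan_windows(res, window_spec(sizes = size), n_null = n_null,
                       seed = seed, config = cfg)
  # naive loop: direct single-sequence calls, no batching or reuse
  for (w in sample(seq_len(120 - size + 1), 8)) {
    win <- substr(res, w, w + size - 1)
    f <- fold_partition(win, cfg, bppm = FALSE)
    nulls <- make_null_set(win, n = n_null,
                           seed = utrscan:::derive_seed(seed, size, w))
    ne <- vapply(nulls$members, function(m)
      fold_partition(m, cfg, bppm = FALSE)$g_ensemble, 0)
    nm <- vapply(nulls$members, function(m)
      fold_mfe(m, cfg)$e_mfe, 0)
    row <- prof[prof$start == w, ]
    expect_equal(row$e_mfe, fold_mfe(win, cfg)$e_mfe)
    expect_equal(row$g_ensemble, f$g_ensemble)
    expect_equal(row$g_per_nt, f$g_ensemble / size)
    expect_equal(row$s_ens, segment_score(f$g_ensemble, ne)$s)
    expect_equal(row$s_mfe, segment_score(fold_mfe(win, cfg)$e_mfe, nm,
                                          kind = "mfe")$s)
  }
})

test_that("ensemble free energy stays below MFE across a whole scan", {
  set.seed(51)
  prof <- scan_windows(random_rna(140), window_spec(sizes = c(30L, 50L)),
                       n_null = 0, seed = 1)
  expect_true(all(prof$g_ensemble <= prof$e_mfe + 1e-9))
  expect_true(all(diff(prof$centre[prof$size == 30]) == 1))
})

test_that("a planted hairpin pulls the energy-per-nucleotide minimum to its locus", {
  bg <- random_background(200, c(A = 0.3, C = 0.2, G = 0.2, U = 0.3),
                          seed = 6)
  planted <- plant_hairpin(bg, stem_length = 12L, loop_length = 4L,
                           position = 91L, stem_gc = 1, seed = 6)
  prof <- scan_windows(planted, window_spec(sizes = 50L), n_null = 0,
                       seed = 1)
  truth <- attr(planted, "truth")$interval
  best <- prof$centre[which.min(prof$g_per_nt)]
  expect_gte(best, truth[1] - 5)
  expect_lte(best, truth[2] + 5)
})

test_that("null energy profiles track composition", {
  # G/C-rich half folds more stably than the A/U-rich half even in nulls
  set.seed(61)
  gc_half <- paste(sample(c("G", "C"), 70, TRUE), collapse = "")
  au_half <- paste(sample(c("A", "U"), 70, TRUE), collapse = "")
  prof <- null_energy_profile(seq_record("halves",
                                         paste0(gc_half, au_half)),
                              window = 40L, n_null = 8, seed = 2)
  left <- mean(prof$null_g_per_nt[prof$centre <= 40])
  right <- mean(prof$null_g_per_nt[prof$centre >= 100])
  expect_lt(left, right)
})

test_that("whole-sequence scramble calibration brackets an exchangeable native", {
  set.seed(71)
  s <- random_rna(110)
  cal <- calibrate_with_scrambles(seq_record("x", s), n_scrambles = 6,
                                  window = 50L, n_null = 6, seed = 3)
  expect_equal(nrow(cal), 6L)
  # native minimum lies inside (or at) the support of the scramble minima,
  # up to ordinary sampling spread
  expect_gte(attr(cal, "quantile_ens"), 0)
  expect_lte(attr(cal, "quantile_ens"), 1)
  expect_true(is.finite(attr(cal, "native_min_s_ens")))
  expect_error(calibrate_with_scrambles(seq_record("x", s),
                                        n_scrambles = 0), "n_scrambles")
})
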