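## Sliding-window folding scans: segment z-scores against dinucleotide-
## preserving nulls, energy-per-nucleotide profiles, and whole-sequence
## scramble calibration.

#' Window specification for a scan
#'
#' Windows of every size in `sizes` are slid along the sequence in single
#' (or `stride`) nucleotide steps; only fully contained windows are folded.
#' The reported centre of a window is `start + floor((size - 1) / 2)`
#' (left-of-middle for even sizes).
#'
#' @param sizes Window lengths (default 30 to 100 in steps of 2).
#' @param stride Step between window starts (default 1).
#' @return A `window_spec`.
#' @export
window_spec <- function(sizes = seq(30L, 100L, by = 2L), stride = 1L) {
  sizes <- as.integer(sizes)
  stride <- as.integer(stride)
  if (any(sizes < 2L)) stop("window sizes must be >= 2", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  structure(list(sizes = sizes, stride = stride), class = "window_spec")
}

#' Segment score of a folding free energy against a null sample
#'
#' The segment score is the z-score `s = (e - mean(nulls)) / sd(nulls)`
#' of a sequence's folding free energy against the free energies of its
#' dinucleotide-preserving scrambles, using the sample (n-1) standard
#' deviation. Negative scores indicate more stable structure than base
#' composition alone predicts. A degenerate null (zero standard deviation,
#' e.g. a homopolymeric window) yields a score of 0 with `degenerate =
#' TRUE` rather than an infinity.
#'
#' @param e Folding free energy of the native sequence (kcal/mol).
#' @param nulls Free energies of the scrambled sequences (kcal/mol).
#' @param kind Label, `"mfe"` or `"ensemble"`.
#' @return A `segment_score`: `s`, `e`, `null_mean`, `null_sd`, `n_null`,
#'   `degenerate`, `kind`.
#' @examples
#' segment_score(-10, c(-7, -8, -9))$s   # (-10 - (-8)) / 1 = -2
#' @export
segment_score <- function(e, nulls, kind = c("ensemble", "mfe")) {
  kind <- match.arg(kind)
  if (length(nulls) == 0L)
    stop("nulls must be non-empty", call. = FALSE)
  mu <- mean(nulls)
  sigma <- if (length(nulls) >= 2L) sd(nulls) else 0
  degenerate <- !is.finite(sigma) || sigma == 0
  structure(list(s = if (degenerate) 0 else (e - mu) / sigma,
                 e = e, null_mean = mu, null_sd = sigma,
                 n_null = length(nulls), degenerate = degenerate,
                 kind = kind),
            class = "segment_score")
}

#' @export
print.segment_score <- function(x, ...) {
  cat("segment score (", x$kind, "): s = ", format(x$s, digits = 4),
      "  [e = ", format(x$e, digits = 4), ", null ",
      format(x$null_mean, digits = 4), " +/- ",
      format(x$null_sd, digits = 4), ", n = ", x$n_null,
      if (x$degenerate) ", degenerate null" else "", "]\n", sep = "")
  invisible(x)
}

#' Sliding-window folding scan with shuffled nulls
#'
#' For every window size in the specification and every fully contained
#' window, folds the native window for minimum and ensemble free energy,
#' generates `n_null` dinucleotide-preserving scrambles of the window (one
#' null set, shared by both score kinds), folds them, and computes segment
#' scores. The scan is deterministic given `seed`: each window's null set
#' uses a sub-stream derived from `(seed, size, start)`, so results do not
#' depend on evaluation order. With `n_null = 0` only the native energy
#' profile is computed and the score columns are `NA`.
#'
#' @param seq A [seq_record] or residue string.
#' @param spec A [window_spec()].
#' @param n_null Scrambles per window (default 100).
#' @param seed Master seed.
#' @param config A [fold_config()].
#' @return A `scan_profile` data frame, ordered by (size, centre), with
#'   columns `size, start, centre, e_mfe, g_ensemble, g_per_nt,
#'   null_mean_mfe, null_sd_mfe, s_mfe, null_mean_ens, null_sd_ens, s_ens,
#'   degenerate`. `start` and `centre` are in the record's reference
#'   coordinates; `g_per_nt` is the ensemble free energy per nucleotide.
#' @export
scan_windows <- function(seq, spec = window_spec(), n_null = 100L,
                         seed = 1L, config = fold_config()) {
  seq <- as_seq_record(seq)
  n <- nchar(seq$residues)
  sizes <- spec$sizes[spec$sizes <= n]
  if (length(sizes) == 0L)
    stop("all window sizes exceed the sequence length (", n, ")",
         call. = FALSE)
  rows <- list()
  for (size in sizes) {
    starts <- seq(1L, n - size + 1L, by = spec$stride)
    native <- substring(seq$residues, starts, starts + size - 1L)
    en <- fold_energies(native, config)
    null_mat_mfe <- null_mat_ens <- NULL
    if (n_null > 0L) {
      nulls <- unlist(lapply(seq_along(starts), function(w) {
        make_null_set(native[w], n = n_null,
                      seed = derive_seed(seed, size, starts[w]))$members
      }))
      ne <- fold_energies(nulls, config)
      null_mat_mfe <- matrix(ne$e_mfe, nrow = n_null)
      null_mat_ens <- matrix(ne$g_ensemble, nrow = n_null)
    }
    mk <- function(w, kind, mat) {
      if (is.null(mat)) return(list(mean = NA_real_, sd = NA_real_,
                                    s = NA_real_, degen = NA))
      e <- if (kind == "mfe") en$e_mfe[w] else en$g_ensemble[w]
      sc <- segment_score(e, mat[, w], kind = kind)
      list(mean = sc$null_mean, sd = sc$null_sd, s = sc$s,
           degen = sc$degenerate)
    }
    sm <- lapply(seq_along(starts), mk, kind = "mfe", mat = null_mat_mfe)
    se <- lapply(seq_along(starts), mk, kind = "ensemble",
                 mat = null_mat_ens)
    rows[[length(rows) + 1L]] <- data.frame(
      size = size,
      start = seq$offset + starts - 1L,
      centre = seq$offset + (starts - 1L) + (size - 1L) %/% 2L,
      e_mfe = en$e_mfe,
      g_ensemble = en$g_ensemble,
      g_per_nt = en$g_ensemble / size,
      null_mean_mfe = vapply(sm, `[[`, 0, "mean"),
      null_sd_mfe = vapply(sm, `[[`, 0, "sd"),
      s_mfe = vapply(sm, `[[`, 0, "s"),
      null_mean_ens = vapply(se, `[[`, 0, "mean"),
      null_sd_ens = vapply(se, `[[`, 0, "sd"),
      s_ens = vapply(se, `[[`, 0, "s"),
      degenerate = vapply(se, `[[`, NA, "degen") |
        vapply(sm, `[[`, NA, "degen"))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$size, out$centre), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("scan_profile", "data.frame"),
            id = seq$id, seed = seed, n_null = n_null,
            backend = config$backend, sizes = sizes,
            stride = spec$stride)
}

#' Mean scramble energy profile along a sequence
#'
#' The null counterpart of the native energy-per-nucleotide profile: for
#' each window centre, the mean ensemble free energy per nucleotide over
#' the window's dinucleotide-preserving null set. Extrema that co-locate
#' with the native profile's indicate composition-driven (rather than
#' sequence-order-driven) stability.
#'
#' @inheritParams scan_windows
#' @param window Single window size (default 50).
#' @return A data frame `(centre, null_g_per_nt, g_per_nt)` with the null
#'   and native per-nucleotide ensemble energies.
#' @export
null_energy_profile <- function(seq, window = 50L, n_null = 100L,
                                seed = 1L, config = fold_config()) {
  prof <- scan_windows(seq, window_spec(sizes = window), n_null = n_null,
                       seed = seed, config = config)
  data.frame(centre = prof$centre,
             null_g_per_nt = prof$null_mean_ens / prof$size,
             g_per_nt = prof$g_per_nt)
}

#' Whole-sequence scramble calibration of a windowed scan
#'
#' Assesses whether the spikes of a windowed segment-score profile are
#' unusual for the sequence's dinucleotide composition: the entire sequence
#' is scrambled (dinucleotide-preserving) `n_scrambles` times, each
#' scramble receives the identical sliding-window scan, and the minimum
#' segment score per scramble is recorded. The native minimum's empirical
#' quantile within that distribution close to 0 indicates genuinely
#' exceptional structure; a mid-range quantile reproduces composition-only
#' behaviour.
#'
#' @inheritParams scan_windows
#' @param n_scrambles Whole-sequence scrambles (default 100).
#' @param window Window size for the scans (default 50).
#' @return A `scramble_calibration`: data frame of per-scramble minima
#'   (`min_s_mfe`, `min_s_ens`) with attributes `native_min_s_mfe`,
#'   `native_min_s_ens`, `quantile_mfe`, `quantile_ens`.
#' @export
calibrate_with_scrambles <- function(seq, n_scrambles = 100L, window = 50L,
                                     n_null = 100L, seed = 1L,
                                     config = fold_config()) {
  if (n_scrambles <= 0L) stop("n_scrambles must be > 0", call. = FALSE)
  seq <- as_seq_record(seq)
  spec <- window_spec(sizes = window)
  scrambles <- make_null_set(seq, n = n_scrambles,
                             seed = derive_seed(seed, 7L))$members
  native <- scan_windows(seq, spec, n_null = n_null, seed = seed,
                         config = config)
  mins <- vapply(seq_len(n_scrambles), function(k) {
    p <- scan_windows(seq_record(paste0("scramble", k), scrambles[k]),
                      spec, n_null = n_null,
                      seed = derive_seed(seed, 11L, k), config = config)
    c(min(p$s_mfe), min(p$s_ens))
  }, numeric(2))
  out <- data.frame(scramble = seq_len(n_scrambles),
                    min_s_mfe = mins[1, ], min_s_ens = mins[2, ])
  structure(out, class = c("scramble_calibration", "data.frame"),
            native_min_s_mfe = min(native$s_mfe),
            native_min_s_ens = min(native$s_ens),
            quantile_mfe = mean(mins[1, ] <= min(native$s_mfe)),
            quantile_ens = mean(mins[2, ] <= min(native$s_ens)))
}
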