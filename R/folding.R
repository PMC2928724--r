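## User-facing folding operations: MFE structure, partition function /
## ensemble free energy, base-pair probabilities, centroid pairs and
## percent-paired profiles. Both backends return the same fold_result
## container.

encode_residues <- function(res) {
  match(strsplit(res, "")[[1]], RNA_ALPHABET) - 1L
}

pairs_to_dotbracket <- function(partner, n) {
  db <- rep(".", n)
  paired <- which(!is.na(partner) & partner > seq_len(n))
  db[paired] <- "("
  db[partner[paired]] <- ")"
  paste(db, collapse = "")
}

dotbracket_to_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  partner <- rep(NA_integer_, length(chars))
  stack <- integer()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- k; partner[k] <- i
    }
  }
  partner
}

new_fold_result <- function(seq, config, e_mfe = NA_real_,
                            mfe_structure = NA_character_,
                            g_ensemble = NA_real_, bppm = NULL) {
  structure(list(id = seq$id, residues = seq$residues, offset = seq$offset,
                 backend = config$backend, temperature = config$temperature,
                 e_mfe = e_mfe, mfe_structure = mfe_structure,
                 g_ensemble = g_ensemble, bppm = bppm),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat("fold_result '", x$id, "' (", nchar(x$residues), " nt, ",
      x$backend, " backend)\n", sep = "")
  if (!is.na(x$e_mfe))
    cat("  MFE: ", format(x$e_mfe, nsmall = 2), " kcal/mol\n", sep = "")
  if (!is.na(x$g_ensemble))
    cat("  ensemble free energy: ", format(x$g_ensemble, nsmall = 2),
        " kcal/mol\n", sep = "")
  if (!is.null(x$bppm))
    cat("  base-pair probability matrix: ", nrow(x$bppm), "x",
        ncol(x$bppm), "\n", sep = "")
  invisible(x)
}

#' Minimum free energy structure
#'
#' Folds a sequence for its minimum free energy over all pseudoknot-free
#' secondary structures under the configured energy model, returning one
#' witness structure in dot-bracket notation. A sequence admitting no pair
#' (e.g. shorter than the minimum hairpin loop plus two) returns the open
#' chain at 0.0 kcal/mol.
#'
#' @param seq A [seq_record] or residue string.
#' @param config A [fold_config()].
#' @return A `fold_result` with `e_mfe` and `mfe_structure` set.
#' @examples
#' fold_mfe("AAAAAAAAAA")$e_mfe   # 0: no Watson-Crick/GU pair possible
#' @export
fold_mfe <- function(seq, config = fold_config()) {
  seq <- as_seq_record(seq)
  n <- nchar(seq$residues)
  if (config$backend == "reference") {
    r <- c_fold(encode_residues(seq$residues), engine_params(config),
                TRUE, FALSE, FALSE)
    new_fold_result(seq, config, e_mfe = r$e_mfe,
                    mfe_structure = pairs_to_dotbracket(r$mfe_pairs, n))
  } else {
    r <- rnafold_fold_many(seq$residues, pf = FALSE,
                           temperature = config$temperature,
                           parameter_set = config$parameter_set)[[1]]
    new_fold_result(seq, config, e_mfe = r$e_mfe,
                    mfe_structure = r$mfe_structure)
  }
}

#' Partition function and base-pair probabilities
#'
#' Computes the ensemble free energy `-RT log Z`, where `Z` sums Boltzmann
#' weights over all pseudoknot-free structures, and (optionally) the matrix
#' of marginal pairing probabilities `p(i,j)`. The MFE structure is computed
#' alongside. For an unpairable sequence `Z = 1`, the ensemble free energy
#' is 0 and all probabilities are 0.
#'
#' @param seq A [seq_record] or residue string.
#' @param config A [fold_config()].
#' @param bppm Whether to compute the base-pair probability matrix
#'   (default `TRUE`).
#' @return A `fold_result` with `e_mfe`, `mfe_structure`, `g_ensemble` and
#'   (optionally) `bppm` set.
#' @export
fold_partition <- function(seq, config = fold_config(), bppm = TRUE) {
  seq <- as_seq_record(seq)
  n <- nchar(seq$residues)
  if (config$backend == "reference") {
    r <- c_fold(encode_residues(seq$residues), engine_params(config),
                TRUE, TRUE, bppm)
    new_fold_result(seq, config, e_mfe = r$e_mfe,
                    mfe_structure = pairs_to_dotbracket(r$mfe_pairs, n),
                    g_ensemble = r$g_ensemble,
                    bppm = if (bppm) r$bppm)
  } else {
    r <- rnafold_fold_many(seq$residues, pf = TRUE, bppm = bppm,
                           temperature = config$temperature,
                           parameter_set = config$parameter_set)[[1]]
    new_fold_result(seq, config, e_mfe = r$e_mfe,
                    mfe_structure = r$mfe_structure,
                    g_ensemble = r$g_ensemble,
                    bppm = if (bppm) r$bppm)
  }
}

## batch MFE + ensemble energies for scans; one engine/RNAfold invocation
fold_energies <- function(residues, config, pf = TRUE) {
  if (length(residues) == 0L)
    return(data.frame(e_mfe = numeric(), g_ensemble = numeric()))
  if (config$backend == "reference") {
    m <- c_fold_energies(lapply(residues, encode_residues),
                         engine_params(config), pf)
    data.frame(e_mfe = m[, 1], g_ensemble = m[, 2])
  } else {
    r <- rnafold_fold_many(residues, pf = pf,
                           temperature = config$temperature,
                           parameter_set = config$parameter_set)
    data.frame(e_mfe = vapply(r, `[[`, 0, "e_mfe"),
               g_ensemble = if (pf) vapply(r, `[[`, 0, "g_ensemble")
                            else NA_real_)
  }
}

#' Centroid base pairs (probability above a threshold)
#'
#' Extracts the set of individual base pairs whose probability exceeds
#' `threshold` from a fold result's base-pair probability matrix. At the
#' default threshold of 0.5 the set is automatically conflict-free: two
#' pairs sharing a base cannot both have probability above one half.
#' Thresholds below 0.5 are rejected for that reason.
#'
#' @param result A `fold_result` carrying a `bppm`.
#' @param threshold Probability cut-off (default 0.5).
#' @return A `centroid_structure`: data frame of pairs `(i, j, p)` with
#'   `i < j` in local 1-based coordinates, plus attributes `threshold` and
#'   `min_pair_probability`.
#' @export
centroid_pairs <- function(result, threshold = 0.5) {
  if (threshold < 0.5)
    stop("threshold below 0.5 would allow conflicting pairs; refusing",
         call. = FALSE)
  if (is.null(result$bppm))
    stop("fold_result has no base-pair probability matrix; ",
         "run fold_partition(..., bppm = TRUE)", call. = FALSE)
  m <- result$bppm
  idx <- which(upper.tri(m) & m > threshold, arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1], j = idx[, 2],
                      p = m[idx])
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, class = c("centroid_structure", "data.frame"),
            threshold = threshold,
            min_pair_probability = if (nrow(pairs)) min(pairs$p) else NA_real_)
}

#' Percent-paired profile in sliding windows
#'
#' Summarises a base-pair probability matrix as two per-window percentages:
#' `pct_discrete`, the percentage of bases in the window participating in
#' some individual pair with probability above 0.5, and `pct_weighted`, the
#' percentage of bases whose total pairing probability (row sum of the
#' matrix) exceeds 0.5. Only fully contained windows are reported; window
#' centres follow `start + floor((window - 1) / 2)` in the record's
#' reference coordinates.
#'
#' @param result A `fold_result` carrying a `bppm`.
#' @param window Window length (default 50).
#' @return A data frame `(centre, pct_discrete, pct_weighted)`; empty, with
#'   a warning, when the sequence is shorter than `window`.
#' @export
percent_paired_windows <- function(result, window = 50L) {
  if (is.null(result$bppm))
    stop("fold_result has no base-pair probability matrix", call. = FALSE)
  m <- result$bppm
  n <- nrow(m)
  if (window > n) {
    warning("window (", window, ") longer than sequence (", n,
            "); empty profile", call. = FALSE)
    return(data.frame(centre = integer(), pct_discrete = numeric(),
                      pct_weighted = numeric()))
  }
  discrete <- apply(m, 1, max) > 0.5
  weighted <- rowSums(m) > 0.5
  starts <- seq_len(n - window + 1L)
  centre <- result$offset + (starts - 1L) + (window - 1L) %/% 2L
  cum_d <- cumsum(c(0L, discrete))
  cum_w <- cumsum(c(0L, weighted))
  data.frame(centre = centre,
             pct_discrete = 100 * (cum_d[starts + window] - cum_d[starts]) /
               window,
             pct_weighted = 100 * (cum_w[starts + window] - cum_w[starts]) /
               window)
}
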