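## Structural comparison of mutant constructs to a reference sequence:
## ensemble delta-delta-G, pairing status of the mutated region, and
## alternative-helix detection from centroid pair diffs.

#' Compare a mutant construct to its reference sequence
#'
#' Folds both sequences with the partition function, extracts centroid
#' pairs (probability > 0.5), and reports the ensemble free-energy
#' difference `ddg_ensemble = G_mutant - G_reference` (positive =
#' destabilised), the MFE difference alongside, whether the mutated region
#' is free of centroid pairs, and the pair sets lost and gained by the
#' mutation.
#'
#' @param endo Reference [seq_record] (e.g. the endogenous insert).
#' @param mutant Mutant [seq_record]; must have the same length (the
#'   substitution design preserves length).
#' @param region `c(start, end)` mutated interval in reference coordinates.
#' @param config A [fold_config()]; use the thermodynamic backend to
#'   reproduce published kcal/mol values.
#' @return A `mutant_comparison`.
#' @export
compare_construct <- function(endo, mutant, region,
                              config = fold_config()) {
  endo <- as_seq_record(endo, "endogenous")
  mutant <- as_seq_record(mutant, "mutant")
  if (nchar(endo$residues) != nchar(mutant$residues))
    stop("sequences differ in length (", nchar(endo$residues), " vs ",
         nchar(mutant$residues), "); substitution mutants preserve length",
         call. = FALSE)
  check_region(endo, region[1], region[2])
  fe <- fold_partition(endo, config, bppm = TRUE)
  fm <- fold_partition(mutant, config, bppm = TRUE)
  ce <- centroid_pairs(fe)
  cm <- centroid_pairs(fm)
  key <- function(d) paste(d$i, d$j)
  lost <- ce[!(key(ce) %in% key(cm)), c("i", "j", "p")]
  gained <- cm[!(key(cm) %in% key(ce)), c("i", "j", "p")]
  rownames(lost) <- rownames(gained) <- NULL
  ## local coordinates of the mutated region
  a <- region[1] - endo$offset + 1L
  b <- region[2] - endo$offset + 1L
  in_region <- (cm$i >= a & cm$i <= b) | (cm$j >= a & cm$j <= b)
  structure(list(name = mutant$id, region = c(region[1], region[2]),
                 offset = endo$offset,
                 ddg_ensemble = fm$g_ensemble - fe$g_ensemble,
                 ddg_mfe = fm$e_mfe - fe$e_mfe,
                 mutated_region_unpaired = !any(in_region),
                 lost_pairs = as.data.frame(lost),
                 gained_pairs = as.data.frame(gained),
                 endo_fold = fe, mutant_fold = fm),
            class = "mutant_comparison")
}

#' @export
print.mutant_comparison <- function(x, ...) {
  cat("mutant_comparison '", x$name, "' (mutated +", x$region[1], "..+",
      x$region[2], ")\n", sep = "")
  cat("  ddG ensemble: ", sprintf("%+.2f", x$ddg_ensemble),
      " kcal/mol (MFE: ", sprintf("%+.2f", x$ddg_mfe), ")\n", sep = "")
  cat("  mutated region unpaired in centroid: ",
      x$mutated_region_unpaired, "\n", sep = "")
  cat("  centroid pairs lost: ", nrow(x$lost_pairs), ", gained: ",
      nrow(x$gained_pairs), "\n", sep = "")
  invisible(x)
}

#' Cluster gained centroid pairs into alternative helices
#'
#' Pairs `(i, j)` and `(i + 1, j - 1)` are stacked neighbours; maximal
#' chains of stacked gained pairs define the alternative helices a mutation
#' induces. Each helix is reported with its two strand intervals.
#'
#' @param comparison A `mutant_comparison`, or a data frame of pairs
#'   `(i, j)`.
#' @return A data frame with one row per helix: `i_start, i_end, j_start,
#'   j_end, n_pairs`, in the comparison's reference coordinates.
#' @export
alternative_helix_report <- function(comparison) {
  pairs <- if (inherits(comparison, "mutant_comparison"))
    comparison$gained_pairs else as.data.frame(comparison)
  offset <- if (inherits(comparison, "mutant_comparison"))
    comparison$offset else 1L
  if (nrow(pairs) == 0L)
    return(data.frame(i_start = integer(), i_end = integer(),
                      j_start = integer(), j_end = integer(),
                      n_pairs = integer()))
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  key <- paste(pairs$i, pairs$j)
  helix <- integer(nrow(pairs))
  current <- 0L
  for (k in seq_len(nrow(pairs))) {
    prev <- paste(pairs$i[k] - 1L, pairs$j[k] + 1L)
    if (k > 1L && prev %in% key && helix[match(prev, key)] > 0L) {
      helix[k] <- helix[match(prev, key)]
    } else {
      current <- current + 1L
      helix[k] <- current
    }
  }
  out <- do.call(rbind, lapply(split(pairs, helix), function(h)
    data.frame(i_start = min(h$i), i_end = max(h$i),
               j_start = min(h$j), j_end = max(h$j),
               n_pairs = nrow(h))))
  out <- out[order(out$i_start), , drop = FALSE]
  coords <- c("i_start", "i_end", "j_start", "j_end")
  out[coords] <- out[coords] + (offset - 1L)
  rownames(out) <- NULL
  out
}
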