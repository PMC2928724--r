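## Cross-species conservation: pairwise percent similarity from optimal
## global alignment, orthologous-region projection, and G/C composition.

#' Pairwise percent similarity by global alignment
#'
#' Aligns two sequences globally (Needleman-Wunsch with affine gaps, via
#' Biostrings) and reports `100 * matches / aligned_length`, counting gap
#' columns in the denominator. The original k-tuple alignment heuristics of
#' commercial packages are not reproduced; percent identity from an optimal
#' global alignment is the reproducible surrogate, so percentages may
#' deviate slightly from values computed with such heuristics.
#'
#' @param a,b [seq_record]s or residue strings.
#' @param scoring List of `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (defaults 1, 0, -3, -1).
#' @return A `similarity_result`: ids, `percent_similarity`,
#'   `aligned_length`, `matches`, and the gap penalties used.
#' @export
pairwise_similarity <- function(a, b,
                                scoring = list(match = 1, mismatch = 0,
                                               gap_open = -3,
                                               gap_extend = -1)) {
  a <- as_seq_record(a, "a"); b <- as_seq_record(b, "b")
  al <- align_global(a$residues, b$residues, scoring)
  matches <- sum(al$pa == al$pb & al$pa != "-")
  len <- length(al$pa)
  structure(list(id_a = a$id, id_b = b$id,
                 percent_similarity = 100 * matches / len,
                 aligned_length = len, matches = matches,
                 gap_open = scoring$gap_open,
                 gap_extend = scoring$gap_extend),
            class = "similarity_result")
}

align_global <- function(ra, rb, scoring) {
  mat <- matrix(scoring$mismatch, 4, 4,
                dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  diag(mat) <- scoring$match
  al <- Biostrings::pairwiseAlignment(
    ra, rb, type = "global", substitutionMatrix = mat,
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  list(pa = strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]],
       pb = strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]],
       alignment = al)
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("similarity ", x$id_a, " vs ", x$id_b, ": ",
      format(x$percent_similarity, digits = 4), "% (", x$matches, "/",
      x$aligned_length, " aligned columns)\n", sep = "")
  invisible(x)
}

#' G+C fraction of a sequence
#'
#' @param x A [seq_record] or residue string.
#' @return Fraction of residues that are G or C, in `[0, 1]`.
#' @export
gc_content <- function(x) {
  x <- as_seq_record(x)
  composition(x)$gc_fraction
}

#' Project a reference interval onto another sequence through an alignment
#'
#' Aligns `target` to `reference` globally and maps the reference interval
#' `[start, end]` (reference coordinates) through the alignment, returning
#' the orthologous region of the target. Used to locate, for example, a
#' stem-loop element of one species' UTR in another species' UTR.
#'
#' @param reference,target [seq_record]s.
#' @param start,end Interval in the reference record's coordinates.
#' @inheritParams pairwise_similarity
#' @return A [seq_record] for the projected target region (offset = its
#'   1-based start in the target).
#' @export
project_region <- function(reference, target, start, end,
                           scoring = list(match = 1, mismatch = 0,
                                          gap_open = -3, gap_extend = -1)) {
  reference <- as_seq_record(reference, "reference")
  target <- as_seq_record(target, "target")
  check_region(reference, start, end)
  al <- align_global(reference$residues, target$residues, scoring)
  ## column-wise positions in each sequence (NA at gap columns)
  posa <- cumsum(al$pa != "-"); posa[al$pa == "-"] <- NA
  posb <- cumsum(al$pb != "-"); posb[al$pb == "-"] <- NA
  i <- start - reference$offset + 1L
  j <- end - reference$offset + 1L
  cols <- which(!is.na(posa) & posa >= i & posa <= j & !is.na(posb))
  if (length(cols) == 0L)
    stop("reference interval aligns entirely to gaps in the target",
         call. = FALSE)
  bs <- min(posb[cols]); be <- max(posb[cols])
  seq_record(paste0(target$id, "_proj_", start, "-", end),
             substr(target$residues, bs, be), offset = as.integer(bs),
             source = paste0("projected from ", reference$id, " +", start,
                             "..+", end))
}

#' Conservation summary of a reference UTR against orthologues
#'
#' For each orthologous sequence: whole-sequence percent similarity to the
#' reference, percent similarity over the projected element region, and
#' G+C fraction.
#'
#' @param reference A [seq_record] (e.g. the human UTR).
#' @param others Named list of orthologous [seq_record]s.
#' @param start,end Element interval in reference coordinates.
#' @inheritParams pairwise_similarity
#' @return A data frame, one row per orthologue.
#' @export
conservation_report <- function(reference, others, start, end,
                                scoring = list(match = 1, mismatch = 0,
                                               gap_open = -3,
                                               gap_extend = -1)) {
  element <- extract_region(reference, start, end)
  do.call(rbind, lapply(names(others), function(nm) {
    o <- others[[nm]]
    proj <- project_region(reference, o, start, end, scoring)
    data.frame(species = nm,
               utr_similarity =
                 pairwise_similarity(reference, o, scoring)$percent_similarity,
               element_similarity =
                 pairwise_similarity(element, proj, scoring)$percent_similarity,
               gc_fraction = gc_content(o))
  }))
}
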