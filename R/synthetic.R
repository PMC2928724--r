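## Synthetic benchmark generators: composition-controlled backgrounds,
## planted hairpin elements with known pair sets, and A-substitution mutant
## series. Truth annotations travel as the "truth" attribute and round-trip
## through JSON sidecars.

#' Random background sequence with controlled composition
#'
#' Samples a sequence from either independent draws of a mononucleotide
#' distribution or a first-order Markov chain matching a dinucleotide
#' table (started from the chain's stationary distribution), emulating the
#' composition bias that dinucleotide-preserving shuffles conserve.
#'
#' @param length Sequence length.
#' @param composition Either a named mononucleotide probability vector
#'   (`c(A=, C=, G=, U=)`) or a 4x4 dinucleotide count/frequency matrix
#'   such as [dinucleotide_counts()] returns.
#' @param seed Integer seed.
#' @param id Record id.
#' @return A [seq_record] with a `truth` attribute recording the spec.
#' @export
random_background <- function(length,
                              composition = c(A = 0.25, C = 0.25,
                                              G = 0.25, U = 0.25),
                              seed = 1L, id = "background") {
  stopifnot(length >= 1L)
  set.seed(derive_seed(seed, 1L))
  if (is.matrix(composition)) {
    trans <- composition / pmax(rowSums(composition), .Machine$double.eps)
    active <- rowSums(composition) > 0
    if (!any(active))
      stop("dinucleotide table has no transitions", call. = FALSE)
    ## stationary start distribution of the chain
    start <- stationary_distribution(trans, active)
    v <- integer(length)
    v[1] <- sample.int(4L, 1L, prob = start)
    for (k in seq_len(length - 1L)) {
      p <- trans[v[k], ]
      if (sum(p) <= 0)
        stop("dinucleotide transition graph is disconnected: no exit from ",
             RNA_ALPHABET[v[k]], call. = FALSE)
      v[k + 1L] <- sample.int(4L, 1L, prob = p)
    }
  } else {
    comp <- composition[RNA_ALPHABET]
    comp[is.na(comp)] <- 0
    if (any(comp < 0) || sum(comp) <= 0)
      stop("composition must be non-negative with positive sum",
           call. = FALSE)
    v <- sample.int(4L, length, replace = TRUE, prob = comp)
  }
  out <- seq_record(id, paste(RNA_ALPHABET[v], collapse = ""),
                    source = "synthetic background")
  attr(out, "truth") <- list(kind = "background", length = length,
                             seed = seed)
  out
}

stationary_distribution <- function(trans, active) {
  sub <- trans[active, active, drop = FALSE]
  ev <- eigen(t(sub))
  k <- which.min(abs(ev$values - 1))
  v <- abs(Re(ev$vectors[, k]))
  start <- numeric(4)
  start[active] <- v / sum(v)
  start
}

#' Plant a perfect hairpin into a background sequence
#'
#' Overwrites the background at `position` with a perfect stem-loop: a
#' random 5' arm at the requested G/C fraction, an unpaired loop, and the
#' reverse complement of the arm. The exact planted pair set is recorded in
#' the `truth` attribute, enabling recovery-rate benchmarking of folding
#' and scanning.
#'
#' @param background A [seq_record].
#' @param stem_length Stem length in base pairs (0 leaves the background
#'   unchanged).
#' @param loop_length Unpaired loop length (>= 3).
#' @param position 1-based start of the element in the record's local
#'   coordinates.
#' @param stem_gc Target G/C fraction of the stem arm (default 1).
#' @param seed Integer seed for the arm sequence.
#' @return The modified [seq_record]; `truth` holds the planted pairs
#'   (local coordinates) and the element interval.
#' @export
plant_hairpin <- function(background, stem_length, loop_length = 4L,
                          position = 1L, stem_gc = 1, seed = 1L) {
  stopifnot(stem_length >= 0L)
  if (stem_length == 0L) return(background)
  if (loop_length < 3L)
    stop("loop_length must be >= 3 (minimum hairpin loop)", call. = FALSE)
  n <- nchar(background$residues)
  span <- 2L * stem_length + loop_length
  if (position < 1L || position + span - 1L > n)
    stop("hairpin (", span, " nt at ", position,
         ") does not fit in the background (", n, " nt)", call. = FALSE)
  set.seed(derive_seed(seed, 2L))
  n_gc <- round(stem_gc * stem_length)
  arm <- c(sample(c("G", "C"), n_gc, replace = TRUE),
           sample(c("A", "U"), stem_length - n_gc, replace = TRUE))
  arm <- sample(arm)
  loop <- sample(c("A", "U"), loop_length, replace = TRUE)
  element <- paste(c(arm, loop,
                     strsplit(rc_string(paste(arm, collapse = "")),
                              "")[[1]]), collapse = "")
  res <- background$residues
  substr(res, position, position + span - 1L) <- element
  out <- seq_record(background$id, res,
                    offset = background$offset,
                    source = paste0(background$source, " + planted hairpin"))
  i <- position + seq_len(stem_length) - 1L
  j <- position + span - seq_len(stem_length)
  attr(out, "truth") <- list(kind = "planted_hairpin",
                             pairs = data.frame(i = i, j = j),
                             interval = c(position, position + span - 1L),
                             stem_length = stem_length,
                             loop_length = loop_length,
                             stem_gc = stem_gc, seed = seed)
  out
}

#' A-substitution mutant series
#'
#' One adenine-substituted mutant per region, named by the
#' `<start>/<end>A` convention.
#'
#' @param seq A [seq_record].
#' @param regions List of `c(start, end)` intervals (reference
#'   coordinates).
#' @param residue Substituting residue (default `"A"`).
#' @return A named list of [seq_record]s.
#' @export
make_mutant_series <- function(seq, regions, residue = "A") {
  seq <- as_seq_record(seq)
  out <- lapply(regions, function(r)
    apply_substitution(seq, r[1], r[2], residue))
  names(out) <- vapply(regions, function(r)
    paste0(r[1], "/", r[2], residue), "")
  out
}

#' Write / read a truth sidecar
#'
#' Serialises a synthetic record's `truth` attribute to JSON so benchmark
#' annotations survive FASTA round trips.
#'
#' @param x A [seq_record] with a `truth` attribute.
#' @param path JSON path.
#' @return `write_truth`: `path` invisibly; `read_truth`: the truth list.
#' @export
write_truth <- function(x, path) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("record has no truth annotation", call. = FALSE)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  t <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(t$pairs)) t$pairs <- as.data.frame(t$pairs)
  if (!is.null(t$interval)) t$interval <- as.integer(t$interval)
  t
}
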