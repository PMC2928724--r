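## Sequence records, FASTA I/O, coordinate handling and reconstruction of
## cloned inserts from overlapping oligonucleotide pairs.

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Create a sequence record
#'
#' A `seq_record` holds an identified RNA sequence together with a 1-based
#' coordinate offset, so that positions can be reported in the +1 numbering
#' of a reference transcript (the first residue of the record sits at
#' position `offset`). DNA input (T/t) is normalised to RNA (U) and case is
#' folded to upper; IUPAC ambiguity codes are rejected.
#'
#' @param id Character label.
#' @param residues Character scalar of residues over `A,C,G,U` (or `T`,
#'   which is converted).
#' @param offset 1-based position of the first residue in reference
#'   coordinates (default 1).
#' @param source Free-text provenance (accession, construct name, or a
#'   synthetic-data specification).
#' @return An object of class `seq_record`.
#' @examples
#' seq_record("toy", "ACGT")   # residues become "ACGU"
#' @export
seq_record <- function(id, residues, offset = 1L, source = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  res <- normalise_residues(residues)
  if (nchar(res) == 0L)
    stop("sequence '", id, "' is empty", call. = FALSE)
  bad <- gsub(paste0("[", paste(RNA_ALPHABET, collapse = ""), "]"), "", res)
  if (nchar(bad) > 0L)
    stop("sequence '", id, "' contains residues outside {A,C,G,U}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","),
         call. = FALSE)
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1L)
    stop("offset must be an integer >= 1", call. = FALSE)
  structure(list(id = id, residues = res, offset = offset, source = source),
            class = "seq_record")
}

normalise_residues <- function(x) {
  chartr("t", "U", chartr("T", "U", toupper(x)))
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  cat("seq_record '", x$id, "': ", n, " nt, positions +", x$offset, "..+",
      x$offset + n - 1L, "\n", sep = "")
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(" ", shown, "\n", sep = "")
  if (nzchar(x$source)) cat("  source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' @export
as.character.seq_record <- function(x, ...) x$residues

#' @export
length.seq_record <- function(x) nchar(x$residues)

as_seq_record <- function(x, id = "seq") {
  if (inherits(x, "seq_record")) x else seq_record(id, x)
}

#' Read sequences from a FASTA file
#'
#' T/t residues are normalised to U and case is folded to upper; the
#' coordinate offset of every record defaults to 1.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [seq_record] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L)
    stop("FASTA format error at line 1: file is empty", call. = FALSE)
  if (!startsWith(trimws(lines[content[1]]), ">"))
    stop("FASTA format error at line ", content[1],
         ": expected a '>' header, found '",
         substr(trimws(lines[content[1]]), 1, 20), "'", call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  recs <- lapply(seq_along(set), function(k)
    seq_record(ids[k], as.character(set[[k]]), source = path))
  names(recs) <- ids
  recs
}

#' Write sequence records to a FASTA file
#'
#' @param records A [seq_record] or list of them.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "residues"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Watson-Crick complement (A-U, G-C) in reversed order. Needed to interpret
#' antisense oligonucleotides on the sense strand.
#'
#' @param x A [seq_record] or residue string.
#' @return An object of the same kind as the input.
#' @export
reverse_complement <- function(x) {
  if (inherits(x, "seq_record")) {
    r <- x
    r$residues <- rc_string(x$residues)
    r$id <- paste0(x$id, "_rc")
    return(r)
  }
  rc_string(normalise_residues(x))
}

rc_string <- function(res) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", res), "")[[1]]), collapse = "")
}

#' Trim cloning adapters from an assembled insert
#'
#' Removes a leading clamp+HindIII motif and a trailing NcoI-containing
#' motif (the NcoI site carries the downstream initiator context, so
#' everything from the motif to the 3' end is adapter). If an expected
#' adapter is absent a warning is raised and that end is left unchanged.
#' The offset is reset so the first remaining residue is +1.
#'
#' @param x A [seq_record].
#' @param adapters Character pair `c(leading=, trailing=)`; defaults to the
#'   HindIII clamp `CCAAGCUU` and the NcoI motif `CCAUGG` (RNA alphabet).
#' @return The trimmed [seq_record], with attribute `removed` giving the
#'   number of residues removed at each end.
#' @export
trim_adapters <- function(x, adapters = c(leading = "CCAAGCUU",
                                          trailing = "CCAUGG")) {
  x <- as_seq_record(x)
  lead <- normalise_residues(adapters[["leading"]])
  trail <- normalise_residues(adapters[["trailing"]])
  res <- x$residues
  rm5 <- 0L
  if (nzchar(lead)) {
    if (startsWith(res, lead)) {
      res <- substr(res, nchar(lead) + 1L, nchar(res))
      rm5 <- nchar(lead)
    } else {
      warning("leading adapter ", lead, " not found in '", x$id,
              "'; 5' end left unchanged", call. = FALSE)
    }
  }
  rm3 <- 0L
  if (nzchar(trail)) {
    hits <- gregexpr(trail, res, fixed = TRUE)[[1]]
    if (hits[1] > 0) {
      pos <- hits[length(hits)]          # NcoI motif nearest the 3' end
      rm3 <- nchar(res) - pos + 1L
      res <- substr(res, 1L, pos - 1L)
    } else {
      warning("trailing adapter ", trail, " not found in '", x$id,
              "'; 3' end left unchanged", call. = FALSE)
    }
  }
  out <- seq_record(x$id, res, offset = 1L, source = x$source)
  attr(out, "removed") <- c(p5 = rm5, p3 = rm3)
  out
}

#' Assemble an insert from an overlapping oligonucleotide pair
#'
#' Models anneal/extension of two long oligonucleotides whose 3' ends share
#' a complementary overlap: the extension product's sense strand is the
#' sense oligo extended 3' by the reverse complement of the antisense
#' oligo's non-overlapping 5' portion. The overlap is the longest exact
#' complementary match of at least `min_overlap` residues. Adapters are then
#' trimmed with [trim_adapters()].
#'
#' @param sense,antisense Oligonucleotide sequences, 5' to 3' (DNA accepted;
#'   normalised to RNA).
#' @param name Construct label for the result.
#' @param min_overlap Minimum exact complementary overlap (default 8).
#' @param trim Trim adapters from the product (default `TRUE`).
#' @param insert_length Optional annotated insert length; when the trimmed
#'   product is longer (e.g. a junctional spacer residue next to the
#'   restriction site), it is truncated to this length and the dropped tail
#'   is recorded in attribute `junction_trimmed`.
#' @return A [seq_record] for the sense strand of the product.
#' @export
assemble_insert <- function(sense, antisense, name = "insert",
                            min_overlap = 8L, trim = TRUE,
                            insert_length = NULL) {
  s <- normalise_residues(if (inherits(sense, "seq_record"))
    sense$residues else sense)
  a <- normalise_residues(if (inherits(antisense, "seq_record"))
    antisense$residues else antisense)
  rca <- rc_string(a)
  ns <- nchar(s); na <- nchar(rca)
  overlap <- 0L
  for (k in seq(min(ns, na), 1L)) {
    if (substr(s, ns - k + 1L, ns) == substr(rca, 1L, k)) { overlap <- k; break }
  }
  if (overlap < min_overlap)
    stop("no unique complementary 3' overlap of >= ", min_overlap,
         " nt between sense and antisense oligos (longest exact match: ",
         overlap, " nt)", call. = FALSE)
  product <- seq_record(name, paste0(s, substr(rca, overlap + 1L, na)),
                        source = "anneal/extension product")
  attr(product, "overlap") <- overlap
  if (!trim) return(product)
  out <- trim_adapters(product)
  attr(out, "overlap") <- overlap
  if (!is.null(insert_length) && nchar(out$residues) > insert_length) {
    dropped <- substr(out$residues, insert_length + 1L, nchar(out$residues))
    out$residues <- substr(out$residues, 1L, insert_length)
    attr(out, "junction_trimmed") <- dropped
  }
  out
}

check_region <- function(x, start, end) {
  lo <- x$offset
  hi <- x$offset + nchar(x$residues) - 1L
  if (start > end || start < lo || end > hi)
    stop("region +", start, "..+", end, " out of range for '", x$id,
         "' (valid: +", lo, "..+", hi, ")", call. = FALSE)
  invisible(TRUE)
}

#' Extract a subsequence by reference coordinates
#'
#' `start` and `end` are inclusive positions in the record's reference
#' numbering (respecting its `offset`); the result's offset is `start`.
#'
#' @param x A [seq_record].
#' @param start,end 1-based inclusive interval in reference coordinates.
#' @return A [seq_record].
#' @export
extract_region <- function(x, start, end) {
  x <- as_seq_record(x)
  check_region(x, start, end)
  i <- start - x$offset + 1L
  j <- end - x$offset + 1L
  out <- seq_record(paste0(x$id, "_", start, "-", end),
                    substr(x$residues, i, j), offset = as.integer(start),
                    source = x$source)
  out
}

#' Residue composition of a region
#'
#' @param x A [seq_record].
#' @param start,end Reference coordinates of the region (defaults: the whole
#'   record).
#' @return A `composition_table`: residue counts, the region, and the G+C
#'   fraction.
#' @examples
#' composition(seq_record("g4", "GGGG"))
#' @export
composition <- function(x, start = NULL, end = NULL) {
  x <- as_seq_record(x)
  if (is.null(start)) start <- x$offset
  if (is.null(end)) end <- x$offset + nchar(x$residues) - 1L
  sub <- extract_region(x, start, end)
  chars <- strsplit(sub$residues, "")[[1]]
  counts <- vapply(RNA_ALPHABET, function(b) sum(chars == b), 0L)
  structure(list(id = x$id, counts = counts,
                 start = as.integer(start), end = as.integer(end),
                 gc_fraction = unname((counts["G"] + counts["C"]) /
                                        length(chars))),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("composition of '", x$id, "' +", x$start, "..+", x$end, ": ",
      paste0(x$counts, names(x$counts), collapse = " "),
      " (G+C ", format(100 * x$gc_fraction, digits = 4), "%)\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.composition_table <- function(x, ...) {
  data.frame(id = x$id, start = x$start, end = x$end,
             A = x$counts[["A"]], C = x$counts[["C"]],
             G = x$counts[["G"]], U = x$counts[["U"]],
             gc_fraction = x$gc_fraction)
}

#' Substitute a run of residues
#'
#' Replaces every position of `[start, end]` (reference coordinates) with
#' `residue`, as in adenine-substitution mutagenesis, and names the result
#' `<id>-<start>/<end><residue>`.
#'
#' @param x A [seq_record].
#' @param start,end Region to replace, in reference coordinates.
#' @param residue Replacement residue (default `"A"`).
#' @return A [seq_record].
#' @export
apply_substitution <- function(x, start, end, residue = "A") {
  x <- as_seq_record(x)
  residue <- normalise_residues(residue)
  stopifnot(nchar(residue) == 1L, residue %in% RNA_ALPHABET)
  check_region(x, start, end)
  i <- start - x$offset + 1L
  j <- end - x$offset + 1L
  res <- x$residues
  substr(res, i, j) <- strrep(residue, j - i + 1L)
  seq_record(paste0(x$id, "-", start, "/", end, residue), res,
             offset = x$offset, source = x$source)
}
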