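## Packaged oligonucleotide set for the proximal TGF-beta1 5' UTR and its
## adenine-substitution mutants, and reconstruction of the +1..+167 inserts.

#' Packaged TGF-beta1 construct oligonucleotides
#'
#' Returns the overlapping sense/antisense oligonucleotide pairs used to
#' build the 167-nt proximal TGF-beta1 5' UTR reporter inserts (endogenous
#' numbering +1..+167 of the NM_000660 transcript) and their
#' adenine-substitution mutants. Oligos are DNA as synthesised, 5' to 3',
#' with a clamp+HindIII adapter on the sense 5' end and an NcoI-containing
#' adapter on the antisense 5' end.
#'
#' @return A named list of pairs, each `list(name, sense, antisense)`.
#' @export
tgfb1_table1_oligos <- function() {
  path <- system.file("extdata", "tgfb1_table1_oligos.fasta",
                      package = "utrscan", mustWork = TRUE)
  lines <- readLines(path)
  heads <- grep("^>", lines)
  ends <- c(heads[-1] - 1L, length(lines))
  seqs <- mapply(function(h, e) paste(lines[(h + 1L):e], collapse = ""),
                 heads, ends)
  ids <- sub("^>", "", lines[heads])
  name <- sub("\\|.*$", "", ids)
  strand <- sub("^.*\\|", "", ids)
  out <- lapply(unique(name), function(nm) {
    list(name = nm,
         sense = seqs[name == nm & strand == "sense"][[1]],
         antisense = seqs[name == nm & strand == "antisense"][[1]])
  })
  names(out) <- unique(name)
  out
}

#' Mutated interval of each packaged construct
#'
#' @return A named list of `c(start, end)` intervals (+1-based insert
#'   coordinates) for the adenine-substitution constructs.
#' @export
tgfb1_mutant_regions <- function() {
  list(`pGL3-77/105A` = c(77L, 105L),
       `pGL3-92/105A` = c(92L, 105L),
       `pGL3-92/98A`  = c(92L, 98L),
       `pGL3-99/105A` = c(99L, 105L),
       `pGL3-50/56A`  = c(50L, 56L))
}

#' Reconstruct the +1..+167 inserts from the packaged oligonucleotides
#'
#' Assembles each construct by anneal/extension of its oligo pair
#' ([assemble_insert()]) and reconstructs the endogenous insert from the
#' same material: the pGL3-50/56A sense oligo is endogenous everywhere
#' except its 50..56 A-run, which is restored from the pGL3-92/105A sense
#' oligo (endogenous through +91). Two junction quirks of the printed oligos
#' are handled explicitly rather than silently:
#'
#' * the long antisense oligos carry one spacer residue between insert
#'   position +167 and the NcoI site, so the trimmed extension product is
#'   168 nt; the result is truncated to the annotated 167 (attribute
#'   `junction_trimmed` records the dropped residue);
#' * the pGL3-92/98A sense oligo shows an 8-residue A-run for the 7-position
#'   92..98 substitution; this is consistent because the endogenous residue
#'   at +99 is itself A.
#'
#' @param insert_length Annotated insert length (default 167).
#' @return A named list of [seq_record]s: `endogenous` first, then the five
#'   mutants.
#' @export
tgfb1_inserts <- function(insert_length = 167L) {
  oligos <- tgfb1_table1_oligos()
  inserts <- lapply(oligos, function(o)
    assemble_insert(o$sense, o$antisense, name = o$name,
                    insert_length = insert_length))
  ## endogenous sense oligo: 50/56A sense with the A-run region (oligo
  ## positions 58..64 behind the 8-nt adapter) restored from 92/105A sense
  s5056 <- oligos[["pGL3-50/56A"]]$sense
  s92105 <- oligos[["pGL3-92/105A"]]$sense
  endo_sense <- paste0(substr(s5056, 1L, 57L), substr(s92105, 58L, 64L),
                       substr(s5056, 65L, nchar(s5056)))
  endo <- assemble_insert(endo_sense, oligos[["pGL3-50/56A"]]$antisense,
                          name = "endogenous",
                          insert_length = insert_length)
  endo$source <- "assembled from packaged construct oligos"
  c(list(endogenous = endo), inserts)
}
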