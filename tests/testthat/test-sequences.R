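test_that("FASTA reading normalises DNA to RNA and round-trips", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">one", "ACGT"), path)
  recs <- read_fasta(path)
  expect_equal(as.character(recs$one), "ACGU")

  # mixed-case multi-entry file against a character-by-character parse
  lines <- c(">a desc", "acgu", "GGcc", ">b", "uuAA", ">c", "gcGC")
  manual <- list(a = "ACGUGGCC", b = "UUAA", c = "GCGC")
  path2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(lines, path2)
  recs2 <- read_fasta(path2)
  expect_equal(lapply(recs2, as.character), manual)

  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs2, out)
  back <- read_fasta(out)
  expect_equal(lapply(back, `[[`, "residues"),
               lapply(recs2, `[[`, "residues"))
})

test_that("malformed or empty FASTA is rejected with the offending line", {
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_error(read_fasta(empty), "line 1")
  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGU", ">late"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("sequence records validate their invariants", {
  expect_error(seq_record("x", ""), "empty")
  expect_error(seq_record("x", "ACGN"), "outside")
  expect_error(seq_record("x", "ACGU", offset = 0), "offset")
  r <- seq_record("x", "acgt", offset = 5)
  expect_equal(r$residues, "ACGU")
  expect_equal(length(r), 4L)
})

test_that("reverse complement is a Watson-Crick involution", {
  expect_equal(reverse_complement("ACGU"), "ACGU")  # own reverse complement
  set.seed(11)
  for (k in 1:20) {
    s <- random_rna(sample(5:40, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
  r <- seq_record("x", "GGAU")
  expect_equal(as.character(reverse_complement(r)), "AUCC")
})

test_that("antisense oligo tails reverse-complement into the sense strand", {
  oligos <- tgfb1_table1_oligos()
  endo <- tgfb1_inserts()$endogenous
  # 3' tail of the pGL3-92/105A antisense beyond the T-run is endogenous
  tail_rc <- reverse_complement("acggggcgtcccccctgcccccg")
  expect_true(grepl(tail_rc, as.character(endo), fixed = TRUE))
})

test_that("adapter trimming removes clamp+HindIII and NcoI motifs", {
  r <- seq_record("x", paste0("ccaagctt", "CCUUCGCGCC"))
  t1 <- trim_adapters(r, c(leading = "CCAAGCUU", trailing = ""))
  expect_equal(t1$residues, "CCUUCGCGCC")
  expect_equal(attr(t1, "removed")[["p5"]], 8L)

  r2 <- seq_record("y", "GGAUGGAUCC")
  w <- testthat::capture_warnings(t2 <- trim_adapters(r2))
  expect_length(w, 2L)                    # both ends reported absent
  expect_match(w, "not found", all = TRUE)
  expect_equal(t2$residues, "GGAUGGAUCC")
  expect_equal(unname(attr(t2, "removed")), c(0L, 0L))

  # both-end adapters on a toy 40-mer leave the interior 26-mer
  toy <- paste0("CCAAGCUU", strrep("AGUC", 6), "CCAUGGGG")
  t3 <- trim_adapters(seq_record("z", toy))
  expect_equal(t3$residues, strrep("AGUC", 6))
  expect_equal(unname(attr(t3, "removed")), c(8L, 8L))
  expect_equal(t3$offset, 1L)
})

test_that("anneal/extension assembly equals a hand-written extension", {
  # 18+18-mer pair overlapping by 10: product is the 26-mer written by hand
  sense <- "GGAUCCGUACGUACGGCC"
  overlap <- substr(sense, 9, 18)
  anti_rc <- paste0(overlap, "AAUUGGCC")   # sense-strand continuation
  antisense <- reverse_complement(anti_rc)
  prod <- assemble_insert(sense, antisense, trim = FALSE)
  expect_equal(as.character(prod), paste0(sense, "AAUUGGCC"))
  expect_equal(attr(prod, "overlap"), 10L)

  # fully complementary pair: zero extension
  full <- assemble_insert("GGAUCCGUACGUACGGCC",
                          reverse_complement("GGAUCCGUACGUACGGCC"),
                          trim = FALSE)
  expect_equal(as.character(full), "GGAUCCGUACGUACGGCC")

  expect_error(assemble_insert("GGGGGGGGGGGG", "GGGGGGGGGGGG"),
               "overlap")
})

test_that("the endogenous insert reconstructs to the published 167-mer", {
  ins <- tgfb1_inserts()
  endo <- ins$endogenous
  expect_equal(length(endo), 167L)
  expect_equal(substr(as.character(endo), 1, 21), "CCUUCGCGCCCUGGGCCAUCU")
  comp <- composition(endo, 59, 138)
  expect_equal(comp$counts, c(A = 4L, C = 36L, G = 36L, U = 4L))
  expect_equal(comp$gc_fraction, 72 / 80)
  # junctional spacer residue next to the NcoI site is flagged, not silent
  expect_equal(attr(endo, "junction_trimmed"), "C")
})

test_that("every mutant assembly equals an A-substitution of the endogenous", {
  ins <- tgfb1_inserts()
  regions <- tgfb1_mutant_regions()
  for (nm in names(regions)) {
    r <- regions[[nm]]
    expect_equal(as.character(ins[[nm]]),
                 as.character(apply_substitution(ins$endogenous,
                                                 r[1], r[2], "A")),
                 info = nm)
    expect_equal(length(ins[[nm]]), 167L)
  }
  # the 92/98A sense oligo's 8-residue A-run is consistent because the
  # endogenous +99 is itself adenine
  expect_equal(substr(as.character(ins$endogenous), 99, 99), "A")
})

test_that("region extraction respects reference coordinates", {
  ins <- tgfb1_inserts()
  stem <- extract_region(ins$endogenous, 77, 106)
  expect_equal(length(stem), 30L)
  expect_equal(stem$offset, 77L)
  # independent string-slice oracle
  expect_equal(as.character(stem),
               substr(as.character(ins$endogenous), 77, 106))
  # full range is the identity
  full <- extract_region(ins$endogenous, 1, 167)
  expect_equal(as.character(full), as.character(ins$endogenous))
  expect_error(extract_region(ins$endogenous, 100, 200), "valid: \\+1\\.\\.\\+167")

  shifted <- seq_record("s", "ACGUACGU", offset = 10)
  expect_equal(as.character(extract_region(shifted, 12, 15)), "GUAC")
})

test_that("composition matches a per-character tally and is permutation-invariant", {
  expect_equal(composition(seq_record("g", "GGGG"))$counts,
               c(A = 0L, C = 0L, G = 4L, U = 0L))
  expect_equal(composition(seq_record("g", "GGGG"))$gc_fraction, 1)
  set.seed(3)
  s <- random_rna(200)
  tally <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "U")))
  expect_equal(composition(seq_record("r", s))$counts,
               setNames(as.integer(tally), c("A", "C", "G", "U")))
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(composition(seq_record("p", perm))$counts,
               composition(seq_record("r", s))$counts)
  expect_equal(sum(composition(seq_record("r", s))$counts), 200L)
})

test_that("substitution replaces exactly the requested run", {
  r <- seq_record("x", "GGGGGGGGGG")
  m <- apply_substitution(r, 3, 6, "A")
  expect_equal(as.character(m), "GGAAAAGGGG")
  expect_equal(m$id, "x-3/6A")
  # substituting a residue by itself changes nothing
  same <- apply_substitution(r, 3, 6, "G")
  expect_equal(as.character(same), as.character(r))
  expect_error(apply_substitution(r, 8, 12, "A"), "out of range")
})
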