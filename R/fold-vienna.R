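## Thermodynamic backend: adapter to the ViennaRNA RNAfold program.

#' Is the RNAfold program available?
#'
#' The thermodynamic backend shells out to `RNAfold` (ViennaRNA); this
#' reports whether the program is on the PATH.
#'
#' @return Logical scalar.
#' @export
rnafold_available <- function() nzchar(Sys.which("RNAfold"))

## Fold many residue strings in a single RNAfold invocation.
## Returns a list per sequence: e_mfe, mfe_structure, and when pf=TRUE
## g_ensemble (and the bppm matrix when bppm=TRUE).
rnafold_fold_many <- function(residues, pf = TRUE, bppm = FALSE,
                              temperature = 37, parameter_set = "default") {
  if (!rnafold_available())
    stop("RNAfold not found on the PATH; the thermodynamic backend needs ",
         "ViennaRNA installed. Use backend='reference' otherwise.",
         call. = FALSE)
  par_args <- character()
  if (parameter_set == "turner1999")
    par_args <- c("-P", shQuote(vienna_parameter_file("rna_turner1999.par")))
  n <- length(residues)
  ids <- sprintf("s%06d", seq_len(n))
  dir <- tempfile("rnafold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  infile <- file.path(dir, "in.fa")
  writeLines(rbind(paste0(">", ids), toupper(residues)), infile)
  args <- c("--noPS", if (pf) "-p", par_args,
            if (temperature != 37) c("-T", format(temperature)),
            "--infile", shQuote(infile))
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  out <- suppressWarnings(system2("RNAfold", args, stdout = TRUE,
                                  stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("RNAfold exited with status ", status, call. = FALSE)
  heads <- grep("^>", out)
  if (length(heads) != n)
    stop("unexpected RNAfold output: ", length(heads), " records for ",
         n, " inputs", call. = FALSE)
  lapply(seq_len(n), function(k) {
    block <- out[heads[k]:(if (k < n) heads[k + 1] - 1L else length(out))]
    mfe_line <- block[3L]
    structure_str <- sub("\\s.*$", "", mfe_line)
    e_mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", mfe_line))
    res <- list(e_mfe = e_mfe, mfe_structure = structure_str)
    if (pf) {
      ens_line <- grep("\\[", block, value = TRUE)[1L]
      res$g_ensemble <- as.numeric(sub(".*\\[\\s*(-?[0-9.]+)\\]\\s*$",
                                       "\\1", ens_line))
      if (bppm) {
        ps <- file.path(dir, paste0(ids[k], "_dp.ps"))
        res$bppm <- parse_dotplot_bppm(ps, nchar(residues[k]))
      }
    }
    res
  })
}

## ViennaRNA installs its energy-parameter tables under
## <prefix>/share/ViennaRNA next to the RNAfold binary.
vienna_parameter_file <- function(name) {
  prefix <- dirname(dirname(Sys.which("RNAfold")))
  path <- file.path(prefix, "share", "ViennaRNA", name)
  if (!file.exists(path))
    stop("ViennaRNA parameter table not found: ", path,
         "; use parameter_set = 'default'", call. = FALSE)
  path
}

## RNAfold dot plots list 'i j sqrt(p) ubox' entries; square to recover p.
parse_dotplot_bppm <- function(ps_path, n) {
  if (!file.exists(ps_path))
    stop("RNAfold dot plot not found: ", ps_path, call. = FALSE)
  lines <- grep(" ubox$", readLines(ps_path), value = TRUE)
  lines <- grep("^[0-9]", lines, value = TRUE)
  m <- matrix(0, n, n)
  if (length(lines)) {
    f <- do.call(rbind, lapply(strsplit(lines, "\\s+"), function(x)
      as.numeric(x[1:3])))
    p <- f[, 3]^2
    m[cbind(f[, 1], f[, 2])] <- p
    m[cbind(f[, 2], f[, 1])] <- p
  }
  m
}
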