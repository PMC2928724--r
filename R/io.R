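## Tabular artefacts and run manifests.

#' Write a scan or pairing profile as TSV
#'
#' Header-bearing TSV with one row per window and floats at 6 significant
#' digits; column order is the profile's. Refuses to write an empty
#' profile and never overwrites silently.
#'
#' @param profile A `scan_profile` or any profile data frame.
#' @param path Output path.
#' @param overwrite Allow replacing an existing file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, overwrite = FALSE) {
  df <- as.data.frame(profile)
  if (nrow(df) == 0L) stop("profile is empty; nothing written",
                           call. = FALSE)
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite ", path, " (set overwrite = TRUE)",
         call. = FALSE)
  num <- vapply(df, is.numeric, NA) & !vapply(df, is.integer, NA)
  df[num] <- lapply(df[num], signif, digits = 6L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write composition tables as TSV
#'
#' Columns: id, start, end, A, C, G, U, gc_fraction.
#'
#' @param tables A `composition_table` or list of them.
#' @inheritParams write_profile
#' @return `path`, invisibly.
#' @export
write_composition <- function(tables, path, overwrite = FALSE) {
  if (inherits(tables, "composition_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, as.data.frame))
  write_profile(df, path, overwrite = overwrite)
}

#' Write a base-pair probability matrix as sparse TSV
#'
#' Emits `(i, j, p)` triples with `i < j` and `p >= min_p`.
#'
#' @param result A `fold_result` carrying a `bppm`.
#' @param path Output path.
#' @param min_p Smallest probability emitted (default 1e-6).
#' @inheritParams write_profile
#' @return `path`, invisibly.
#' @export
write_bppm <- function(result, path, min_p = 1e-6, overwrite = FALSE) {
  if (is.null(result$bppm))
    stop("fold_result has no base-pair probability matrix", call. = FALSE)
  m <- result$bppm
  idx <- which(upper.tri(m) & m >= min_p, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], p = m[idx])
  df <- df[order(df$i, df$j), , drop = FALSE]
  write_profile(df, path, overwrite = overwrite)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed, package and R versions, and md5
#' checksums of the declared artefacts, so every artefact is reproducible
#' from its manifest alone.
#'
#' @param path Manifest path (JSON).
#' @param config Arbitrary configuration list (should include the seed).
#' @param artefacts Character vector of artefact paths to checksum.
#' @return `path`, invisibly.
#' @export
run_manifest <- function(path, config = list(), artefacts = character()) {
  manifest <- list(
    package = "utrscan",
    package_version = as.character(utils::packageVersion("utrscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    artefacts = lapply(setNames(artefacts, basename(artefacts)),
                       function(f) list(path = f,
                                        md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
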