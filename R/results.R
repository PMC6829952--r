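#' Write result tables and a run manifest
#'
#' Writes each table as a deterministic tab-separated file (sorted rows,
#' fixed column order, `\n` line endings) plus `manifest.json` recording the
#' configuration, seed and MD5 checksums of the inputs and outputs. Two runs
#' with identical inputs and configuration produce byte-identical files.
#'
#' @param tables Named list of data frames; each is written as
#'   `<name>.tsv`.
#' @param out_dir Output directory, created if absent.
#' @param config Named list recorded verbatim in the manifest (include the
#'   thresholds used).
#' @param seed Integer seed recorded in the manifest.
#' @param input_paths Character vector of input file paths to checksum
#'   (optional).
#' @return Invisibly, the paths written (manifest last).
#' @export
write_results <- function(tables, out_dir, config = list(), seed = NA_integer_,
                          input_paths = character()) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  paths <- character(0)
  for (nm in sort(names(tables))) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  inputs <- if (length(input_paths))
    as.list(tools::md5sum(input_paths)) else NULL
  outputs <- as.list(tools::md5sum(paths))
  names(outputs) <- basename(names(outputs))
  manifest <- list(config = config, seed = seed,
                   input_checksums = inputs, output_checksums = outputs)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, mp))
}
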