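#' Construct a staged expression matrix
#'
#' Container for FPKM-scale expression values over a staged, replicated
#' design. Columns are ordered by stage (in `stage_order`) then replicate.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names sample identifiers. All values must be
#'   finite and non-negative (FPKM scale).
#' @param samples Data frame with columns `sample_id`, `stage`, `replicate`
#'   describing every column of `values`.
#' @param stage_order Character vector giving the time-axis order of stage
#'   labels. Defaults to order of first appearance in `samples`.
#' @return An object of class `germ_expr`: a list with elements `values`,
#'   `samples` and `stage_order`.
#' @examples
#' m <- matrix(1:12, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sh <- data.frame(sample_id = paste0("s", 1:4),
#'                  stage = rep(c("0", "24"), each = 2), replicate = c(1, 2, 1, 2))
#' expr <- expression_matrix(m, sh)
#' stage_labels(expr)
#' @export
expression_matrix <- function(values, samples, stage_order = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names", call. = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "stage", "replicate")
  if (!all(req %in% names(samples)))
    stop("`samples` needs columns sample_id, stage, replicate", call. = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  samples$stage <- as.character(samples$stage)
  samples$replicate <- as.integer(samples$replicate)
  if (is.null(stage_order)) stage_order <- unique(samples$stage)
  stage_order <- as.character(stage_order)

  x <- structure(
    list(values = values, samples = samples, stage_order = stage_order),
    class = "germ_expr"
  )
  validate_expression(x)
  # normalise column order: stage order, then replicate
  ord <- order(match(samples$stage, stage_order), samples$replicate)
  x$samples <- samples[ord, , drop = FALSE]
  rownames(x$samples) <- NULL
  x$values <- values[, x$samples$sample_id, drop = FALSE]
  x
}

validate_expression <- function(x) {
  v <- x$values
  s <- x$samples
  if (anyDuplicated(rownames(v)))
    stop("duplicate gene identifiers in expression matrix: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(s$sample_id))
    stop("duplicate sample identifiers in sample sheet", call. = FALSE)
  missing_cols <- setdiff(colnames(v), s$sample_id)
  if (length(missing_cols))
    stop("sample sheet does not cover matrix column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(s$sample_id, colnames(v))
  if (length(extra))
    stop("sample sheet lists sample(s) absent from matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (anyDuplicated(s[, c("stage", "replicate")]))
    stop("duplicate (stage, replicate) pair in sample sheet", call. = FALSE)
  if (!all(s$stage %in% x$stage_order))
    stop("sample sheet stage(s) absent from stage order: ",
         paste(setdiff(s$stage, x$stage_order), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(v) | v < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "expression values must be finite and >= 0; first offence at gene '%s', sample '%s'",
      rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.germ_expr <- function(x, ...) {
  cat(sprintf("germ_expr: %d genes x %d samples; stages: %s\n",
              nrow(x$values), ncol(x$values),
              paste(x$stage_order, collapse = ", ")))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x A `germ_expr` object.
#' @export
stage_labels <- function(x) x$stage_order

#' Samples belonging to one stage
#' @param x A `germ_expr` object.
#' @param stage Stage label.
#' @return Character vector of sample ids, replicate order.
#' @keywords internal
stage_samples <- function(x, stage) {
  if (!stage %in% x$stage_order)
    stop("unknown stage '", stage, "'; known stages: ",
         paste(x$stage_order, collapse = ", "), call. = FALSE)
  s <- x$samples[x$samples$stage == stage, , drop = FALSE]
  s$sample_id[order(s$replicate)]
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix file is tab-separated with a first column `gene_id` and one
#' column per sample; the sample sheet is tab-separated with columns
#' `sample_id`, `stage`, `replicate`. Stage order is the order of first
#' appearance in the sheet unless overridden.
#'
#' @param matrix_path Path to the expression TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @param stage_order Optional explicit stage order.
#' @return A [expression_matrix()] object.
#' @export
read_expression <- function(matrix_path, sample_sheet_path, stage_order = NULL) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    stop("expression matrix needs a gene_id column plus sample columns", call. = FALSE)
  gene_ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     col[bad[1]], gene_ids[bad[1]], names(vals)[j]), call. = FALSE)
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  sheet <- utils::read.delim(sample_sheet_path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
  names(sheet) <- tolower(names(sheet))
  expression_matrix(m, sheet, stage_order = stage_order)
}

#' Write an expression matrix and sample sheet as TSV
#'
#' Inverse of [read_expression()]; round-trips exactly (values written with
#' full precision).
#'
#' @param x A `germ_expr` object.
#' @param matrix_path,sample_sheet_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_expression <- function(x, matrix_path, sample_sheet_path) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path, exact = TRUE)
  write_tsv(x$samples, sample_sheet_path)
  invisible(c(matrix_path, sample_sheet_path))
}

# deterministic TSV writer used for all outputs; exact = TRUE serialises
# doubles with %.17g so read.delim restores them bit for bit
write_tsv <- function(df, path, exact = FALSE) {
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      out[[j]] <- if (exact) sprintf("%.17g", col) else
        formatC(col, digits = 15, format = "g")
    } else {
      out[[j]] <- as.character(col)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
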