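#' Construct a Mapman-style category map
#'
#' Holds the hierarchical BIN catalogue (dot-separated integer codes such as
#' `"2.1.3"`) and the (bincode, gene) assignments. Ancestor bins of every
#' assigned code are always present in the catalogue; a gene may belong to
#' several bins.
#'
#' @param bins Data frame with columns `bincode`, `name`.
#' @param assignments Data frame with columns `bincode`, `gene_id`.
#' @return An object of class `mapman_map` with elements `bins` and
#'   `assignments` (both de-duplicated and sorted).
#' @export
category_map <- function(bins, assignments) {
  bins <- as.data.frame(bins, stringsAsFactors = FALSE)
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  bins$bincode <- as.character(bins$bincode)
  bins$name <- as.character(bins$name)
  assignments$bincode <- as.character(assignments$bincode)
  assignments$gene_id <- as.character(assignments$gene_id)
  check_bincodes(c(bins$bincode, assignments$bincode))
  # auto-create missing ancestors
  anc <- unique(unlist(lapply(bins$bincode, bin_ancestors)))
  new <- setdiff(anc, bins$bincode)
  if (length(new))
    bins <- rbind(bins, data.frame(bincode = new, name = new,
                                   stringsAsFactors = FALSE))
  if (!all(assignments$bincode %in% bins$bincode))
    stop("assignment references bincode(s) absent from catalogue: ",
         paste(setdiff(assignments$bincode, bins$bincode), collapse = ", "),
         call. = FALSE)
  bins <- bins[!duplicated(bins$bincode), , drop = FALSE]
  bins <- bins[order_bincodes(bins$bincode), , drop = FALSE]
  assignments <- unique(assignments)
  assignments <- assignments[order(match(assignments$bincode,
                                         bins$bincode),
                                   assignments$gene_id), , drop = FALSE]
  rownames(bins) <- rownames(assignments) <- NULL
  structure(list(bins = bins, assignments = assignments),
            class = "mapman_map")
}

#' @export
print.mapman_map <- function(x, ...) {
  cat(sprintf("mapman_map: %d bins, %d assignments over %d genes\n",
              nrow(x$bins), nrow(x$assignments),
              length(unique(x$assignments$gene_id))))
  invisible(x)
}

check_bincodes <- function(codes) {
  bad <- codes[!grepl("^[0-9]+(\\.[0-9]+)*$", codes)]
  if (length(bad))
    stop("malformed bincode(s): ", paste(unique(bad), collapse = ", "),
         "; expected dot-separated integers like '2.1.3'", call. = FALSE)
  invisible(codes)
}

# strict ancestors of a bincode: "2.1.3" -> c("2", "2.1")
bin_ancestors <- function(code) {
  parts <- strsplit(code, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2) return(character(0))
  vapply(seq_len(length(parts) - 1L),
         function(i) paste(parts[seq_len(i)], collapse = "."), "")
}

# numeric-aware ordering of bincodes ("10" after "2", "2.1" after "2")
order_bincodes <- function(codes) {
  if (!length(codes)) return(integer(0))
  parts <- lapply(strsplit(codes, ".", fixed = TRUE), as.integer)
  depth <- max(lengths(parts), 1L)
  mat <- matrix(unlist(lapply(parts, function(p)
    c(p, rep(-1L, depth - length(p))))), ncol = depth, byrow = TRUE)
  do.call(order, as.data.frame(mat))
}

#' Roll a category map up to ancestor bins
#'
#' After roll-up every gene assigned to a bin is also a member of each
#' ancestor bin, so aggregate categories (e.g. `"2"` major CHO metabolism)
#' contain the union of their sub-bins.
#'
#' @param map A `mapman_map`.
#' @return A `mapman_map` with the ancestor-closed assignment set.
#' @export
rollup_category_map <- function(map) {
  a <- map$assignments
  anc <- lapply(a$bincode, bin_ancestors)
  n_anc <- lengths(anc)
  extra <- data.frame(bincode = unlist(anc),
                      gene_id = rep(a$gene_id, n_anc),
                      stringsAsFactors = FALSE)
  category_map(map$bins, rbind(a, extra))
}

#' Genes of one bin
#' @param map A `mapman_map`.
#' @param bincode A bin code present in the catalogue.
#' @return Character vector of gene ids.
#' @export
bin_genes <- function(map, bincode) {
  sort(unique(map$assignments$gene_id[map$assignments$bincode == bincode]))
}

#' Read a Mapman mapping file
#'
#' Accepts the classic 5-column Mapman "mapping" export: tab-separated with
#' header `BINCODE, NAME, IDENTIFIER, DESCRIPTION, TYPE`; fields may be
#' single-quoted. Rows with an empty identifier define the bin catalogue
#' only. Identifiers are lower-cased by default, matching Mapman exports.
#'
#' @param path Path to the mapping TSV.
#' @param case_fold Lower-case gene identifiers (default `TRUE`).
#' @param rollup Apply [rollup_category_map()] before returning
#'   (default `TRUE`).
#' @return A `mapman_map`.
#' @export
read_mapman_mapping <- function(path, case_fold = TRUE, rollup = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  names(raw) <- toupper(trimws(names(raw)))
  need <- c("BINCODE", "NAME", "IDENTIFIER")
  if (!all(need %in% names(raw)))
    stop("mapping file must have columns BINCODE, NAME, IDENTIFIER",
         call. = FALSE)
  unq <- function(x) gsub("^'|'$", "", trimws(x))
  bincode <- unq(raw$BINCODE)
  name <- unq(raw$NAME)
  ident <- unq(raw$IDENTIFIER)
  if (case_fold) ident <- tolower(ident)
  check_bincodes(bincode)
  bins <- data.frame(bincode = bincode, name = name,
                     stringsAsFactors = FALSE)
  bins <- bins[!duplicated(bins$bincode), , drop = FALSE]
  has_gene <- !is.na(ident) & nzchar(ident)
  assignments <- data.frame(bincode = bincode[has_gene],
                            gene_id = ident[has_gene],
                            stringsAsFactors = FALSE)
  map <- category_map(bins, assignments)
  if (rollup) rollup_category_map(map) else map
}

#' Write a category map in Mapman mapping format
#'
#' @param map A `mapman_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mapman_mapping <- function(map, path) {
  name_of <- stats::setNames(map$bins$name, map$bins$bincode)
  cat_rows <- data.frame(BINCODE = map$bins$bincode,
                         NAME = map$bins$name,
                         IDENTIFIER = "", DESCRIPTION = "", TYPE = "",
                         stringsAsFactors = FALSE)
  a <- map$assignments
  gene_rows <- data.frame(BINCODE = a$bincode,
                          NAME = unname(name_of[a$bincode]),
                          IDENTIFIER = a$gene_id,
                          DESCRIPTION = "", TYPE = "T",
                          stringsAsFactors = FALSE)
  write_tsv(rbind(cat_rows, gene_rows), path)
  invisible(path)
}
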