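#' Gene-by-stage expression mask
#'
#' A gene counts as expressed at a stage when at least `min_replicates` of
#' that stage's replicates reach `threshold` FPKM. The defaults (1 FPKM in
#' at least 2 replicates) are the conventional presence call; both are
#' configurable.
#'
#' @param expr A `germ_expr`.
#' @param threshold FPKM presence threshold (default 1).
#' @param min_replicates Minimum replicates at or above threshold
#'   (default 2).
#' @return Logical matrix, genes x stages.
#' @export
expressed_mask <- function(expr, threshold = 1, min_replicates = 2L) {
  stopifnot(threshold >= 0, min_replicates >= 1)
  stages <- expr$stage_order
  out <- sapply(stages, function(st) {
    ids <- stage_samples(expr, st)
    if (min_replicates > length(ids))
      stop("min_replicates (", min_replicates, ") exceeds the ",
           length(ids), " replicate(s) of stage '", st, "'", call. = FALSE)
    rowSums(expr$values[, ids, drop = FALSE] >= threshold) >= min_replicates
  })
  colnames(out) <- stages
  out
}

#' Stage-specific gene partition
#'
#' A gene is stage-specific when it is expressed at exactly one stage. The
#' partition of the Venn diagram over stages: one gene set per stage, plus
#' the complement (genes expressed at zero or at two or more stages).
#'
#' @param mask Logical gene x stage matrix from [expressed_mask()].
#' @return Named list: one sorted gene vector per stage, plus
#'   `shared_or_unexpressed`.
#' @export
venn_partition <- function(mask) {
  n_stages <- rowSums(mask)
  specific <- n_stages == 1
  out <- lapply(colnames(mask), function(st)
    sort(rownames(mask)[specific & mask[, st]]))
  names(out) <- colnames(mask)
  out$shared_or_unexpressed <- sort(rownames(mask)[!specific])
  out
}

#' Annotate stage-specific genes with their categories
#'
#' @param specific_sets List from [venn_partition()].
#' @param map A `mapman_map`; rolled up before the join so aggregate bins
#'   are listed too.
#' @return Data frame `stage`, `gene_id`, `bincodes` (comma-joined, empty
#'   for unannotated genes, which are retained).
#' @export
annotate_specific <- function(specific_sets, map) {
  map <- rollup_category_map(map)
  a <- map$assignments
  stages <- setdiff(names(specific_sets), "shared_or_unexpressed")
  rows <- lapply(stages, function(st) {
    genes <- specific_sets[[st]]
    if (!length(genes))
      return(data.frame(stage = character(), gene_id = character(),
                        bincodes = character(), stringsAsFactors = FALSE))
    bcs <- vapply(genes, function(g) {
      b <- a$bincode[a$gene_id == g]
      paste(b[order_bincodes(b)], collapse = ",")
    }, "")
    data.frame(stage = st, gene_id = genes, bincodes = unname(bcs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stage-specific gene counts
#'
#' @param specific_sets List from [venn_partition()].
#' @return Data frame `stage`, `n_specific`.
#' @export
specific_summary <- function(specific_sets) {
  stages <- setdiff(names(specific_sets), "shared_or_unexpressed")
  data.frame(stage = stages,
             n_specific = vapply(specific_sets[stages], length, 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}
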