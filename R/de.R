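#' Build the two contrast systems over a stage order
#'
#' The fixed-reference system compares every later stage to the baseline
#' (first) stage; the continuous system compares every stage to its
#' immediate predecessor. For a six-stage design each system has five
#' contrasts, and the first contrast of both systems is identical.
#'
#' @param stage_order Character vector of stage labels, time order.
#' @return List with elements `fixed` and `continuous`, each a data frame
#'   with columns `test`, `ref`, `system`, `contrast_id`.
#' @examples
#' build_contrast_systems(c("0", "0.75", "6", "24", "48", "144"))$fixed
#' @export
build_contrast_systems <- function(stage_order) {
  stage_order <- as.character(stage_order)
  if (length(stage_order) < 2)
    stop("need at least two stages", call. = FALSE)
  test <- stage_order[-1]
  fixed <- data.frame(test = test, ref = stage_order[1], system = "fixed",
                      stringsAsFactors = FALSE)
  continuous <- data.frame(test = test,
                           ref = stage_order[-length(stage_order)],
                           system = "continuous", stringsAsFactors = FALSE)
  fixed$contrast_id <- paste0(fixed$test, "_vs_", fixed$ref)
  continuous$contrast_id <- paste0(continuous$test, "_vs_", continuous$ref)
  list(fixed = fixed, continuous = continuous)
}

#' Per-gene mean expression of one stage
#'
#' Arithmetic mean of replicate FPKM values after adding the pseudo-count
#' to every value. The pseudo-count guarantees finite log ratios for genes
#' with zero expression.
#'
#' @param expr A `germ_expr`.
#' @param stage Stage label.
#' @param pseudocount Value added to every FPKM before averaging
#'   (default 0.5).
#' @return Named numeric vector, one mean per gene.
#' @export
stage_means <- function(expr, stage, pseudocount = 0.5) {
  ids <- stage_samples(expr, stage)
  rowMeans(expr$values[, ids, drop = FALSE] + pseudocount)
}

#' Per-gene signal statistics (M, D) for one contrast
#'
#' `M` is the log2 ratio of pseudo-counted stage means (test over
#' reference); `D` is the absolute difference of the stage means (FPKM
#' units; the pseudo-count cancels in the difference).
#'
#' @param expr A `germ_expr`.
#' @param contrast One-row data frame (or list) with `test` and `ref` stage
#'   labels.
#' @param pseudocount See [stage_means()].
#' @return Data frame `gene_id`, `M`, `D`.
#' @export
signal_statistics <- function(expr, contrast, pseudocount = 0.5) {
  mt <- stage_means(expr, contrast$test, pseudocount)
  mr <- stage_means(expr, contrast$ref, pseudocount)
  data.frame(gene_id = rownames(expr$values),
             M = log2(mt / mr),
             D = abs(mt - mr),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical noise distribution for one contrast
#'
#' For every gene and every unordered pair of replicates within the same
#' stage (both stages of the contrast pooled) this computes the absolute
#' log2 ratio `|M*|` and the absolute difference `D*` of the two
#' pseudo-counted replicate values. The pooled cloud is the null against
#' which [de_probability()] ranks each gene's signal.
#'
#' @inheritParams signal_statistics
#' @return Data frame with columns `m` (`|M*|`, `>= 0`) and `d` (`D*`,
#'   `>= 0`), `2 * choose(r, 2) * n_genes` rows for `r` replicates per
#'   stage.
#' @export
noise_distribution <- function(expr, contrast, pseudocount = 0.5) {
  pieces <- lapply(c(contrast$ref, contrast$test), function(stage) {
    ids <- stage_samples(expr, stage)
    if (length(ids) < 2)
      stop("stage '", stage, "' has a single replicate; the noise ",
           "distribution needs >= 2 replicates per stage (supply ",
           "simulated technical replicates or use fold-change-only calls)",
           call. = FALSE)
    v <- expr$values[, ids, drop = FALSE] + pseudocount
    pr <- utils::combn(length(ids), 2)
    do.call(rbind, lapply(seq_len(ncol(pr)), function(j) {
      a <- v[, pr[1, j]]
      b <- v[, pr[2, j]]
      cbind(m = abs(log2(a / b)), d = abs(a - b))
    }))
  })
  out <- as.data.frame(do.call(rbind, pieces))
  rownames(out) <- NULL
  out
}

#' Nonparametric probability of differential expression
#'
#' For each gene, the fraction of noise points strictly dominated by the
#' gene's signal: `(m*, d*)` counts when `m* < |M|` and `d* < D`. Ties
#' count against the gene, so a gene with `M = 0, D = 0` has probability
#' exactly 0.
#'
#' @param signal Data frame from [signal_statistics()].
#' @param noise Data frame from [noise_distribution()].
#' @return Numeric vector of probabilities in `[0, 1]`, one per signal row.
#' @export
de_probability <- function(signal, noise) {
  if (nrow(noise) == 0)
    stop("empty noise distribution", call. = FALSE)
  nm <- noise$m
  nd <- noise$d
  total <- length(nm)
  aM <- abs(signal$M)
  aD <- signal$D
  # offline 2D dominance count: sweep genes by |M| ascending, insert noise
  # points with m* < |M| into a Fenwick tree indexed by the rank of d*, and
  # query the prefix count of d* values strictly below D
  om <- order(nm)
  nm_s <- nm[om]
  nd_s <- nd[om]
  d_all <- sort(nd)
  d_rank <- rank(nd_s, ties.method = "first")
  qpos <- findInterval(aD, d_all, left.open = TRUE)  # # of d* < D per gene
  tree <- integer(total)
  counts <- numeric(length(aM))
  ptr <- 0L
  for (i in order(aM)) {
    while (ptr < total && nm_s[ptr + 1L] < aM[i]) {
      ptr <- ptr + 1L
      j <- d_rank[ptr]
      while (j <= total) {
        tree[j] <- tree[j] + 1L
        j <- j + bitwAnd(j, -j)
      }
    }
    j <- qpos[i]
    cnt <- 0L
    while (j > 0L) {
      cnt <- cnt + tree[j]
      j <- j - bitwAnd(j, -j)
    }
    counts[i] <- cnt
  }
  counts / total
}

#' Apply the fold-change and probability thresholds
#'
#' A gene is called `up` when its fold change `2^M` is at least
#' `fc_threshold` and its probability at least `prob_threshold`; `down`
#' symmetrically for `2^-M`; otherwise `ns`. Both thresholds are inclusive.
#'
#' @param M Log2 ratio vector.
#' @param probability Probability vector.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param prob_threshold Probability threshold (default 0.8).
#' @return Character vector in `{"up", "down", "ns"}`.
#' @export
call_de <- function(M, probability, fc_threshold = 2, prob_threshold = 0.8) {
  stopifnot(fc_threshold > 0, prob_threshold > 0)
  lfc <- log2(fc_threshold)
  out <- rep("ns", length(M))
  pass <- probability >= prob_threshold
  out[pass & M >= lfc] <- "up"
  out[pass & -M >= lfc] <- "down"
  out
}

#' Run the differential-expression caller over a set of contrasts
#'
#' @param expr A `germ_expr`.
#' @param contrasts Data frame of contrasts as produced by
#'   [build_contrast_systems()] (rows with `test`, `ref`, `system`,
#'   `contrast_id`), or one element of that list.
#' @param pseudocount,fc_threshold,prob_threshold See [stage_means()] and
#'   [call_de()].
#' @return Data frame `gene_id`, `contrast_id`, `system`, `test`, `ref`,
#'   `M`, `D`, `probability`, `call`, ordered by contrast then gene.
#' @examples
#' sim <- simulate_expression(simulation_config(n_genes = 200, genes_per_category = 10, seed = 3),
#'                            germination_schedule())
#' cs <- build_contrast_systems(stage_labels(sim$expr))
#' de <- run_de(sim$expr, cs$fixed)
#' table(de$call, de$contrast_id)
#' @export
run_de <- function(expr, contrasts, pseudocount = 0.5,
                   fc_threshold = 2, prob_threshold = 0.8) {
  res <- lapply(seq_len(nrow(contrasts)), function(i) {
    ct <- contrasts[i, ]
    sig <- signal_statistics(expr, ct, pseudocount)
    noise <- noise_distribution(expr, ct, pseudocount)
    prob <- de_probability(sig, noise)
    data.frame(gene_id = sig$gene_id,
               contrast_id = ct$contrast_id,
               system = ct$system,
               test = ct$test, ref = ct$ref,
               M = sig$M, D = sig$D,
               probability = prob,
               call = call_de(sig$M, prob, fc_threshold, prob_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(match(out$contrast_id, contrasts$contrast_id),
                   out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Read externally produced DE calls
#'
#' Accepts a TSV with columns `gene_id`, `contrast_id`, `call` (values
#' `up`/`down`/`ns`), allowing the enrichment and activity stages to run on
#' calls from any external caller.
#'
#' @param path Path to the TSV.
#' @return Data frame with those three columns.
#' @export
read_de_calls <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "contrast_id", "call")
  if (!all(need %in% names(x)))
    stop("DE-call file must have columns gene_id, contrast_id, call",
         call. = FALSE)
  bad <- setdiff(unique(x$call), c("up", "down", "ns"))
  if (length(bad))
    stop("unknown call value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  x[, need]
}
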