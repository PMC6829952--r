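#' Enrichment universe
#'
#' @param expr A `germ_expr`.
#' @param map A `mapman_map`.
#' @param mode `"annotated"` (genes present in both the matrix and the
#'   mapping; default) or `"all_measured"` (every matrix gene).
#' @return Sorted character vector of gene ids.
#' @export
build_universe <- function(expr, map, mode = c("annotated", "all_measured")) {
  mode <- match.arg(mode)
  measured <- rownames(expr$values)
  out <- switch(mode,
                annotated = intersect(measured, unique(map$assignments$gene_id)),
                all_measured = measured)
  if (length(out) == 0)
    stop("empty enrichment universe (no measured gene is annotated)",
         call. = FALSE)
  sort(out)
}

#' Two-tailed hypergeometric p-value
#'
#' Exact two-sided test of the overlap `k` between a category of size `K`
#' and a draw of `n` differentially expressed genes from a universe of `N`.
#' The default two-sided method is minimum-likelihood summation (the
#' convention of Fisher's exact test): the p-value sums the point
#' probabilities of every table no more likely than the observed one, using
#' a relative tolerance of 1e-7 for the likelihood comparison.
#' `method = "double"` doubles the smaller tail instead (capped at 1).
#'
#' @param N Universe size.
#' @param K Category size within the universe.
#' @param n Number of DE genes (of one direction) within the universe.
#' @param k Overlap, `max(0, n + K - N) <= k <= min(n, K)`.
#' @param method Two-sided convention, `"minlike"` (default) or `"double"`.
#' @return p-value in `[0, 1]`.
#' @examples
#' hypergeom_two_tailed(20, 5, 8, 5)
#' stats::fisher.test(matrix(c(5, 3, 0, 12), 2))$p.value  # same convention
#' @export
hypergeom_two_tailed <- function(N, K, n, k, method = c("minlike", "double")) {
  method <- match.arg(method)
  check_contingency(N, K, n, k)
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  support <- lo:hi
  probs <- stats::dhyper(support, K, N - K, n)
  pk <- probs[k - lo + 1L]
  p <- if (method == "minlike") {
    sum(probs[probs <= pk * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= k])
    upper <- sum(probs[support >= k])
    min(1, 2 * min(lower, upper))
  }
  min(max(p, 0), 1)
}

check_contingency <- function(N, K, n, k) {
  if (any(c(N, K, n, k) != floor(c(N, K, n, k))) || any(c(N, K, n, k) < 0))
    stop("N, K, n, k must be non-negative integers", call. = FALSE)
  if (K > N || n > N)
    stop("K and n must not exceed N", call. = FALSE)
  if (k > min(K, n) || k < max(0, n + K - N))
    stop("k outside the feasible range for (N, K, n)", call. = FALSE)
  invisible(TRUE)
}

# p-values for every k in the support of (N, K, n) at once (minlike method);
# used for grid sweeps
hyper_p_profile <- function(N, K, n) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  support <- lo:hi
  probs <- stats::dhyper(support, K, N - K, n)
  o <- order(probs)
  cum <- cumsum(probs[o])
  sorted <- probs[o]
  idx <- findInterval(probs * (1 + 1e-7), sorted)
  p <- pmin(pmax(cum[idx], 0), 1)
  data.frame(k = support, p = p)
}

#' Convert a two-tailed p-value to a signed Z-value
#'
#' `Z = sign(observed - expected) * qnorm(1 - p/2)`, zero when observed
#' equals expected, with `|Z|` capped at `z_cap`. This reproduces the
#' 1.96 significance convention exactly: `|Z| >= qnorm(0.975)` iff
#' `p <= 0.05`.
#'
#' @param p Two-tailed p-value(s) in `[0, 1]`.
#' @param observed Observed overlap(s).
#' @param expected Expected overlap(s) `n * K / N`.
#' @param z_cap Cap on `|Z|` (default 8); p-values that underflow to 0 map
#'   to `±z_cap` with a warning.
#' @return Signed Z-value(s).
#' @export
p_to_z <- function(p, observed, expected, z_cap = 8) {
  if (any(p < 0 | p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  sgn <- sign(observed - expected)
  if (any(p == 0 & sgn != 0))
    warning("p-value underflow to 0; Z capped at ", z_cap, call. = FALSE)
  z <- ifelse(sgn == 0, 0, sgn * stats::qnorm(1 - p / 2))
  pmin(pmax(z, -z_cap), z_cap)
}

#' Directional category enrichment over all contrasts
#'
#' For every rolled-up bin of at least `min_bin_size` universe genes, every
#' contrast, and each direction (`up`, `down`), computes the two-tailed
#' hypergeometric p-value of the overlap between the bin and the DE genes
#' of that direction, and the signed Z-value. `n` counts DE genes of one
#' direction only; both directions share the same universe.
#'
#' @param de Data frame of DE calls with columns `gene_id`, `contrast_id`,
#'   `call` (from [run_de()] or [read_de_calls()]).
#' @param map A `mapman_map` (rolled up automatically).
#' @param universe Character vector from [build_universe()].
#' @param min_bin_size Smallest universe-restricted bin tested (default 5).
#' @param z_cap See [p_to_z()].
#' @param method Two-sided convention, see [hypergeom_two_tailed()].
#' @return Data frame `bincode`, `bin_name`, `contrast_id`, `direction`,
#'   `N`, `K`, `n`, `k`, `expected`, `p`, `Z`, ordered by bin, contrast,
#'   direction.
#' @export
enrich_all <- function(de, map, universe, min_bin_size = 5, z_cap = 8,
                       method = c("minlike", "double")) {
  method <- match.arg(method)
  map <- rollup_category_map(map)
  a <- map$assignments[map$assignments$gene_id %in% universe, , drop = FALSE]
  bin_sizes <- table(a$bincode)
  keep <- names(bin_sizes)[bin_sizes >= min_bin_size]
  keep <- keep[order_bincodes(keep)]
  name_of <- stats::setNames(map$bins$name, map$bins$bincode)
  N <- length(universe)
  contrast_ids <- unique(de$contrast_id)
  de_u <- de[de$gene_id %in% universe, , drop = FALSE]

  rows <- list()
  for (ct in contrast_ids) {
    dct <- de_u[de_u$contrast_id == ct, , drop = FALSE]
    for (dir in c("up", "down")) {
      de_genes <- unique(dct$gene_id[dct$call == dir])
      n <- length(de_genes)
      for (bc in keep) {
        members <- a$gene_id[a$bincode == bc]
        K <- length(unique(members))
        k <- length(intersect(de_genes, members))
        expected <- n * K / N
        p <- hypergeom_two_tailed(N, K, n, k, method = method)
        rows[[length(rows) + 1L]] <- data.frame(
          bincode = bc, bin_name = unname(name_of[bc]),
          contrast_id = ct, direction = dir,
          N = N, K = K, n = n, k = k,
          expected = expected, p = p,
          Z = p_to_z(p, k, expected, z_cap),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bincode = character(), bin_name = character(),
               contrast_id = character(), direction = character(),
               N = integer(), K = integer(), n = integer(), k = integer(),
               expected = numeric(), p = numeric(), Z = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(match(out$bincode, keep),
                   match(out$contrast_id, contrast_ids),
                   match(out$direction, c("up", "down"))), ]
  rownames(out) <- NULL
  out
}
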