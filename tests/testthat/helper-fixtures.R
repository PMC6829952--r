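# Shared fixtures and independent oracles, built in code at test time.

# small two-stage, three-replicate expression object with chosen values
tiny_expr <- function(values = NULL, stages = c("0", "24"), reps = 3) {
  n_samp <- length(stages) * reps
  if (is.null(values)) {
    values <- matrix(seq_len(4 * n_samp), nrow = 4,
                     dimnames = list(paste0("g", 1:4), NULL))
  }
  colnames(values) <- unlist(lapply(stages, function(s)
    paste0("T", s, "_r", seq_len(reps))))
  samples <- data.frame(
    sample_id = colnames(values),
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), times = length(stages)))
  expression_matrix(values, samples, stage_order = stages)
}

tiny_map <- function() {
  category_map(
    bins = data.frame(bincode = c("2", "2.1", "11"),
                      name = c("major CHO metabolism",
                               "major CHO metabolism.synthesis",
                               "lipid metabolism")),
    assignments = data.frame(bincode = c("2.1", "2.1", "11", "11"),
                             gene_id = c("g1", "g2", "g3", "g4")))
}

# enumeration oracle for the two-tailed hypergeometric p (minlike),
# via direct combinatorial point probabilities — exact in double for N <= 40
hyper_oracle <- function(N, K, n, k) {
  j <- max(0, n + K - N):min(n, K)
  probs <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  pk <- probs[j == k]
  sum(probs[probs <= pk * (1 + 1e-7)])
}

hyper_oracle_profile <- function(N, K, n) {
  j <- max(0, n + K - N):min(n, K)
  probs <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  vapply(seq_along(j), function(i)
    sum(probs[probs <= probs[i] * (1 + 1e-7)]), 0)
}

# brute-force DE probability: per-gene loop over every noise point
brute_de_probability <- function(signal, noise) {
  vapply(seq_len(nrow(signal)), function(i)
    mean(noise$m < abs(signal$M[i]) & noise$d < signal$D[i]), 0)
}

# brute-force stage-specific classifier: per-gene scan of the mask
brute_specific <- function(mask) {
  out <- lapply(colnames(mask), function(st) character(0))
  names(out) <- colnames(mask)
  shared <- character(0)
  for (g in rownames(mask)) {
    on <- colnames(mask)[mask[g, ]]
    if (length(on) == 1) out[[on]] <- c(out[[on]], g) else shared <- c(shared, g)
  }
  out <- lapply(out, sort)
  out$shared_or_unexpressed <- sort(shared)
  out
}

# random DE-call table over a random category map, for enrichment properties
random_de_instance <- function(seed) {
  set.seed(seed)
  n_genes <- sample(30:80, 1)
  genes <- sprintf("r%03d", seq_len(n_genes))
  bins <- data.frame(bincode = as.character(1:4),
                     name = paste("bin", 1:4))
  assignments <- data.frame(
    bincode = sample(bins$bincode, n_genes, replace = TRUE),
    gene_id = genes)
  map <- category_map(bins, assignments)
  de <- data.frame(
    gene_id = genes,
    contrast_id = "t_vs_r",
    call = sample(c("up", "down", "ns"), n_genes, replace = TRUE,
                  prob = c(0.25, 0.25, 0.5)))
  list(map = map, de = de, genes = genes)
}

# schedule whose planted trajectories ramp monotonically in expression:
# every continuous step is a full 2-fold change, so both contrast systems
# see the same direction at every active stage
monotone_schedule <- function(stage_labels = c("0", "0.75", "6", "24", "48", "144")) {
  s <- stage_labels
  ramp <- seq(1.25, by = 1.25, length.out = 5)
  list(
    schedule_entry("2", +1, s[2:6], ramp, 0.6),
    schedule_entry("4", +1, s[2:6], ramp, 0.6),
    schedule_entry("11", -1, s[2:6], ramp, 0.6),
    schedule_entry("13", +1, s[2:6], ramp, 0.6),
    schedule_entry("29", -1, s[2:6], ramp, 0.6)
  )
}
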