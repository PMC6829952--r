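#' Simulation configuration for a staged germination time course
#'
#' Defaults emulate the study design the pipeline targets: six germination
#' stages (0, 0.75, 6, 24, 48 and 144 h after imbibition) with three
#' replicates each, FPKM-scale baselines drawn log-normally, and
#' multiplicative log-normal replicate noise.
#'
#' @param n_genes Total genes in the matrix.
#' @param n_categories Number of functional bins; the first
#'   `n_categories * genes_per_category` genes are assigned one bin each,
#'   remaining genes stay unannotated.
#' @param genes_per_category Genes per bin.
#' @param stage_labels Stage labels in time order (hours).
#' @param replicates Replicates per stage.
#' @param baseline_meanlog,baseline_sdlog Parameters of the log-normal
#'   baseline FPKM distribution (natural-log scale).
#' @param noise_sd Replicate noise standard deviation on the log2 scale.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_categories = 20L,
                              genes_per_category = 40L,
                              stage_labels = c("0", "0.75", "6", "24", "48", "144"),
                              replicates = 3L,
                              baseline_meanlog = 3,
                              baseline_sdlog = 1,
                              noise_sd = 0.25,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_categories = as.integer(n_categories),
              genes_per_category = as.integer(genes_per_category),
              stage_labels = as.character(stage_labels),
              replicates = as.integer(replicates),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0, cfg$n_categories > 0,
            cfg$genes_per_category > 0, cfg$replicates > 0,
            length(cfg$stage_labels) >= 2, cfg$noise_sd >= 0)
  if (cfg$n_categories * cfg$genes_per_category > cfg$n_genes)
    stop("n_categories * genes_per_category exceeds n_genes", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Define a planted category activation schedule
#'
#' Each entry plants a perturbation on one category: at every active stage
#' the stage mean of a responding gene is its baseline times
#' `2^(direction * effect)`. `effect` may be a single log2 magnitude or one
#' value per active stage (a profile), which lets a schedule encode
#' early-peaking versus late-peaking trajectories.
#'
#' @param category Bincode of the perturbed category.
#' @param direction `+1` (up) or `-1` (down).
#' @param active_stages Stage labels at which the perturbation applies; must
#'   exclude the baseline (first) stage.
#' @param effect Log2 fold-change magnitude(s), `>= 0`; scalar or one per
#'   active stage.
#' @param responder_fraction Fraction of the category's genes that respond,
#'   in `[0, 1]`.
#' @return A list of class `schedule_entry`.
#' @export
schedule_entry <- function(category, direction, active_stages, effect,
                           responder_fraction) {
  stopifnot(direction %in% c(-1, 1),
            all(is.finite(effect)), all(effect >= 0),
            responder_fraction >= 0, responder_fraction <= 1)
  if (!length(effect) %in% c(1L, length(active_stages)))
    stop("`effect` must be scalar or one value per active stage", call. = FALSE)
  structure(list(category = as.character(category),
                 direction = direction,
                 active_stages = as.character(active_stages),
                 effect = rep_len(effect, length(active_stages)),
                 responder_fraction = responder_fraction),
            class = "schedule_entry")
}

#' The canonical planted germination schedule
#'
#' Returns the schedule used throughout the package's validation runs. It
#' plants the activation order that germinating seeds are expected to show:
#' carbohydrate (CHO) mobilisation first, then lipid metabolism, then
#' protein metabolism, against a background of null categories. Concretely
#' (1-based stage indices into the six-stage design, stage 1 = dry seed
#' baseline):
#'
#' * bin `"2"` (major CHO metabolism): up-regulated from stage 2 onward,
#'   effect profile peaking early then decaying.
#' * bin `"11"` (lipid metabolism): up-regulated at stages 3-5, early peak.
#' * bin `"29"` (protein metabolism): up-regulated at stages 3-5 with a
#'   ramping profile, so its detectable onset and its peak come later than
#'   lipid's.
#'
#' All other categories are unperturbed (responder fraction 0, i.e. absent
#' from the schedule).
#'
#' @param effect_size Peak log2 fold-change magnitude (default 2).
#' @param responder_fraction Fraction of each planted category's genes that
#'   respond (default 0.6).
#' @param stage_labels Stage labels of the design (default the six-stage
#'   layout of [simulation_config()]).
#' @return List of [schedule_entry()] objects, with attribute
#'   `planted_order` giving the intended activation order.
#' @export
germination_schedule <- function(effect_size = 2,
                                 responder_fraction = 0.6,
                                 stage_labels = c("0", "0.75", "6", "24", "48", "144")) {
  s <- stage_labels
  sched <- list(
    schedule_entry("2", +1, s[2:6],
                   effect_size * c(1, 1, 0.75, 0.5, 0.5),
                   responder_fraction),
    schedule_entry("11", +1, s[3:5],
                   effect_size * c(1, 1, 0.75),
                   responder_fraction),
    schedule_entry("29", +1, s[3:5],
                   effect_size * c(0.4, 0.8, 1),
                   responder_fraction)
  )
  attr(sched, "planted_order") <- c("2", "11", "29")
  sched
}

# Mapman-style top-level bins used for simulated category maps
.sim_bin_catalogue <- data.frame(
  bincode = c("1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12",
              "13", "23", "26", "27", "28", "29", "30", "34", "35", "16",
              "17", "20", "21", "24", "25", "31", "33", "15"),
  name = c("photosynthesis", "major CHO metabolism", "minor CHO metabolism",
           "glycolysis", "fermentation", "gluconeogenesis",
           "oxidative pentose phosphate", "TCA cycle",
           "mitochondrial electron transport", "cell wall",
           "lipid metabolism", "N-metabolism", "amino acid metabolism",
           "nucleotide metabolism", "misc", "RNA", "DNA", "protein",
           "signalling", "transport", "not assigned", "secondary metabolism",
           "hormone metabolism", "stress", "redox", "biodegradation",
           "C1-metabolism", "cell", "development", "metal handling"),
  stringsAsFactors = FALSE
)

#' Simulate an expression matrix with a planted activation schedule
#'
#' Baseline gene means are drawn log-normally from a single seeded stream;
#' per-stage replicate noise uses deterministic per-stage substreams derived
#' from the same seed, so stages are independently reproducible. For each
#' responding gene at each active stage the stage mean is
#' `baseline * 2^(direction * effect)`; every replicate value is the stage
#' mean times `2^N(0, noise_sd)`.
#'
#' @param config A [simulation_config()].
#' @param schedule List of [schedule_entry()] objects (possibly empty for a
#'   null simulation).
#' @return A list with elements `expr` (a `germ_expr`), `map` (a
#'   `mapman_map`) and `truth` (data frame `gene_id`, `stage`, `direction`
#'   with the planted direction, 0 for unperturbed gene-stage pairs at
#'   non-baseline stages).
#' @examples
#' sim <- simulate_expression(simulation_config(n_genes = 200, genes_per_category = 10, seed = 7),
#'                            germination_schedule())
#' sim$expr
#' @export
simulate_expression <- function(config, schedule = list()) {
  stopifnot(inherits(config, "sim_config"))
  stages <- config$stage_labels
  baseline_stage <- stages[1]
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))

  # category map: one bin per block of genes_per_category genes
  cat_codes <- .sim_bin_catalogue$bincode[seq_len(config$n_categories)]
  bins <- .sim_bin_catalogue[seq_len(config$n_categories), , drop = FALSE]
  n_assigned <- config$n_categories * config$genes_per_category
  assignments <- data.frame(
    bincode = rep(cat_codes, each = config$genes_per_category),
    gene_id = genes[seq_len(n_assigned)],
    stringsAsFactors = FALSE)
  map <- category_map(bins, assignments)

  for (e in schedule) {
    if (!e$category %in% cat_codes)
      stop("schedule references unknown category '", e$category, "'",
           call. = FALSE)
    if (baseline_stage %in% e$active_stages)
      stop("schedule may not perturb the baseline stage", call. = FALSE)
    if (!all(e$active_stages %in% stages))
      stop("schedule references unknown stage(s): ",
           paste(setdiff(e$active_stages, stages), collapse = ", "),
           call. = FALSE)
  }

  set.seed(config$seed)
  baseline <- stats::rlnorm(n, meanlog = config$baseline_meanlog,
                            sdlog = config$baseline_sdlog)

  # planted log2 effect per gene x stage
  shift <- matrix(0, n, length(stages), dimnames = list(genes, stages))
  for (e in schedule) {
    members <- assignments$gene_id[assignments$bincode == e$category]
    n_resp <- round(e$responder_fraction * length(members))
    responders <- if (n_resp > 0) sample(members, n_resp) else character(0)
    for (i in seq_along(e$active_stages))
      shift[responders, e$active_stages[i]] <-
        e$direction * e$effect[i]
  }

  reps <- config$replicates
  sample_ids <- unlist(lapply(seq_along(stages), function(s)
    sprintf("T%s_r%d", stages[s], seq_len(reps))))
  values <- matrix(NA_real_, n, length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (s in seq_along(stages)) {
    set.seed(config$seed + s)  # per-stage substream
    stage_mean <- baseline * 2^shift[, s]
    for (r in seq_len(reps)) {
      noise <- stats::rnorm(n, mean = 0, sd = config$noise_sd)
      values[, (s - 1L) * reps + r] <- stage_mean * 2^noise
    }
  }

  samples <- data.frame(
    sample_id = sample_ids,
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), times = length(stages)),
    stringsAsFactors = FALSE)
  expr <- expression_matrix(values, samples, stage_order = stages)

  non_base <- stages[-1]
  truth <- data.frame(
    gene_id = rep(genes, times = length(non_base)),
    stage = rep(non_base, each = n),
    direction = as.integer(sign(shift[, non_base])),
    stringsAsFactors = FALSE)
  truth <- truth[order(match(truth$stage, stages), truth$gene_id), ]
  rownames(truth) <- NULL

  list(expr = expr, map = map, truth = truth)
}
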