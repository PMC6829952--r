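#' Run the full stage-wise pathway-activity analysis
#'
#' Orchestrates the pipeline end to end: builds both contrast systems from
#' the stage order, calls differential expression per contrast, computes
#' directional category enrichment, derives sigma-Z activity tables for the
#' fixed-reference and continuous systems, the quadrant concordance between
#' them, the activation timetable (fixed system), and the stage-specific
#' gene partition.
#'
#' @param expr A `germ_expr`.
#' @param map A `mapman_map`.
#' @param de Optional pre-computed DE table (columns `gene_id`,
#'   `contrast_id`, `call`; see [read_de_calls()]). When supplied it must
#'   cover the contrast ids of both systems and the caller is skipped.
#' @param pseudocount,fc_threshold,prob_threshold DE-caller settings, see
#'   [run_de()].
#' @param universe_mode See [build_universe()].
#' @param min_bin_size,z_cap,method Enrichment settings, see
#'   [enrich_all()].
#' @param activity_threshold Significance threshold for sigma-Z
#'   (default 1.96).
#' @param expression_threshold,min_replicates Presence-call settings for
#'   the stage-specific partition, see [expressed_mask()].
#' @return Named list of result tables: `de`, `enrichment`,
#'   `activity_fixed`, `activity_continuous`, `concordance`, `timetable`,
#'   `specific` (annotated stage-specific genes), `specific_summary`.
#' @examples
#' sim <- simulate_expression(simulation_config(n_genes = 300, genes_per_category = 10, seed = 11),
#'                            germination_schedule())
#' res <- run_germination_analysis(sim$expr, sim$map)
#' head(res$timetable)
#' @export
run_germination_analysis <- function(expr, map, de = NULL,
                                     pseudocount = 0.5,
                                     fc_threshold = 2,
                                     prob_threshold = 0.8,
                                     universe_mode = "annotated",
                                     min_bin_size = 5,
                                     z_cap = 8,
                                     method = "minlike",
                                     activity_threshold = 1.96,
                                     expression_threshold = 1,
                                     min_replicates = 2L) {
  systems <- build_contrast_systems(expr$stage_order)
  all_contrasts <- rbind(systems$fixed, systems$continuous)
  all_contrasts <- all_contrasts[!duplicated(all_contrasts$contrast_id), ,
                                 drop = FALSE]
  if (is.null(de)) {
    de <- run_de(expr, all_contrasts, pseudocount = pseudocount,
                 fc_threshold = fc_threshold, prob_threshold = prob_threshold)
  } else {
    missing_ct <- setdiff(all_contrasts$contrast_id, unique(de$contrast_id))
    if (length(missing_ct))
      stop("supplied DE calls lack contrast(s): ",
           paste(missing_ct, collapse = ", "), call. = FALSE)
  }
  universe <- build_universe(expr, map, universe_mode)
  enrichment <- enrich_all(de, map, universe, min_bin_size = min_bin_size,
                           z_cap = z_cap, method = method)
  act <- activity_table(enrichment, threshold = activity_threshold)
  pick <- function(system_df)
    act[act$contrast_id %in% system_df$contrast_id, , drop = FALSE]
  act_fixed <- pick(systems$fixed)
  act_cont <- pick(systems$continuous)
  act_fixed$system <- "fixed"
  act_cont$system <- "continuous"
  conc <- concordance(act_fixed, act_cont, threshold = activity_threshold)
  tt <- activation_timetable(act_fixed, expr$stage_order,
                             threshold = activity_threshold)
  mask <- expressed_mask(expr, expression_threshold, min_replicates)
  sets <- venn_partition(mask)
  list(de = de,
       enrichment = enrichment,
       activity_fixed = act_fixed,
       activity_continuous = act_cont,
       concordance = conc,
       timetable = tt,
       specific = annotate_specific(sets, map),
       specific_summary = specific_summary(sets))
}
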