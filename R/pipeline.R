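# End-to-end run: generate -> simulate -> analyze, mirroring the order of
# the retention, divergence and KO analyses.

#' Run the full synthetic pipeline
#'
#' Generates a synthetic dataset, pushes it through the complete analysis
#' chain (normalization, expression summarization, ohnologon expression
#' assignment, retention binning, extreme-decile contrast, stratified and
#' category analyses, divergence metrics, Ka correlation, KO-fitness
#' binning) and returns a deterministic report bundle.  Identical
#' configurations (including the master seed) give identical bundles.
#'
#' @param config A [generator_config]; its `seed` drives every stage.
#' @param interval Retention bin width in log2 units (default 0.2).
#' @param min_count Minimum ohnologons per reported bin (default 30).
#' @param normalization Between-array normalization method.
#' @param ko_interval KO-analysis bin width (default 0.5).
#' @param outdir If non-`NULL`, all tables plus a JSON summary are written
#'   there.
#' @return A list with elements `tables` (the generated tables),
#'   `levels`, `records` (ohnologons with assigned levels), `bins`,
#'   `decile`, `lowess`, `strata_complex`, `strata_phylo`, `categories`,
#'   `divergence`, `ka_correlation`, `ko`, and `summary` (flat list of the
#'   headline numbers).
#' @export
run_end_to_end <- function(config = generator_config(), interval = 0.2,
                           min_count = 30,
                           normalization = c("quantile", "scale", "none"),
                           ko_interval = 0.5, outdir = NULL) {
  normalization <- match.arg(normalization)
  stage <- "generate"
  bundle <- tryCatch({
    tabs <- generate_all(config)
    stage <- "normalize"
    expr <- normalize_between_arrays(tabs$expression, normalization)
    stage <- "summarize"
    levels <- summarize_expression(expr, floor = "auto")
    stage <- "assign"
    records <- assign_ohnologon_expression(tabs$ohnologons, levels,
                                           seed = stage_seed(config, "assign"))
    stage <- "retention"
    bins <- bin_retention(records, interval = interval, min_count = min_count)
    decile <- extreme_decile_comparison(records)
    low <- if (nrow(bins) >= 5) {
      lowess_curve((bins$lo + bins$hi) / 2, bins$retention)
    } else NULL
    stage <- "stratified"
    ann_complex <- data.frame(
      ohnologon_id = tabs$annotation$ohnologon_id,
      stratum = ifelse(tabs$annotation$in_complex == 1, "complex", "other"),
      stringsAsFactors = FALSE)
    strata_complex <- stratified_retention(records, ann_complex,
                                           interval = 1, min_count = min_count)
    ann_phylo <- data.frame(ohnologon_id = tabs$annotation$ohnologon_id,
                            stratum = tabs$annotation$phylo_group,
                            stringsAsFactors = FALSE)
    strata_phylo <- stratified_retention(records, ann_phylo)
    ann_cat <- data.frame(ohnologon_id = tabs$annotation$ohnologon_id,
                          category = tabs$annotation$category,
                          stringsAsFactors = FALSE)
    categories <- category_enrichment(records, ann_cat)
    stage <- "divergence"
    divergence <- analyze_divergence(tabs$ka, expr, levels,
                                     seed = stage_seed(config, "assign"))
    pair_lvl <- divergence$pairs$level[match(tabs$ka$pair_id,
                                             divergence$pairs$pair_id)]
    ka_cor <- correlate_with_expression(tabs$ka$ka, pair_lvl)
    stage <- "ko"
    ko_levels <- data.frame(gene_id = tabs$population$gene_id,
                            level = tabs$population$log2_X0,
                            stringsAsFactors = FALSE)
    ko <- ko_fitness_by_expression(tabs$ko_fitness, ko_levels,
                                   interval = ko_interval)
    list(tables = tabs, levels = levels, records = records, bins = bins,
         decile = decile, lowess = low, strata_complex = strata_complex,
         strata_phylo = strata_phylo, categories = categories,
         divergence = divergence, ka_correlation = ka_cor, ko = ko)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  bundle$summary <- list(
    seed = config$seed,
    n_genes = config$n_genes,
    retention_overall = mean(bundle$records$retained),
    retention_bottom_decile = bundle$decile$freq_bottom,
    retention_top_decile = bundle$decile$freq_top,
    decile_fold = bundle$decile$fold,
    decile_p = bundle$decile$p,
    ka_r = bundle$ka_correlation$r,
    ka_p = bundle$ka_correlation$p,
    pearson_divergence_r = bundle$divergence$correlations$pearson_divergence_vs_level$r,
    euclidean_divergence_r = bundle$divergence$correlations$euclidean_divergence_vs_level$r,
    ko_fitness_r = bundle$ko$correlation$r,
    lambda0T = attr(bundle$tables$retention, "lambda0T"))
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    prov <- list(seed = config$seed)
    write_table(bundle$bins, file.path(outdir, "retention_bins.tsv"), prov)
    write_table(data.frame(bundle$decile[c("freq_bottom", "freq_top", "fold", "p")]),
                file.path(outdir, "extreme_deciles.tsv"), prov)
    write_table(bundle$strata_complex, file.path(outdir, "strata_complex.tsv"), prov)
    write_table(bundle$strata_phylo, file.path(outdir, "strata_phylo.tsv"), prov)
    if (!is.null(bundle$categories)) {
      write_table(bundle$categories, file.path(outdir, "categories.tsv"), prov)
    }
    write_table(bundle$divergence$pairs, file.path(outdir, "divergence_pairs.tsv"), prov)
    write_table(bundle$ko$bins, file.path(outdir, "ko_bins.tsv"), prov)
    jsonlite::write_json(bundle$summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    generate_all(config, dir = outdir)
  }
  bundle
}
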