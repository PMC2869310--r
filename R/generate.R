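# Seeded synthetic-data generator.  Emulates the statistical structure of
# the ciliate microarray / ohnologon data the pipeline was designed for:
# log-normal expression levels, ~58-condition profiles, expression-dependent
# retention after WGD, a complex-membership retention bonus, expression-
# dependent Ka and expression-profile divergence, and a yeast-like
# heterozygous-KO fitness table.  All randomness flows from one master seed.

#' Generator configuration
#'
#' Defaults encode the stated world the generator emulates: 58 hybridization
#' conditions; log2 expression levels Normal(8, 2) (a convention, the source
#' data's distribution parameters are unpublished); cost parameters k = 0.01,
#' M = 2^14 so that the bulk of genes sit well below the expression capacity;
#' Ne = 25 placing the median gene near the nearly-neutral boundary
#' (4*Ne*s ~ 1) so retention varies smoothly with expression; a genome-wide
#' expected retention of 0.5 matching ~49% gene loss after a recent WGD;
#' a complex-membership fraction of 0.15 (~1,200 of ~8,000 yeast-homolog
#' genes) with a 2x dosage-constraint bonus on |w''(1)|; phylogenetic-group
#' frequencies ~0.58/0.13/0.29 (species-specific/ciliate/ancient-eukaryotic);
#' and a Ka coupling targeting a Ka-vs-expression correlation near -0.3.
#'
#' @param n_genes Number of ancestral (pre-WGD) genes.
#' @param mu,sigma Mean and sd of log2 optimal expression levels.
#' @param n_conditions Number of expression-profile conditions.
#' @param profile_sd SD (log2) of the per-condition biological signal shared
#'   by both members of an ohnolog pair.
#' @param noise_sd SD (log2) of member-specific within-profile noise.
#' @param divergence_coupling Strength of the expression dependence of
#'   profile divergence: member-specific noise is multiplied by
#'   `exp(divergence_coupling * (mu - log2 X0) / sigma)`, so low-expression
#'   pairs diverge more.  0 disables the coupling.
#' @param ka_baseline,ka_slope,ka_sd Ka of a retained pair is
#'   `max(0, ka_baseline + ka_slope * (log2 X0 - mu) + Normal(0, ka_sd))`;
#'   the negative slope makes highly expressed genes evolve slower.
#' @param complex_fraction Fraction of genes encoding protein-complex
#'   subunits.
#' @param complex_bonus Multiplier on the selection coefficient (that is, on
#'   `|w''(1)|`) for complex members, emulating dosage-balance constraints.
#' @param n_categories Number of functional categories.
#' @param category_fraction Fraction of genes carrying a category label.
#' @param category_rate_sd SD of the log-normal per-category multiplier on
#'   the neutral loss rate `lambda0` (category-specific retention
#'   heterogeneity at fixed expression).
#' @param phylo_fractions Probabilities of the three phylogenetic groups
#'   `species_specific`, `ciliate`, `eukaryotic`.
#' @param phylo_rate Per-group multipliers on `lambda0` (species-specific
#'   genes are lost more, ancient genes less).
#' @param ko_noise_sd SD of per-condition noise in the KO-fitness table.
#' @param ko_n_conditions Number of KO culture conditions.
#' @param k,M Cost-function parameters shared by all genes.
#' @param Ne Effective population size for the loss simulation.
#' @param target_retention Genome-wide expected retention used to calibrate
#'   `lambda0 * T` (see [calibrate_loss_hazard()]).
#' @param seed Master seed; every stage derives its own stream from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 20000, mu = 8, sigma = 2,
                             n_conditions = 58, profile_sd = 1,
                             noise_sd = 0.2, divergence_coupling = 0.5,
                             ka_baseline = 0.2, ka_slope = -0.02,
                             ka_sd = 0.115,
                             complex_fraction = 0.15, complex_bonus = 2,
                             n_categories = 23, category_fraction = 0.6,
                             category_rate_sd = 0.25,
                             phylo_fractions = c(species_specific = 0.58,
                                                 ciliate = 0.13,
                                                 eukaryotic = 0.29),
                             phylo_rate = c(species_specific = 1.2,
                                            ciliate = 0.9,
                                            eukaryotic = 0.7),
                             ko_noise_sd = 0.01, ko_n_conditions = 5,
                             k = 0.01, M = 2^14, Ne = 25,
                             target_retention = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes > 0, cfg$sigma > 0, cfg$n_conditions >= 1,
            cfg$complex_fraction >= 0, cfg$complex_fraction <= 1,
            cfg$category_fraction >= 0, cfg$category_fraction <= 1,
            abs(sum(cfg$phylo_fractions) - 1) < 1e-8,
            cfg$target_retention > 0, cfg$target_retention < 1)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "generator_config"
  cfg
}

# Derive a sub-seed for a named stage from the master seed (kept < 2^31).
stage_seed <- function(config, stage) {
  offsets <- c(population = 11L, retention = 23L, expression = 37L,
               ka = 53L, ko = 71L, assign = 89L, cascade = 97L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  (config$seed * 1009L + offsets[[stage]]) %% 2147483647L
}

#' Generate the ancestral gene population
#'
#' Draws `n_genes` optimal expression levels `X0 = 2^z`, `z ~ Normal(mu,
#' sigma)` (clipped at `0.9 * M` with a warning if the tail exceeds the
#' expression capacity), and assigns protein-complex membership,
#' phylogenetic group and functional-category labels at the configured
#' fractions.  Category sizes follow a geometric (Zipf-like) decay.
#'
#' @param config A [generator_config].
#' @return A data.frame with columns `gene_id`, `X0`, `log2_X0`,
#'   `in_complex`, `phylo_group`, `category` (NA when unannotated), plus a
#'   `"category_rate"`/`"phylo_rate"` attribute mapping labels to loss-rate
#'   multipliers.
#' @export
generate_gene_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(stage_seed(config, "population"))
  n <- config$n_genes
  z <- stats::rnorm(n, config$mu, config$sigma)
  X0 <- 2^z
  if (any(X0 >= config$M)) {
    warning(sum(X0 >= config$M), " gene(s) exceeded the expression capacity M; ",
            "clipped at 0.9 * M", call. = FALSE)
    X0 <- pmin(X0, 0.9 * config$M)
  }
  in_complex <- stats::runif(n) < config$complex_fraction
  phylo <- sample(names(config$phylo_fractions), n, replace = TRUE,
                  prob = config$phylo_fractions)
  # Zipf-like category weights; a configured fraction of genes is annotated
  cat_names <- sprintf("cat_%02d", seq_len(config$n_categories))
  w <- 1 / seq_len(config$n_categories)
  category <- rep(NA_character_, n)
  annotated <- stats::runif(n) < config$category_fraction
  category[annotated] <- sample(cat_names, sum(annotated), replace = TRUE,
                                prob = w / sum(w))
  category_rate <- stats::setNames(
    exp(stats::rnorm(config$n_categories, 0, config$category_rate_sd)), cat_names)
  out <- data.frame(gene_id = sprintf("gene_%05d", seq_len(n)),
                    X0 = pmin(X0, 0.9 * config$M),
                    log2_X0 = log2(pmin(X0, 0.9 * config$M)),
                    in_complex = in_complex,
                    phylo_group = phylo,
                    category = category,
                    stringsAsFactors = FALSE)
  attr(out, "category_rate") <- category_rate
  attr(out, "phylo_rate") <- config$phylo_rate
  out
}

#' Per-gene neutral-loss-rate multiplier from annotations
#'
#' Combines the category- and phylogenetic-group multipliers attached to a
#' generated population into one per-gene factor on `lambda0`.
#'
#' @param population Output of [generate_gene_population()].
#' @return Numeric vector of multipliers (1 for unannotated genes).
#' @export
loss_rate_multiplier <- function(population) {
  crate <- attr(population, "category_rate")
  prate <- attr(population, "phylo_rate")
  m <- rep(1, nrow(population))
  has_cat <- !is.na(population$category)
  if (!is.null(crate)) m[has_cat] <- m[has_cat] * crate[population$category[has_cat]]
  if (!is.null(prate)) m <- m * prate[population$phylo_group]
  unname(m)
}

#' Simulate retention for a generated population
#'
#' Builds calibrated gene models, applies the complex-membership bonus to the
#' selection coefficients and the annotation multipliers to `lambda0`,
#' calibrates `lambda0 * T` so genome-wide expected retention matches the
#' configured target, and draws retention outcomes.
#'
#' @inheritParams loss_rate_multiplier
#' @param config A [generator_config].
#' @return The [simulate_retention()] data.frame, with the population's
#'   annotation columns (`in_complex`, `phylo_group`, `category`, `gene_id`)
#'   appended and the calibrated `lambda0 * T` in attribute `"lambda0T"`.
#' @export
generate_retention <- function(population, config) {
  stopifnot(inherits(config, "generator_config"))
  genes <- gene_model(population$X0, k = config$k, M = config$M)
  mult <- ifelse(population$in_complex, config$complex_bonus, 1)
  s <- sel_coeff_halving(genes, "exact") * mult
  lt <- calibrate_loss_hazard(s, config$Ne, config$target_retention)
  params <- pop_gen_params(Ne = config$Ne,
                           lambda0 = lt * loss_rate_multiplier(population),
                           T = 1)
  out <- simulate_retention(genes, params, coeff_method = "exact",
                            seed = stage_seed(config, "retention"),
                            s_multiplier = mult,
                            ohnologon_id = sub("^gene", "ohn", population$gene_id))
  out$gene_id <- population$gene_id
  out$in_complex <- population$in_complex
  out$phylo_group <- population$phylo_group
  out$category <- population$category
  attr(out, "lambda0T") <- lt
  out
}

#' Generate the genes-by-conditions expression matrix
#'
#' Each ancestral gene contributes a shared per-condition biological profile
#' (log2 deviations `Normal(0, profile_sd)` around `log2 X0`).  A retained
#' ohnologon contributes two member genes (`_a`, `_b`), a lost one a single
#' gene.  Each member adds its own noise with sd
#' `noise_sd * exp(divergence_coupling * (mu - log2 X0) / sigma)`, so
#' low-expression ohnolog pairs have more divergent profiles (lower Pearson
#' correlation, larger Euclidean distance).  Signals are returned on the
#' linear scale, ready for [summarize_expression()].
#'
#' @param retention Output of [generate_retention()] (or any data.frame with
#'   `gene_id`, `expression_level`, `retained`).
#' @param config A [generator_config].
#' @return A data.frame: `gene_id` then `cond_1 ... cond_n` signal columns.
#' @export
generate_expression_matrix <- function(retention, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(stage_seed(config, "expression"))
  nc <- config$n_conditions
  z <- retention$expression_level
  noise <- config$noise_sd *
    exp(config$divergence_coupling * (config$mu - z) / config$sigma)
  n <- nrow(retention)
  base <- matrix(stats::rnorm(n * nc, 0, config$profile_sd), n, nc)
  make_member <- function(suffix, rows) {
    eps <- matrix(stats::rnorm(length(rows) * nc), length(rows), nc) * noise[rows]
    sig <- 2^(z[rows] + base[rows, , drop = FALSE] + eps)
    df <- data.frame(gene_id = paste0(retention$gene_id[rows], suffix), sig,
                     stringsAsFactors = FALSE)
    names(df) <- c("gene_id", paste0("cond_", seq_len(nc)))
    df
  }
  ret <- which(retention$retained == 1)
  out <- rbind(make_member("_a", seq_len(n)), make_member("_b", ret))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate the paralog-pair Ka table
#'
#' One row per retained ohnologon: non-synonymous divergence
#' `Ka = max(0, ka_baseline + ka_slope * (log2 X0 - mu) + Normal(0, ka_sd))`.
#'
#' @inheritParams generate_expression_matrix
#' @return A data.frame `pair_id`, `gene_a`, `gene_b`, `ka`.
#' @export
generate_ka_table <- function(retention, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(stage_seed(config, "ka"))
  pairs <- retention[retention$retained == 1, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no retained pairs to assign Ka values", call. = FALSE)
  ka <- config$ka_baseline +
    config$ka_slope * (pairs$expression_level - config$mu) +
    stats::rnorm(nrow(pairs), 0, config$ka_sd)
  data.frame(pair_id = pairs$ohnologon_id,
             gene_a = paste0(pairs$gene_id, "_a"),
             gene_b = paste0(pairs$gene_id, "_b"),
             ka = pmax(0, ka),
             stringsAsFactors = FALSE)
}

#' Generate the heterozygous-KO fitness table
#'
#' Yeast-like structure: for each gene the heterozygous-deletion fitness in
#' each culture condition is `1 - s_exact(gene) + Normal(0, ko_noise_sd)`,
#' where `s_exact` is the exact expression-halving selection coefficient, so
#' mean fitness loss grows with expression level.  Values are capped at
#' `1 + 3 * ko_noise_sd` (a heterozygote is never markedly fitter than wild
#' type).
#'
#' @param population Output of [generate_gene_population()].
#' @param config A [generator_config].
#' @return A long data.frame `gene_id`, `condition`, `fitness`.
#' @export
generate_ko_fitness_table <- function(population, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(stage_seed(config, "ko"))
  genes <- gene_model(population$X0, k = config$k, M = config$M)
  s <- sel_coeff_halving(genes, "exact")
  nc <- config$ko_n_conditions
  n <- nrow(population)
  fit <- pmin(rep(1 - s, each = nc) + stats::rnorm(n * nc, 0, config$ko_noise_sd),
              1 + 3 * config$ko_noise_sd)
  data.frame(gene_id = rep(population$gene_id, each = nc),
             condition = rep(sprintf("ko_cond_%d", seq_len(nc)), times = n),
             fitness = fit,
             stringsAsFactors = FALSE)
}

#' Generate the full set of input tables
#'
#' Runs all generator stages under the master seed and (optionally) writes
#' the five TSVs plus a provenance config snapshot.
#'
#' @param config A [generator_config].
#' @param dir Output directory; `NULL` (default) skips writing.
#' @return Invisibly, a list with `population`, `retention` (the ohnologon
#'   table), `expression`, `annotation`, `ka`, `ko_fitness`, `config`.
#' @export
generate_all <- function(config = generator_config(), dir = NULL) {
  population <- generate_gene_population(config)
  retention <- generate_retention(population, config)
  expression <- generate_expression_matrix(retention, config)
  ka <- generate_ka_table(retention, config)
  ko <- generate_ko_fitness_table(population, config)
  members <- ifelse(retention$retained == 1,
                    paste0(retention$gene_id, "_a,", retention$gene_id, "_b"),
                    paste0(retention$gene_id, "_a"))
  ohnologons <- data.frame(ohnologon_id = retention$ohnologon_id,
                           wgd_level = "recent",
                           members = members,
                           retained = retention$retained,
                           stringsAsFactors = FALSE)
  annotation <- data.frame(gene_id = population$gene_id,
                           ohnologon_id = retention$ohnologon_id,
                           category = population$category,
                           phylo_group = population$phylo_group,
                           in_complex = as.integer(population$in_complex),
                           stringsAsFactors = FALSE)
  bundle <- list(population = population, retention = retention,
                 expression = expression, ohnologons = ohnologons,
                 annotation = annotation, ka = ka, ko_fitness = ko,
                 config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    prov <- list(seed = config$seed)
    write_table(expression, file.path(dir, "expression.tsv"), provenance = prov)
    write_table(ohnologons, file.path(dir, "ohnologons.tsv"), provenance = prov)
    write_table(annotation, file.path(dir, "annotation.tsv"), provenance = prov)
    write_table(ka, file.path(dir, "ka.tsv"), provenance = prov)
    write_table(ko, file.path(dir, "ko_fitness.tsv"), provenance = prov)
    cfg <- config
    cfg$phylo_fractions <- paste(sprintf("%s=%g", names(cfg$phylo_fractions),
                                         cfg$phylo_fractions), collapse = ",")
    cfg$phylo_rate <- paste(sprintf("%s=%g", names(cfg$phylo_rate),
                                    cfg$phylo_rate), collapse = ",")
    write_config(unclass(cfg), file.path(dir, "generator_config.yml"))
  }
  invisible(bundle)
}
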