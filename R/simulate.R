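# Stochastic gene-loss simulator: per-gene selection coefficients against
# copy loss are turned into loss-fixation hazards scaled by the classical
# diffusion fixation-probability ratio, then into Bernoulli retention
# outcomes per ohnologon.

#' Population-genetic parameters for the loss simulator
#'
#' @param Ne Effective population size (individuals).
#' @param lambda0 Neutral per-copy loss-fixation rate (events per copy per
#'   time unit).
#' @param T Elapsed time since the whole-genome duplication (time units).
#'   Only the product `lambda0 * T` matters for retention probabilities.
#' @return A list of class `pop_gen_params`.
#' @export
pop_gen_params <- function(Ne, lambda0, T) {
  stopifnot(is.numeric(Ne), Ne > 0, is.numeric(lambda0), all(lambda0 > 0),
            is.numeric(T), T > 0)
  structure(list(Ne = Ne, lambda0 = lambda0, T = T), class = "pop_gen_params")
}

#' Fixation-rate ratio of a deleterious loss allele
#'
#' Probability that a gene-loss allele with selection coefficient `s`
#' against it fixes, relative to a neutral allele, under genic selection in
#' a diffusion model: `r(s) = 4 Ne s / (exp(4 Ne s) - 1)`, with `r(0) = 1`
#' by continuity.  Strictly decreasing in `s`; effectively zero once
#' `4 Ne s >> 1`.
#'
#' @param s Selection coefficient(s) against the loss, `s >= 0`.
#' @param Ne Effective population size.
#' @return Numeric vector in `(0, 1]` (0 in the limit `s = Inf`).
#' @export
fixation_rate_ratio <- function(s, Ne) {
  stopifnot(is.numeric(Ne), Ne > 0)
  if (any(s < 0, na.rm = TRUE)) {
    stop("s must be >= 0 (advantageous gene loss is out of scope)", call. = FALSE)
  }
  S <- 4 * Ne * s
  r <- ifelse(S == 0, 1, S / expm1(S))
  r[is.nan(r) | S == Inf] <- 0
  r
}

#' Expected probability that both ohnolog copies survive
#'
#' Each ohnologon starts with two copies after the WGD.  Loss of the first
#' copy fixes with hazard `lambda0 * r(s)` per copy; once one copy is lost
#' the survivor carries the full dosage constraint and is not lost again.
#' Hence `P(retained at time T) = exp(-2 * lambda0 * r(s) * T)`.
#'
#' @inheritParams fixation_rate_ratio
#' @param params A [pop_gen_params]; `lambda0` may be a vector (per-gene
#'   neutral loss rates, e.g. functional-category modifiers).
#' @return Numeric vector of retention probabilities in `(0, 1]`.
#' @export
expected_retention <- function(s, params) {
  stopifnot(inherits(params, "pop_gen_params"))
  exp(-2 * params$lambda0 * params$T * fixation_rate_ratio(s, params$Ne))
}

#' Calibrate the neutral loss hazard for a target genome-wide retention
#'
#' Given the selection coefficients of a gene population and `Ne`, solves for
#' the product `lambda0 * T` such that the mean expected retention equals
#' `target`.  This is the documented calibration used to anchor simulations
#' at a genome-wide retention comparable to the ~50% gene loss observed
#' after a recent WGD.
#'
#' @param s Vector of selection coefficients (one per ohnologon).
#' @param Ne Effective population size.
#' @param target Desired mean retention probability (default 0.5).
#' @return The scalar `lambda0 * T`.
#' @export
calibrate_loss_hazard <- function(s, Ne, target = 0.5) {
  stopifnot(target > 0, target < 1, length(s) >= 1)
  r <- fixation_rate_ratio(s, Ne)
  if (all(r == 0)) stop("all genes fully constrained; cannot reach target", call. = FALSE)
  f <- function(log_lt) mean(exp(-2 * exp(log_lt) * r)) - target
  # mean retention spans (0,1) monotonically in lambda0*T
  sol <- stats::uniroot(f, lower = -40, upper = 40, tol = 1e-12)
  exp(sol$root)
}

#' Simulate post-WGD retention outcomes
#'
#' Draws one Bernoulli retention outcome per ohnologon at its expected
#' retention probability.  Selection coefficients come from the gene models
#' via [sel_coeff_halving()]; an optional multiplier (`s_multiplier`)
#' emulates extra dosage constraints such as protein-complex membership.
#'
#' @param genes A [gene_model] holding one calibrated model per ohnologon.
#' @param params A [pop_gen_params].
#' @param coeff_method Passed to [sel_coeff_halving()] (`"exact"` default).
#' @param seed Integer seed; required for reproducibility.
#' @param s_multiplier Optional per-gene multiplier on the selection
#'   coefficient (default 1).
#' @param ohnologon_id Optional IDs (default `ohn_1 ... ohn_n`).
#' @return A data.frame with columns `ohnologon_id`, `expression_level`
#'   (log2 of `X0`), `s`, `p_retained` (analytic expectation) and `retained`
#'   (0/1 draw).
#' @export
simulate_retention <- function(genes, params, coeff_method = c("exact", "taylor"),
                               seed, s_multiplier = 1, ohnologon_id = NULL) {
  stopifnot(inherits(genes, "gene_model"), inherits(params, "pop_gen_params"))
  coeff_method <- match.arg(coeff_method)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n <- length(genes)
  if (n == 0) {
    return(data.frame(ohnologon_id = character(), expression_level = numeric(),
                      s = numeric(), p_retained = numeric(), retained = integer()))
  }
  if (is.null(ohnologon_id)) ohnologon_id <- paste0("ohn_", seq_len(n))
  s <- sel_coeff_halving(genes, coeff_method) * rep_len(s_multiplier, n)
  p <- expected_retention(s, params)
  set.seed(seed)
  retained <- as.integer(stats::runif(n) < p)
  data.frame(ohnologon_id = ohnologon_id,
             expression_level = log2(genes$X0),
             s = s, p_retained = p, retained = retained,
             stringsAsFactors = FALSE)
}

#' Simulate a cascade of successive whole-genome duplications
#'
#' Emulates a lineage that underwent `n_wgd` successive WGDs (most recent
#' last).  Between consecutive WGDs each surviving gene copy is lost with
#' probability `1 - exp(-lambda0 * r(s) * T)` for that epoch, except that a
#' gene's last remaining copy is never lost (every ancestral gene is still
#' observable today, matching how ohnologons are reconstructed from a
#' sequenced genome).  An ohnologon of a given WGD is a set of surviving
#' genes descending from one lineage present at that WGD; it is *retained*
#' when both post-WGD daughter lineages still contain at least one gene.
#'
#' @param genes A [gene_model], one entry per ancestral (pre-WGD) gene.
#' @param params A [pop_gen_params]; `lambda0` here is recycled across
#'   epochs (length 1 or `n_wgd`), oldest epoch first.
#' @param n_wgd Number of successive WGDs (default 3: old, intermediary,
#'   recent).
#' @param coeff_method Passed to [sel_coeff_halving()].
#' @param seed Integer seed.
#' @return A data.frame with one row per observable ohnologon: `ohnologon_id`,
#'   `wgd_level` (`"recent"`, `"intermediary"`, `"old"`, or `"wgd<k>"` beyond
#'   three), `ancestor_id`, `expression_level`, `n_members`, `retained`.
#' @export
simulate_wgd_cascade <- function(genes, params, n_wgd = 3,
                                 coeff_method = c("exact", "taylor"), seed) {
  stopifnot(inherits(genes, "gene_model"), inherits(params, "pop_gen_params"))
  coeff_method <- match.arg(coeff_method)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n <- length(genes)
  s <- sel_coeff_halving(genes, coeff_method)
  lam <- rep_len(params$lambda0, n_wgd)
  p_loss <- 1 - exp(-outer(fixation_rate_ratio(s, params$Ne) * params$T, lam))
  set.seed(seed)
  ncopies <- 2^n_wgd
  present <- matrix(FALSE, n, ncopies)
  present[, 1] <- TRUE
  for (e in seq_len(n_wgd)) {
    width <- 2^(n_wgd - e)          # final columns per lineage after WGD e
    # duplicate: lineage occupying block j now occupies blocks 2j-1, 2j
    old_width <- 2 * width
    for (j in rev(seq_len(2^(e - 1)))) {
      blk <- present[, (j - 1) * old_width + 1, drop = TRUE]
      present[, (2 * j - 1 - 1) * width + 1] <- blk
      present[, (2 * j - 1) * width + 1] <- blk
    }
    # loss epoch after WGD e: each present lineage-start may be lost
    starts <- (seq_len(2^e) - 1) * width + 1
    blk <- present[, starts, drop = FALSE]
    lost <- blk & (matrix(stats::runif(n * 2^e), n) < p_loss[, e])
    newblk <- blk & !lost
    dead <- rowSums(newblk) == 0
    if (any(dead)) {
      # last-copy immortality: keep one random previously present lineage
      for (g in which(dead)) {
        alive <- which(blk[g, ])
        keep1 <- if (length(alive) == 1) alive else sample(alive, 1)
        newblk[g, keep1] <- TRUE
      }
    }
    present[, starts] <- newblk
  }
  # collect ohnologons per WGD level
  level_name <- function(e) {
    age <- n_wgd - e # 0 = most recent
    if (n_wgd >= 3 && age <= 2) c("recent", "intermediary", "old")[age + 1]
    else if (n_wgd == 2 && age <= 1) c("recent", "old")[age + 1]
    else paste0("wgd", e)
  }
  out <- vector("list", n_wgd)
  lvl_expr <- log2(genes$X0)
  for (e in seq_len(n_wgd)) {
    width <- 2^(n_wgd - e)
    parent_width <- 2 * width
    nparents <- 2^(e - 1)
    counts <- matrix(0L, n, nparents)
    left <- matrix(FALSE, n, nparents)
    right <- matrix(FALSE, n, nparents)
    for (j in seq_len(nparents)) {
      cols <- (j - 1) * parent_width + seq_len(parent_width)
      counts[, j] <- rowSums(present[, cols, drop = FALSE])
      left[, j] <- rowSums(present[, cols[seq_len(width)], drop = FALSE]) > 0
      right[, j] <- rowSums(present[, cols[width + seq_len(width)], drop = FALSE]) > 0
    }
    exists <- counts > 0
    idx <- which(exists, arr.ind = TRUE)
    out[[e]] <- data.frame(
      ohnologon_id = sprintf("g%d_%s_%d", idx[, 1], level_name(e), idx[, 2]),
      wgd_level = level_name(e),
      ancestor_id = paste0("anc_", idx[, 1]),
      expression_level = lvl_expr[idx[, 1]],
      n_members = counts[exists],
      retained = as.integer(left[exists] & right[exists]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
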