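# Ohnolog expression-divergence metrics, Ka-vs-expression correlation, and
# the heterozygous-KO fitness analysis.

#' Pearson similarity between two ohnolog expression profiles
#'
#' Correlation of the two members' per-condition profiles: 1 means perfectly
#' conserved regulation, lower values mean diverged expression patterns.
#' Returns `NA` (with a message) when either profile is constant.
#'
#' @param a,b Numeric expression vectors over the same conditions (same
#'   order, length >= 2).
#' @return The Pearson correlation coefficient, or `NA`.
#' @export
pearson_divergence <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length", call. = FALSE)
  if (length(a) < 2) stop("profiles need at least 2 conditions", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    message("constant expression profile: correlation undefined, reported as NA")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Euclidean distance between two ohnolog expression profiles
#'
#' @inheritParams pearson_divergence
#' @return Non-negative distance; 0 iff the profiles are identical.
#' @export
euclidean_divergence <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Correlate a per-gene (or per-pair) quantity with expression level
#'
#' Pearson correlation with a two-sided p-value from the t distribution,
#' after dropping incomplete observations.
#'
#' @param values Numeric vector (e.g. Ka, divergence, minimal KO fitness).
#' @param levels Numeric expression levels, same length.
#' @return A list `r`, `p`, `n`.
#' @export
correlate_with_expression <- function(values, levels) {
  if (length(values) != length(levels)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(values) & is.finite(levels)
  if (sum(ok) < 3) stop("need at least 3 complete observations", call. = FALSE)
  ct <- stats::cor.test(values[ok], levels[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Divergence metrics for a table of ohnolog pairs
#'
#' Computes per-pair Pearson and Euclidean profile divergence from an
#' expression matrix, then correlates each divergence measure with the
#' pair's expression level.  To express both as *divergence* (larger = more
#' diverged), the Pearson measure enters the correlation as `1 - r`; with
#' expression-dependent divergence both correlations are negative
#' (`1 - r` and distance both shrink as expression grows).
#'
#' @param pairs A data.frame `pair_id`, `gene_a`, `gene_b`.
#' @param expression An expression matrix data.frame (`gene_id` + condition
#'   columns), linear scale; profiles are compared on the log2 scale.
#' @param levels A data.frame `gene_id`, `level`; the pair's level is that
#'   of a random member (`member = "random"`, seeded), or the max or mean.
#' @param member How to pick the pair's expression level.
#' @param seed Seed for `member = "random"`.
#' @return A list with `pairs` (per-pair `pearson`, `euclidean`, `level`)
#'   and `correlations` (`pearson_divergence_vs_level`,
#'   `euclidean_divergence_vs_level`, each a `list(r, p, n)`).
#' @export
analyze_divergence <- function(pairs, expression, levels,
                               member = c("random", "max", "mean"), seed = 1L) {
  member <- match.arg(member)
  stopifnot(all(c("pair_id", "gene_a", "gene_b") %in% names(pairs)),
            "gene_id" %in% names(expression))
  num <- setdiff(names(expression), "gene_id")
  m <- log2(as.matrix(expression[num]))
  rownames(m) <- expression$gene_id
  keep <- pairs$gene_a %in% rownames(m) & pairs$gene_b %in% rownames(m)
  if (any(!keep)) message(sum(!keep), " pair(s) dropped: missing expression profile")
  pr <- pairs[keep, , drop = FALSE]
  pe <- vapply(seq_len(nrow(pr)), function(i) {
    a <- m[pr$gene_a[[i]], ]; b <- m[pr$gene_b[[i]], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }, numeric(1))
  eu <- vapply(seq_len(nrow(pr)), function(i) {
    euclidean_divergence(m[pr$gene_a[[i]], ], m[pr$gene_b[[i]], ])
  }, numeric(1))
  lvl <- stats::setNames(levels$level, levels$gene_id)
  la <- unname(lvl[pr$gene_a]); lb <- unname(lvl[pr$gene_b])
  level <- switch(member,
                  max = pmax(la, lb),
                  mean = (la + lb) / 2,
                  random = {
                    set.seed(seed)
                    ifelse(stats::runif(nrow(pr)) < 0.5, la, lb)
                  })
  out_pairs <- data.frame(pair_id = pr$pair_id, pearson = pe, euclidean = eu,
                          level = level, stringsAsFactors = FALSE)
  list(pairs = out_pairs,
       correlations = list(
         pearson_divergence_vs_level = correlate_with_expression(1 - pe, level),
         euclidean_divergence_vs_level = correlate_with_expression(eu, level)))
}

#' Heterozygous-KO fitness binned by expression level
#'
#' Per gene, the KO fitness is the minimum across all culture conditions
#' (the most sensitive condition).  Genes are then grouped into
#' fixed-interval expression bins (same engine as the retention analysis)
#' and each bin reports the mean minimal fitness with a normal-approximation
#' 95% confidence interval; the overall Pearson correlation of minimal
#' fitness with expression level is also returned.
#'
#' @param ko A long data.frame `gene_id`, `condition`, `fitness`.
#' @param levels A data.frame `gene_id`, `level`.
#' @param interval Expression-bin width in log2 units (default 0.5).
#' @param min_count Minimum genes per reported bin (default 30).
#' @param ci How to build the 95% CI: `"normal"` (default,
#'   `mean +/- 1.96 sd/sqrt(n)`) or `"bootstrap"` (percentile, 1000
#'   resamples, seeded).
#' @param seed Seed for the bootstrap CI.
#' @return A list: `genes` (per-gene `gene_id`, `min_fitness`, `level`),
#'   `bins` (`lo`, `hi`, `n`, `mean_fitness`, `ci_lo`, `ci_hi`),
#'   `correlation` (`list(r, p, n)`), `n_dropped` (genes without a level).
#' @export
ko_fitness_by_expression <- function(ko, levels, interval = 0.5, min_count = 30,
                                     ci = c("normal", "bootstrap"), seed = 1L) {
  ci <- match.arg(ci)
  stopifnot(all(c("gene_id", "fitness") %in% names(ko)),
            all(c("gene_id", "level") %in% names(levels)))
  mins <- tapply(ko$fitness, ko$gene_id, min)
  g <- data.frame(gene_id = names(mins), min_fitness = as.numeric(mins),
                  stringsAsFactors = FALSE)
  lvl <- stats::setNames(levels$level, levels$gene_id)
  g$level <- unname(lvl[g$gene_id])
  n_dropped <- sum(is.na(g$level))
  if (n_dropped > 0) {
    message(n_dropped, " gene(s) dropped from the KO analysis: no expression level")
    g <- g[!is.na(g$level), , drop = FALSE]
  }
  b <- fixed_bins(g$level, interval)
  f <- factor(b$index)
  stat <- function(v) {
    n <- length(v); m <- mean(v)
    if (ci == "normal") {
      half <- 1.96 * stats::sd(v) / sqrt(n)
      c(m, m - half, m + half)
    } else {
      bs <- vapply(seq_len(1000), function(i) mean(v[sample.int(n, n, TRUE)]),
                   numeric(1))
      c(m, stats::quantile(bs, 0.025, names = FALSE),
        stats::quantile(bs, 0.975, names = FALSE))
    }
  }
  if (ci == "bootstrap") set.seed(seed)
  st <- vapply(split(g$min_fitness, f), stat, numeric(3))
  idx <- as.numeric(levels(f))
  bins <- data.frame(lo = idx * interval, hi = (idx + 1) * interval,
                     n = as.integer(table(f)),
                     mean_fitness = st[1, ], ci_lo = st[2, ], ci_hi = st[3, ])
  bins <- bins[order(bins$lo), , drop = FALSE]
  bins <- bins[bins$n >= min_count, , drop = FALSE]
  rownames(bins) <- NULL
  correlation <- if (nrow(g) >= 3) {
    correlate_with_expression(g$min_fitness, g$level)
  } else list(r = NA_real_, p = NA_real_, n = nrow(g))
  list(genes = g, bins = bins, correlation = correlation,
       n_dropped = n_dropped)
}
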