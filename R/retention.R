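# Retention-analysis pipeline: expression summarization, between-array
# normalization, ohnologon expression assignment, fixed-interval binning,
# extreme-decile comparison, stratified and functional-category analyses.

#' Collapse probe-level signals to gene-level medians
#'
#' Microarray designs with several (e.g. six) probes per gene are summarized
#' by taking, per gene and condition, the median of the probe signals.
#'
#' @param probes A data.frame whose first column `gene_id` maps each probe
#'   row to its gene; remaining columns are numeric condition signals.
#' @return A data.frame with one row per gene (original order of first
#'   appearance) and the same condition columns.
#' @export
probe_median <- function(probes) {
  stopifnot(is.data.frame(probes), "gene_id" %in% names(probes))
  if (any(is.na(probes$gene_id) | probes$gene_id == "")) {
    stop("probe rows with missing gene_id", call. = FALSE)
  }
  num <- setdiff(names(probes), "gene_id")
  ids <- unique(probes$gene_id)
  idx <- split(seq_len(nrow(probes)), factor(probes$gene_id, levels = ids))
  med <- t(vapply(idx, function(rows) {
    vapply(num, function(cn) stats::median(probes[[cn]][rows]), numeric(1))
  }, numeric(length(num))))
  out <- data.frame(gene_id = ids, med, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out) <- c("gene_id", num)
  out
}

#' Between-array normalization
#'
#' Makes condition columns comparable before summarization.  `"quantile"`
#' forces all columns onto the common distribution of per-rank column means
#' (ties receive the mean of the tied quantile values); `"scale"` rescales
#' each column so medians agree with their geometric mean; `"none"` is a
#' pass-through.
#'
#' @param mat A data.frame with a `gene_id` column and >= 2 numeric
#'   condition columns.
#' @param method One of `"quantile"`, `"scale"`, `"none"`.
#' @return The normalized data.frame (same shape).
#' @export
normalize_between_arrays <- function(mat, method = c("quantile", "scale", "none")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(mat), "gene_id" %in% names(mat))
  num <- setdiff(names(mat), "gene_id")
  if (length(num) < 2 && method != "none") {
    stop("need at least 2 condition columns to normalize", call. = FALSE)
  }
  x <- as.matrix(mat[num])
  if (!is.numeric(x)) stop("non-numeric signal values", call. = FALSE)
  if (anyNA(x)) stop("missing signal values are not supported", call. = FALSE)
  if (method == "quantile") {
    n <- nrow(x)
    target <- rowMeans(apply(x, 2, sort))
    x <- apply(x, 2, function(col) {
      stats::approx(seq_len(n), target, xout = rank(col, ties.method = "average"),
                    rule = 2)$y
    })
  } else if (method == "scale") {
    med <- apply(x, 2, stats::median)
    if (any(med <= 0)) stop("scale normalization needs positive column medians",
                            call. = FALSE)
    x <- sweep(x, 2, med / exp(mean(log(med))), "/")
  }
  mat[num] <- x
  mat
}

#' Summarize per-gene expression level
#'
#' The expression level of a gene is the log2 of the median signal across
#' all conditions.
#'
#' @param mat A data.frame with `gene_id` and numeric condition columns
#'   (positive signals).
#' @param floor Pseudo-signal floor for non-positive values: `NULL` (error
#'   on any signal <= 0), `"auto"` (smallest positive observed value), or a
#'   positive number.
#' @return A data.frame `gene_id`, `level` (log2 units).
#' @export
summarize_expression <- function(mat, floor = NULL) {
  stopifnot(is.data.frame(mat), "gene_id" %in% names(mat))
  num <- setdiff(names(mat), "gene_id")
  x <- as.matrix(mat[num])
  if (any(x <= 0)) {
    if (is.null(floor)) {
      stop("non-positive signals; set a pseudo-signal floor to proceed",
           call. = FALSE)
    }
    fl <- if (identical(floor, "auto")) min(x[x > 0]) else as.numeric(floor)
    if (!is.finite(fl) || fl <= 0) stop("floor must be a positive number", call. = FALSE)
    x[x < fl] <- fl
  }
  data.frame(gene_id = mat$gene_id,
             level = log2(apply(x, 1, stats::median)),
             stringsAsFactors = FALSE)
}

#' Assign an expression level to each ohnologon
#'
#' The level of an ohnologon is that of one member gene chosen uniformly at
#' random (reproducible under `seed`).  Records with any member lacking a
#' level are dropped; the dropped count is reported in the `"n_dropped"`
#' attribute and a message.
#'
#' @param records A data.frame with `ohnologon_id` and `members`
#'   (comma-separated member gene IDs).
#' @param levels A data.frame `gene_id`, `level` (e.g. from
#'   [summarize_expression()]).
#' @param seed Integer seed.
#' @return `records` with a `level` column appended (dropped rows removed).
#' @export
assign_ohnologon_expression <- function(records, levels, seed) {
  stopifnot(is.data.frame(records), all(c("ohnologon_id", "members") %in% names(records)),
            all(c("gene_id", "level") %in% names(levels)))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  lvl <- stats::setNames(levels$level, levels$gene_id)
  members <- strsplit(records$members, ",", fixed = TRUE)
  known <- vapply(members, function(m) all(m %in% names(lvl)), logical(1))
  n_drop <- sum(!known)
  if (n_drop > 0) {
    message(n_drop, " ohnologon(s) dropped: member(s) without expression level")
  }
  out <- records[known, , drop = FALSE]
  members <- members[known]
  set.seed(seed)
  pick <- vapply(members, function(m) m[[sample.int(length(m), 1)]], character(1))
  out$level <- unname(lvl[pick])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_drop
  out
}

# Fixed-interval half-open bins anchored at multiples of the interval.
# Shared by the retention and KO-fitness analyses.
fixed_bins <- function(level, interval) {
  stopifnot(interval > 0)
  idx <- floor(level / interval + 1e-9)
  list(index = idx, lo = idx * interval, hi = (idx + 1) * interval)
}

#' Bin ohnologons by expression level and compute retention frequency
#'
#' Ohnologons are grouped into half-open fixed-interval bins
#' `[lo, lo + interval)` anchored at multiples of the interval; bins with
#' fewer than `min_count` ohnologons are excluded (their count is kept in
#' the `"excluded"` attribute).  Retention frequency per bin is the fraction
#' of ohnologons that retained both copies.
#'
#' @param records A data.frame with numeric `level` and 0/1 `retained`.
#' @param interval Bin width in log2 units (typically 0.2 or 1).
#' @param min_count Minimum ohnologons per reported bin (default 30).
#' @return A data.frame `lo`, `hi`, `n`, `retention`, with attribute
#'   `"excluded"` = data.frame of the excluded bins.
#' @export
bin_retention <- function(records, interval = 0.2, min_count = 30) {
  stopifnot(is.data.frame(records), all(c("level", "retained") %in% names(records)))
  if (nrow(records) == 0) {
    out <- data.frame(lo = numeric(), hi = numeric(), n = integer(),
                      retention = numeric())
    attr(out, "excluded") <- out
    return(out)
  }
  b <- fixed_bins(records$level, interval)
  f <- factor(b$index)
  n <- as.integer(table(f))
  ret <- tapply(records$retained, f, mean)
  idx <- as.numeric(levels(f))
  out <- data.frame(lo = idx * interval, hi = (idx + 1) * interval,
                    n = n, retention = as.numeric(ret))
  out <- out[order(out$lo), , drop = FALSE]
  keep <- out$n >= min_count
  excluded <- out[!keep, , drop = FALSE]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- rownames(excluded) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# 2x2 retained/lost significance test: Pearson chi-square without continuity
# correction, Fisher's exact test when any expected count < 5.
test_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || sum(tab) == 0) stop("invalid 2x2 table", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(p = stats::fisher.test(tab)$p.value, test = "fisher")
  } else {
    list(p = suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
         test = "chisq")
  }
}

#' Compare retention between the expression extremes
#'
#' Contrasts retention frequency of the 10% least and 10% most expressed
#' ohnologons.  Ties in level are broken by a stable sort on `ohnologon_id`
#' for reproducibility.  Significance from a 2x2 retained/lost test
#' (Pearson chi-square without continuity correction; Fisher's exact test
#' when any expected count < 5).
#'
#' @param records A data.frame with `ohnologon_id`, `level`, `retained`.
#' @param fraction Tail fraction (default 0.10).
#' @return A list: `freq_bottom`, `freq_top`, `fold` (top/bottom; `Inf` with
#'   `fold_infinite = TRUE` when the bottom frequency is 0), `p`, `test`,
#'   `n_tail`.
#' @export
extreme_decile_comparison <- function(records, fraction = 0.10) {
  stopifnot(is.data.frame(records),
            all(c("ohnologon_id", "level", "retained") %in% names(records)))
  n <- nrow(records)
  if (n < 20) stop("need at least 20 records for an extreme-decile comparison",
                   call. = FALSE)
  ord <- order(records$level, records$ohnologon_id)
  n_tail <- max(1L, floor(n * fraction))
  bottom <- records$retained[ord[seq_len(n_tail)]]
  top <- records$retained[ord[seq(n - n_tail + 1, n)]]
  fb <- mean(bottom); ft <- mean(top)
  tab <- rbind(bottom = c(sum(bottom), n_tail - sum(bottom)),
               top = c(sum(top), n_tail - sum(top)))
  tst <- if (fb == ft) list(p = 1, test = "none") else test_2x2(tab)
  fold_inf <- fb == 0 && ft > 0
  list(freq_bottom = fb, freq_top = ft,
       fold = if (fold_inf) Inf else if (fb == 0) 1 else ft / fb,
       fold_infinite = fold_inf, p = tst$p, test = tst$test, n_tail = n_tail)
}

# split n sorted items into q groups of equal size (+/- 1)
equal_groups <- function(n, q) {
  bounds <- floor(seq(0, n, length.out = q + 1))
  rep(seq_len(q), times = diff(bounds))
}

#' Stratified retention analysis
#'
#' Computes retention frequencies within strata (functional categories,
#' protein-complex membership, phylogenetic groups, ...), either per
#' expression quartile (equal-size groups within each stratum, the
#' functional-category design) or per fixed-interval expression bin (the
#' complex-vs-others design).  A record may map to any number of strata;
#' strata with fewer than `quartiles` records are skipped with a message.
#'
#' @param records A data.frame with `ohnologon_id`, `level`, `retained`.
#' @param annotation A data.frame `ohnologon_id`, `stratum` (possibly
#'   several rows per ohnologon).
#' @param quartiles Number of equal-size expression groups per stratum
#'   (default 4); ignored when `interval` is given.
#' @param interval If non-`NULL`, use fixed-interval bins of this width
#'   (with `min_count`) instead of quartiles.
#' @param min_count Minimum records per reported bin in interval mode.
#' @return A data.frame `stratum`, `group` (quartile index or bin lower
#'   bound), `n`, `retention`, `mean_level`.
#' @export
stratified_retention <- function(records, annotation, quartiles = 4,
                                 interval = NULL, min_count = 30) {
  stopifnot(all(c("ohnologon_id", "level", "retained") %in% names(records)),
            all(c("ohnologon_id", "stratum") %in% names(annotation)))
  merged <- merge(annotation, records, by = "ohnologon_id")
  res <- lapply(split(merged, merged$stratum), function(d) {
    if (nrow(d) < quartiles) {
      message("stratum '", d$stratum[[1]], "' skipped: only ", nrow(d), " records")
      return(NULL)
    }
    if (is.null(interval)) {
      ord <- order(d$level, d$ohnologon_id)
      d <- d[ord, , drop = FALSE]
      g <- equal_groups(nrow(d), quartiles)
      data.frame(stratum = d$stratum[[1]], group = seq_len(quartiles),
                 n = as.integer(table(g)),
                 retention = as.numeric(tapply(d$retained, g, mean)),
                 mean_level = as.numeric(tapply(d$level, g, mean)),
                 stringsAsFactors = FALSE)
    } else {
      bs <- bin_retention(d, interval = interval, min_count = min_count)
      if (nrow(bs) == 0) return(NULL)
      mean_lvl <- vapply(seq_len(nrow(bs)), function(i) {
        mean(d$level[d$level >= bs$lo[i] & d$level < bs$hi[i]])
      }, numeric(1))
      data.frame(stratum = d$stratum[[1]], group = bs$lo, n = bs$n,
                 retention = bs$retention, mean_level = mean_lvl,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Functional-category retention enrichment
#'
#' Reproduces the category-table design: categories with at most `min_genes`
#' annotated records are discarded; redundant categories (pairwise overlap
#' `shared / min(sizes)` above `overlap`) are collapsed keeping the larger
#' list; each surviving category is compared with all remaining records
#' (retention: 2x2 chi-square / Fisher; expression: Welch t-test), and its
#' per-expression-quartile retention is reported.
#'
#' @param records A data.frame with `ohnologon_id`, `level`, `retained`.
#' @param annotation A data.frame `ohnologon_id`, `category` (several rows
#'   per ohnologon allowed).
#' @param min_genes Categories must have strictly more records than this
#'   (default 400).
#' @param overlap Redundancy threshold on pairwise overlap (default 0.90).
#' @param quartiles Number of expression quartiles (default 4).
#' @return A data.frame, one row per surviving category: `category`, `n`,
#'   `retention`, `retention_others`, `p_retention`, `mean_level`,
#'   `mean_level_others`, `p_level`, and `retention_q1..q<quartiles>`.
#' @export
category_enrichment <- function(records, annotation, min_genes = 400,
                                overlap = 0.90, quartiles = 4) {
  stopifnot(all(c("ohnologon_id", "level", "retained") %in% names(records)),
            all(c("ohnologon_id", "category") %in% names(annotation)))
  annotation <- annotation[!is.na(annotation$category) &
                             annotation$ohnologon_id %in% records$ohnologon_id, ]
  lists <- split(annotation$ohnologon_id, annotation$category)
  lists <- lapply(lists, unique)
  lists <- lists[lengths(lists) > min_genes]
  if (length(lists) == 0) return(NULL)
  # redundancy removal: scan by decreasing size, keep a category only if it
  # does not overlap an already-kept one by more than the threshold
  ord <- order(-lengths(lists), names(lists))
  kept <- character()
  for (nm in names(lists)[ord]) {
    redundant <- any(vapply(kept, function(kp) {
      length(intersect(lists[[nm]], lists[[kp]])) /
        min(length(lists[[nm]]), length(lists[[kp]])) > overlap
    }, logical(1)))
    if (!redundant) kept <- c(kept, nm)
  }
  kept <- sort(kept)
  rec <- records[!duplicated(records$ohnologon_id), ]
  rows <- lapply(kept, function(nm) {
    inside <- rec$ohnologon_id %in% lists[[nm]]
    a <- rec[inside, ]; b <- rec[!inside, ]
    tab <- rbind(c(sum(a$retained), sum(1 - a$retained)),
                 c(sum(b$retained), sum(1 - b$retained)))
    pt <- test_2x2(tab)$p
    pl <- stats::t.test(a$level, b$level)$p.value
    d <- a[order(a$level, a$ohnologon_id), ]
    g <- equal_groups(nrow(d), quartiles)
    qret <- as.numeric(tapply(d$retained, g, mean))
    row <- data.frame(category = nm, n = nrow(a),
                      retention = mean(a$retained),
                      retention_others = mean(b$retained),
                      p_retention = pt,
                      mean_level = mean(a$level),
                      mean_level_others = mean(b$level),
                      p_level = pl, stringsAsFactors = FALSE)
    for (q in seq_len(quartiles)) row[[paste0("retention_q", q)]] <- qret[[q]]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lowess visual-aid smoother
#'
#' Locally-weighted polynomial regression through binned retention points,
#' for plotting only (never used in statistics).  With fewer than 5 points
#' the input is passed through unchanged with a warning.
#'
#' @param x,y Numeric vectors (e.g. bin mid-level and retention frequency).
#' @param span Lowess smoother span `f` (default 2/3).
#' @return A data.frame `x`, `y` of smoothed points, ordered by `x`.
#' @export
lowess_curve <- function(x, y, span = 2 / 3) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) {
    warning("fewer than 5 points: returning input unchanged", call. = FALSE)
    ord <- order(x)
    return(data.frame(x = x[ord], y = y[ord]))
  }
  sm <- stats::lowess(x, y, f = span)
  data.frame(x = sm$x, y = sm$y)
}
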