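# Retention pipeline: summarization, normalization, ohnologon expression
# assignment, binning, extreme deciles, stratified and category analyses.

test_that("probe medians match a brute-force per-column median", {
  probes <- data.frame(gene_id = "g1", matrix(1:6, 6, 1))
  names(probes)[2] <- "c1"
  expect_equal(probe_median(probes)$c1, 3.5)
  single <- data.frame(gene_id = "g2", c1 = 7, c2 = 9)
  expect_equal(probe_median(single)[, c("c1", "c2")],
               data.frame(c1 = 7, c2 = 9))
  set.seed(42)
  big <- data.frame(gene_id = rep(sprintf("g%02d", 1:10), each = 6),
                    matrix(rnorm(60 * 58), 60, 58))
  names(big)[-1] <- paste0("c", 1:58)
  got <- probe_median(big)
  for (g in unique(big$gene_id)) {
    block <- as.matrix(big[big$gene_id == g, -1])
    expect_equal(as.numeric(got[got$gene_id == g, -1]),
                 unname(apply(block, 2, median)), tolerance = 1e-12)
  }
  expect_error(probe_median(data.frame(gene_id = c("a", NA), c1 = 1:2)),
               "missing gene_id")
})

test_that("quantile normalization: hand example, properties, limma oracle", {
  m <- data.frame(gene_id = c("a", "b", "c"), x = c(1, 2, 3), y = c(4, 5, 6))
  got <- normalize_between_arrays(m, "quantile")
  expect_equal(got$x, c(2.5, 3.5, 4.5))
  expect_equal(got$y, c(2.5, 3.5, 4.5))
  # identical columns unchanged
  m2 <- data.frame(gene_id = c("a", "b"), x = c(1, 5), y = c(1, 5))
  expect_equal(normalize_between_arrays(m2, "quantile"), m2)
  # column means equal after normalization; sorted columns identical
  set.seed(7)
  m3 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   matrix(rlnorm(200 * 6), 200, 6))
  got3 <- normalize_between_arrays(m3, "quantile")
  mm <- as.matrix(got3[-1])
  expect_equal(as.numeric(colMeans(mm)), rep(mean(mm[, 1]), 6), tolerance = 1e-12)
  srt <- apply(mm, 2, sort)
  expect_true(all(abs(srt - srt[, 1]) < 1e-12))
  # independent oracle: limma's quantile normalization (no ties here)
  ref <- limma::normalizeBetweenArrays(as.matrix(m3[-1]), method = "quantile")
  expect_equal(unname(mm), unname(ref), tolerance = 1e-10)
  expect_error(normalize_between_arrays(data.frame(gene_id = "a", x = 1), "quantile"),
               "at least 2")
})

test_that("expression summarization is the log2 of the median signal", {
  m <- data.frame(gene_id = c("g1", "g2"),
                  c1 = c(8, 2), c2 = c(8, 4), c3 = c(8, 8))
  lv <- summarize_expression(m)
  expect_equal(lv$level, c(3, 2))
  # permutation invariance
  mp <- m[, c("gene_id", "c3", "c1", "c2")]
  expect_equal(summarize_expression(mp)$level, lv$level)
  # zeros: error unless a floor is configured
  mz <- data.frame(gene_id = "g1", c1 = 0, c2 = 4, c3 = 8)
  expect_error(summarize_expression(mz), "floor")
  expect_equal(summarize_expression(mz, floor = "auto")$level, 2)
  expect_equal(summarize_expression(mz, floor = 1)$level, 2)
})

test_that("ohnologon expression assignment picks members reproducibly", {
  levels <- data.frame(gene_id = c("a", "b", "c"), level = c(1, 5, 5))
  rec <- data.frame(ohnologon_id = c("o1", "o2"),
                    members = c("a", "b,c"), stringsAsFactors = FALSE)
  got <- assign_ohnologon_expression(rec, levels, seed = 1)
  expect_equal(got$level, c(1, 5)) # singleton + equal-level pair
  # missing member level drops the record with a logged count
  rec2 <- rbind(rec, data.frame(ohnologon_id = "o3", members = "a,zzz"))
  expect_message(got2 <- assign_ohnologon_expression(rec2, levels, seed = 1),
                 "dropped")
  expect_equal(nrow(got2), 2)
  expect_equal(attr(got2, "n_dropped"), 1)
  # over many seeds each member of an unequal pair is chosen ~50%
  lv <- data.frame(gene_id = c("p", "q"), level = c(2, 9))
  pair <- data.frame(ohnologon_id = "o", members = "p,q",
                     stringsAsFactors = FALSE)
  picks <- vapply(1:10000, function(s) {
    assign_ohnologon_expression(pair, lv, seed = s)$level
  }, numeric(1))
  expect_lt(abs(mean(picks == 2) - 0.5), 0.015)
  expect_identical(assign_ohnologon_expression(pair, lv, seed = 99)$level,
                   assign_ohnologon_expression(pair, lv, seed = 99)$level)
})

test_that("fixed-interval binning: hand counts, exclusion, partition", {
  rec <- make_records(level = rep(0.5, 40), retained = rep(1, 40))
  bs <- bin_retention(rec, interval = 1)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$retention, 1.0)
  expect_equal(c(bs$lo, bs$hi), c(0, 1))
  # 29 records in a bin -> excluded
  bs29 <- bin_retention(make_records(rep(0.5, 29), rep(1, 29)), interval = 1)
  expect_equal(nrow(bs29), 0)
  expect_equal(attr(bs29, "excluded")$n, 29)
  # constructed 3-bin toy: counts 50/60/40, retained 10/30/30
  rec3 <- make_records(
    level = c(rep(0.5, 50), rep(1.5, 60), rep(2.5, 40)),
    retained = c(rep(1, 10), rep(0, 40), rep(1, 30), rep(0, 30),
                 rep(1, 30), rep(0, 10)))
  bs3 <- bin_retention(rec3, interval = 1)
  expect_equal(bs3$n, c(50L, 60L, 40L))
  expect_equal(bs3$retention, c(0.2, 0.5, 0.75))
  # partition + count conservation on random data
  set.seed(3)
  recr <- make_records(rnorm(500, 0, 3), rbinom(500, 1, 0.5))
  bsr <- bin_retention(recr, interval = 0.2, min_count = 5)
  excl <- attr(bsr, "excluded")
  expect_equal(sum(bsr$n) + sum(excl$n), 500)
  all_bins <- rbind(bsr[c("lo", "hi")], excl[c("lo", "hi")])
  in_bin <- vapply(recr$level, function(l) {
    sum(l >= all_bins$lo & l < all_bins$hi)
  }, numeric(1))
  expect_true(all(in_bin == 1)) # every record in exactly one bin
  # bins anchored at multiples of the interval
  expect_true(all(abs(bsr$lo / 0.2 - round(bsr$lo / 0.2)) < 1e-9))
  expect_equal(nrow(bin_retention(make_records(numeric(0), integer(0)))), 0)
})

test_that("extreme-decile comparison: hand counts and chi-square oracle", {
  all_ret <- make_records(level = seq_len(40), retained = rep(1, 40))
  res <- extreme_decile_comparison(all_ret)
  expect_equal(res[c("freq_bottom", "freq_top", "fold", "p")],
               list(freq_bottom = 1, freq_top = 1, fold = 1, p = 1))
  # constructed 100 records: bottom decile 2/10 retained, top 8/10
  ret <- c(rep(1, 2), rep(0, 8), rbinom(80, 1, 0.5), rep(1, 8), rep(0, 2))
  rec <- make_records(level = seq_len(100), retained = ret)
  res <- extreme_decile_comparison(rec)
  expect_equal(res$freq_bottom, 0.2)
  expect_equal(res$freq_top, 0.8)
  expect_equal(res$fold, 4.0)
  # p equals the brute-force 2x2 chi-square when expected counts allow
  big <- make_records(level = seq_len(1000),
                      retained = c(rep(c(1, 0), c(30, 70)),
                                   rbinom(800, 1, 0.5),
                                   rep(c(1, 0), c(60, 40))))
  resb <- extreme_decile_comparison(big)
  expect_equal(resb$test, "chisq")
  expect_equal(resb$p, oracle_chisq_p(rbind(c(30, 70), c(60, 40))),
               tolerance = 1e-12)
  # zero bottom retention flags an infinite fold
  zed <- make_records(seq_len(100), c(rep(0, 50), rep(1, 50)))
  resz <- extreme_decile_comparison(zed)
  expect_true(resz$fold_infinite)
  expect_equal(resz$fold, Inf)
  expect_error(extreme_decile_comparison(make_records(1:10, rep(1, 10))),
               "at least 20")
})

test_that("stratified retention: hand example, consistency, conservation", {
  rec <- make_records(level = 1:8, retained = c(0, 0, 1, 0, 1, 1, 1, 1))
  ann <- data.frame(ohnologon_id = rec$ohnologon_id, stratum = "s1")
  got <- stratified_retention(rec, ann)
  expect_equal(got$retention, c(0, 0.5, 1, 1))
  expect_equal(got$n, rep(2L, 4))
  # two disjoint strata partition the records: weighted mean = global mean
  set.seed(9)
  rec2 <- make_records(rnorm(200), rbinom(200, 1, 0.6))
  ann2 <- data.frame(ohnologon_id = rec2$ohnologon_id,
                     stratum = rep(c("A", "B"), each = 100))
  got2 <- stratified_retention(rec2, ann2)
  wmean <- sum(got2$retention * got2$n) / sum(got2$n)
  expect_equal(wmean, mean(rec2$retained), tolerance = 1e-12)
  # undersized stratum skipped with a message
  ann3 <- rbind(ann2, data.frame(ohnologon_id = rec2$ohnologon_id[1:2],
                                 stratum = "tiny"))
  expect_message(got3 <- stratified_retention(rec2, ann3), "skipped")
  expect_false("tiny" %in% got3$stratum)
  # interval mode uses the fixed-interval engine
  goti <- stratified_retention(rec2, ann2, interval = 1, min_count = 5)
  expect_true(all(goti$n >= 5))
  expect_true(all(abs(goti$group - round(goti$group)) < 1e-9))
})

test_that("category enrichment applies size and overlap filters", {
  set.seed(21)
  n <- 1600
  rec <- make_records(level = rnorm(n), retained = rbinom(n, 1, 0.5))
  ids <- rec$ohnologon_id
  # big: 500 members; sub: 450 of those (95% overlap) -> sub eliminated;
  # small: 399 members -> below the >400 threshold
  ann <- rbind(
    data.frame(ohnologon_id = ids[1:500], category = "big"),
    data.frame(ohnologon_id = ids[26:475], category = "sub"),
    data.frame(ohnologon_id = ids[600:998], category = "small"),
    data.frame(ohnologon_id = ids[700:1160], category = "other"))
  got <- category_enrichment(rec, ann, min_genes = 400, overlap = 0.90)
  expect_setequal(got$category, c("big", "other"))
  # overlap below the threshold keeps both
  ann2 <- rbind(
    data.frame(ohnologon_id = ids[1:500], category = "big"),
    data.frame(ohnologon_id = ids[101:550], category = "shifted"))
  got2 <- category_enrichment(rec, ann2, min_genes = 400)
  expect_setequal(got2$category, c("big", "shifted"))
})

test_that("category enrichment statistics match brute-force oracles", {
  # constructed: category retention 30/50, rest 20/50
  rec <- make_records(level = c(rnorm(50, 2), rnorm(50, 0)),
                      retained = c(rep(c(1, 0), c(30, 20)),
                                   rep(c(1, 0), c(20, 30))))
  ann <- data.frame(ohnologon_id = rec$ohnologon_id[1:50], category = "cat")
  got <- category_enrichment(rec, ann, min_genes = 10)
  expect_equal(got$retention, 0.6)
  expect_equal(got$retention_others, 0.4)
  expect_equal(got$p_retention, oracle_chisq_p(rbind(c(30, 20), c(20, 30))),
               tolerance = 1e-12)
  expect_equal(got$p_level,
               t.test(rec$level[1:50], rec$level[51:100])$p.value,
               tolerance = 1e-12)
  expect_true(all(c("retention_q1", "retention_q4") %in% names(got)))
})

test_that("lowess smoother: degenerate and noisy inputs", {
  expect_warning(got <- lowess_curve(1:3, c(1, 2, 3)), "fewer than 5")
  expect_equal(got$y, c(1, 2, 3))
  x <- seq(0, 1, length.out = 50)
  expect_equal(lowess_curve(x, rep(0.4, 50))$y, rep(0.4, 50))
  lin <- lowess_curve(x, 2 * x + 1)
  expect_equal(lin$y, 2 * lin$x + 1, tolerance = 1e-6)
  set.seed(4)
  sig <- 1 / (1 + exp(-10 * (x - 0.5)))
  noisy <- sig + rnorm(50, 0, 0.1)
  sm <- lowess_curve(x, noisy, span = 0.5)
  expect_lt(sd(sm$y - sig), 0.1)
})
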