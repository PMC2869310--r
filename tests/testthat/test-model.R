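# Cost function, benefit calibration, fitness, curvature and the derived
# selection coefficients.

test_that("expression cost matches hand evaluation and domain rules", {
  expect_equal(expression_cost(0, k = 0.3, M = 7), 0)
  expect_equal(expression_cost(50, k = 0.01, M = 100), 1.0)
  expect_gt(expression_cost(99.999, k = 0.01, M = 100), 100)
  expect_error(expression_cost(100, k = 0.01, M = 100), "saturated")
  expect_error(expression_cost(-1, k = 0.01, M = 100), "non-negative")
  expect_error(expression_cost(1, k = 0, M = 100), "k must be")
  # strictly increasing and convex on a grid
  X <- seq(0, 90, by = 1)
  cc <- expression_cost(X, k = 0.01, M = 100)
  expect_true(all(diff(cc) > 0))
  expect_true(all(diff(diff(cc)) > 0))
})

test_that("benefit calibration solves normalization and optimality", {
  b50 <- calibrate_benefit(50, k = 0.01, M = 100)
  expect_equal(b50$b, 2.0)
  expect_equal(b50$a, 0.0)
  b25 <- calibrate_benefit(25, k = 0.01, M = 100)
  expect_equal(b25$b, 25 * 0.01 / 0.75^2, tolerance = 1e-12)
  # vanishing expression needs vanishing marginal benefit
  expect_lt(calibrate_benefit(1e-6, k = 0.01, M = 100)$b, 1e-6)
  expect_error(calibrate_benefit(0, k = 0.01, M = 100), "X0")
  expect_error(calibrate_benefit(100, k = 0.01, M = 100), "X0")
})

test_that("fitness is calibrated: w(1) = 1, w'(1) = 0, w''(1) < 0 on a grid", {
  grid <- param_grid()
  g <- gene_model(grid$X0, k = grid$k, M = grid$M)
  expect_gte(length(g), 100)
  expect_true(all(abs(fitness(1, g) - 1) < 1e-12))
  h <- 1e-5
  wprime <- (fitness(1 + h, g) - fitness(1 - h, g)) / (2 * h)
  expect_true(all(abs(wprime) < 1e-6))
  expect_true(all(curvature_at_optimum(g) < 0))
})

test_that("fitness hand examples and domain errors", {
  g <- ref_gene()
  expect_equal(fitness(0.5, g), 2 / 3, tolerance = 1e-12)
  expect_equal(fitness(0, g), 0) # affine with a = 0: no benefit, no cost
  expect_error(fitness(2, g), "capacity")
  expect_error(fitness(-0.1, g), "non-negative")
})

test_that("curvature examples and growth with X0", {
  expect_equal(curvature_at_optimum(ref_gene()), -4.0)
  expect_equal(curvature_at_optimum(gene_model(25, 0.01, 100)),
               -25^2 * 2 * 0.01 / (100 * 0.75^3), tolerance = 1e-12)
  X0 <- c(10, 30, 50, 70, 90)
  curv <- curvature_at_optimum(gene_model(X0, 0.01, 100))
  expect_true(all(diff(abs(curv)) > 0))
})

test_that("Taylor expansion is exact at x = 1 and third-order accurate nearby", {
  g <- ref_gene()
  expect_equal(taylor_fitness(1, g), 1.0)
  expect_equal(taylor_fitness(0.5, g), 1 + 0.5 * (-4) * 0.25)
  expect_lt(abs(taylor_fitness(0.99, g) - fitness(0.99, g)), 1e-4)
  # error scales like |x - 1|^3: err / |x-1|^3 stays within a bounded band
  dx <- c(0.02, 0.04, 0.06, 0.08, 0.1)
  for (side in c(-1, 1)) {
    x <- 1 + side * dx
    ratio <- abs(taylor_fitness(x, g) - fitness(x, g)) / dx^3
    expect_lt(max(ratio) / min(ratio), 2)
  }
})

test_that("halving selection coefficient: examples, positivity, monotonicity", {
  g <- ref_gene()
  expect_equal(sel_coeff_halving(g, "taylor"), 0.5)
  expect_equal(sel_coeff_halving(g, "exact"), 1 / 3, tolerance = 1e-12)
  tiny <- gene_model(1e-4, 0.01, 100)
  expect_lt(sel_coeff_halving(tiny, "taylor"), 1e-6)
  expect_lt(sel_coeff_halving(tiny, "exact"), 1e-6)
  X0 <- seq(5, 95, by = 5)
  gs <- gene_model(X0, 0.01, 100)
  for (m in c("taylor", "exact")) {
    s <- sel_coeff_halving(gs, m)
    expect_true(all(s >= 0))
    expect_true(all(diff(s) > 0))
  }
})

test_that("Taylor halving coefficient grows more accurate as X0/M shrinks", {
  M <- 100
  X0 <- c(80, 60, 40, 20, 10, 5, 1)  # decreasing X0/M
  g <- gene_model(X0, 0.01, M)
  rel_err <- abs(sel_coeff_halving(g, "taylor") - sel_coeff_halving(g, "exact")) /
    sel_coeff_halving(g, "exact")
  expect_true(all(diff(rel_err) < 0))
})

test_that("pseudogenization coefficient equals B'(1), positive, increasing in X0", {
  expect_equal(as.numeric(sel_coeff_pseudogene(ref_gene())), 2.0)
  expect_true(attr(sel_coeff_pseudogene(ref_gene()), "lower_bound"))
  X0 <- seq(1, 95, by = 2)
  s <- as.numeric(sel_coeff_pseudogene(gene_model(X0, 0.01, 100)))
  expect_true(all(s > 0))
  expect_true(all(diff(s) > 0))
  expect_lt(s[[1]], 0.02) # vanishes with X0
})

test_that("missense loss: alpha scaling, monotone in X0, domain check", {
  g <- ref_gene()
  expect_equal(missense_fitness_loss(0, g), 0)
  expect_equal(missense_fitness_loss(0.1, g), 0.2)
  g2 <- gene_model(c(25, 75), 0.01, 100)
  loss <- missense_fitness_loss(0.3, g2)
  expect_lt(loss[[1]], loss[[2]])
  expect_error(missense_fitness_loss(1.2, g), "alpha")
  expect_error(missense_fitness_loss(-0.1, g), "alpha")
})

test_that("custom benefit family is normalized and keeps its curvature", {
  # quadratic benefit matching the affine slope at x = 1 for X0=50,k=0.01,M=100:
  # B(x) = x^2 has B'(1) = 2 = X0*C'(X0), B''(1) = 2
  g <- gene_model(50, 0.01, 100, family = "custom", B = function(x) x^2, Bpp1 = 2)
  expect_equal(fitness(1, g), 1, tolerance = 1e-12)
  expect_equal(curvature_at_optimum(g), 2 - 50^2 * 0.0016, tolerance = 1e-4)
  # a benefit violating the optimality condition is flagged
  expect_warning(gene_model(50, 0.01, 100, family = "custom",
                            B = function(x) 0.5 * x, Bpp1 = 0),
                 "optimum")
})

test_that("model_curves sharpen around the optimum as X0 grows", {
  cv <- model_curves(c(10, 50, 90), k = 0.01, M = 100)
  expect_true(all(c("X0", "x", "w") %in% names(cv)))
  at_opt <- cv[abs(cv$x - 1) < 1e-9, ]
  expect_equal(at_opt$w, rep(1, 3))
  drop_at_half <- vapply(c(10, 50, 90), function(x0) {
    1 - cv$w[cv$X0 == x0 & abs(cv$x - 0.5) < 1e-9]
  }, numeric(1))
  expect_true(all(diff(drop_at_half) > 0))
})
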