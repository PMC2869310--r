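# Core cost-benefit model of gene-expression fitness.
#
# A gene expressed at absolute level X pays a Monod-type resource cost
#   C(X) = k * X / (1 - X/M),    0 <= X < M,
# and draws a benefit B(x) from its product, where x = X/X0 is expression
# relative to the gene's optimal level X0.  Relative fitness is
#   w(x) = B(x) - C(X0 * x),
# calibrated so that w(1) = 1 (normalization) and w'(1) = 0 (optimality).

#' Monod-type cost of gene expression
#'
#' Cost of expressing a gene at absolute level `X` under limiting cellular
#' resources: `C(X) = k * X / (1 - X / M)`.  The cost is zero at `X = 0`,
#' strictly increasing and convex, and diverges as `X` approaches the maximal
#' expression capacity `M`.
#'
#' @param X Absolute expression level(s); must satisfy `0 <= X < M`.
#' @param k Cost scaling factor (fitness per expression unit), `k > 0`.
#' @param M Maximal expression capacity (expression units), `M > 0`.
#' @return Numeric vector of fitness costs.
#' @examples
#' expression_cost(50, k = 0.01, M = 100) # 1
#' @export
expression_cost <- function(X, k, M) {
  check_cost_params(k, M)
  if (any(X < 0)) stop("expression level X must be non-negative", call. = FALSE)
  if (any(X >= M)) {
    stop("expression level X >= M: cellular resources saturated (cost diverges)",
         call. = FALSE)
  }
  k * X / (1 - X / M)
}

#' First derivative of the expression cost
#'
#' `C'(X) = k / (1 - X/M)^2`, the marginal fitness cost of one additional
#' expression unit.
#'
#' @inheritParams expression_cost
#' @return Numeric vector, `C'(X)`.
#' @export
expression_cost_slope <- function(X, k, M) {
  check_cost_params(k, M)
  if (any(X < 0 | X >= M)) stop("X must lie in [0, M)", call. = FALSE)
  k / (1 - X / M)^2
}

#' Second derivative of the expression cost
#'
#' `C''(X) = 2k / (M * (1 - X/M)^3)`; always positive, so the cost is convex
#' and the convexity grows without bound as `X` approaches `M`.
#'
#' @inheritParams expression_cost
#' @return Numeric vector, `C''(X)`.
#' @export
expression_cost_curvature <- function(X, k, M) {
  check_cost_params(k, M)
  if (any(X < 0 | X >= M)) stop("X must lie in [0, M)", call. = FALSE)
  2 * k / (M * (1 - X / M)^3)
}

check_cost_params <- function(k, M) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be > 0", call. = FALSE)
  if (any(!is.finite(M)) || any(M <= 0)) stop("M must be > 0", call. = FALSE)
  invisible(TRUE)
}

#' Calibrate the benefit function of a gene
#'
#' Solves the normalization and optimality conditions at the optimum `x = 1`:
#' `B(1) - C(X0) = 1` and `B'(1) = X0 * C'(X0)`.  For the affine family
#' `B(x) = a + b x` this gives the slope `b = X0 * C'(X0)` and intercept
#' `a = 1 + C(X0) - b`.  For a user-supplied smooth benefit the function is
#' shifted by an additive constant so the normalization holds; the optimality
#' condition is checked numerically and a warning is emitted if it fails.
#'
#' @param X0 Optimal absolute expression level(s), `0 < X0 < M`.
#' @inheritParams expression_cost
#' @param family `"affine"` (default) or `"custom"`.
#' @param B For `family = "custom"`: a vectorized function of relative
#'   expression `x` giving the (uncalibrated) benefit.
#' @param Bpp1 Second derivative of the benefit at `x = 1` (0 for affine).
#' @return A list of class `benefit_function` with elements `family`, `a`
#'   (intercept / additive shift), `b` (slope `B'(1)`), `Bpp1`, and for the
#'   custom family the user function `B`.
#' @export
calibrate_benefit <- function(X0, k, M, family = c("affine", "custom"),
                              B = NULL, Bpp1 = 0) {
  family <- match.arg(family)
  check_cost_params(k, M)
  if (any(X0 <= 0 | X0 >= M)) stop("X0 must lie in (0, M)", call. = FALSE)
  b <- X0 * expression_cost_slope(X0, k, M)
  if (family == "affine") {
    a <- 1 + expression_cost(X0, k, M) - b
    out <- list(family = "affine", a = a, b = b, Bpp1 = rep_len(0, length(b)))
  } else {
    if (!is.function(B)) stop("custom family requires a benefit function B", call. = FALSE)
    a <- 1 + expression_cost(X0, k, M) - B(1)
    h <- 1e-5
    b_num <- (B(1 + h) - B(1 - h)) / (2 * h)
    if (any(abs(b_num - b) > 1e-3 * pmax(1, abs(b)))) {
      warning("custom benefit does not satisfy B'(1) = X0 * C'(X0); ",
              "gene is not at its expression optimum", call. = FALSE)
    }
    if (any(b_num <= 0)) {
      stop("benefit must be increasing at x = 1 (B'(1) > 0)", call. = FALSE)
    }
    out <- list(family = "custom", a = a, b = b_num, Bpp1 = rep_len(Bpp1, length(a)),
                B = B)
  }
  class(out) <- "benefit_function"
  out
}

#' Construct (and calibrate) gene models
#'
#' A gene model bundles the cost parameters `(k, M)`, the optimal expression
#' level `X0` and a calibrated benefit function.  All arguments are recycled
#' to a common length, so a single call can hold a whole gene population.
#'
#' @inheritParams calibrate_benefit
#' @return An object of class `gene_model` with vector fields `X0`, `k`, `M`
#'   and a calibrated `benefit`.
#' @examples
#' g <- gene_model(X0 = 50, k = 0.01, M = 100)
#' fitness(1, g)  # exactly 1
#' @export
gene_model <- function(X0, k = 0.01, M = 100, family = c("affine", "custom"),
                       B = NULL, Bpp1 = 0) {
  family <- match.arg(family)
  n <- if (length(X0) == 0) 0L else max(length(X0), length(k), length(M))
  X0 <- rep_len(as.numeric(X0), n)
  k <- rep_len(as.numeric(k), n)
  M <- rep_len(as.numeric(M), n)
  ben <- calibrate_benefit(X0, k, M, family = family, B = B, Bpp1 = Bpp1)
  structure(list(X0 = X0, k = k, M = M, benefit = ben),
            class = "gene_model")
}

#' @export
length.gene_model <- function(x) length(x$X0)

#' @export
`[.gene_model` <- function(x, i) {
  ben <- x$benefit
  sub <- list(family = ben$family, a = ben$a[i], b = ben$b[i], Bpp1 = ben$Bpp1[i])
  if (ben$family == "custom") sub$B <- ben$B
  class(sub) <- "benefit_function"
  structure(list(X0 = x$X0[i], k = x$k[i], M = x$M[i], benefit = sub),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<gene_model: %d gene%s, %s benefit>\n", n,
              if (n == 1) "" else "s", x$benefit$family))
  cat(sprintf("  X0: %s\n", summary_range(x$X0)))
  cat(sprintf("  k : %s   M: %s\n", summary_range(x$k), summary_range(x$M)))
  invisible(x)
}

summary_range <- function(v) {
  if (length(unique(v)) == 1) format(v[[1]], digits = 6)
  else sprintf("[%s, %s]", format(min(v), digits = 6), format(max(v), digits = 6))
}

# Recycling rule for (x, gene) pairs: either side may be scalar, or the
# lengths must match exactly.
align_x_gene <- function(x, gene) {
  n <- length(gene)
  m <- length(x)
  if (m == n) return(list(x = x, i = seq_len(n)))
  if (m == 1) return(list(x = rep_len(x, n), i = seq_len(n)))
  if (n == 1) return(list(x = x, i = rep_len(1L, m)))
  stop("length of x (", m, ") must be 1 or match the number of genes (", n, ")",
       call. = FALSE)
}

benefit_value <- function(x, gene, i) {
  ben <- gene$benefit
  if (ben$family == "affine") ben$a[i] + ben$b[i] * x
  else ben$a[i] + ben$B(x)
}

#' Relative fitness of a gene at relative expression x
#'
#' `w(x) = B(x) - C(X0 * x)`.  For a calibrated gene `w(1) = 1` exactly and
#' `w'(1) = 0`.
#'
#' @param x Relative expression level(s), `0 <= x < M/X0`; `x = 1` is the
#'   optimum, `x = 1/2` models the loss of one of two ohnolog copies.
#' @param gene A [gene_model].
#' @return Numeric vector of relative fitness values.
#' @export
fitness <- function(x, gene) {
  stopifnot(inherits(gene, "gene_model"))
  al <- align_x_gene(x, gene)
  x <- al$x; i <- al$i
  if (any(x < 0)) stop("relative expression x must be non-negative", call. = FALSE)
  X <- gene$X0[i] * x
  if (any(X >= gene$M[i])) {
    stop("x * X0 >= M: expression beyond cellular capacity", call. = FALSE)
  }
  benefit_value(x, gene, i) - expression_cost_pointwise(X, gene$k[i], gene$M[i])
}

# internal: elementwise cost without re-validating k, M (already validated)
expression_cost_pointwise <- function(X, k, M) k * X / (1 - X / M)

#' Curvature of the fitness function at the optimum
#'
#' `w''(1) = B''(1) - X0^2 * C''(X0)`, always negative for a calibrated gene:
#' the sharper (more negative) the curvature, the stronger selection against
#' deviations from optimal expression.  For a fixed cost function and affine
#' benefit its magnitude grows with `X0`.
#'
#' @inheritParams fitness
#' @return Numeric vector, `w''(1)` (negative).
#' @export
curvature_at_optimum <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  gene$benefit$Bpp1 - gene$X0^2 * expression_cost_curvature(gene$X0, gene$k, gene$M)
}

#' Second-order Taylor approximation of fitness around the optimum
#'
#' `w(x) ~ 1 + w''(1) * (x - 1)^2 / 2`; accurate to third order near `x = 1`,
#' and the more accurate globally the smaller `X0/M` is.
#'
#' @inheritParams fitness
#' @return Numeric vector of approximate fitness values.
#' @export
taylor_fitness <- function(x, gene) {
  stopifnot(inherits(gene, "gene_model"))
  al <- align_x_gene(x, gene)
  1 + 0.5 * curvature_at_optimum(gene)[al$i] * (al$x - 1)^2
}

#' Selection coefficient against halving of expression
#'
#' Fitness loss when expression drops to `x = 1/2`, the first-order model of
#' losing one of the two gene copies created by a whole-genome duplication.
#' `method = "taylor"` evaluates the quadratic expansion, `s = -w''(1)/8`;
#' `method = "exact"` evaluates the full model, `s = 1 - w(1/2)`.
#'
#' @inheritParams fitness
#' @param method `"taylor"` or `"exact"`.
#' @return Numeric vector of non-negative selection coefficients.
#' @export
sel_coeff_halving <- function(gene, method = c("taylor", "exact")) {
  method <- match.arg(method)
  if (method == "taylor") -curvature_at_optimum(gene) / 8
  else 1 - fitness(0.5, gene)
}

#' Selection coefficient against pseudogenization
#'
#' Cost of expressing a functionless peptide at unchanged level: the benefit
#' is lost while the full expression cost is still paid.  At first order this
#' equals `B'(1) = X0 * C'(X0)`; a dominant-negative peptide could cost more,
#' so the value is a lower bound (flagged in the `"lower_bound"` attribute).
#'
#' @inheritParams fitness
#' @return Numeric vector with attribute `lower_bound = TRUE`.
#' @export
sel_coeff_pseudogene <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  structure(gene$X0 * expression_cost_slope(gene$X0, gene$k, gene$M),
            lower_bound = TRUE)
}

#' Fitness loss of a missense allele
#'
#' A missense mutation leaves expression (hence cost) unchanged but scales
#' the benefit down by a fraction `alpha`.  At the expression optimum the
#' fitness loss is `alpha * B(1) = alpha * (1 + C(X0))`: mutations of equal
#' functional effect are more deleterious in highly expressed genes because
#' of the larger expression cost already sunk into them.
#'
#' @param alpha Fractional decrease of the benefit caused by the allele, in
#'   `[0, 1]`.
#' @inheritParams fitness
#' @return Numeric vector of fitness losses.
#' @export
missense_fitness_loss <- function(alpha, gene) {
  stopifnot(inherits(gene, "gene_model"))
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]", call. = FALSE)
  al <- align_x_gene(alpha, gene)
  i <- al$i
  al$x * (1 + expression_cost_pointwise(gene$X0[i], gene$k[i], gene$M[i]))
}

#' Fitness curves over a grid of relative expression
#'
#' Evaluates `w(x)` over an `x` grid for one or more optimal expression
#' levels, reproducing the characteristic family of curves: the higher `X0`,
#' the sharper the fitness peak at `x = 1`.
#'
#' @param X0 Vector of optimal expression levels.
#' @inheritParams expression_cost
#' @param x Grid of relative expression values.
#' @return A data.frame with columns `X0`, `x`, `w`.
#' @export
model_curves <- function(X0, k = 0.01, M = 100,
                         x = seq(0, 2, by = 0.02)) {
  rows <- lapply(X0, function(x0) {
    g <- gene_model(x0, k = k, M = M)
    xs <- x[x * x0 < M]
    data.frame(X0 = x0, x = xs, w = fitness(xs, g))
  })
  do.call(rbind, rows)
}
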