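#' Fit a beta-uniform mixture to a p-value distribution
#'
#' The observed p-values from a differential-expression analysis are
#' modelled as a mixture of uniformly distributed noise and a Beta(alpha, 1)
#' signal component with density
#' \deqn{f(x) = \lambda + (1-\lambda)\,\alpha\, x^{\alpha-1},}
#' where `lambda` in (0,1) is the noise weight and `alpha` in (0,1) the beta
#' shape. Parameters are estimated by maximum likelihood on the logit scale
#' (the likelihood can be multimodal for weak signal, so a multi-start
#' bounded optimization is used: a fixed low-discrepancy grid of starts plus
#' seeded random starts, best run kept).
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @param n_starts Number of optimizer starts (first four from a fixed grid,
#'   the rest drawn under `seed`).
#' @param seed Integer seed for the random starts.
#' @param force Fit even when fewer than 100 p-values are supplied
#'   (estimates are unstable at small n; refused by default).
#' @return A `bum_fit` list: `lambda_mix`, `alpha`, `n_obs`,
#'   `log_likelihood`, and `pi0_upper = lambda + (1-lambda) * alpha`, the
#'   usual upper bound on the fraction of true nulls.
#' @examples
#' p <- rbum(2000, lambda_mix = 0.7, alpha = 0.3, seed = 1)
#' fit_bum(p, seed = 1)
#' @export
fit_bum <- function(p_values, n_starts = 8L, seed = 1L, force = FALSE) {
  x <- as.numeric(p_values)
  if (anyNA(x) || any(x <= 0 | x > 1))
    stop2("all p-values must lie in (0, 1]")
  if (length(x) < 100L) {
    if (!force) {
      warn2("fewer than 100 p-values; refusing to fit (use force = TRUE)")
      stop2("too few p-values for a stable beta-uniform mixture fit")
    }
    warn2("fitting a beta-uniform mixture to fewer than 100 p-values; ",
          "estimates may be unstable")
  }
  if (length(unique(x)) == 1L)
    stop2("degenerate input: all p-values identical")

  lx <- log(x)
  eps <- 1e-4
  # negative log-likelihood on the logit scale, both params in (eps, 1-eps)
  to_unit <- function(t) eps + (1 - 2 * eps) * stats::plogis(t)
  nll <- function(theta) {
    lambda <- to_unit(theta[[1]]); alpha <- to_unit(theta[[2]])
    -sum(log(lambda + (1 - lambda) * alpha * exp((alpha - 1) * lx)))
  }

  grid <- rbind(c(0.25, 0.25), c(0.25, 0.75), c(0.75, 0.25), c(0.9, 0.6))
  starts <- grid[seq_len(min(nrow(grid), n_starts)), , drop = FALSE]
  n_rand <- max(0L, n_starts - nrow(starts))
  if (n_rand > 0L) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    starts <- rbind(starts, matrix(stats::runif(2 * n_rand, 0.05, 0.95),
                                   ncol = 2))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    theta0 <- stats::qlogis((starts[k, ] - eps) / (1 - 2 * eps))
    res <- tryCatch(
      stats::optim(theta0, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop2("beta-uniform mixture optimization failed on all starts")

  lambda <- to_unit(best$par[[1]]); alpha <- to_unit(best$par[[2]])
  structure(
    list(lambda_mix = lambda, alpha = alpha, n_obs = length(x),
         log_likelihood = -best$value,
         pi0_upper = lambda + (1 - lambda) * alpha),
    class = "bum_fit"
  )
}

#' @export
print.bum_fit <- function(x, ...) {
  cat("Beta-uniform mixture fit\n")
  cat(sprintf("  lambda (noise weight): %.4f\n", x$lambda_mix))
  cat(sprintf("  alpha  (beta shape):   %.4f\n", x$alpha))
  cat(sprintf("  n = %d   logLik = %.2f   pi0 upper bound = %.4f\n",
              x$n_obs, x$log_likelihood, x$pi0_upper))
  invisible(x)
}

#' Beta-uniform mixture density
#'
#' Evaluates `lambda + (1 - lambda) * alpha * x^(alpha - 1)` at p-values
#' `x` in `(0, 1]`.
#'
#' @param x Numeric vector in `(0, 1]`.
#' @param fit A `bum_fit`, or a list with `lambda_mix` and `alpha`.
#' @return Density values (positive reals).
#' @export
bum_density <- function(x, fit) {
  if (any(x <= 0 | x > 1)) stop2("x must lie in (0, 1]")
  lambda <- fit$lambda_mix; alpha <- fit$alpha
  lambda + (1 - lambda) * alpha * x^(alpha - 1)
}

#' Draw p-values from a beta-uniform mixture
#'
#' Samples from `f(x) = lambda + (1 - lambda) * alpha * x^(alpha - 1)`:
#' with probability `lambda` a Uniform(0,1) draw, otherwise a Beta(alpha, 1)
#' draw (inverse CDF `u^(1/alpha)`).
#'
#' @param n Number of draws.
#' @param lambda_mix Noise weight in (0, 1).
#' @param alpha Beta shape in (0, 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of p-values in (0, 1].
#' @export
rbum <- function(n, lambda_mix, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  noise <- stats::runif(n) < lambda_mix
  p <- numeric(n)
  p[noise] <- stats::runif(sum(noise))
  p[!noise] <- stats::runif(sum(!noise))^(1 / alpha)
  pmax(p, .Machine$double.xmin)
}

#' Bonferroni significance threshold
#'
#' The score-zero threshold used to discriminate positively from negatively
#' scoring genes: `alpha_level / n_genes`, the Bonferroni-adjusted
#' significance level over the number of genes expressed.
#'
#' @param n_genes Number of genes tested (>= 1).
#' @param alpha_level Family-wise significance level (default 0.05).
#' @return `alpha_level / n_genes`.
#' @export
bonferroni_threshold <- function(n_genes, alpha_level = 0.05) {
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 1)
    stop2("n_genes must be a positive integer")
  alpha_level / n_genes
}

#' Score genes by log signal-to-noise around a threshold
#'
#' Converts p-values to additive node scores
#' \deqn{s(x) = (\alpha - 1)\,(\ln x - \ln \tau),}
#' the log-ratio of the Beta(alpha, 1) signal density at the observed
#' p-value versus at the threshold `tau`. Scores are zero at `x = tau`,
#' positive for `x < tau`, negative above, and strictly decreasing in `x`
#' for `alpha < 1`. Natural logarithms are used; any other base rescales
#' every score by the same constant and cannot change which connected
#' subgraph is heaviest.
#'
#' @param table A `gene_table` (or data.frame with `gene` and `p_value`).
#' @param fit A `bum_fit` (only `alpha` is used).
#' @param tau Score-zero threshold in (0, 1); typically
#'   [bonferroni_threshold()] over the genes in `table`.
#' @return A `node_scores` list: `tau`, `alpha_used`, and `scores`, a named
#'   numeric vector over `table$gene`.
#' @export
score_nodes <- function(table, fit,
                        tau = bonferroni_threshold(nrow(table))) {
  assert_scalar_number(tau, "tau")
  if (tau <= 0 || tau >= 1) stop2("tau must lie in (0, 1)")
  alpha <- fit$alpha
  if (is.null(alpha) || alpha <= 0 || alpha >= 1)
    stop2("fit$alpha must lie in (0, 1)")
  s <- (alpha - 1) * (log(table$p_value) - log(tau))
  structure(
    list(tau = tau, alpha_used = alpha,
         scores = stats::setNames(s, table$gene)),
    class = "node_scores"
  )
}

#' @export
print.node_scores <- function(x, ...) {
  cat(sprintf("Node scores for %d genes (alpha = %.4f, tau = %.3g)\n",
              length(x$scores), x$alpha_used, x$tau))
  cat(sprintf("  positive-scoring genes: %d\n", sum(x$scores > 0)))
  invisible(x)
}
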