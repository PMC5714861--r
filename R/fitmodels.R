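#' Fit a power law Y = m * X^n by nonlinear least squares
#'
#' Levenberg–Marquardt iteration on the untransformed residuals, initialised
#' from the ordinary least-squares fit of log(y) on log(x). Convergence is
#' declared when the relative change in the (weighted) residual sum of
#' squares falls below `1e-10`, with a cap of 200 iterations; non-convergence
#' is reported explicitly in the returned object and as a warning, never
#' silently. Standard errors come from the Jacobian at the optimum and
#' coefficient p-values from the t distribution on `length(x) - 2` degrees of
#' freedom.
#'
#' @param data A data frame holding the predictor and response.
#' @param x,y Columns of `data` (tidy-eval): the marker counts and the bin
#'   statistic (both strictly positive; at least 3 distinct x values).
#' @param weights Optional column of per-point weights for a weighted fit
#'   (default unweighted).
#' @return An object of class `power_law_fit` with [tidy()], [glance()],
#'   [predict()][predict.power_law_fit()] and
#'   [autoplot()][ggplot2::autoplot()] methods.
#' @export
#' @examples
#' d <- tibble::tibble(x = c(200, 500, 1000, 2000), y = 26.6 * x^0.34)
#' fit_power_law(d, x, y)
fit_power_law <- function(data, x, y, weights = NULL) {
  xv <- as.numeric(eval_tidy(enquo(x), data))
  yv <- as.numeric(eval_tidy(enquo(y), data))
  wq <- enquo(weights)
  wv <- if (rlang::quo_is_null(wq)) rep(1, length(xv)) else as.numeric(eval_tidy(wq, data))
  if (length(xv) != length(yv)) abort("`x` and `y` must have equal length.")
  if (any(!is.finite(xv)) || any(!is.finite(yv)) || any(xv <= 0) || any(yv <= 0)) {
    abort("Power-law fitting needs strictly positive, finite x and y.")
  }
  if (length(unique(xv)) < 3L) abort("Need at least 3 distinct x values.")
  if (any(!is.finite(wv)) || any(wv < 0)) abort("Weights must be non-negative.")

  # log-log OLS initialisation
  init <- coef(lm(log(yv) ~ log(xv), weights = wv))
  m0 <- exp(unname(init[1L]))
  n0 <- unname(init[2L])

  rss_of <- function(m, n) sum(wv * (yv - m * xv^n)^2)
  theta <- c(m0, n0)
  rss <- rss_of(theta[1L], theta[2L])
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  max_iter <- 200L
  while (iter < max_iter) {
    iter <- iter + 1L
    m <- theta[1L]; n <- theta[2L]
    f <- m * xv^n
    r <- yv - f
    J <- cbind(xv^n, f * log(xv))
    JtWJ <- crossprod(J * wv, J)
    g <- crossprod(J * wv, r)
    step_ok <- FALSE
    for (tries in 1:25) {
      A <- JtWJ + lambda * diag(diag(JtWJ), 2L)
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        new_rss <- if (cand[1L] > 0) rss_of(cand[1L], cand[2L]) else Inf
        if (is.finite(new_rss) && new_rss <= rss) {
          theta <- cand
          lambda <- max(lambda / 10, 1e-12)
          step_ok <- TRUE
          if (rss - new_rss <= 1e-10 * max(rss, 1e-300) || new_rss < 1e-300) {
            rss <- new_rss
            converged <- TRUE
          }
          rss <- new_rss
          break
        }
      }
      lambda <- lambda * 10
    }
    if (converged || !step_ok) {
      if (!step_ok && rss <= 1e-20 * sum(wv * yv^2)) converged <- TRUE
      break
    }
  }
  if (!converged && !(rss <= 1e-20 * sum(wv * yv^2))) {
    if (iter >= max_iter) {
      warn("fit_power_law did not converge within 200 iterations.")
    } else {
      converged <- TRUE  # stalled with no improving step: at a local optimum
    }
  } else {
    converged <- TRUE
  }

  m <- theta[1L]; n <- theta[2L]
  f <- m * xv^n
  J <- cbind(xv^n, f * log(xv))
  JtWJ <- crossprod(J * wv, J)
  df_res <- length(xv) - 2L
  s2 <- if (df_res > 0) rss / df_res else NA_real_
  vcov <- tryCatch(s2 * solve(JtWJ), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vcov), 0))
  tval <- theta / se
  pval <- 2 * pt(-abs(tval), df_res)
  pval[se == 0] <- NA_real_

  structure(
    list(
      coefficients = c(m = m, n = n),
      std_error = setNames(se, c("m", "n")),
      p_value = setNames(pval, c("m", "n")),
      rss = rss, df_residual = df_res, fitted_values = f,
      data = tibble(x = xv, y = yv, w = wv),
      converged = converged, iterations = iter
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> Y = %.4g * X^%.4g  (RSS %.4g, %s in %d iter)\n",
              x$coefficients["m"], x$coefficients["n"], x$rss,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) object$coefficients

#' @rdname fit_power_law
#' @param object,x A `power_law_fit`.
#' @param newdata Optional data frame (or numeric vector) of new x values.
#' @param ... Unused.
#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) {
    object$data$x
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    newdata$x
  }
  unname(object$coefficients["m"] * xv^object$coefficients["n"])
}

#' @rdname fit_power_law
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(
    term = c("m", "n"),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_error),
    statistic = unname(x$coefficients / x$std_error),
    p.value = unname(x$p_value)
  )
}

#' @rdname fit_power_law
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(
    rss = x$rss,
    sigma = if (x$df_residual > 0) sqrt(x$rss / x$df_residual) else NA_real_,
    df.residual = x$df_residual,
    nobs = nrow(x$data),
    converged = x$converged,
    iterations = x$iterations
  )
}

#' Closed-form resolution theory for recombination-bin maps
#'
#' With `a` average recombination events per line and `X` lines, the pooled
#' bin number is `a * X` and the average bin size `G / (a * X)` Mb for a
#' genome of `G` Mb. Inverting the size formula gives the number of lines
#' needed to reach a target bin size. All functions are vectorised over `a`.
#'
#' @param a Mean recombination events per line (per population type).
#' @param n_lines Number of lines `X`.
#' @param genome_length_mb Genome length in Mb (default 2,300, maize).
#' @return `theoretical_bin_number()`: `a * X` (real-valued);
#'   `theoretical_bin_size()`: Mb per bin; `required_lines()`: lines needed
#'   for a target bin size, rounded to the nearest integer.
#' @export
#' @examples
#' theoretical_bin_number(16, 200)
#' theoretical_bin_size(16, 1)
#' required_lines(c(16, 41, 72, 86), 0.057)
theoretical_bin_number <- function(a, n_lines) {
  if (any(a <= 0)) abort("`a` must be positive.")
  a * n_lines
}

#' @rdname theoretical_bin_number
#' @export
theoretical_bin_size <- function(a, n_lines, genome_length_mb = 2300) {
  if (any(a * n_lines == 0)) abort("`a * n_lines` must be nonzero.")
  genome_length_mb / (a * n_lines)
}

#' @rdname theoretical_bin_number
#' @param target_size_mb Target average bin size in Mb (> 0).
#' @export
required_lines <- function(a, target_size_mb, genome_length_mb = 2300) {
  if (any(target_size_mb <= 0)) abort("`target_size_mb` must be positive.")
  if (any(a <= 0)) abort("`a` must be positive.")
  round(genome_length_mb / (a * target_size_mb))
}

#' Markers needed to reach a target bin size under a fitted power law
#'
#' Inverts a bin-size power law `Y = m * X^n` (with `n < 0`, size shrinking
#' with marker number) at a target size: `X = (m / target)^(-1/n)`, rounded
#' to the nearest integer. Note that evaluating a power law whose printed
#' coefficients were rounded to two decimals can move the implied marker
#' count by tens of percent at small target sizes, so published marker
#' requirements are generally not recoverable from published rounded
#' formulas.
#'
#' @param fit A [fit_power_law()] object, or a numeric vector with named
#'   elements `m` and `n`.
#' @param target_size_mb Target bin size in Mb (> 0).
#' @return Required marker count (nearest integer).
#' @export
#' @examples
#' required_markers(c(m = 250.04, n = -0.51), 250.04)
required_markers <- function(fit, target_size_mb) {
  cf <- if (inherits(fit, "power_law_fit")) coef(fit) else fit
  m <- unname(cf["m"])
  n <- unname(cf["n"])
  if (!is.finite(m) || !is.finite(n)) abort("`fit` must provide coefficients m and n.")
  if (n >= 0) abort("Bin size must decrease with marker number (n < 0).")
  if (any(target_size_mb <= 0)) abort("`target_size_mb` must be positive.")
  round((m / target_size_mb)^(-1 / n))
}

#' Average bin size matching one gene per bin
#'
#' Divides the genome length by the gene count, reported in Kb. With the
#' maize defaults (2,300 Mb, 40,000 genes) the exact value is 57.5 Kb; the
#' reported figure truncates to the integer 57 Kb, which is also the target
#' used when inverting the resolution formulas.
#'
#' @param genome_length_mb Genome length in Mb.
#' @param gene_count Number of annotated genes.
#' @param truncate Truncate to an integer number of Kb (default `TRUE`).
#' @return Bin size in Kb.
#' @export
gene_density_bin_kb <- function(genome_length_mb = 2300, gene_count = 40000,
                                truncate = TRUE) {
  kb <- genome_length_mb * 1000 / gene_count
  if (truncate) trunc(kb) else kb
}

#' Resolution-theory summary table for a set of population types
#'
#' @param a Named numeric vector of mean events per line (names = population
#'   types).
#' @param line_counts Line counts at which to evaluate the theoretical bin
#'   number and size.
#' @param genome_length_mb,gene_count Genome constants.
#' @return A tibble with the theoretical bin number and size at each line
#'   count and the lines required to hit the one-gene-per-bin target.
#' @export
resolution_summary <- function(a, line_counts = c(50, 100, 150, 200),
                               genome_length_mb = 2300, gene_count = 40000) {
  if (is.null(names(a))) names(a) <- sprintf("pop%d", seq_along(a))
  target_mb <- gene_density_bin_kb(genome_length_mb, gene_count) / 1000
  grid <- expand.grid(population = names(a), n_lines = line_counts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$a <- a[grid$population]
  out <- as_tibble(grid)
  out$bin_number <- theoretical_bin_number(out$a, out$n_lines)
  out$bin_size_mb <- theoretical_bin_size(out$a, out$n_lines, genome_length_mb)
  out$lines_for_gene_target <- required_lines(out$a, target_mb, genome_length_mb)
  out
}
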