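#' Species abundance distribution models
#'
#' Constructors for the candidate abundance distributions. All models are
#' continuous densities on the abundance axis, normalized on `[1, Inf)` (or
#' `[1, x_max]` where a finite upper support applies); read counts being
#' integers, samples are drawn from the continuous law by inverse-CDF and
#' rounded to the nearest integer (clamped to >= 1), which preserves both
#' the tail exponent and the head mass.
#'
#' * `power_law(alpha, x_min)`: P(x) ~ x^-(1+alpha), the pure power law whose
#'   complementary cumulative distribution (and rank-abundance curve) decays
#'   as x^-alpha.
#' * `truncated_power_law(beta, lambda)`: P(x) ~ x^-(1+beta) exp(-lambda x);
#'   `lambda = 0` reduces exactly to `power_law(beta)`.
#' * `lognormal_model(meanlog, sdlog)`, `weibull_model(shape, scale)`:
#'   broad-but-light-tailed alternatives, renormalized to `[1, Inf)`.
#' * `double_power_law(delta, alpha, x_c)`: two power-law regimes, head
#'   exponent `delta` on `[1, x_c]` and tail exponent `alpha` above, joined
#'   continuously; branch constants come from [double_pl_constants()].
#' * `shifted_power_law(alpha, x0, x_max)`: P(x) ~ (x + x0)^-(1+alpha), a
#'   power-law tail with a flattened head; with `x0 = 0, x_max = Inf` it is
#'   the pure power law.
#'
#' @param alpha,beta,delta Tail/head exponents (CCD convention: density
#'   exponent is 1 + alpha).
#' @param x_min Lower support of the pure power law (>= 1).
#' @param lambda Exponential truncation rate (>= 0).
#' @param meanlog,sdlog Lognormal parameters on the log scale.
#' @param shape,scale Weibull parameters.
#' @param x_c Transition abundance between the two power-law regimes.
#' @param x0 Abundance shift (>= 0).
#' @param x_max Upper support (may be `Inf`).
#' @return An object of class `sad_model`.
#' @name sad_models
NULL

new_sad_model <- function(family, params) {
  structure(list(family = family, params = params),
            class = c(paste0("sad_", family), "sad_model"))
}

#' @rdname sad_models
#' @export
power_law <- function(alpha, x_min = 1) {
  if (alpha <= 0) stop_domain("power law needs alpha > 0")
  if (x_min < 1) stop_domain("x_min must be >= 1")
  new_sad_model("power_law", list(alpha = alpha, x_min = x_min))
}

#' @rdname sad_models
#' @export
truncated_power_law <- function(beta, lambda) {
  if (lambda < 0) stop_domain("lambda must be >= 0")
  if (lambda == 0 && beta <= 0) stop_domain("lambda = 0 requires beta > 0")
  new_sad_model("truncated_power_law", list(beta = beta, lambda = lambda))
}

#' @rdname sad_models
#' @export
lognormal_model <- function(meanlog, sdlog) {
  if (sdlog <= 0) stop_domain("sdlog must be > 0")
  new_sad_model("lognormal", list(meanlog = meanlog, sdlog = sdlog))
}

#' @rdname sad_models
#' @export
weibull_model <- function(shape, scale) {
  if (shape <= 0 || scale <= 0) stop_domain("shape and scale must be > 0")
  new_sad_model("weibull", list(shape = shape, scale = scale))
}

#' @rdname sad_models
#' @export
double_power_law <- function(delta, alpha, x_c) {
  k <- double_pl_constants(delta, alpha, x_c)
  new_sad_model("double_power_law",
                list(delta = delta, alpha = alpha, x_c = x_c,
                     A = k[["A"]], B = k[["B"]]))
}

#' @rdname sad_models
#' @export
shifted_power_law <- function(alpha, x0, x_max = Inf) {
  A <- shifted_pl_constant(alpha, x0, x_max)
  new_sad_model("shifted_power_law",
                list(alpha = alpha, x0 = x0, x_max = x_max, A = A))
}

#' @export
print.sad_model <- function(x, ...) {
  p <- vapply(x$params, function(v) format(v, digits = 4), character(1))
  cat(sprintf("sad_model <%s>: %s\n", x$family,
              paste(names(p), p, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Branch constants of the double power law
#'
#' Derives the head and tail constants (A, B) of the continuous density
#' P(x) = A x^-(1+delta) on `[1, x_c]`, B x^-(1+alpha) above, from the two
#' defining constraints: continuity at `x_c`
#' (A x_c^-(1-delta) = B x_c^-(1+alpha)) and unit total mass on `[1, Inf)`.
#'
#' @param delta Head exponent (any real; delta -> 0 handled by its limit).
#' @param alpha Tail exponent, > 0 so the tail is integrable.
#' @param x_c Transition abundance, >= 1.
#' @return Named vector `c(A =, B =)`.
#' @export
double_pl_constants <- function(delta, alpha, x_c) {
  if (alpha <= 0) stop_domain("tail exponent alpha must be > 0 for a normalizable density")
  if (x_c < 1) stop_domain("x_c must be >= 1")
  delta <- unname(delta); alpha <- unname(alpha); x_c <- unname(x_c)
  # integral of x^-(1+delta) over [1, x_c]; log limit as delta -> 0
  head_int <- if (abs(delta) < 1e-9) log(x_c) else (1 - x_c^(-delta)) / delta
  A <- 1 / (head_int + x_c^(-delta) / alpha)
  c(A = A, B = A * x_c^(alpha - delta))
}

#' Normalization constant of the shifted power law
#'
#' A = alpha * ((1 + x0)^-alpha - (x_max + x0)^-alpha)^-1, so that
#' P(x) = A (x + x0)^-(1+alpha) integrates to 1 on `[1, x_max]`.
#'
#' @inheritParams sad_models
#' @return The constant A.
#' @export
shifted_pl_constant <- function(alpha, x0, x_max = Inf) {
  if (alpha <= 0) stop_domain("alpha must be > 0")
  if (x0 < 0) stop_domain("x0 must be >= 0")
  if (x_max <= 1) stop_domain("x_max must exceed the lower support 1")
  alpha <- unname(alpha); x0 <- unname(x0); x_max <- unname(x_max)
  upper <- if (is.finite(x_max)) (x_max + x0)^(-alpha) else 0
  alpha / ((1 + x0)^(-alpha) - upper)
}

# ---- density -----------------------------------------------------------

#' Model density, CDF, quantile, mean and samplers
#'
#' S3 generics over `sad_model` objects. Densities are continuous and
#' normalized on the model support; `sad_cdf` and `sad_quantile` are exact
#' closed forms except for the truncated power law, whose quantile is
#' inverted numerically (monotone grid + Newton polishing).
#'
#' @param model An `sad_model`.
#' @param x,q Abundance values (>= 1).
#' @param p Probabilities in (0, 1).
#' @param log Return log-density?
#' @return Numeric vector (density/CDF/quantile/mean).
#' @name sad_ops
NULL

#' @rdname sad_ops
#' @export
sad_density <- function(model, x, log = FALSE) UseMethod("sad_density")

#' @export
sad_density.sad_power_law <- function(model, x, log = FALSE) {
  a <- model$params$alpha; xm <- model$params$x_min
  ld <- ifelse(x >= xm, log(a) + a * base::log(xm) - (1 + a) * base::log(x), -Inf)
  if (log) ld else exp(ld)
}

#' @export
sad_density.sad_truncated_power_law <- function(model, x, log = FALSE) {
  b <- model$params$beta; lam <- model$params$lambda
  lZ <- tpl_log_norm(b, lam)
  ld <- ifelse(x >= 1, -(1 + b) * base::log(x) - lam * x - lZ, -Inf)
  if (log) ld else exp(ld)
}

#' @export
sad_density.sad_lognormal <- function(model, x, log = FALSE) {
  mu <- model$params$meanlog; s <- model$params$sdlog
  ltail <- plnorm(1, mu, s, lower.tail = FALSE, log.p = TRUE)
  ld <- ifelse(x >= 1, dlnorm(x, mu, s, log = TRUE) - ltail, -Inf)
  if (log) ld else exp(ld)
}

#' @export
sad_density.sad_weibull <- function(model, x, log = FALSE) {
  k <- model$params$shape; sc <- model$params$scale
  ltail <- pweibull(1, k, sc, lower.tail = FALSE, log.p = TRUE)
  ld <- ifelse(x >= 1, dweibull(x, k, sc, log = TRUE) - ltail, -Inf)
  if (log) ld else exp(ld)
}

#' @export
sad_density.sad_double_power_law <- function(model, x, log = FALSE) {
  p <- model$params
  ld <- ifelse(x < 1, -Inf,
        ifelse(x <= p$x_c,
               base::log(p$A) - (1 + p$delta) * base::log(x),
               base::log(p$B) - (1 + p$alpha) * base::log(x)))
  if (log) ld else exp(ld)
}

#' @export
sad_density.sad_shifted_power_law <- function(model, x, log = FALSE) {
  p <- model$params
  ld <- ifelse(x >= 1 & x <= p$x_max,
               base::log(p$A) - (1 + p$alpha) * base::log(x + p$x0), -Inf)
  if (log) ld else exp(ld)
}

# log of the normalization integral of x^-(1+beta) exp(-lambda x) on [1, Inf):
# lambda^beta * GammaUpper(-beta, lambda), with the negative-parameter
# incomplete gamma obtained from the a -> a+1 recurrence.
tpl_log_norm <- function(beta, lambda) {
  if (lambda == 0) {
    if (beta <= 0) stop_domain("beta must be > 0 when lambda = 0")
    return(-base::log(beta))
  }
  base::log(upper_inc_gamma(-beta, lambda)) + beta * base::log(lambda)
}

# Upper incomplete gamma Gamma(a, x) for a > -1 (a != 0 handled exactly;
# a = 0 is the exponential integral E1).
upper_inc_gamma <- function(a, x) {
  if (a > 0) {
    gamma(a) * stats::pgamma(x, a, lower.tail = FALSE)
  } else if (a == 0) {
    pracma::expint(x)
  } else {
    (upper_inc_gamma(a + 1, x) - x^a * exp(-x)) / a
  }
}

# ---- CDF ---------------------------------------------------------------

#' @rdname sad_ops
#' @export
sad_cdf <- function(model, q) UseMethod("sad_cdf")

#' @export
sad_cdf.sad_power_law <- function(model, q) {
  a <- model$params$alpha; xm <- model$params$x_min
  ifelse(q < xm, 0, 1 - (q / xm)^(-a))
}

#' @export
sad_cdf.sad_truncated_power_law <- function(model, q) {
  b <- model$params$beta; lam <- model$params$lambda
  if (lam == 0) return(sad_cdf(power_law(b), q))
  Z <- upper_inc_gamma(-b, lam)
  vapply(q, function(v) {
    if (v < 1) return(0)
    1 - upper_inc_gamma(-b, lam * v) / Z
  }, numeric(1))
}

#' @export
sad_cdf.sad_lognormal <- function(model, q) {
  mu <- model$params$meanlog; s <- model$params$sdlog
  p1 <- plnorm(1, mu, s)
  ifelse(q < 1, 0, (plnorm(q, mu, s) - p1) / (1 - p1))
}

#' @export
sad_cdf.sad_weibull <- function(model, q) {
  k <- model$params$shape; sc <- model$params$scale
  p1 <- pweibull(1, k, sc)
  ifelse(q < 1, 0, (pweibull(q, k, sc) - p1) / (1 - p1))
}

#' @export
sad_cdf.sad_double_power_law <- function(model, q) {
  p <- model$params
  head_int <- function(v) {
    if (abs(p$delta) < 1e-9) base::log(v) else (1 - v^(-p$delta)) / p$delta
  }
  p_head <- p$A * head_int(p$x_c)
  vapply(q, function(v) {
    if (v < 1) return(0)
    if (v <= p$x_c) p$A * head_int(v)
    else p_head + p$B * (p$x_c^(-p$alpha) - v^(-p$alpha)) / p$alpha
  }, numeric(1))
}

#' @export
sad_cdf.sad_shifted_power_law <- function(model, q) {
  p <- model$params
  ifelse(q < 1, 0,
         pmin(1, p$A / p$alpha * ((1 + p$x0)^(-p$alpha) - (pmin(q, p$x_max) + p$x0)^(-p$alpha))))
}

# ---- quantile ----------------------------------------------------------

#' @rdname sad_ops
#' @export
sad_quantile <- function(model, p) UseMethod("sad_quantile")

#' @export
sad_quantile.sad_power_law <- function(model, p) {
  a <- model$params$alpha; xm <- model$params$x_min
  xm * (1 - p)^(-1 / a)
}

#' @export
sad_quantile.sad_lognormal <- function(model, p) {
  mu <- model$params$meanlog; s <- model$params$sdlog
  p1 <- plnorm(1, mu, s)
  qlnorm(p1 + p * (1 - p1), mu, s)
}

#' @export
sad_quantile.sad_weibull <- function(model, p) {
  k <- model$params$shape; sc <- model$params$scale
  p1 <- pweibull(1, k, sc)
  qweibull(p1 + p * (1 - p1), k, sc)
}

#' @export
sad_quantile.sad_double_power_law <- function(model, p) {
  pr <- model$params
  head_int <- function(v) {
    if (abs(pr$delta) < 1e-9) base::log(v) else (1 - v^(-pr$delta)) / pr$delta
  }
  p_head <- pr$A * head_int(pr$x_c)
  out <- numeric(length(p))
  h <- p <= p_head
  if (abs(pr$delta) < 1e-9) {
    out[h] <- exp(p[h] / pr$A)
  } else {
    out[h] <- (1 - pr$delta * p[h] / pr$A)^(-1 / pr$delta)
  }
  out[!h] <- (pr$x_c^(-pr$alpha) - pr$alpha * (p[!h] - p_head) / pr$B)^(-1 / pr$alpha)
  out
}

#' @export
sad_quantile.sad_shifted_power_law <- function(model, p) {
  pr <- model$params
  lo <- (1 + pr$x0)^(-pr$alpha)
  hi <- if (is.finite(pr$x_max)) (pr$x_max + pr$x0)^(-pr$alpha) else 0
  (lo - p * (lo - hi))^(-1 / pr$alpha) - pr$x0
}

#' @export
sad_quantile.sad_truncated_power_law <- function(model, p) {
  b <- model$params$beta; lam <- model$params$lambda
  if (lam == 0) return(sad_quantile(power_law(b), p))
  # monotone inversion: log-spaced grid up to the 1 - 1e-12 quantile,
  # interpolate in log x, then polish with two Newton steps.
  hi <- 10
  while (sad_cdf(model, hi) < 1 - 1e-12 && hi < 1e15) hi <- hi * 10
  grid <- exp(seq(0, base::log(hi), length.out = 4096))
  cdf <- sad_cdf(model, grid)
  keep <- !duplicated(cdf)
  x <- exp(approx(cdf[keep], base::log(grid[keep]), xout = p, rule = 2)$y)
  for (i in 1:2) {
    f <- sad_cdf(model, x) - p
    x <- pmax(1, x - f / sad_density(model, x))
  }
  x
}

# ---- mean --------------------------------------------------------------

#' @rdname sad_ops
#' @export
mean_abundance <- function(model) UseMethod("mean_abundance")

#' @export
mean_abundance.sad_power_law <- function(model) {
  a <- model$params$alpha; xm <- model$params$x_min
  if (a <= 1) {
    stop_sads("mean diverges for alpha <= 1 on unbounded support",
              "sads_diverging_mean_error")
  }
  a * xm / (a - 1)
}

#' @export
mean_abundance.sad_truncated_power_law <- function(model) {
  b <- model$params$beta; lam <- model$params$lambda
  if (lam == 0) return(mean_abundance(power_law(b)))
  # E[x] = Z(beta-1, lambda) / Z(beta, lambda)
  exp(tpl_log_norm(b - 1, lam) - tpl_log_norm(b, lam))
}

#' @export
mean_abundance.sad_lognormal <- function(model) {
  integrate_mean(model)
}

#' @export
mean_abundance.sad_weibull <- function(model) {
  integrate_mean(model)
}

integrate_mean <- function(model) {
  stats::integrate(function(x) x * sad_density(model, x), 1, Inf,
                   rel.tol = 1e-10)$value
}

#' @export
mean_abundance.sad_double_power_law <- function(model) {
  p <- model$params
  if (p$alpha <= 1) {
    stop_sads("mean diverges: tail alpha <= 1 on unbounded support",
              "sads_diverging_mean_error")
  }
  head_term <- if (abs(1 - p$delta) < 1e-9) {
    base::log(p$x_c)
  } else {
    (p$x_c^(1 - p$delta) - 1) / (1 - p$delta)
  }
  p$A * head_term + p$B * p$x_c^(1 - p$alpha) / (p$alpha - 1)
}

#' @export
mean_abundance.sad_shifted_power_law <- function(model) {
  p <- model$params
  a <- p$alpha; x0 <- p$x0; xm <- p$x_max
  if (is.infinite(xm)) {
    if (a <= 1) {
      stop_sads("mean diverges for alpha <= 1 with x_max = Inf",
                "sads_diverging_mean_error")
    }
    return(a * (1 + x0) / (a - 1) - x0)
  }
  if (abs(1 - a) < 1e-9) {  # logarithmic limit at alpha = 1
    return(p$A * base::log((xm + x0) / (1 + x0)) - x0)
  }
  a / (1 - a) * ((xm + x0)^(1 - a) - (1 + x0)^(1 - a)) /
    ((1 + x0)^(-a) - (xm + x0)^(-a)) - x0
}

# ---- sampling ----------------------------------------------------------

#' @rdname sad_ops
#' @param n Number of abundances to draw.
#' @param seed Explicit RNG seed; the same seed reproduces the same draws.
#' @param discretize Round draws to integer read counts (default). Set to
#'   `FALSE` for draws from the continuous law itself, e.g. to study the
#'   estimators free of discretization effects.
#' @export
sad_sample <- function(model, n, seed = NULL, discretize = TRUE) {
  if (n < 1) stop_domain("n must be >= 1")
  with_seed(seed, {
    x <- sad_quantile(model, runif(n))
    if (discretize) discretize_abundance(x, model) else x
  })
}

# Round continuous draws to integer reads: nearest integer, clamped to the
# model support. Rounding (rather than flooring) keeps the discretized head
# mass centred on the continuous law, so refitting recovers the generating
# parameters.
discretize_abundance <- function(x, model) {
  out <- pmax(1, floor(x + 0.5))
  xm <- model$params$x_max
  if (!is.null(xm) && is.finite(xm)) out <- pmin(out, floor(xm))
  out
}

#' Draw abundances until a target read total is reached
#'
#' Draws OTU abundances from `model` until the cumulative read count reaches
#' `n_reads`, keeping the final overshooting draw. This is the in-silico
#' community generator: the number of draws is the generated richness.
#'
#' @inheritParams sad_ops
#' @param n_reads Target total reads (>= 1).
#' @param seed Explicit RNG seed.
#' @return An [abundance_vector] of the generated community.
#' @export
sample_to_reads <- function(model, n_reads, seed = NULL) {
  if (n_reads < 1) stop_domain("n_reads must be >= 1")
  with_seed(seed, {
    xs <- vector("list", 0L)
    tot <- 0
    # chunk size adapted to the model mean so most runs need few rounds
    chunk <- 4096L
    repeat {
      x <- discretize_abundance(sad_quantile(model, runif(chunk)), model)
      cs <- tot + cumsum(x)
      if (cs[length(cs)] >= n_reads) {
        k <- which(cs >= n_reads)[1L]
        xs[[length(xs) + 1L]] <- x[seq_len(k)]
        break
      }
      xs[[length(xs) + 1L]] <- x
      tot <- cs[length(cs)]
    }
    abundance_vector(unlist(xs))
  })
}

# ---- (de)serialization -------------------------------------------------

#' Serialize a model to a JSON parameter record
#'
#' @param model An `sad_model`.
#' @return A JSON string with the family name and parameters.
#' @export
sad_model_json <- function(model) {
  params <- lapply(model$params, function(v) if (is.infinite(v)) NULL else v)
  params <- params[!vapply(params, is.null, logical(1))]
  jsonlite::toJSON(list(family = model$family, params = params),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname sad_model_json
#' @param json JSON produced by `sad_model_json()`.
#' @export
parse_sad_model <- function(json) {
  rec <- jsonlite::fromJSON(json)
  p <- lapply(rec$params, function(v) if (is.null(v)) Inf else v)
  switch(rec$family,
    power_law = power_law(p$alpha, p$x_min),
    truncated_power_law = truncated_power_law(p$beta, p$lambda),
    lognormal = lognormal_model(p$meanlog, p$sdlog),
    weibull = weibull_model(p$shape, p$scale),
    double_power_law = double_power_law(p$delta, p$alpha, p$x_c),
    shifted_power_law = shifted_power_law(p$alpha, p$x0,
                                          if (is.null(rec$params$x_max)) Inf else p$x_max),
    stop_domain(paste0("unknown model family: ", rec$family))
  )
}
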