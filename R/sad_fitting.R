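#' Maximum-likelihood fits of abundance distributions
#'
#' All fits maximize the continuous likelihood on the abundance support, the
#' convention in which each candidate family is normalized. A fit is a
#' `sad_fit` object carrying the fitted model, the maximized log-likelihood,
#' the number of abundances fitted `n`, the free-parameter count `V`, the
#' AIC (-2 logL + 2V), per-parameter standard errors where available, a
#' convergence flag and the iteration count.
#'
#' @name sad_fitting
NULL

new_sad_fit <- function(model, logL, n, V, stderr = NULL, converged = TRUE,
                        iterations = NA_integer_, data = NULL, extra = list()) {
  structure(c(list(
    model = model, logL = logL, n = n, V = V,
    AIC = -2 * logL + 2 * V,
    stderr = stderr, converged = converged, iterations = iterations,
    data = data
  ), extra), class = "sad_fit")
}

#' @export
print.sad_fit <- function(x, ...) {
  cat(sprintf("sad_fit <%s>: logL = %.2f, AIC = %.2f, n = %d, V = %d, %s\n",
              x$model$family, x$logL, x$AIC, x$n, x$V,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  print(x$model)
  invisible(x)
}

as_abundances <- function(x) {
  if (inherits(x, "abundance_vector")) x$x else as.numeric(x)
}

#' Fit a pure power law by closed-form MLE
#'
#' The continuous MLE of the tail exponent above `x_min` is
#' `alpha = n / sum(log(x / x_min))`, with standard error `alpha / sqrt(n)`.
#'
#' @param x Abundances (an [abundance_vector] or a numeric vector).
#' @param x_min Lower support of the fit; only abundances >= x_min enter.
#' @return A `sad_fit`.
#' @export
fit_power_law <- function(x, x_min = 1) {
  xs <- as_abundances(x)
  xs <- xs[xs >= x_min]
  n <- length(xs)
  if (n < 10) stop_domain("need at least 10 abundances >= x_min")
  slog <- sum(log(xs / x_min))
  if (slog == 0) {
    # every abundance equals x_min: the MLE diverges
    return(new_sad_fit(power_law(1e6, x_min), -Inf, n, 1L,
                       converged = FALSE, data = xs))
  }
  alpha <- n / slog
  model <- power_law(alpha, x_min)
  logL <- sum(sad_density(model, xs, log = TRUE))
  new_sad_fit(model, logL, n, 1L,
              stderr = c(alpha = alpha / sqrt(n)),
              iterations = 0L, data = xs)
}

#' Fit the candidate families and compare them by AIC
#'
#' Fits the pure power law (closed form) and the truncated power law,
#' lognormal and Weibull (bounded quasi-Newton on transformed parameters,
#' three starts each) to the same abundances, then assembles the Akaike
#' comparison.
#'
#' @param x Abundances.
#' @param families Subset of
#'   `c("power_law", "truncated_power_law", "lognormal", "weibull")`.
#' @return A `model_comparison` (see [akaike()]).
#' @export
fit_candidate_models <- function(x, families = c("power_law",
                                                 "truncated_power_law",
                                                 "lognormal", "weibull")) {
  xs <- as_abundances(x)
  fits <- lapply(families, function(f) {
    switch(f,
      power_law = fit_power_law(xs),
      truncated_power_law = fit_truncated_power_law(xs),
      lognormal = fit_lognormal(xs),
      weibull = fit_weibull(xs),
      stop_domain(paste0("unknown family: ", f))
    )
  })
  names(fits) <- families
  akaike(fits)
}

# Generic bounded multi-start optimizer over transformed parameters.
optim_fit <- function(xs, nll, starts, untransform, build, V) {
  best <- NULL
  iters <- 0L
  for (s in starts) {
    o <- tryCatch(
      optim(s, nll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    iters <- iters + o$counts[1]
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    return(new_sad_fit(build(untransform(starts[[1]])), -Inf, length(xs), V,
                       converged = FALSE, data = xs))
  }
  pars <- untransform(best$par)
  model <- build(pars)
  # observed-information standard errors on the natural scale
  stderr <- tryCatch({
    H <- pracma::hessian(function(p) nll_natural(p, xs, build), pars)
    se <- sqrt(diag(solve(H)))
    setNames(se, names(pars))
  }, error = function(e) NULL)
  new_sad_fit(model, -best$value, length(xs), V, stderr = stderr,
              converged = best$convergence == 0, iterations = as.integer(iters),
              data = xs)
}

nll_natural <- function(pars, xs, build) {
  m <- tryCatch(build(pars), error = function(e) NULL)
  if (is.null(m)) return(1e10)
  ll <- sum(sad_density(m, xs, log = TRUE))
  if (!is.finite(ll)) 1e10 else -ll
}

#' @rdname sad_fitting
#' @inheritParams fit_power_law
#' @export
fit_truncated_power_law <- function(x) {
  xs <- as_abundances(x)
  if (length(xs) < 10) stop_domain("need at least 10 abundances")
  build <- function(p) truncated_power_law(p[["beta"]], p[["lambda"]])
  nll <- function(par) {
    p <- c(beta = par[1], lambda = exp(par[2]))
    nll_natural(p, xs, build)
  }
  alpha0 <- fit_power_law(xs)$model$params$alpha
  starts <- list(c(alpha0, log(1 / max(xs))),
                 c(alpha0 / 2, log(10 / max(xs))),
                 c(1, log(1e-3)))
  fit <- optim_fit(xs, nll, starts,
                   untransform = function(par) c(beta = par[1], lambda = exp(par[2])),
                   build = build, V = 2L)
  # lambda = 0 boundary: if the pure power law does at least as well, take it
  pl_ll <- -nll_natural(c(beta = alpha0, lambda = 0), xs, build)
  if (is.finite(pl_ll) && pl_ll >= fit$logL) {
    model <- truncated_power_law(alpha0, 0)
    fit <- new_sad_fit(model, pl_ll, length(xs), 2L,
                       stderr = c(beta = alpha0 / sqrt(length(xs)), lambda = NA),
                       iterations = fit$iterations, data = xs)
  }
  fit
}

#' @rdname sad_fitting
#' @export
fit_lognormal <- function(x) {
  xs <- as_abundances(x)
  if (length(xs) < 10) stop_domain("need at least 10 abundances")
  build <- function(p) lognormal_model(p[["meanlog"]], p[["sdlog"]])
  nll <- function(par) {
    nll_natural(c(meanlog = par[1], sdlog = exp(par[2])), xs, build)
  }
  m0 <- mean(log(xs)); s0 <- max(sd(log(xs)), 0.1)
  starts <- list(c(m0, log(s0)), c(m0 - 2, log(2 * s0)), c(0, log(1)))
  optim_fit(xs, nll, starts,
            untransform = function(par) c(meanlog = par[1], sdlog = exp(par[2])),
            build = build, V = 2L)
}

#' @rdname sad_fitting
#' @export
fit_weibull <- function(x) {
  xs <- as_abundances(x)
  if (length(xs) < 10) stop_domain("need at least 10 abundances")
  build <- function(p) weibull_model(p[["shape"]], p[["scale"]])
  nll <- function(par) {
    nll_natural(c(shape = exp(par[1]), scale = exp(par[2])), xs, build)
  }
  starts <- list(c(log(0.5), log(mean(xs))),
                 c(log(1), log(stats::median(xs))),
                 c(log(0.2), log(1)))
  optim_fit(xs, nll, starts,
            untransform = function(par) c(shape = exp(par[1]), scale = exp(par[2])),
            build = build, V = 2L)
}

# ---- double power law --------------------------------------------------

# Tail scan: for every candidate cutoff (unique abundance with >= min_tail
# points at or above it), fit the tail exponent by closed-form MLE and score
# the fit by the Kolmogorov-Smirnov distance between fitted and empirical
# tail CDF; keep the KS-minimizing cutoff (smallest on ties).
tail_cutoff_scan <- function(xs, min_tail = 10) {
  cand <- sort(unique(xs))
  n_tail <- vapply(cand, function(v) sum(xs >= v), numeric(1))
  cand <- cand[n_tail >= min_tail]
  if (length(cand) == 0) {
    stop_sads("fewer than 10 points above every candidate cutoff",
              "sads_insufficient_tail_error")
  }
  best <- NULL
  for (xm in cand) {
    t <- xs[xs >= xm]
    nt <- length(t)
    slog <- sum(log(t / xm))
    if (slog == 0) next
    a <- nt / slog
    tt <- sort(t)
    emp_hi <- seq_len(nt) / nt
    fitted <- 1 - (tt / xm)^(-a)
    ks <- max(pmax(abs(fitted - emp_hi), abs(fitted - c(0, emp_hi[-nt]))))
    if (is.null(best) || ks < best$ks) {
      best <- list(x_c = xm, alpha = a, ks = ks, n_tail = nt)
    }
  }
  if (is.null(best)) stop_domain("tail scan failed: all candidate tails degenerate")
  best
}

#' Fit the power-law tail with an automatic lower cutoff
#'
#' Clauset-style tail fit: scans candidate lower cutoffs over the unique
#' abundance values, fits the tail exponent above each by closed-form MLE,
#' and keeps the cutoff minimizing the Kolmogorov-Smirnov distance between
#' fitted and empirical tail CDF.
#'
#' @inheritParams fit_power_law
#' @param min_tail Minimum number of points a candidate tail must hold.
#' @return A `sad_fit` whose model is a [power_law()] with the selected
#'   `x_min`; carries `ks` and `n_tail`.
#' @export
fit_power_law_tail <- function(x, min_tail = 10) {
  xs <- as_abundances(x)
  best <- tail_cutoff_scan(xs, min_tail)
  t <- xs[xs >= best$x_c]
  model <- power_law(best$alpha, best$x_c)
  logL <- sum(sad_density(model, t, log = TRUE))
  new_sad_fit(model, logL, length(t), 2L,
              stderr = c(alpha = best$alpha / sqrt(best$n_tail), x_min = NA),
              iterations = 1L, data = xs,
              extra = list(ks = best$ks, n_tail = best$n_tail))
}

# Head MLE: power law truncated to [1, x_c].
head_mle <- function(xs, x_c) {
  xh <- xs[xs <= x_c]
  if (length(xh) < 10) stop_domain("fewer than 10 abundances below the cutoff")
  nh <- length(xh)
  slog <- sum(log(xh))
  profile <- function(d) {
    norm <- if (abs(d) < 1e-9) log(x_c) else (1 - x_c^(-d)) / d
    -nh * log(norm) - (1 + d) * slog - nh * 0  # logL up to the A x^-1-d normalization
  }
  o <- optimize(profile, c(1e-6, 20), maximum = TRUE, tol = 1e-10)
  # observed information for a 1-D stderr
  h <- 1e-4 * max(o$maximum, 1)
  d2 <- (profile(o$maximum + h) - 2 * profile(o$maximum) + profile(o$maximum - h)) / h^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  list(delta = o$maximum, stderr = se, n_head = nh)
}

#' Fit the double power law by the two-stage procedure
#'
#' Stage 1 fits the tail exponent `alpha` and the cutoff `x_c` by scanning
#' candidate cutoffs (the unique abundance values with at least `min_tail`
#' tail points) and minimizing the Kolmogorov-Smirnov distance between the
#' fitted and empirical tail CDF. Stage 2 fits the head exponent `delta` by
#' MLE restricted to `[1, x_c]`. Branch constants then follow from
#' [double_pl_constants()]; V = 3.
#'
#' @inheritParams fit_power_law
#' @param min_tail Minimum number of points a candidate tail must hold.
#' @param x_c Optional fixed cutoff, skipping the stage-1 scan. `x_c <= 1`
#'   degenerates to the pure power law: the fit then equals
#'   [fit_power_law()] with both exponents set to the tail MLE.
#' @return A `sad_fit` whose model is a [double_power_law()]; the fit also
#'   carries `ks` (the minimized tail KS distance) and a `degenerate` flag
#'   set when the abundances span fewer than two decades.
#' @export
fit_double_power_law <- function(x, min_tail = 10, x_c = NULL) {
  xs <- as_abundances(x)
  if (length(xs) < 50) stop_domain("need at least 50 abundances")
  degenerate <- (log10(max(xs)) - log10(min(xs))) < 2
  if (!is.null(x_c) && x_c <= 1) {
    pl <- fit_power_law(xs)
    a <- pl$model$params$alpha
    model <- double_power_law(a, a, 1)
    return(new_sad_fit(model, pl$logL, length(xs), 3L,
                       stderr = c(delta = unname(pl$stderr["alpha"]),
                                  alpha = unname(pl$stderr["alpha"]), x_c = NA),
                       iterations = 1L, data = xs,
                       extra = list(ks = NA_real_, n_tail = length(xs),
                                    n_head = 0L, degenerate = degenerate)))
  }
  tail_fit <- if (is.null(x_c)) {
    tail_cutoff_scan(xs, min_tail)
  } else {
    t <- xs[xs >= x_c]
    if (length(t) < min_tail) {
      stop_sads("fewer than 10 points above the fixed cutoff",
                "sads_insufficient_tail_error")
    }
    list(x_c = x_c, alpha = length(t) / sum(log(t / x_c)), ks = NA_real_,
         n_tail = length(t))
  }
  head_fit <- head_mle(xs, tail_fit$x_c)
  model <- double_power_law(head_fit$delta, tail_fit$alpha, tail_fit$x_c)
  logL <- sum(sad_density(model, xs, log = TRUE))
  new_sad_fit(model, logL, length(xs), 3L,
              stderr = c(delta = head_fit$stderr,
                         alpha = tail_fit$alpha / sqrt(tail_fit$n_tail),
                         x_c = NA),
              iterations = 1L, data = xs,
              extra = list(ks = tail_fit$ks, n_tail = tail_fit$n_tail,
                           n_head = head_fit$n_head, degenerate = degenerate))
}

# ---- shifted power law -------------------------------------------------

#' Fit the shifted power law by alternating fixed-point iteration
#'
#' Iterates the two maximum-likelihood score equations of the density
#' P(x) = A (x + x0)^-(1+alpha) on `[1, Inf)`:
#' `alpha <- S / sum(log((x_i + x0) / (1 + x0)))` and
#' `1 + x0 <- alpha S / ((1 + alpha) sum(1 / (x_i + x0)))`,
#' stopping when both parameter updates move less than `tol`. The x0
#' update carries the "1 +" on the left-hand side: that form is the actual
#' stationarity condition of the likelihood (the package's tests verify the
#' fixed point coincides with direct likelihood maximization).
#'
#' @inheritParams fit_power_law
#' @param tol Convergence tolerance T on both parameter updates.
#' @param max_iter Iteration cap; exceeding it returns a non-converged fit
#'   with the iteration trace attached.
#' @param alpha_init,x0_init Initial guesses.
#' @return A `sad_fit` whose model is a [shifted_power_law()] (x_max = Inf;
#'   a finite x_max is estimated separately, see [estimate_x_max()]).
#' @export
fit_shifted_power_law <- function(x, tol = 1e-6, max_iter = 10000,
                                  alpha_init = 1, x0_init = 1) {
  xs <- as_abundances(x)
  S <- length(xs)
  if (S < 10) stop_domain("need at least 10 abundances")
  a <- alpha_init; x0 <- x0_init
  trace <- matrix(NA_real_, nrow = 0, ncol = 2,
                  dimnames = list(NULL, c("alpha", "x0")))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    a_new <- S / sum(log((xs + x0) / (1 + x0)))
    x0_new <- a_new * S / ((1 + a_new) * sum(1 / (xs + x0))) - 1
    x0_new <- max(x0_new, 0)
    if (it <= 50 || it %% 100 == 0) trace <- rbind(trace, c(a_new, x0_new))
    if (abs(x0_new - x0) < tol && abs(a_new - a) < tol) {
      a <- a_new; x0 <- x0_new
      converged <- TRUE
      break
    }
    a <- a_new; x0 <- x0_new
  }
  model <- shifted_power_law(a, x0)
  logL <- sum(sad_density(model, xs, log = TRUE))
  stderr <- tryCatch({
    nll <- function(p) {
      m <- shifted_power_law(p[1], max(p[2], 0))
      -sum(sad_density(m, xs, log = TRUE))
    }
    H <- pracma::hessian(nll, c(a, x0))
    setNames(sqrt(diag(solve(H))), c("alpha", "x0"))
  }, error = function(e) NULL)
  new_sad_fit(model, logL, S, 2L, stderr = stderr, converged = converged,
              iterations = it, data = xs, extra = list(trace = trace, tol = tol))
}

#' Recover the maximum abundance from the observed mean
#'
#' Solves the implicit mean-abundance equation of the shifted power law for
#' the upper support `x_max`, so that the model's mean matches the mean
#' abundance observed in the data. The mean is monotone increasing in
#' `x_max`, so a bracketed 1-D root search on log(x_max) suffices.
#'
#' @param alpha,x0 Parameters from a converged shifted power-law fit.
#' @param observed_mean Mean reads per OTU in the data (> 1).
#' @return The root `x_max`; if even `x_max = 1e18` cannot reach the
#'   observed mean the result is `Inf` with attribute `unbounded = TRUE`.
#' @export
estimate_x_max <- function(alpha, x0, observed_mean) {
  if (observed_mean <= 1) stop_domain("observed_mean must exceed 1 (the support minimum)")
  f <- function(lx) {
    mean_abundance(shifted_power_law(alpha, x0, exp(lx))) - observed_mean
  }
  lo <- log(max(observed_mean, 1 + 1e-6))
  hi <- log(1e18)
  if (f(hi) < 0) {
    out <- Inf
    attr(out, "unbounded") <- TRUE
    return(out)
  }
  if (f(lo) > 0) lo <- log(1 + 1e-9)
  exp(uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

# ---- AIC comparison ----------------------------------------------------

#' Akaike comparison of fitted models
#'
#' AIC = -2 logL + 2V; delta AIC is relative to the best (smallest) AIC
#' among converged fits; Akaike weights w_i = exp(-delta_i / 2) normalized
#' to sum to 1 can be read as the probability that model i is the best of
#' the candidate set.
#'
#' @param fits A (optionally named) list of `sad_fit` objects on the same
#'   data vector.
#' @return A `model_comparison`: data.frame with one row per fit (family,
#'   logL, V, AIC, delta_aic, weight, converged) plus the fits as an
#'   attribute. Non-converged fits keep their row but are excluded from the
#'   delta-AIC baseline and get weight 0, with a warning.
#' @export
akaike <- function(fits) {
  if (inherits(fits, "sad_fit")) fits <- list(fits)
  if (length(fits) < 1) stop_domain("need at least one fit")
  stopifnot(all(vapply(fits, inherits, logical(1), "sad_fit")))
  datas <- lapply(fits, `[[`, "data")
  if (length(fits) > 1) {
    same <- vapply(datas[-1], identical, logical(1), datas[[1]])
    if (!all(same)) {
      stop_sads("fits were made on differing data vectors; AIC is not comparable",
                "sads_comparison_error")
    }
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop_domain("no converged fit to compare")
  if (!all(conv)) {
    warning("excluding non-converged fit(s) from the delta-AIC baseline: ",
            paste(vapply(fits[!conv], function(f) f$model$family, character(1)),
                  collapse = ", "))
  }
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  delta <- aic - min(aic[conv])
  w <- ifelse(conv, exp(-delta / 2), 0)
  w <- w / sum(w)
  out <- data.frame(
    family = vapply(fits, function(f) f$model$family, character(1)),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    V = vapply(fits, `[[`, numeric(1), "V"),
    AIC = aic,
    delta_aic = delta,
    weight = w,
    converged = conv,
    stringsAsFactors = FALSE
  )
  rownames(out) <- names(fits)
  attr(out, "fits") <- fits
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model_comparison (best family: ",
      x$family[which.min(x$delta_aic)], ")\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
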