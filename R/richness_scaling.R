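#' Zeta-function theory of richness scaling
#'
#' For a community whose number of OTUs at abundance x is n_x = A x^-(1+alpha)
#' with abundances in `[1, N_max]`, the richness is S = A zeta(1+alpha) in the
#' large-N_max limit, and the reads-per-species ratio and the scaling of S
#' with sequencing effort N follow from the zeta sums: S grows linearly with
#' N for alpha > 1 (gamma = 1) and as N^alpha for alpha < 1 (gamma = alpha).
#'
#' @name richness_theory
NULL

#' Expected reads per species for alpha > 1
#'
#' N/S = zeta(alpha) / zeta(1+alpha): the mean abundance of the discrete
#' power-law community, finite only when alpha > 1.
#'
#' @param alpha Tail exponent, > 1.
#' @return The reads-per-species ratio.
#' @export
reads_per_species <- function(alpha) {
  if (alpha <= 1) {
    stop_sads(paste0("reads-per-species diverges for alpha <= 1; ",
                     "use richness_given_effort() for the sublinear regime"),
              "sads_divergent_sum_error")
  }
  zeta_fn(alpha) / zeta_fn(1 + alpha)
}

#' Theoretical accumulation exponent gamma
#'
#' gamma = alpha for alpha < 1 and gamma = 1 for alpha > 1; at the boundary
#' alpha = 1 the scaling is linear with a logarithmic correction (warned).
#'
#' @param alpha Tail exponent, > 0.
#' @return min(alpha, 1).
#' @export
theoretical_gamma <- function(alpha) {
  if (alpha <= 0) stop_domain("alpha must be > 0")
  if (alpha == 1) {
    warning("alpha = 1: S ~ N up to a logarithmic correction")
  }
  min(alpha, 1)
}

#' Richness expected at a given sequencing effort
#'
#' For alpha < 1: S = N (1-alpha) zeta(1+alpha) / N_max^(1-alpha) (inverting
#' the continuous-limit reads integral, valid when N_max^(1-alpha) >> 1).
#' For alpha > 1: S = N zeta(1+alpha) / zeta(alpha). At alpha = 1 the
#' harmonic sum gives S = N zeta(2) / (log N_max + 0.5772), with a warning.
#'
#' @param alpha Tail exponent, > 0.
#' @param N Total reads, >= 1.
#' @param N_max Abundance of the most abundant OTU, >= 1.
#' @return Expected richness S.
#' @export
richness_given_effort <- function(alpha, N, N_max) {
  if (alpha <= 0) stop_domain("alpha must be > 0")
  if (N < 1 || N_max < 1) stop_domain("N and N_max must be >= 1")
  if (alpha == 1) {
    warning("alpha = 1 boundary: linear scaling with logarithmic correction")
    return(N * zeta_fn(2) / (log(N_max) + 0.57721566490153286))
  }
  if (alpha > 1) return(N * zeta_fn(1 + alpha) / zeta_fn(alpha))
  if (N_max^(1 - alpha) <= 10) {
    warning("N_max^(1-alpha) is not >> 1; the continuous-limit inversion is inaccurate")
  }
  N * (1 - alpha) * zeta_fn(1 + alpha) / N_max^(1 - alpha)
}

#' Most-abundant-OTU abundance implied by richness
#'
#' From the single-OTU tail condition (exactly one OTU at or above N_max):
#' N_max = (S / (alpha zeta(1+alpha)))^(1/alpha), i.e. S scales as
#' N_max^alpha.
#'
#' @param S Species richness, >= 1.
#' @param alpha Tail exponent, > 0.
#' @return N_max.
#' @export
n_max_from_richness <- function(S, alpha) {
  if (S < 1) stop_domain("S must be >= 1")
  if (alpha <= 0) stop_domain("alpha must be > 0")
  (S / (alpha * zeta_fn(1 + alpha)))^(1 / alpha)
}

# ---- accumulation curves -----------------------------------------------

#' Species accumulation (rarefaction) curve
#'
#' Richness of random subsamples of reads at each grid size, averaged over
#' replicates. Two engines:
#'
#' * `"hypergeometric"` (default): subsampling without replacement from the
#'   observed read pool — rarefaction proper. Each replicate permutes the
#'   pool once; the richness at every grid size is read off the nested
#'   prefixes, so grid points within a replicate share one subsample.
#' * `"multinomial"`: reads drawn with replacement from the relative
#'   abundances, the effectively-infinite-pool regime appropriate when the
#'   abundance vector represents a community far larger than any subsample
#'   (model-scale communities); requires every grid point << total reads.
#'
#' @param v An [abundance_vector].
#' @param grid Integer read depths, all within `[1, total_reads(v)]`.
#'   Default: 20 log-spaced depths up to the total.
#' @param replicates Subsamples per grid point (default 10).
#' @param seed Explicit RNG seed.
#' @param method `"hypergeometric"` or `"multinomial"`.
#' @return An `accumulation_curve`: data.frame with columns `N`, `S_mean`,
#'   `S_sd`, with the replicate count and seed as attributes.
#' @export
accumulation_curve <- function(v, grid = NULL, replicates = 10, seed = NULL,
                               method = c("hypergeometric", "multinomial")) {
  stopifnot(inherits(v, "abundance_vector"))
  method <- match.arg(method)
  N <- total_reads(v)
  if (is.null(grid)) {
    grid <- unique(round(10^seq(0, log10(N), length.out = 20)))
  }
  grid <- sort(unique(round(grid)))
  if (any(grid < 1)) stop_domain("grid depths must be >= 1")
  if (any(grid > N)) {
    stop_domain("grid depth exceeds the total reads; extrapolation beyond the pool is a model-based operation")
  }
  if (replicates < 1) stop_domain("replicates must be >= 1")
  S_mat <- with_seed(seed, {
    if (method == "hypergeometric") {
      pool <- rep.int(seq_len(nrow(v)), v$x)
      vapply(seq_len(replicates), function(r) {
        perm <- pool[sample.int(N)]
        first <- sort(which(!duplicated(perm)))
        findInterval(grid, first)
      }, numeric(length(grid)))
    } else {
      p <- v$x / N
      vapply(seq_len(replicates), function(r) {
        vapply(grid, function(n) sum(rmultinom(1, n, p) > 0), numeric(1))
      }, numeric(length(grid)))
    }
  })
  S_mat <- matrix(S_mat, nrow = length(grid))
  out <- data.frame(
    N = grid,
    S_mean = rowMeans(S_mat),
    S_sd = apply(S_mat, 1, sd)
  )
  if (replicates == 1) out$S_sd <- 0
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  attr(out, "S_observed") <- richness(v)
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Closed-form expected rarefaction richness
#'
#' The hypergeometric expectation
#' E\[S(n)\] = sum_i (1 - choose(N - x_i, n) / choose(N, n)), the analytic
#' mean of without-replacement subsampling at depth n.
#'
#' @param v An [abundance_vector].
#' @param n Subsample depths (reads).
#' @return Expected richness at each depth.
#' @export
expected_richness_hypergeometric <- function(v, n) {
  stopifnot(inherits(v, "abundance_vector"))
  N <- total_reads(v)
  if (any(n < 0 | n > N)) stop_domain("depths must lie in [0, total reads]")
  vapply(n, function(k) {
    lp <- lchoose(N - v$x, k) - lchoose(N, k)
    sum(1 - exp(lp))
  }, numeric(1))
}

# ---- gamma fitting -----------------------------------------------------

#' Fit the accumulation exponent gamma
#'
#' Ordinary least squares of log10(S) on log10(N) over a window of the
#' curve: S ~ N^gamma. The 95% confidence half-width uses the t distribution
#' with (points - 2) degrees of freedom, so for daily time series the
#' interval reflects the number of days observed.
#'
#' @param curve An `accumulation_curve`, or any data.frame with columns `N`
#'   and `S_mean` (or `S`).
#' @param window Optional `c(N_lo, N_hi)` restricting the fitted points.
#' @return A `gamma_fit`: list with `gamma`, `ci95` (half-width), `se`,
#'   `n_points`, `intercept` (log10 scale), and the fitted window.
#' @export
fit_gamma <- function(curve, window = NULL) {
  df <- as.data.frame(curve)
  S <- if ("S_mean" %in% names(df)) df$S_mean else df$S
  N <- df$N
  if (!is.null(window)) {
    keep <- N >= window[1] & N <= window[2]
    N <- N[keep]; S <- S[keep]
  }
  if (length(N) < 3) stop_domain("need at least 3 curve points")
  if (any(N <= 0) || any(S <= 0)) stop_domain("nonpositive N or S in the fitted window")
  fit <- lm(log10(S) ~ log10(N))
  sm <- suppressWarnings(summary(fit))  # noiseless curves fit exactly
  se <- sm$coefficients[2, 2]
  gamma <- unname(coef(fit)[2])
  df_resid <- length(N) - 2
  ci95 <- if (is.nan(se)) 0 else qt(0.975, df_resid) * se
  structure(list(
    gamma = gamma,
    ci95 = ci95,
    se = if (is.nan(se)) 0 else se,
    n_points = length(N),
    intercept = unname(coef(fit)[1]),
    window = range(N)
  ), class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("gamma_fit: gamma = %.3f +/- %.3f (95%% CI, %d points)\n",
              x$gamma, x$ci95, x$n_points))
  if (!is.null(x$breakpoint)) {
    cat(sprintf("  piecewise: break at N = %g, gamma2 = %.3f +/- %.3f\n",
                x$breakpoint, x$gamma2, x$ci95_2))
  }
  invisible(x)
}

#' Two-regime (piecewise) gamma fit
#'
#' Exhaustive breakpoint search over interior grid points (at least three
#' points per segment) minimizing the total squared error of two log-log
#' OLS segments; both slopes are returned.
#'
#' @inheritParams fit_gamma
#' @return A `gamma_fit` with `gamma` (first regime), `gamma2` (second),
#'   `breakpoint` and per-slope confidence half-widths.
#' @export
fit_gamma_piecewise <- function(curve) {
  df <- as.data.frame(curve)
  S <- if ("S_mean" %in% names(df)) df$S_mean else df$S
  N <- df$N
  if (length(N) < 6) stop_domain("need at least 6 points (3 per segment)")
  if (any(N <= 0) || any(S <= 0)) stop_domain("nonpositive N or S")
  lx <- log10(N); ly <- log10(S)
  best <- NULL
  for (k in 3:(length(N) - 3)) {
    f1 <- lm(ly[1:k] ~ lx[1:k])
    f2 <- lm(ly[(k + 1):length(N)] ~ lx[(k + 1):length(N)])
    sse <- sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
    if (is.null(best) || sse < best$sse) best <- list(k = k, f1 = f1, f2 = f2, sse = sse)
  }
  half_ci <- function(f, n) {
    se <- suppressWarnings(summary(f))$coefficients[2, 2]
    if (is.nan(se)) 0 else qt(0.975, n - 2) * se
  }
  k <- best$k
  structure(list(
    gamma = unname(coef(best$f1)[2]),
    gamma2 = unname(coef(best$f2)[2]),
    breakpoint = N[k],
    ci95 = half_ci(best$f1, k),
    ci95_2 = half_ci(best$f2, length(N) - k),
    se = suppressWarnings(summary(best$f1))$coefficients[2, 2],
    n_points = length(N),
    intercept = unname(coef(best$f1)[1]),
    window = range(N)
  ), class = "gamma_fit")
}

#' Chao1 richness estimate
#'
#' S_obs + f1^2 / (2 f2) with the bias-corrected f1 (f1 - 1) / 2 variant
#' when no doubletons are present; a lower-bound estimator included for
#' comparison with the scaling-based view of richness.
#'
#' @param v An [abundance_vector].
#' @return The Chao1 estimate.
#' @export
chao1 <- function(v) {
  stopifnot(inherits(v, "abundance_vector"))
  f1 <- sum(v$x == 1)
  f2 <- sum(v$x == 2)
  S <- richness(v)
  if (f2 > 0) S + f1^2 / (2 * f2) else S + f1 * (f1 - 1) / 2
}
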