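#' Parameter-versus-effort trajectories and community generation at scale
#'
#' The extrapolation procedure fits each distribution parameter as a simple
#' function of the total sequencing effort (reads), using fits over
#' increasingly aggregated sample subsets, and then generates an in-silico
#' community at an arbitrary target depth from the trajectory-evaluated
#' model. Two functional forms are used: power-plus-constant
#' `c1 * N^c2 + c3` (for the cutoff x_c, the shift x0 and the mean
#' abundance) and saturating exponential `c1 * (1 + sign * c2 * exp(-N/c3))`
#' (for the exponents), which approaches the plateau c1 as N grows.
#'
#' @name extrapolation
NULL

trajectory_curve <- function(type = c("power_const", "sat_exp"), coef, sign = -1) {
  type <- match.arg(type)
  stopifnot(length(coef) == 3)
  structure(list(type = type, coef = unname(coef), sign = sign),
            class = "trajectory_curve")
}

eval_curve <- function(curve, N) {
  cf <- curve$coef
  switch(curve$type,
    power_const = cf[1] * N^cf[2] + cf[3],
    sat_exp = cf[1] * (1 + curve$sign * cf[2] * exp(-N / cf[3]))
  )
}

#' Construct a trajectory model
#'
#' @param region `"upper"` or `"deep"`.
#' @param curves Named list of trajectory curves (one per parameter).
#' @return A `trajectory_model`.
#' @export
trajectory_model <- function(region, curves) {
  region <- match.arg(region, c("upper", "deep"))
  stopifnot(all(vapply(curves, inherits, logical(1), "trajectory_curve")))
  structure(list(region = region, curves = curves), class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat("trajectory_model <", x$region, ">\n", sep = "")
  for (nm in names(x$curves)) {
    cv <- x$curves[[nm]]
    cf <- signif(cv$coef, 4)
    form <- if (cv$type == "power_const") {
      sprintf("%g * N^%g + %g", cf[1], cf[2], cf[3])
    } else {
      sprintf("%g * (1 %s %g * exp(-N/%g))", cf[1],
              if (cv$sign > 0) "+" else "-", cf[2], cf[3])
    }
    cat(sprintf("  %s = %s\n", nm, form))
  }
  invisible(x)
}

#' Evaluate a trajectory model at a read depth
#'
#' @param traj A `trajectory_model`.
#' @param N Total reads at which to evaluate.
#' @return Named numeric vector of parameter values.
#' @export
eval_trajectory <- function(traj, N) {
  stopifnot(inherits(traj, "trajectory_model"))
  vapply(traj$curves, eval_curve, numeric(1), N = N)
}

#' Reference parameter trajectories for the two ocean surveys
#'
#' The fitted trajectory coefficients for the upper-ocean (double power law:
#' x_c, head exponent delta, tail exponent alpha) and deep-ocean (shifted
#' power law: shift x0, exponent alpha, mean abundance) surveys, used as
#' defaults by [generate_at_scale()].
#'
#' @param region `"upper"` or `"deep"`.
#' @return A `trajectory_model`.
#' @export
default_trajectories <- function(region = c("upper", "deep")) {
  region <- match.arg(region)
  if (region == "upper") {
    trajectory_model("upper", list(
      x_c = trajectory_curve("power_const", c(0.0002, 1.1, 52.6)),
      delta = trajectory_curve("sat_exp", c(0.32, 0.71, 570007), sign = +1),
      alpha = trajectory_curve("sat_exp", c(1.42, 0.2, 110185), sign = -1)
    ))
  } else {
    trajectory_model("deep", list(
      x0 = trajectory_curve("power_const", c(0.000003, 1.1, -1)),
      alpha = trajectory_curve("sat_exp", c(0.88, 0.45, 363263), sign = -1),
      mean_x = trajectory_curve("power_const", c(0.00042, 0.97, 23.6))
    ))
  }
}

#' Fitted parameters along increasingly aggregated sample subsets
#'
#' For each subset size, draws `reps` random sample subsets, aggregates
#' them, fits the region's distribution family, and bins the fitted
#' parameters by log-spaced total-read bins, reporting mean and sd per bin.
#' Non-converged fits are dropped with a warning; empty bins are omitted.
#'
#' @param table An [otu_table].
#' @param family `"double"` (upper-ocean) or `"shifted"` (deep-ocean).
#' @param subset_sizes Sample-subset sizes to draw (default: log-spaced from
#'   1 to all samples).
#' @param reps Random subsets per size.
#' @param seed Explicit RNG seed.
#' @param bins Number of log-spaced total-read bins.
#' @return A data.frame with one row per bin and parameter: `N_reads` (bin
#'   mean), `parameter`, `mean`, `sd`, `n_fits`.
#' @export
parameter_series <- function(table, family = c("double", "shifted"),
                             subset_sizes = NULL, reps = 10, seed = NULL,
                             bins = 8) {
  stopifnot(inherits(table, "otu_table"))
  family <- match.arg(family)
  if (reps < 1) stop_domain("reps must be >= 1")
  n_samp <- ncol(table)
  if (is.null(subset_sizes)) {
    subset_sizes <- unique(round(10^seq(0, log10(n_samp), length.out = 8)))
  }
  if (any(subset_sizes < 1 | subset_sizes > n_samp)) {
    stop_domain("subset sizes must lie in [1, number of samples]")
  }
  rows <- with_seed(seed, {
    out <- list()
    for (sz in subset_sizes) {
      for (r in seq_len(reps)) {
        samples <- colnames(table)[sample.int(n_samp, sz)]
        v <- aggregate_counts(table, samples)
        fit <- tryCatch(
          if (family == "double") fit_double_power_law(v) else fit_shifted_power_law(v),
          error = function(e) NULL
        )
        if (is.null(fit) || !isTRUE(fit$converged)) {
          warning(sprintf("dropping non-converged %s fit (subset size %d)", family, sz))
          next
        }
        p <- fit$model$params
        pars <- if (family == "double") {
          c(delta = p$delta, alpha = p$alpha, x_c = p$x_c)
        } else {
          c(alpha = p$alpha, x0 = p$x0, mean_x = mean(v$x))
        }
        out[[length(out) + 1L]] <- data.frame(
          N_reads = total_reads(v), parameter = names(pars), value = unname(pars),
          stringsAsFactors = FALSE
        )
        if (sz == n_samp) break  # all further full-table subsets are identical
      }
    }
    out
  })
  if (length(rows) == 0) stop_domain("no converged fits in any subset")
  df <- do.call(rbind, rows)
  brks <- 10^seq(log10(min(df$N_reads)) - 1e-9, log10(max(df$N_reads)) + 1e-9,
                 length.out = bins + 1)
  df$bin <- cut(df$N_reads, brks, include.lowest = TRUE)
  agg <- do.call(rbind, lapply(split(df, list(df$bin, df$parameter), drop = TRUE),
    function(g) data.frame(
      N_reads = mean(g$N_reads), parameter = g$parameter[1],
      mean = mean(g$value), sd = if (nrow(g) > 1) sd(g$value) else 0,
      n_fits = nrow(g), stringsAsFactors = FALSE
    )))
  rownames(agg) <- NULL
  agg[order(agg$parameter, agg$N_reads), ]
}

#' Fit trajectory curves to a parameter series
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the stated functional
#' form to each parameter's (N_reads, mean) series.
#'
#' @param series Output of [parameter_series()] (or a data.frame with
#'   columns `N_reads`, `parameter`, `mean`).
#' @param forms Named list mapping each parameter to
#'   `list(type = "power_const"|"sat_exp", sign = +1/-1)`.
#' @param region Region label for the returned model.
#' @return A `trajectory_model` with fitted coefficients.
#' @export
fit_trajectories <- function(series, forms, region = "upper") {
  curves <- list()
  for (par in names(forms)) {
    g <- series[series$parameter == par, ]
    if (nrow(g) < 4) stop_domain(paste0("need >= 4 series points for parameter ", par))
    type <- forms[[par]]$type
    sgn <- if (is.null(forms[[par]]$sign)) -1 else forms[[par]]$sign
    fit <- tryCatch({
      if (type == "power_const") {
        st <- list(c1 = max(g$mean[which.max(g$N_reads)], 1e-6) / max(g$N_reads),
                   c2 = 1, c3 = min(g$mean))
        minpack.lm::nlsLM(mean ~ c1 * N_reads^c2 + c3, data = g, start = st,
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        st <- list(c1 = g$mean[which.max(g$N_reads)],
                   c2 = 0.5, c3 = stats::median(g$N_reads))
        minpack.lm::nlsLM(mean ~ c1 * (1 + sgn * c2 * exp(-N_reads / c3)),
                          data = cbind(g, sgn = sgn), start = st,
                          lower = c(-Inf, 0, 1),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) {
      stop_sads(sprintf("trajectory fit failed for parameter '%s': %s",
                        par, conditionMessage(e)), "sads_fit_error")
    })
    curves[[par]] <- trajectory_curve(type, coef(fit), sign = sgn)
  }
  trajectory_model(region, curves)
}

#' Generate an in-silico community at a target sequencing depth
#'
#' Evaluates the trajectory model at `N_target` reads, builds the
#' corresponding distribution (double power law for the upper ocean;
#' shifted power law with a finite x_max recovered from the trajectory mean
#' abundance via [estimate_x_max()] for the deep ocean), and draws
#' abundances by inverse-CDF until the cumulative reads reach the target,
#' keeping the final overshooting draw. The generated richness is the
#' number of draws.
#'
#' @param traj A `trajectory_model` (see [default_trajectories()]).
#' @param N_target Target total reads.
#' @param seed Explicit RNG seed.
#' @param reference Optional reference richness; when given, the result
#'   carries `ratio = S / reference`.
#' @return An `extrapolation_result`: list with `region`, `N_target`,
#'   `params` (evaluated parameters, including the derived `x_max` for the
#'   deep region), `S` (generated richness), `total_reads` (>= N_target),
#'   `ratio` (or NA) and `seed`.
#' @export
generate_at_scale <- function(traj, N_target, seed = NULL, reference = NULL) {
  stopifnot(inherits(traj, "trajectory_model"))
  if (N_target < 1) stop_domain("N_target must be >= 1")
  params <- eval_trajectory(traj, N_target)
  model <- tryCatch({
    if (traj$region == "upper") {
      double_power_law(params[["delta"]], params[["alpha"]], params[["x_c"]])
    } else {
      x_max <- estimate_x_max(params[["alpha"]], max(params[["x0"]], 0),
                              params[["mean_x"]])
      params <- c(params, x_max = as.numeric(x_max))
      shifted_power_law(params[["alpha"]], max(params[["x0"]], 0), x_max)
    }
  }, error = function(e) {
    stop_sads(sprintf("evaluated parameters are not normalizable at N = %g (%s): %s",
                      N_target, paste(signif(params, 4), collapse = ", "),
                      conditionMessage(e)), "sads_domain_error")
  })
  v <- sample_to_reads(model, N_target, seed = seed)
  structure(list(
    region = traj$region,
    N_target = N_target,
    params = params,
    S = richness(v),
    total_reads = total_reads(v),
    ratio = if (is.null(reference)) NA_real_ else richness(v) / reference,
    seed = seed
  ), class = "extrapolation_result")
}

#' @export
print.extrapolation_result <- function(x, ...) {
  cat(sprintf("extrapolation_result <%s>: S = %d at N = %g reads%s\n",
              x$region, x$S, x$N_target,
              if (is.na(x$ratio)) "" else sprintf(" (ratio %.2f)", x$ratio)))
  invisible(x)
}

#' Seed-averaged richness ratio at scale
#'
#' Convenience wrapper running [generate_at_scale()] over several seeds and
#' summarizing the richness and its ratio to a reference count.
#'
#' @inheritParams generate_at_scale
#' @param reference Reference richness for the ratio.
#' @param n_seeds Number of independent generations.
#' @param base_seed Seed from which per-run seeds are derived.
#' @return List with `mean_S`, `sd_S`, `mean_ratio`, `sd_ratio`, `runs`
#'   (data.frame of per-seed results).
#' @export
richness_ratio_at_scale <- function(traj, N_target, reference, n_seeds = 10,
                                    base_seed = 1) {
  runs <- do.call(rbind, lapply(seq_len(n_seeds), function(i) {
    r <- generate_at_scale(traj, N_target, seed = child_seed(base_seed, i),
                           reference = reference)
    data.frame(seed = i, S = r$S, ratio = r$ratio)
  }))
  list(mean_S = mean(runs$S), sd_S = sd(runs$S),
       mean_ratio = mean(runs$ratio), sd_ratio = sd(runs$ratio),
       runs = runs)
}
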