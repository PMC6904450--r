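#' Synthetic surveys, mesocosm time series and Yule communities
#'
#' Generators that emulate the shapes of the analyzed datasets — a
#' many-sample upper-ocean-like survey, a few-sample deep-ocean-like survey
#' and a daily mesocosm time series — with known ground truth, so every
#' pipeline stage can be exercised without external downloads. A latent
#' community is drawn once from an abundance model; samples are then
#' conditionally independent multinomial draws from its relative
#' abundances (an optional Dirichlet dispersion knob perturbs the per-sample
#' composition; it defaults to off).
#'
#' @name synthetic_data
NULL

# Latent community: either a fixed number of OTUs or draws accumulated to a
# target read total.
synth_community <- function(model, n_otus = NULL, target_reads = NULL, seed = NULL) {
  if (is.null(n_otus) == is.null(target_reads)) {
    stop_domain("set exactly one of n_otus / target_reads")
  }
  if (!is.null(n_otus)) {
    abundance_vector(sad_sample(model, n_otus, seed = seed))
  } else {
    sample_to_reads(model, target_reads, seed = seed)
  }
}

#' Simulate an expedition-like OTU survey table
#'
#' Draws a latent community from `model`, then draws each sample
#' multinomially from the community's relative abundances.
#'
#' @param model An `sad_model` for the latent community's abundances.
#' @param n_samples Number of samples (columns).
#' @param reads_per_sample Reads per sample: a scalar or a length-`n_samples`
#'   schedule.
#' @param seed Explicit RNG seed.
#' @param n_otus,target_reads Latent community size: exactly one of a fixed
#'   OTU count or a target read total.
#' @param dispersion Dirichlet concentration-inverse: 0 (default) for
#'   identical per-sample compositions; larger values perturb each sample's
#'   relative abundances around the community composition.
#' @return List with `table` (an [otu_table]) and `truth` (generating model
#'   JSON, true latent richness and abundances).
#' @export
synth_survey <- function(model, n_samples, reads_per_sample, seed = NULL,
                         n_otus = NULL, target_reads = NULL, dispersion = 0) {
  if (n_samples < 1) stop_domain("n_samples must be >= 1")
  depths <- rep_len(reads_per_sample, n_samples)
  if (any(depths < 1)) stop_domain("reads_per_sample must be >= 1")
  if (!is.null(target_reads) && target_reads < n_samples) {
    stop_domain("target_reads smaller than the number of samples")
  }
  with_seed(seed, {
    comm <- synth_community(model, n_otus, target_reads, seed = NULL)
    p <- comm$x / sum(comm$x)
    counts <- vapply(seq_len(n_samples), function(j) {
      pj <- if (dispersion > 0) {
        # Dirichlet(p / dispersion) perturbation via gamma draws
        g <- stats::rgamma(length(p), shape = p / dispersion)
        if (sum(g) == 0) p else g / sum(g)
      } else p
      rmultinom(1, depths[j], pj)[, 1]
    }, numeric(length(p)))
    table <- otu_table(counts, otu_ids = comm$otu_id,
                       sample_ids = sprintf("sample_%03d", seq_len(n_samples)))
    list(
      table = table,
      truth = list(model = sad_model_json(model), S_true = richness(comm),
                   x_true = comm$x, seed = seed)
    )
  })
}

#' Simulate a mesocosm daily time series
#'
#' One sample per day from a fixed latent community (default: a pure power
#' law with exponent 0.53, the mesocosm-like regime), with per-day read
#' depths lognormally scattered around a configurable mean. Columns are
#' time-ordered (`day_01`, `day_02`, ...).
#'
#' @param days Number of daily samples (>= 2).
#' @param mean_depth Mean reads per day.
#' @param cv_depth Coefficient of variation of the daily depth (lognormal).
#' @param alpha Latent community power-law exponent.
#' @param community_reads Read total of the latent community pool.
#' @param seed Explicit RNG seed.
#' @return As [synth_survey()]: list with `table` and `truth`.
#' @export
synth_mesocosm <- function(days = 20, mean_depth = 1e4, cv_depth = 0.5,
                           alpha = 0.53, community_reads = 1e6, seed = NULL) {
  if (days < 2) stop_domain("days must be >= 2")
  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv_depth^2))
    depths <- pmax(10, round(rlnorm(days, log(mean_depth) - sdlog^2 / 2, sdlog)))
    out <- synth_survey(power_law(alpha), n_samples = days,
                        reads_per_sample = depths, seed = NULL,
                        target_reads = community_reads)
    colnames(out$table) <- sprintf("day_%02d", seq_len(days))
    out$truth$alpha <- alpha
    out$truth$depths <- depths
    out
  })
}

#' Cumulative richness over a time-ordered table
#'
#' Aggregates the first k samples for k = 1..n and reports the cumulative
#' reads and richness — the empirical material for the mesocosm
#' accumulation exponent.
#'
#' @param table A time-ordered [otu_table] (e.g. from [synth_mesocosm()]).
#' @return data.frame with columns `day`, `N`, `S`.
#' @export
cumulative_richness <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  do.call(rbind, lapply(seq_len(ncol(table)), function(k) {
    v <- aggregate_counts(table, colnames(table)[seq_len(k)])
    data.frame(day = k, N = total_reads(v), S = richness(v))
  }))
}

#' Simulate a Yule community
#'
#' Stochastic growth process in which, at each event, either a new OTU of
#' abundance 1 appears (innovation, rate proportional to g times the number
#' of OTUs) or an existing read replicates (growth, rate proportional to s
#' times the number of reads, i.e. preferential attachment by abundance).
#' Both OTU count and read count then grow exponentially in process time
#' and the abundance distribution develops a power-law tail whose CCD
#' exponent equals the rate ratio g/s.
#'
#' @param g_over_s Innovation-to-growth rate ratio (> 0); the expected tail
#'   exponent.
#' @param n_events Total number of events (>= 1000).
#' @param seed Explicit RNG seed.
#' @return An [abundance_vector]; every event adds exactly one read, so the
#'   total abundance equals `n_events`.
#' @export
yule_community <- function(g_over_s, n_events, seed = NULL) {
  if (g_over_s <= 0) stop_domain("g_over_s must be > 0")
  if (n_events < 1000) stop_domain("n_events must be >= 1000")
  with_seed(seed, {
    n_events <- as.integer(n_events)
    # pool[j] = OTU id of read j; the first event founds the first OTU
    pool <- integer(n_events)
    S <- 0L
    N <- 0L
    r <- g_over_s
    u <- runif(n_events)
    w <- runif(n_events)
    for (e in seq_len(n_events)) {
      if (N == 0L || u[e] * (r * S + N) < r * S) {
        S <- S + 1L
        N <- N + 1L
        pool[N] <- S
      } else {
        N <- N + 1L
        pool[N] <- pool[1L + as.integer(w[e] * (N - 1L))]
      }
    }
    abundance_vector(tabulate(pool, nbins = S))
  })
}
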