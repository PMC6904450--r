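# Internal helpers: typed conditions, seeded evaluation, zeta.

stop_sads <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "sads_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_domain <- function(msg) stop_sads(msg, "sads_domain_error")
stop_parse <- function(msg) stop_sads(msg, "sads_parse_error")
stop_lookup <- function(msg) stop_sads(msg, "sads_lookup_error")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. A NULL seed leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_domain("`seed` must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a master seed; keeps results < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1000 + k) %% 2147483647
}

#' Riemann zeta function
#'
#' Thin wrapper around [pracma::zeta()] restricted to the real axis s > 1,
#' where the abundance-scaling theory needs it.
#'
#' @param s Argument, s > 1.
#' @return zeta(s) as a double.
#' @export
zeta_fn <- function(s) {
  if (any(s <= 1)) stop_domain("zeta_fn requires s > 1 (series diverges at s <= 1)")
  Re(pracma::zeta(s))
}
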