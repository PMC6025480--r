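# internal utilities: seed handling and truncated-normal draws

# Evaluate expr under a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of one master seed into independent per-stage seeds,
#' keyed by a stage name, so every pipeline stage is independently
#' reproducible. The result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param key character stage key (e.g. "phantom", "acq:quantitative:coronal").
#' @return An integer seed.
#' @export
deriveSeed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master))
  h <- 0
  for (b in utf8ToInt(paste0(key, ":"))) h <- (h * 131 + b) %% 2147480009
  as.integer((abs(as.numeric(master)) %% 1000003 * 2083 + h) %% 2147480009)
}

# Truncated-normal draws by inverse-CDF transform.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  # guard against u hitting 0/1 in floating point
  u <- pmin(pmax(u, .Machine$double.xmin), 1 - .Machine$double.eps)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

# Cell-center coordinates along one axis of a regular grid.
cellCenters <- function(n, spacing, origin = 0) origin + (seq_len(n) - 0.5) * spacing
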