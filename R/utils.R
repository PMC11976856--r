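# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.np_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.np_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.np_check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    .np_stop("%s is missing required column(s): %s", what,
             paste(miss, collapse = ", "))
  }
  invisible(df)
}

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
.np_with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .np_stop("a single integer `seed` is required")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# lognormal sdlog giving a multiplicative coefficient of variation `cv`
.np_sdlog <- function(cv) sqrt(log1p(cv^2))

# Draw `e` so that cor(out, z) == r exactly (sample correlation), with the
# marginal location/scale set afterwards by the caller.  Degenerate inputs
# (zero variance, n < 3 with |r| < 1) are a generation error.
.np_correlated_vector <- function(z, r) {
  n <- length(z)
  if (n < 3L) .np_stop("need at least 3 observations to plant a correlation")
  if (abs(r) > 1) .np_stop("target correlation must be in [-1, 1]")
  sz <- stats::sd(z)
  if (!is.finite(sz) || sz == 0) {
    .np_stop("cannot plant a correlation against a constant vector")
  }
  zs <- (z - mean(z)) / sz
  if (abs(r) == 1) return(r * zs)
  e <- stats::rnorm(n)
  # residualize e on zs so the construction is exact, not approximate
  w <- e - mean(e) - sum((e - mean(e)) * zs) / sum(zs^2) * zs
  sw <- stats::sd(w)
  if (!is.finite(sw) || sw == 0) {
    .np_stop("correlation planting failed: degenerate residual (n too small?)")
  }
  r * zs + sqrt(1 - r^2) * (w / sw)
}

.np_now <- function() as.numeric(proc.time()[["elapsed"]])
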