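# Internal helpers.

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Truncated normal draws by inverse-CDF (exact, vectorised).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# Symmetric inverse square root via eigendecomposition; regularises
# non-positive-definite input by flooring eigenvalues, with a warning.
sym_inv_sqrt <- function(V, floor_eig = 1e-10) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) {
    warning("covariance matrix not positive definite; regularising",
            call. = FALSE)
    e$values <- pmax(e$values, floor_eig)
  }
  e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*%
    t(e$vectors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# residual SD without the f >= 0 domain check (the inner optimiser may
# probe negative predictions in linear test models)
.resid_sd <- function(f, r) sqrt((r$sd_prop * f)^2 + r$sd_add^2)
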