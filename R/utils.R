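# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls never perturb user randomness.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream of child seeds from a master seed; kept < 2^31.
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) + 104729 * as.double(index)) %%
               (.Machine$integer.max - 1L)) + 1L
}

# Symmetry check tolerant of NA (pattern must match exactly).
.isSymmetricNA <- function(M, tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) return(FALSE)
  naM <- is.na(M)
  if (!identical(naM, t(naM))) return(FALSE)
  d <- abs(M - t(M))
  all(d[!is.na(d)] <= tol)
}

# Average a near-symmetric matrix with its transpose (NA-preserving).
.symmetrize <- function(M) {
  out <- (M + t(M)) / 2
  out[is.na(M)] <- NA_real_
  out
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be strictly positive", call. = FALSE)
  invisible(x)
}

# Standard error of the mean.
.se <- function(x) stats::sd(x) / sqrt(length(x))
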