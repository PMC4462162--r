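#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Deterministic child seed for a named random stream, so one root seed
# drives several independent generators.  Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Central-difference gradient of a scalar function.
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, numeric(1))
}

# Central-difference Hessian of a scalar function.
num_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  hv <- h * pmax(1, abs(x))
  f0 <- f(x)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + hv[i]
    xm <- x; xm[i] <- x[i] - hv[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / hv[i]^2
    if (i < p) for (j in (i + 1L):p) {
      xpp <- x; xpp[i] <- x[i] + hv[i]; xpp[j] <- x[j] + hv[j]
      xpm <- x; xpm[i] <- x[i] + hv[i]; xpm[j] <- x[j] - hv[j]
      xmp <- x; xmp[i] <- x[i] - hv[i]; xmp[j] <- x[j] + hv[j]
      xmm <- x; xmm[i] <- x[i] - hv[i]; xmm[j] <- x[j] - hv[j]
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * hv[i] * hv[j])
    }
  }
  (H + t(H)) / 2
}

# Invert a (negative) Hessian into a covariance matrix, guarding against
# indefiniteness from finite differencing.
safe_cov_from_hessian <- function(H) {
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)) {
    e <- eigen((H + t(H)) / 2, symmetric = TRUE)
    vals <- pmax(e$values, max(e$values) * 1e-10)
    V <- e$vectors %*% diag(1 / vals, length(vals)) %*% t(e$vectors)
  }
  (V + t(V)) / 2
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp for a matrix (families x quadrature nodes).
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}
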