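# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a reproducible stream seed from a base seed and a counter; result
# stays in [1, 2^31 - 2] so it is always a valid integer seed
deriveSeed <- function(seed, k) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  # two rounds of a Lehmer-style multiplicative step, exact in doubles
  s <- (s * 48271) %% m
  s <- (s + as.double(k) * 69621) %% m
  s <- (s * 48271) %% m
  as.integer(s %% (m - 1) + 1)
}

isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}

assertCount <- function(x, name, min = 1L) {
  if (!isWholeNumber(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  as.integer(round(x))
}

assertProb <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (open && (x <= 0 || x >= 1))
    stop(sprintf("'%s' must lie strictly in (0, 1)", name), call. = FALSE)
  if (!open && (x < 0 || x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  x
}

frobenius <- function(m) sqrt(sum(m^2))

symmetrize <- function(m) (m + t(m)) / 2

# stationary AR(1) filter with unit marginal variance preserved:
# x_1 = z_1, x_t = phi x_{t-1} + sqrt(1 - phi^2) z_t
ar1Filter <- function(z, phi) {
  if (phi == 0) return(z)
  n <- length(z)
  innov <- c(z[1L], sqrt(1 - phi^2) * z[-1L])
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# split-Rhat (Gelman et al.): draws is an iterations x chains matrix
splitRhat <- function(draws) {
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  segs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(segs)
  means <- colMeans(segs)
  vars <- apply(segs, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(if (B <= 1e-300) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

defaultParcelLabels <- function(p) paste0("R", seq_len(p))
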