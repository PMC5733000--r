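# Internal Hamiltonian Monte Carlo sampler used by both model fitters.
#
# The sampler works on an unconstrained parameter vector; each model
# supplies a joint log-posterior-with-gradient function (constraint
# transforms and their Jacobians are the model's responsibility).  Warmup
# does dual-averaging step-size adaptation in two windows with a diagonal
# mass matrix estimated between them; sampling runs at a fixed step size
# with the trajectory length jittered uniformly over `leapfrogRange`.

hmcControl <- function(control = list()) {
  ctl <- list(
    initStep = 0.05,
    targetAccept = 0.8,
    leapfrogRange = c(8L, 16L),
    maxDeltaH = 1000,
    gammaDA = 0.05, t0DA = 10, kappaDA = 0.75
  )
  ctl[names(control)] <- control
  ctl
}

# logpGrad(theta) must return list(logp = scalar, grad = vector)
hmcChain <- function(logpGrad, theta0, nWarmup, nIter, seed, ctl) {
  set.seed(seed)
  d <- length(theta0)
  theta <- theta0
  cur <- logpGrad(theta)
  if (!is.finite(cur$logp)) stop("non-finite log-posterior at the initial value")
  invMass <- rep(1, d)
  Lmin <- ctl$leapfrogRange[1L]; Lmax <- ctl$leapfrogRange[2L]

  leap <- function(theta, r, grad, eps, L) {
    for (l in seq_len(L)) {
      r <- r + 0.5 * eps * grad
      theta <- theta + eps * invMass * r
      lg <- logpGrad(theta)
      if (!is.finite(lg$logp) || any(!is.finite(lg$grad)))
        return(list(ok = FALSE))
      grad <- lg$grad
      r <- r + 0.5 * eps * grad
    }
    list(ok = TRUE, theta = theta, r = r, logp = lg$logp, grad = grad)
  }

  onePhase <- function(n, eps, adapt, keep) {
    # dual averaging state
    mu <- log(10 * eps); logEps <- log(eps); logEpsBar <- 0; hBar <- 0
    draws <- if (keep) matrix(NA_real_, n, d) else NULL
    lps <- if (keep) numeric(n) else NULL
    acc <- 0; div <- 0
    for (it in seq_len(n)) {
      r0 <- stats::rnorm(d) / sqrt(invMass)
      L <- if (Lmax > Lmin) sample.int(Lmax - Lmin + 1L, 1L) + Lmin - 1L else Lmin
      h0 <- -cur$logp + 0.5 * sum(invMass * r0^2)
      prop <- leap(theta, r0, cur$grad, exp(logEps), L)
      if (!prop$ok) {
        alpha <- 0; div <- div + 1
      } else {
        h1 <- -prop$logp + 0.5 * sum(invMass * prop$r^2)
        dH <- h0 - h1
        if (!is.finite(dH) || dH < -ctl$maxDeltaH) {
          alpha <- 0; div <- div + 1
        } else {
          alpha <- min(1, exp(dH))
          if (stats::runif(1) < alpha) {
            theta <<- prop$theta
            cur <<- list(logp = prop$logp, grad = prop$grad)
            acc <- acc + 1
          }
        }
      }
      if (adapt) {
        m <- it
        hBar <- (1 - 1 / (m + ctl$t0DA)) * hBar +
          (ctl$targetAccept - alpha) / (m + ctl$t0DA)
        logEps <- mu - sqrt(m) / ctl$gammaDA * hBar
        w <- m^(-ctl$kappaDA)
        logEpsBar <- w * logEps + (1 - w) * logEpsBar
      }
      if (keep) { draws[it, ] <- theta; lps[it] <- cur$logp }
    }
    list(draws = draws, lps = lps, acc = acc / max(n, 1L), div = div,
         eps = exp(logEps), epsBar = exp(if (adapt) logEpsBar else logEps))
  }

  n1 <- max(floor(nWarmup / 2), 1L)
  n2 <- max(nWarmup - n1, 1L)
  ph1 <- onePhase(n1, ctl$initStep, adapt = TRUE, keep = TRUE)
  # mass from the later (better-mixed) half of the first window
  tail1 <- ph1$draws[seq.int(max(1L, floor(n1 / 2)), n1), , drop = FALSE]
  v <- apply(tail1, 2L, stats::var)
  if (all(is.finite(v)) && any(v > 0)) invMass <- pmax(v, 1e-8 * max(v))
  ph2 <- onePhase(n2, ph1$epsBar, adapt = TRUE, keep = FALSE)
  smp <- onePhase(nIter, ph2$epsBar, adapt = FALSE, keep = TRUE)

  list(draws = smp$draws, logp = smp$lps, accept = smp$acc,
       divergences = smp$div, stepSize = ph2$epsBar, invMass = invMass)
}

# Runs `nChains` chains; inits is a list of starting vectors (one per
# chain).  Returns draws as an (iterations, chains, dim) array.
hmcSample <- function(logpGrad, inits, nWarmup, nIter, seed, control = list()) {
  ctl <- hmcControl(control)
  nChains <- length(inits)
  d <- length(inits[[1L]])
  draws <- array(NA_real_, c(nIter, nChains, d))
  logp <- matrix(NA_real_, nIter, nChains)
  accept <- numeric(nChains); div <- integer(nChains); eps <- numeric(nChains)
  for (c in seq_len(nChains)) {
    res <- hmcChain(logpGrad, inits[[c]], nWarmup, nIter,
                    seed = deriveSeed(seed, c), ctl = ctl)
    draws[, c, ] <- res$draws
    logp[, c] <- res$logp
    accept[c] <- res$accept; div[c] <- res$divergences; eps[c] <- res$stepSize
  }
  list(draws = draws, logp = logp, accept = accept, divergences = div,
       stepSize = eps)
}
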