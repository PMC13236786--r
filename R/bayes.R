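# Hierarchical binomial-beta model of participant-level classification
# accuracy:
#   C_i ~ Binomial(N_i, p_i)
#   p_i ~ Beta(alpha, beta)
#   alpha ~ Exponential(rate 0.1)   (prior mean 10)
#   beta  ~ Exponential(rate 0.05)  (prior mean 20)
# so the prior pulls the group-level mean alpha/(alpha+beta) toward ~1/3,
# i.e. closer to the 1/6 chance level than a high-accuracy posterior.

#' Specification of the hierarchical accuracy model
#'
#' @param chains MCMC chains.
#' @param iterations Iterations per chain; the first `warmup` are discarded.
#' @param warmup Warm-up (adaptation + burn-in) iterations per chain.
#' @param rate_alpha,rate_beta Exponential hyperprior parameters for the
#'   beta shape parameters.
#' @param rates_are_rates The exponential parameters are read as rates
#'   (means `1/rate`); set `FALSE` to reinterpret them as scales (means
#'   `rate`), which inverts the prior pull.
#' @param seed Integer seed; chains get derived, distinct RNG seeds.
#' @return A list of class `bayes_model_spec`.
#' @export
bayes_model_spec <- function(chains = 4L, iterations = 1000L,
                             warmup = iterations %/% 2L,
                             rate_alpha = 0.1, rate_beta = 0.05,
                             rates_are_rates = TRUE, seed = 1L) {
  stopifnot(chains >= 2L, iterations > warmup, warmup >= 0L,
            rate_alpha > 0, rate_beta > 0)
  structure(list(chains = as.integer(chains), iterations = as.integer(iterations),
                 warmup = as.integer(warmup), rate_alpha = rate_alpha,
                 rate_beta = rate_beta,
                 rates_are_rates = isTRUE(rates_are_rates),
                 seed = as.integer(seed)),
            class = "bayes_model_spec")
}

#' Posterior mean of the group-level beta distribution
#'
#' @param alpha,beta Positive shape parameters (vectors of draws allowed).
#' @return `alpha / (alpha + beta)`.
#' @export
beta_mean <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("beta shape parameters must be positive")
  alpha / (alpha + beta)
}

#' Sample the posterior of the hierarchical accuracy model
#'
#' Runs MCMC (Gibbs/slice sampling via JAGS) on the binomial-beta model,
#' discards the warm-up, derives the group-mean draws
#' `beta_mean = alpha / (alpha + beta)` with their 95% HPDI, and computes
#' split-R-hat and effective-sample-size diagnostics. An R-hat above 1.05 on
#' any monitored parameter raises a convergence warning (and is recorded in
#' the fit).
#'
#' @param report An `accuracy_report` from [score()], or a data frame with
#'   columns `n_correct` and `n_trials`.
#' @param spec A [bayes_model_spec()].
#' @return A list of class `bayes_fit`: `draws` (data frame
#'   `chain,alpha,beta,beta_mean`), `hpdi_95`, `posterior_mean`,
#'   `diagnostics` (data frame `parameter,mean,sd,ci_lo,ci_hi,ess,r_hat`),
#'   `converged`, `spec`.
#' @export
sample_posterior <- function(report, spec = bayes_model_spec()) {
  pp <- if (inherits(report, "accuracy_report")) report$per_participant else report
  stopifnot(all(c("n_correct", "n_trials") %in% names(pp)))
  if (any(pp$n_trials < 1L))
    stop("every participant needs at least one scored trial")
  ra <- if (spec$rates_are_rates) spec$rate_alpha else 1 / spec$rate_alpha
  rb <- if (spec$rates_are_rates) spec$rate_beta else 1 / spec$rate_beta
  model_str <- paste0(
    "model {\n",
    "  for (i in 1:n) {\n",
    "    C[i] ~ dbin(p[i], N[i])\n",
    "    p[i] ~ dbeta(alpha, beta)\n",
    "  }\n",
    "  alpha ~ dexp(", format(ra, digits = 12), ")\n",
    "  beta ~ dexp(", format(rb, digits = 12), ")\n",
    "}\n")
  inits <- lapply(seq_len(spec$chains), function(k)
    list(alpha = 2, beta = 8,
         .RNG.name = "base::Wichmann-Hill",
         .RNG.seed = spec$seed * 1000L + k))
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(C = as.integer(pp$n_correct),
                                      N = as.integer(pp$n_trials),
                                      n = nrow(pp)),
                          inits = inits, n.chains = spec$chains, quiet = TRUE)
  if (spec$warmup > 0L) update(jm, spec$warmup, progress.bar = "none")
  keep <- spec$iterations - spec$warmup
  samp <- rjags::coda.samples(jm, c("alpha", "beta"), n.iter = keep,
                              progress.bar = "none")
  alpha_m <- sapply(samp, function(ch) as.numeric(ch[, "alpha"]))
  beta_m <- sapply(samp, function(ch) as.numeric(ch[, "beta"]))
  bm_m <- beta_mean(alpha_m, beta_m)
  draws <- data.frame(chain = rep(seq_len(spec$chains), each = keep),
                      alpha = as.numeric(alpha_m), beta = as.numeric(beta_m),
                      beta_mean = as.numeric(bm_m))
  diag_one <- function(m, name) {
    dg <- mcmc_diagnostics(m)
    hp <- hpdi(as.numeric(m), 0.95)
    data.frame(parameter = name, mean = mean(m), sd = stats::sd(as.numeric(m)),
               ci_lo = hp[1], ci_hi = hp[2], ess = dg$ess, r_hat = dg$r_hat)
  }
  diagnostics <- rbind(diag_one(alpha_m, "alpha"), diag_one(beta_m, "beta"),
                       diag_one(bm_m, "beta_mean"))
  converged <- all(diagnostics$r_hat <= 1.05)
  if (!converged)
    warning("split R-hat above 1.05 for: ",
            paste(diagnostics$parameter[diagnostics$r_hat > 1.05], collapse = ", "),
            "; inspect the chains before trusting the posterior")
  structure(list(draws = draws,
                 hpdi_95 = hpdi(draws$beta_mean, 0.95),
                 posterior_mean = mean(draws$beta_mean),
                 diagnostics = diagnostics, converged = converged, spec = spec),
            class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat("<bayes_fit> group-mean accuracy ", sprintf("%.3f", x$posterior_mean),
      ", 95% HPDI [", sprintf("%.3f", x$hpdi_95[1]), ", ",
      sprintf("%.3f", x$hpdi_95[2]), "]",
      if (!x$converged) " (NOT CONVERGED)" else "", "\n", sep = "")
  invisible(x)
}

#' Highest-posterior-density interval
#'
#' Narrowest contiguous interval containing the requested posterior mass,
#' found by a sorted-window search over the draws.
#'
#' @param draws Numeric vector of posterior draws (>= 100 for a stable
#'   estimate; fewer are refused).
#' @param mass Probability mass in (0, 1).
#' @return Numeric `(lo, hi)`.
#' @export
hpdi <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie strictly between 0 and 1")
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws for an HPDI")
  s <- sort(draws)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(s[1L], s[n]))
  widths <- s[(k + 1L):n] - s[1L:(n - k)]
  i <- which.min(widths)
  c(s[i], s[i + k])
}

#' Split-R-hat and effective sample size
#'
#' Convergence diagnostics for multi-chain MCMC output: each chain is split
#' in half before the between/within variance ratio is formed (split-R-hat),
#' and the effective sample size is computed on rank-normalized draws from
#' the combined-chain autocorrelations with Geyer's initial positive
#' sequence truncation.
#'
#' @param draws_by_chain Numeric matrix, iterations x chains (>= 2 chains).
#' @return List `(r_hat, ess)`.
#' @export
mcmc_diagnostics <- function(draws_by_chain) {
  m <- as.matrix(draws_by_chain)
  if (ncol(m) < 2L) stop("diagnostics need at least two chains")
  half <- nrow(m) %/% 2L
  if (half < 2L) stop("chains too short to split")
  sp <- cbind(m[seq_len(half), , drop = FALSE],
              m[(nrow(m) - half + 1L):nrow(m), , drop = FALSE])
  list(r_hat = rhat_basic(sp), ess = ess_rank_normalized(sp))
}

rhat_basic <- function(chains) {
  n <- nrow(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

rank_normalize <- function(chains) {
  r <- rank(as.numeric(chains), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(chains), ncol(chains))
}

ess_rank_normalized <- function(chains) {
  z <- rank_normalize(chains)
  n <- nrow(z)
  mchains <- ncol(z)
  vars <- apply(z, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(colMeans(z))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(n * mchains)
  # chain-averaged autocovariances
  max_lag <- n - 1L
  acov <- sapply(seq_len(mchains), function(j) {
    a <- stats::acf(z[, j], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus     # rho[1] is lag 0
  # Geyer initial positive sequence over paired lag sums (0+1, 2+3, ...)
  psum <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    psum <- psum + pair
    t <- t + 2L
  }
  tau <- max(-1 + 2 * psum, 1 / (mchains * n))
  ess <- mchains * n / tau
  min(ess, mchains * n)
}
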