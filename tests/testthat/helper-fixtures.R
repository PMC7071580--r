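# Shared fixtures: reduced-scale designs and generator configs used across
# the suite (2 subjects, 4 titrations, depth 1e4 unless a check needs the
# full scale).

smallDesign <- function(n_subjects = 2, factors = c(1, 2, 3, 4),
                        reps = 4, ntc = 0) {
    TitrationDesign(paste0("S", seq_len(n_subjects)), factors,
                    pcrReplicates = reps, nNTC = ntc)
}

paperDesign <- function(reps = 4, ntc = 12) {
    TitrationDesign(paste0("S", 1:5), c(1, 2, 3, 4, 5, 10, 15),
                    pcrReplicates = reps, nNTC = ntc)
}

# artifact-free, detection-safe config: every true feature has expected
# count >= 20 per replicate at depth 1e5, so presence patterns are
# deterministic for practical purposes
cleanConfig <- function(depthMean = 1e5, seed = 1, ...) {
    SimulationConfig(minProportion = 2e-4, sdlog = 1,
                     depthMean = depthMean,
                     falsePositiveRate = 0, falseNegativeRate = 0,
                     seed = seed, ...)
}

# realistic long-tailed config with rare features near the detection limit
realisticConfig <- function(depthMean = 1e4, seed = 1, ...) {
    SimulationConfig(depthMean = depthMean, seed = seed, ...)
}

# quadrature oracle for the Bayesian titration-specific test: numerical
# integration of the binomial tail over the null and alternative priors
bayesQuadratureOracle <- function(c_obs, n, pi_min, alpha = 1, beta = 1,
                                  w = 0.5) {
    if (c_obs == 0) return(w)
    tail <- function(p) stats::pbinom(c_obs - 1, n, p, lower.tail = FALSE)
    t0 <- stats::integrate(function(p) tail(p) / pi_min, 0, pi_min,
                           rel.tol = 1e-10, abs.tol = 0)$value
    t1 <- stats::integrate(function(p) tail(pi_min + (1 - pi_min) * p) *
                               stats::dbeta(p, alpha, beta),
                           0, 1, rel.tol = 1e-9)$value
    w * t0 / (w * t0 + (1 - w) * t1)
}

# brute-force step-up BH oracle
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
    pmin(1, adj)[order(o)]
}

# direct NB likelihood maximization oracle for replicate averaging
nbOracle <- function(x, depths) {
    nll <- function(par) {
        mu <- exp(par[1]) * depths
        -sum(stats::dnbinom(x, mu = mu, size = exp(par[2]), log = TRUE))
    }
    fit <- stats::optim(c(log(sum(x) / sum(depths)), 2), nll,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 5000))
    exp(fit$par[1])
}

# closed-form simple linear regression oracle (normal equations)
olsOracle <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
    intercept <- (sy - slope * sx) / n
    yhat <- intercept + slope * x
    r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
    list(slope = slope, intercept = intercept, r_squared = r2)
}
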