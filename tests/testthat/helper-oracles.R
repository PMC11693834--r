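# Independent oracles used by the tests. These deliberately re-derive the
# quantities from first principles, by different routes than the package
# (numeric normalization of joint densities; an exact run-length filter),
# so agreement is evidence, not tautology.

# Two-hypothesis Bayes for the changepoint posterior, via explicit joint
# probabilities and normalization.
oracle_omega <- function(delta, predictive_sd, hazard, width = 1) {
  joint_change <- hazard * stats::dunif(0, -width / 2, width / 2)
  joint_stay <- (1 - hazard) * stats::dnorm(delta, mean = 0, sd = predictive_sd)
  joint_change / (joint_change + joint_stay)
}

# Full Bayesian online changepoint (run-length) filter with Gaussian
# likelihood of known noise SD and a Gaussian prior on the mean moment-
# matched to uniform[0,1]. Returns the relative uncertainty of the mixture
# posterior over the latent mean after each observation.
oracle_runlength_tau <- function(x, hazard, noise_sd,
                                 mu0 = 0.5, v0 = 1 / 12) {
  n <- length(x)
  vn <- noise_sd^2
  # run-length state: probability, sum of observations, count
  p <- 1; sx <- 0; k <- 0
  tau <- numeric(n)
  for (t in seq_len(n)) {
    # posterior of the mean for each run length (conjugate Gaussian)
    v_post <- 1 / (1 / v0 + k / vn)
    m_post <- v_post * (mu0 / v0 + sx / vn)
    pred <- stats::dnorm(x[t], m_post, sqrt(v_post + vn))
    grow <- p * (1 - hazard) * pred
    cp <- sum(p * hazard * pred)
    p <- c(cp, grow)
    sx <- c(0, sx) + x[t]
    k <- c(0, k) + 1
    p <- p / sum(p)
    # prune negligible run lengths for speed
    keep <- p > 1e-12
    p <- p[keep]; sx <- sx[keep]; k <- k[keep]
    # mixture posterior moments of the latent mean
    v_post <- 1 / (1 / v0 + k / vn)
    m_post <- v_post * (mu0 / v0 + sx / vn)
    mix_m <- sum(p * m_post)
    mix_v <- sum(p * (v_post + m_post^2)) - mix_m^2
    tau[t] <- mix_v / (mix_v + vn)
  }
  tau
}

# Monte-Carlo mean absolute error of the predictive distribution.
oracle_mc_expected_pe <- function(sigma_tot, n = 1e5) {
  mean(abs(stats::rnorm(n, 0, sigma_tot)))
}
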