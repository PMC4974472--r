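# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: rarefaction by exhaustive enumeration / resampling
# of individuals, and Poisson mixed-model fitting by adaptive Gauss-Hermite
# quadrature maximised with optim.

# exhaustive rarefaction: average richness over all choose(N, n) subsamples
enumerate_rarefaction <- function(counts, n) {
  counts <- counts[counts > 0]
  individuals <- rep(seq_along(counts), counts)
  N <- length(individuals)
  stopifnot(n <= N)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  mean(apply(subsets, 2, function(idx) length(unique(individuals[idx]))))
}

# Monte Carlo rarefaction: mean and SE of richness over random subsamples
mc_rarefaction <- function(counts, n, n_resamples = 10000) {
  individuals <- rep(seq_along(counts), counts)
  s <- replicate(n_resamples, length(unique(sample(individuals, n))))
  list(mean = mean(s), se = stats::sd(s) / sqrt(n_resamples))
}

# all integer partitions of N (multisets of positive counts summing to N)
integer_partitions <- function(N, max_part = N) {
  if (N == 0) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(N, max_part))) {
    for (rest in integer_partitions(N - k, k))
      out[[length(out) + 1]] <- c(k, rest)
  }
  out
}

# Adaptive Gauss-Hermite ML fit of a Poisson GLMM with a single random
# intercept per group: y ~ X beta + u_g, u_g ~ N(0, sigma^2). Returns the
# maximised fixed effects; independent of lme4.
ghq_poisson_fit <- function(y, X, group, n_nodes = 25) {
  gh <- pracma::gaussHermite(n_nodes)
  groups <- split(seq_along(y), group)
  negll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    sigma <- exp(par[length(par)])
    eta <- drop(X %*% beta)
    ll <- 0
    for (idx in groups) {
      h <- function(u)
        sum(stats::dpois(y[idx], exp(eta[idx] + u), log = TRUE)) +
          stats::dnorm(u, 0, sigma, log = TRUE)
      # mode and curvature of the integrand for the adaptive rule
      opt <- stats::optimize(function(u) -h(u), c(-10 * sigma - 5, 10 * sigma + 5))
      u_star <- opt$minimum
      curv <- sum(exp(eta[idx] + u_star)) + 1 / sigma^2
      scale <- sqrt(2 / curv)
      nodes <- u_star + scale * gh$x
      vals <- vapply(nodes, h, numeric(1)) + gh$x^2
      m <- max(vals)
      ll <- ll + log(sum(gh$w * exp(vals - m))) + m + log(scale)
    }
    -ll
  }
  start <- c(stats::coef(stats::glm.fit(X, y, family = stats::poisson())), log(0.3))
  fit <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  list(beta = fit$par[seq_len(ncol(X))], sigma = exp(fit$par[length(fit$par)]),
       logLik = -fit$value, convergence = fit$convergence)
}

# small world configuration used by several tests: no nuisance structure, so
# inside/outside contrasts are driven by the protection factors alone
clean_config <- function(n_studies, sites = c(30, 30), richness = 1, abundance = 1,
                         seed = 1, ...) {
  world_config(
    n_studies = n_studies, sites_per_study = sites, taxon_pool_size = c(15, 30),
    blocks_per_study = 2,
    protection_effect = c(richness = richness, abundance = abundance),
    land_use_effects = setNames(rep(1, 8), land_use_classes()),
    confounder_effects = c(elevation = 0, slope = 0, agri_suitability = 0),
    confounder_protection_correlation = 0, occurrence_fraction = 0,
    sigma_study = 0, sigma_block = 0, random_seed = seed, ...)
}

# small deterministic model data built in code
toy_model_data <- function(n_studies = 4, n_per = 25, seed = 5, beta_prot = 0.3,
                           sigma_study = 0.3) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_studies), function(j) {
    u <- rnorm(1, 0, sigma_study)
    prot <- rep(c("unprotected", "protected"), length.out = n_per)
    x <- rnorm(n_per)
    eta <- 1.2 + u + beta_prot * (prot == "protected") + 0.1 * x
    data.frame(study_id = sprintf("S%d", j), block_id = "B1",
               protected = factor(prot, levels = c("unprotected", "protected")),
               elevation = x, slope = rnorm(n_per), agri_suitability = rnorm(n_per),
               S = rpois(n_per, exp(eta)), y = eta + rnorm(n_per, 0, 0.5))
  }))
}

# ratio of means with a delta-method standard error, for law-of-large-numbers
# checks of generated inside/outside ratios
ratio_of_means <- function(x_in, x_out) {
  m_i <- mean(x_in); m_o <- mean(x_out)
  ratio <- m_i / m_o
  se <- ratio * sqrt(stats::var(x_in) / (length(x_in) * m_i^2) +
                     stats::var(x_out) / (length(x_out) * m_o^2))
  list(ratio = ratio, se = se)
}
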