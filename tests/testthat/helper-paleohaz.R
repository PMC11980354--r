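# shared fixtures built in code

# quick individual-level table drawn from a GM-PH model
sim_individuals <- function(n, model = gompertz_makeham(0.01, 0.005, 0.07),
                            rho = 0, p_female = 0.5, seed = 1) {
  set.seed(seed)
  sex <- rbinom(n, 1, p_female)
  age <- sample_age(n, model, x = sex, rho = rho)
  tibble::tibble(age = as.numeric(age), sex = sex)
}

# minimal mort_fit stub with a chosen log-likelihood, for exact-value tests
# of the LRT arithmetic (both stubs claim the same data)
stub_fit <- function(loglik, covariate, n = 100,
                     family = "gompertz_makeham",
                     digest = list(t = "d", tx = "dx")) {
  k <- (if (family == "gompertz") 2 else 3) + covariate
  cf <- stats::setNames(rep(0.1, k), paleohaz:::.par_names(family, covariate))
  structure(list(family = family, covariate = covariate, coef = cf,
                 se = cf * 0 + 0.1, loglik = loglik, converged = TRUE,
                 n_used = n, digest = digest),
            class = "mort_fit")
}

# random valid GM parameter draw for property loops; beta_max can be
# lowered where an oracle works on the raw (non-log) density and must not
# underflow
random_gm <- function(beta_max = 0.15) {
  gompertz_makeham(a1 = runif(1, 0, 0.03), a2 = runif(1, 1e-4, 0.03),
                   beta = runif(1, 0.01, beta_max))
}
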