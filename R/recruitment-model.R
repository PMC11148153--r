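#' Log-scale expected age-1 recruitment index
#'
#' The process model is white noise on the log scale with a mortality term
#' proportional to release effort: log A = a_s + a'_{yr,s} - q_s * E, where
#' a_s is the stream's mean log recruitment, a' the year deviation, q_s the
#' instantaneous mortality per unit effort, and E the release effort
#' (sterile males released / 1000).
#'
#' @param a_s stream mean log recruitment.
#' @param a_dev year deviation from the stream mean.
#' @param q_s instantaneous mortality per unit effort (>= 0).
#' @param E release effort, thousands of sterile males (>= 0).
#' @return log of the expected recruitment index.
#' @examples
#' log_expected_recruitment(1, 0, 0.5, 2)  # 0
#' @export
log_expected_recruitment <- function(a_s, a_dev, q_s, E) {
  if (any(E < 0)) smr_stop("effort must be non-negative")
  a_s + a_dev - q_s * E
}

#' Negative-binomial log-probability, mean-dispersion form
#'
#' Parameterized by mean mu and overdispersion theta with variance
#' mu + mu^2 / theta; theta -> Inf recovers the Poisson. This is the
#' observation model for recruitment indices (age-1 density x 1000,
#' rounded), whose variance in the field far exceeds the mean.
#'
#' @param y observed count(s), non-negative integers.
#' @param mu expected count, > 0.
#' @param theta overdispersion, > 0.
#' @return log probability mass at `y`.
#' @examples
#' negbin_logpmf(3, mu = 3, theta = 1.5)
#' @export
negbin_logpmf <- function(y, mu, theta) {
  if (any(!is_count(y))) smr_stop("y must be non-negative integers")
  if (any(mu <= 0) || any(theta <= 0)) smr_stop("mu and theta must be positive")
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu))
}

#' Prior configuration for the recruitment model
#'
#' The study's exact low-information priors are not published; these defaults
#' are reconstructions chosen to be weak on each parameter's natural scale,
#' and every one is replaceable. Each prior is a list whose first element is
#' the family (`"normal"`, `"half-normal"`, `"exponential"`, `"gamma"`, or
#' `"uniform"`) followed by named hyperparameters. Families must respect the
#' parameter's support (sigma_a, theta > 0; q >= 0 unless `q_signed`).
#'
#' @param a prior on each stream's mean log recruitment a_s.
#' @param sigma_a prior on the year-deviation standard deviation.
#' @param q prior on instantaneous mortality per unit effort. The default
#'   half-Normal(0, 1.5) spreads the implied percent reduction in
#'   recruitment per 1000 males released broadly over 0-100%.
#' @param theta prior on the negative-binomial overdispersion.
#' @param q_signed allow q < 0 (sensitivity analysis); the q prior must then
#'   be a signed family such as `"normal"`.
#' @return an object of class `smr_priors`.
#' @examples
#' prior_config()
#' prior_config(q = list("half-normal", sd = 0.5))
#' @export
prior_config <- function(a = list("normal", mean = 0, sd = 10),
                         sigma_a = list("half-normal", sd = 2),
                         q = list("half-normal", sd = 1.5),
                         theta = list("half-normal", sd = 5),
                         q_signed = FALSE) {
  pr <- list(a = a, sigma_a = sigma_a, q = q, theta = theta,
             q_signed = isTRUE(q_signed))
  for (nm in c("a", "sigma_a", "q", "theta")) {
    check_prior_spec(pr[[nm]], nm)
  }
  if (!pr$q_signed && pr$q[[1]] == "normal") {
    smr_stop("a signed q prior requires q_signed = TRUE")
  }
  structure(pr, class = "smr_priors")
}

check_prior_spec <- function(spec, name) {
  fams <- c("normal", "half-normal", "exponential", "gamma", "uniform")
  if (!is.list(spec) || !is.character(spec[[1]]) || !(spec[[1]] %in% fams)) {
    smr_stop("prior for ", name, " must be list(<family>, ...) with family in: ",
             paste(fams, collapse = ", "))
  }
  need <- switch(spec[[1]],
                 "normal" = c("mean", "sd"),
                 "half-normal" = "sd",
                 "exponential" = "rate",
                 "gamma" = c("shape", "rate"),
                 "uniform" = c("min", "max"))
  missing_par <- setdiff(need, names(spec))
  if (length(missing_par)) {
    smr_stop("prior for ", name, " (", spec[[1]], ") missing hyperparameter(s): ",
             paste(missing_par, collapse = ", "))
  }
  invisible(spec)
}

# log density of one prior spec at x (vectorized); -Inf outside support
prior_logpdf <- function(x, spec) {
  switch(spec[[1]],
         "normal" = stats::dnorm(x, spec$mean, spec$sd, log = TRUE),
         "half-normal" = ifelse(x < 0, -Inf,
                                log(2) + stats::dnorm(x, 0, spec$sd, log = TRUE)),
         "exponential" = stats::dexp(x, spec$rate, log = TRUE),
         "gamma" = stats::dgamma(x, shape = spec$shape, rate = spec$rate,
                                 log = TRUE),
         "uniform" = stats::dunif(x, spec$min, spec$max, log = TRUE))
}

# random draws from one prior spec (used for initialization and prior checks)
prior_draw <- function(n, spec) {
  switch(spec[[1]],
         "normal" = stats::rnorm(n, spec$mean, spec$sd),
         "half-normal" = abs(stats::rnorm(n, 0, spec$sd)),
         "exponential" = stats::rexp(n, spec$rate),
         "gamma" = stats::rgamma(n, shape = spec$shape, rate = spec$rate),
         "uniform" = stats::runif(n, spec$min, spec$max))
}

#' @export
print.smr_priors <- function(x, ...) {
  fmt <- function(s) paste0(s[[1]], "(",
                            paste(names(s)[-1], unlist(s[-1]), sep = "=",
                                  collapse = ", "), ")")
  cat("Recruitment-model priors:\n")
  for (nm in c("a", "sigma_a", "q", "theta")) {
    cat(sprintf("  %-8s ~ %s\n", nm, fmt(x[[nm]])))
  }
  if (x$q_signed) cat("  (q unconstrained in sign)\n")
  invisible(x)
}

# Validate a ModelParams list against a dataset: a and q named by stream,
# a_dev named by the dataset's stream-year group labels.
check_params <- function(params, data) {
  need <- c("a", "a_dev", "sigma_a", "q", "theta")
  missing_par <- setdiff(need, names(params))
  if (length(missing_par)) {
    smr_stop("params missing element(s): ", paste(missing_par, collapse = ", "))
  }
  if (!all(data$streams %in% names(params$a)) ||
      !all(data$streams %in% names(params$q))) {
    smr_stop("params a and q must be named vectors covering every stream")
  }
  if (!all(data$groups$group %in% names(params$a_dev))) {
    smr_stop("params a_dev must be named by stream-year group (\"<stream> <year>\")")
  }
  invisible(params)
}

#' Joint log-posterior of the recruitment model
#'
#' Sum of the negative-binomial log-likelihood over every survey observation,
#' the Normal(0, sigma_a) log-density of every year deviation, and the prior
#' log-densities of a_s, sigma_a, q_s and theta. Returns -Inf for parameter
#' values outside the model's support (sigma_a or theta <= 0, or q < 0 under
#' the default mortality constraint).
#'
#' @param params list with elements `a` (named by stream), `a_dev` (named by
#'   `"<stream> <year>"` group), `sigma_a`, `q` (named by stream), `theta`.
#' @param data an `smr_recruitment_data` object (see [recruitment_data()]).
#' @param priors an `smr_priors` object.
#' @return scalar log-posterior density (unnormalized).
#' @export
log_posterior <- function(params, data, priors = prior_config()) {
  if (!inherits(data, "smr_recruitment_data")) {
    smr_stop("data must be an smr_recruitment_data object")
  }
  check_params(params, data)
  sigma <- params$sigma_a
  theta <- params$theta
  if (!is.finite(sigma) || !is.finite(theta)) return(-Inf)
  if (sigma <= 0 || theta <= 0) return(-Inf)
  if (!priors$q_signed && any(params$q[data$streams] < 0)) return(-Inf)

  lp <- sum(prior_logpdf(params$a[data$streams], priors$a)) +
    prior_logpdf(sigma, priors$sigma_a) +
    sum(prior_logpdf(params$q[data$streams], priors$q)) +
    prior_logpdf(theta, priors$theta)
  a_dev <- params$a_dev[data$groups$group]
  lp <- lp + sum(stats::dnorm(a_dev, 0, sigma, log = TRUE))
  if (!is.finite(lp)) return(-Inf)

  obs <- data$obs
  gi <- match(obs$group, data$groups$group)
  mu <- exp(log_expected_recruitment(params$a[obs$stream],
                                     a_dev[gi],
                                     params$q[obs$stream],
                                     obs$effort))
  lp + sum(negbin_logpmf(obs$index, mu, theta))
}

#' Percent reduction in recruitment implied by mortality q and effort E
#'
#' Instantaneous mortality acts multiplicatively on survival, e^(-qE), so
#' the expected percent reduction in age-1 recruitment is 100 * (1 - e^(-qE)).
#' E = 1 corresponds to releasing 1000 sterile males.
#'
#' @param q instantaneous mortality per unit effort (>= 0).
#' @param E release effort in thousands of males (>= 0).
#' @return percent reduction in \[0, 100).
#' @examples
#' percent_reduction(log(2), 1)  # 50
#' @export
percent_reduction <- function(q, E = 1) {
  if (any(q < 0) || any(E < 0)) smr_stop("q and E must be non-negative")
  100 * (1 - exp(-q * E))
}
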