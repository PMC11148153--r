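# Sampler internals ----------------------------------------------------------
#
# The posterior is sampled by adaptive random-walk Metropolis-within-Gibbs on
# an unconstrained parameterization: a_s free, year deviations non-centered
# (a_dev = sigma_a * z, z ~ Normal(0,1)) to avoid the hierarchical funnel,
# and sigma_a, q_s, theta on the log scale with Jacobian terms. Because the
# likelihood factorizes over stream-year groups, each block's proposals are
# evaluated with one vectorized pass over the observations and accepted
# per-stream / per-group independently; per-group log-likelihoods are cached.

# unchecked NB log-pmf for the hot loop (public negbin_logpmf validates)
negbin_ll <- function(y, mu, theta) {
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu))
}

# per-group log-likelihood sums given obs-level vectors
group_ll_all <- function(y, mu, theta, gi, G) {
  ll <- negbin_ll(y, mu, theta)
  out <- numeric(G)
  s <- rowsum(ll, gi)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit the age-1 recruitment model by MCMC
#'
#' Samples the joint posterior of the hierarchical negative-binomial
#' recruitment model (see [log_posterior()]) with an adaptive random-walk
#' Metropolis-within-Gibbs sampler. Year deviations use a non-centered
#' parameterization (a_dev = sigma_a * z) and positive parameters are
#' sampled on the log scale; proposal scales adapt toward a 44% acceptance
#' rate during warmup only, so kept draws form a valid Markov chain.
#'
#' @param data an `smr_recruitment_data` object from [recruitment_data()].
#' @param priors an `smr_priors` object; see [prior_config()].
#' @param chains number of chains (default 4).
#' @param iter total iterations per chain (default 5000).
#' @param warmup adaptation iterations discarded from each chain
#'   (default 2000).
#' @param seed integer seed; the full run is reproducible given it.
#' @param fix optional list pinning parameters for sub-model analyses:
#'   `sigma_a`, `theta` (numeric values) and/or `a_dev_zero = TRUE` to drop
#'   year deviations (sigma_a is then treated as fixed).
#' @param init_retries attempts to find a finite starting point per chain.
#' @return an object of class `smr_posterior`: list with `draws` (array
#'   kept-iterations x chains x parameters, natural scale), `rhat` (named
#'   split-R-hat vector), `accept` (mean acceptance rate per block), and
#'   `metadata` (sampler description, dimensions, seed, fixed parameters).
#' @seealso [split_rhat()], [summarize_effect()]
#' @export
fit_mcmc <- function(data, priors = prior_config(), chains = 4, iter = 5000,
                     warmup = 2000, seed = 1, fix = list(),
                     init_retries = 20) {
  if (!inherits(data, "smr_recruitment_data")) {
    smr_stop("data must be an smr_recruitment_data object")
  }
  if (nrow(data$groups) < 2) smr_stop("need at least 2 stream-years of data")
  if (warmup >= iter) smr_stop("warmup must be smaller than iter")
  if (chains < 1) smr_stop("need at least one chain")

  streams <- data$streams
  S <- length(streams)
  groups <- data$groups
  G <- nrow(groups)
  gs <- match(groups$stream, streams)        # stream index per group
  gE <- groups$effort
  obs <- data$obs
  gi <- match(obs$group, groups$group)       # group index per observation
  os <- match(obs$stream, streams)
  y <- obs$index
  oE <- obs$effort

  a_dev_zero <- isTRUE(fix$a_dev_zero)
  fix_sigma <- if (a_dev_zero) fix$sigma_a %||% 1 else fix$sigma_a
  fix_theta <- fix$theta
  q_signed <- priors$q_signed
  # mean positive effort per stream, for the ridge (a_s, q_s) shear update:
  # the likelihood mainly constrains a_s - q_s * Ebar, so a joint move along
  # that direction decorrelates the pair (unit-Jacobian shear, plain MH)
  Ebar <- vapply(seq_len(S), function(s) {
    e <- gE[gs == s & gE > 0]
    if (length(e)) mean(e) else 0
  }, numeric(1))

  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)

  par_names <- c(paste0("a[", streams, "]"),
                 paste0("a_dev[", groups$group, "]"),
                 "sigma_a",
                 paste0("q[", streams, "]"),
                 "theta")
  kept <- iter - warmup
  draws <- array(NA_real_,
                 dim = c(kept, chains, length(par_names)),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 par_names))
  accept_tot <- c(a = 0, z = 0, sigma = 0, q = 0, ridge = 0, theta = 0)
  accept_n <- c(a = 0, z = 0, sigma = 0, q = 0, ridge = 0, theta = 0)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    st <- NULL
    for (try in seq_len(init_retries)) {
      stream_mean <- vapply(seq_len(S), function(s) {
        mean(y[os == s]) + 0.5
      }, numeric(1))
      cand <- list(
        a = log(stream_mean) + stats::rnorm(S, 0, 0.5),
        z = if (a_dev_zero) numeric(G) else stats::rnorm(G, 0, 0.3),
        ls = if (!is.null(fix_sigma)) log(fix_sigma)
             else log(stats::runif(1, 0.3, 1.2)),
        q = abs(stats::rnorm(S, 0, 0.3)),
        lt = if (!is.null(fix_theta)) log(fix_theta)
             else log(stats::runif(1, 0.5, 2)))
      if (q_signed) cand$q <- stats::rnorm(S, 0, 0.3)
      lp0 <- sampler_lp(cand, priors, y, os, gi, oE, G, q_signed)
      if (is.finite(lp0$lp)) { st <- cand; ll_g <- lp0$ll_g; break }
    }
    if (is.null(st)) {
      smr_stop("initialization error: no finite log-posterior after ",
               init_retries, " attempts")
    }

    # adaptive proposal log-scales per scalar
    sc <- list(a = rep(log(0.5), S), z = rep(log(0.8), G),
               ls = log(0.5), q = rep(log(0.5), S), lt = log(0.5),
               r = rep(log(0.3), S))
    sigma <- exp(st$ls)
    theta <- exp(st$lt)

    for (it in seq_len(iter)) {
      adapting <- it <= warmup
      rate <- min(0.25, 1 / sqrt(it))

      ## block 1: stream means a_s (independent across streams)
      prop_a <- st$a + stats::rnorm(S, 0, exp(sc$a))
      mu_new <- exp(prop_a[os] + sigma * st$z[gi] - st$q[os] * oE)
      llg_new <- group_ll_all(y, mu_new, theta, gi, G)
      d_ll <- rowsum(llg_new - ll_g, gs)[, 1]
      d_pr <- prior_logpdf(prop_a, priors$a) - prior_logpdf(st$a, priors$a)
      acc <- log(stats::runif(S)) < d_ll + d_pr
      if (any(acc)) {
        st$a[acc] <- prop_a[acc]
        upd <- gs %in% which(acc)   # proposals independent across streams
        ll_g[upd] <- llg_new[upd]
      }
      accept_tot["a"] <- accept_tot["a"] + mean(acc)
      accept_n["a"] <- accept_n["a"] + 1
      if (adapting) sc$a <- sc$a + rate * ((acc) - 0.44)

      ## block 2: year deviations z (independent across groups)
      if (!a_dev_zero) {
        prop_z <- st$z + stats::rnorm(G, 0, exp(sc$z))
        mu_new <- exp(st$a[os] + sigma * prop_z[gi] - st$q[os] * oE)
        llg_new <- group_ll_all(y, mu_new, theta, gi, G)
        d <- llg_new - ll_g +
          stats::dnorm(prop_z, log = TRUE) - stats::dnorm(st$z, log = TRUE)
        acc <- log(stats::runif(G)) < d
        st$z[acc] <- prop_z[acc]
        ll_g[acc] <- llg_new[acc]
        accept_tot["z"] <- accept_tot["z"] + mean(acc)
        accept_n["z"] <- accept_n["z"] + 1
        if (adapting) sc$z <- sc$z + rate * ((acc) - 0.44)
      }

      ## block 3: log sigma_a (global: rescales every deviation)
      if (is.null(fix_sigma)) {
        prop_ls <- st$ls + stats::rnorm(1, 0, exp(sc$ls))
        s_new <- exp(prop_ls)
        mu_new <- exp(st$a[os] + s_new * st$z[gi] - st$q[os] * oE)
        llg_new <- group_ll_all(y, mu_new, theta, gi, G)
        d <- sum(llg_new - ll_g) +
          prior_logpdf(s_new, priors$sigma_a) + prop_ls -
          prior_logpdf(sigma, priors$sigma_a) - st$ls
        acc <- is.finite(d) && log(stats::runif(1)) < d
        if (acc) { st$ls <- prop_ls; sigma <- s_new; ll_g <- llg_new }
        accept_tot["sigma"] <- accept_tot["sigma"] + acc
        accept_n["sigma"] <- accept_n["sigma"] + 1
        if (adapting) sc$ls <- sc$ls + rate * (acc - 0.44)
      }

      ## block 4: mortality q_s (independent across streams)
      if (q_signed) {
        prop_q <- st$q + stats::rnorm(S, 0, exp(sc$q))
        jac <- 0
      } else {
        # log-scale walk keeps q > 0; Jacobian log(q') - log(q)
        prop_q <- st$q * exp(stats::rnorm(S, 0, exp(sc$q)))
        jac <- log(prop_q) - log(st$q)
      }
      mu_new <- exp(st$a[os] + sigma * st$z[gi] - prop_q[os] * oE)
      llg_new <- group_ll_all(y, mu_new, theta, gi, G)
      d_ll <- rowsum(llg_new - ll_g, gs)[, 1]
      d <- d_ll + prior_logpdf(prop_q, priors$q) -
        prior_logpdf(st$q, priors$q) + jac
      acc <- log(stats::runif(S)) < d & is.finite(d)
      if (any(acc)) {
        st$q[acc] <- prop_q[acc]
        upd <- gs %in% which(acc)
        ll_g[upd] <- llg_new[upd]
      }
      accept_tot["q"] <- accept_tot["q"] + mean(acc)
      accept_n["q"] <- accept_n["q"] + 1
      if (adapting) sc$q <- sc$q + rate * ((acc) - 0.44)

      ## block 4b: ridge shear on (a_s, q_s) for streams with releases
      ridge <- which(Ebar > 0)
      if (length(ridge)) {
        delta <- numeric(S)
        delta[ridge] <- stats::rnorm(length(ridge), 0, exp(sc$r[ridge]))
        prop_a <- st$a + delta
        prop_q <- st$q + delta / pmax(Ebar, 1e-12)
        ok <- q_signed | prop_q >= 0
        mu_new <- exp(prop_a[os] + sigma * st$z[gi] - prop_q[os] * oE)
        llg_new <- group_ll_all(y, mu_new, theta, gi, G)
        d_ll <- rowsum(llg_new - ll_g, gs)[, 1]
        d <- d_ll +
          prior_logpdf(prop_a, priors$a) - prior_logpdf(st$a, priors$a) +
          prior_logpdf(prop_q, priors$q) - prior_logpdf(st$q, priors$q)
        acc <- ok & is.finite(d) & log(stats::runif(S)) < d
        acc[-ridge] <- FALSE
        if (any(acc)) {
          st$a[acc] <- prop_a[acc]
          st$q[acc] <- prop_q[acc]
          upd <- gs %in% which(acc)
          ll_g[upd] <- llg_new[upd]
        }
        accept_tot["ridge"] <- accept_tot["ridge"] + mean(acc[ridge])
        accept_n["ridge"] <- accept_n["ridge"] + 1
        if (adapting) sc$r[ridge] <- sc$r[ridge] + rate * (acc[ridge] - 0.44)
      }

      ## block 5: log theta (global)
      if (is.null(fix_theta)) {
        prop_lt <- st$lt + stats::rnorm(1, 0, exp(sc$lt))
        t_new <- exp(prop_lt)
        mu_cur <- exp(st$a[os] + sigma * st$z[gi] - st$q[os] * oE)
        llg_new <- group_ll_all(y, mu_cur, t_new, gi, G)
        d <- sum(llg_new - ll_g) +
          prior_logpdf(t_new, priors$theta) + prop_lt -
          prior_logpdf(theta, priors$theta) - st$lt
        acc <- is.finite(d) && log(stats::runif(1)) < d
        if (acc) { st$lt <- prop_lt; theta <- t_new; ll_g <- llg_new }
        accept_tot["theta"] <- accept_tot["theta"] + acc
        accept_n["theta"] <- accept_n["theta"] + 1
        if (adapting) sc$lt <- sc$lt + rate * (acc - 0.44)
      }

      if (it > warmup) {
        draws[it - warmup, ch, ] <- c(st$a, sigma * st$z, sigma, st$q, theta)
      }
    }
  }

  rhat <- apply(draws, 3, function(m) split_rhat(m))
  names(rhat) <- par_names
  fixed <- c(if (!is.null(fix_sigma)) "sigma_a",
             if (!is.null(fix_theta)) "theta",
             if (a_dev_zero) "a_dev")
  structure(list(
    draws = draws,
    rhat = rhat,
    accept = ifelse(accept_n > 0, accept_tot / accept_n, NA),
    metadata = list(
      sampler = paste("adaptive random-walk Metropolis-within-Gibbs;",
                      "non-centered year deviations; log-scale positive",
                      "parameters; warmup-only adaptation targeting 0.44"),
      chains = chains, iter = iter, warmup = warmup, kept = kept,
      seed = as.integer(seed), chain_seeds = chain_seeds,
      fixed = fixed, q_signed = q_signed,
      streams = streams, groups = groups$group)),
    class = "smr_posterior")
}

# log-posterior in sampler coordinates, also returning per-group loglik
sampler_lp <- function(st, priors, y, os, gi, oE, G, q_signed) {
  sigma <- exp(st$ls)
  theta <- exp(st$lt)
  mu <- exp(st$a[os] + sigma * st$z[gi] - st$q[os] * oE)
  ll_g <- group_ll_all(y, mu, theta, gi, G)
  lp <- sum(ll_g) + sum(prior_logpdf(st$a, priors$a)) +
    sum(stats::dnorm(st$z, log = TRUE)) +
    prior_logpdf(sigma, priors$sigma_a) + st$ls +
    sum(prior_logpdf(st$q, priors$q)) + (if (q_signed) 0 else sum(log(st$q))) +
    prior_logpdf(theta, priors$theta) + st$lt
  list(lp = lp, ll_g = ll_g)
}

#' Split-chain potential scale reduction (split-R-hat)
#'
#' Gelman-Rubin diagnostic computed after splitting each chain in half, so
#' within-chain trends register as between-chain disagreement. Values near 1
#' indicate the chains sample the same distribution; >= 1 by construction up
#' to numerical tolerance. Constant draws return NA.
#'
#' @param x a matrix of post-warmup draws (iterations x chains), or an
#'   `smr_posterior` object (R-hat per parameter).
#' @param ... unused.
#' @return scalar R-hat, or a named vector for `smr_posterior` input.
#' @export
split_rhat <- function(x, ...) UseMethod("split_rhat")

#' @rdname split_rhat
#' @export
split_rhat.smr_posterior <- function(x, ...) {
  apply(x$draws, 3, function(m) split_rhat(m))
}

#' @rdname split_rhat
#' @export
split_rhat.default <- function(x, ...) {
  m <- as.matrix(x)
  n2 <- nrow(m) %/% 2
  if (n2 < 2 || ncol(m) < 1) smr_stop("need >= 4 draws per chain")
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(n2), j], m[n2 + seq_len(n2), j])
  }))
  mch <- ncol(halves)
  n <- n2
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  var_hat <- (n - 1) / n * W + B / n
  sqrt(var_hat / W)
}

#' Extract posterior draws as a matrix
#'
#' @param x an `smr_posterior` object.
#' @param ... unused.
#' @return matrix with one row per kept draw (chains stacked) and one column
#'   per parameter.
#' @export
as.matrix.smr_posterior <- function(x, ...) {
  d <- x$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[2]), function(ch) d[, ch, ]))
  colnames(out) <- dimnames(d)[[3]]
  out
}

#' Posterior draws of a single parameter
#'
#' @param fit an `smr_posterior` object.
#' @param parameter parameter name, e.g. `"q[Pigeon]"` or `"sigma_a"`.
#' @return numeric vector of draws, chains stacked.
#' @export
posterior_draws <- function(fit, parameter) {
  nm <- dimnames(fit$draws)[[3]]
  if (!parameter %in% nm) {
    smr_stop("unknown parameter '", parameter, "'; available: ",
             paste(utils::head(nm, 8), collapse = ", "), ", ...")
  }
  as.vector(fit$draws[, , match(parameter, nm)])
}

#' Per-stream percent-reduction effect summary
#'
#' Applies [percent_reduction()] to every posterior draw of each stream's
#' mortality parameter q_s at effort E and reports the posterior median and
#' central 95% credible interval — the scale on which release effects are
#' communicated (percent reduction in age-1 recruitment per 1000 sterile
#' males at the default E = 1).
#'
#' @param fit an `smr_posterior` object.
#' @param E effort at which to evaluate the reduction (default 1).
#' @return data.frame with columns `stream`, `E`, `median`, `lower95`,
#'   `upper95` (percent).
#' @export
summarize_effect <- function(fit, E = 1) {
  streams <- fit$metadata$streams
  out <- do.call(rbind, lapply(streams, function(s) {
    q <- posterior_draws(fit, paste0("q[", s, "]"))
    pr <- percent_reduction(pmax(q, 0), E)
    qs <- stats::quantile(pr, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(stream = s, E = E, median = qs[2], lower95 = qs[1],
               upper95 = qs[3], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.smr_posterior <- function(x, ...) {
  md <- x$metadata
  cat("Recruitment-model posterior:", md$chains, "chains x", md$kept,
      "kept draws (", md$iter, "iterations, warmup", md$warmup, ")\n")
  cat("Sampler:", md$sampler, "\n")
  cat("Seed:", md$seed, "\n")
  if (length(md$fixed)) cat("Fixed:", paste(md$fixed, collapse = ", "), "\n")
  cat(sprintf("Split-R-hat: max %.3f (%s)\n", max(x$rhat, na.rm = TRUE),
              names(x$rhat)[which.max(x$rhat)]))
  print(summarize_effect(x), digits = 3)
  invisible(x)
}

#' Write posterior draws to a long-format CSV
#'
#' Columns `chain`, `iteration`, `parameter`, `value`; one row per kept draw
#' per parameter.
#'
#' @param fit an `smr_posterior` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  kept <- dim(d)[1]; nch <- dim(d)[2]
  pn <- dimnames(d)[[3]]
  long <- data.frame(
    chain = rep(rep(seq_len(nch), each = kept), times = length(pn)),
    iteration = rep(seq_len(kept), times = nch * length(pn)),
    parameter = rep(pn, each = kept * nch),
    value = as.vector(d))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
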