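#' Prior specification
#'
#' Independent normal priors on each component of beta, alpha and xi, and a
#' uniform prior on sigma over (0, sigma_max). Defaults are weakly
#' informative (normal sd 10), the common choice in SCR practice; sigma_max
#' defaults (at fit time) to half the domain diameter.
#'
#' @param beta_mean,beta_sd,alpha_mean,alpha_sd,xi_mean,xi_sd normal prior
#'   moments (scalars, recycled across components; sd > 0).
#' @param sigma_max upper bound of the uniform prior on sigma, or NA to use
#'   half the domain diameter.
#' @return object of class \code{scr_prior}.
#' @export
scr_prior <- function(beta_mean = 0, beta_sd = 10, alpha_mean = 0,
                      alpha_sd = 10, xi_mean = 0, xi_sd = 10,
                      sigma_max = NA_real_) {
  stopifnot(beta_sd > 0, alpha_sd > 0, xi_sd > 0,
            is.na(sigma_max) || sigma_max > 0)
  structure(list(beta_mean = beta_mean, beta_sd = beta_sd,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 xi_mean = xi_mean, xi_sd = xi_sd, sigma_max = sigma_max),
            class = "scr_prior")
}

#' MCMC configuration
#'
#' @param iterations total MCMC iterations (the survey protocol in the
#'   package's simulation experiments is 1200).
#' @param burn_in iterations discarded before summaries (default 200);
#'   proposal-scale adaptation runs only during burn-in and is frozen
#'   afterwards so the stationary target is untouched.
#' @param seed master seed; every random draw in the chain derives from it
#'   via per-iteration streams, so the first m iterations are identical
#'   whatever the total length.
#' @param scale_theta named list of initial random-walk scales for blocks
#'   \code{beta}, \code{alpha}, \code{xi}, \code{logsigma}.
#' @param scale_centers initial random-walk scale for activity-center moves
#'   (coordinate units), or NA to use sigma's initial value.
#' @param adapt logical; adapt proposal scales during burn-in (target
#'   acceptance 0.25 for vector blocks, 0.44 for scalar moves).
#' @return object of class \code{scr_mcmc_config}.
#' @export
scr_mcmc_config <- function(iterations = 1200L, burn_in = 200L, seed = 1L,
                            scale_theta = list(beta = 0.1, alpha = 0.1,
                                               xi = 0.1, logsigma = 0.05),
                            scale_centers = NA_real_, adapt = TRUE) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  stopifnot(iterations >= 1L, burn_in >= 0L, burn_in < iterations)
  structure(list(iterations = iterations, burn_in = burn_in,
                 seed = as.integer(seed), scale_theta = scale_theta,
                 scale_centers = scale_centers, adapt = isTRUE(adapt)),
            class = "scr_mcmc_config")
}

# per-iteration stream seed: mixes the master seed and the iteration index
# so chain prefixes do not depend on the total iteration count
iter_seed <- function(master, iter) {
  h <- (as.double(master %% 2147483647L) * 48271) %% 2147483647
  as.integer((h + as.double(iter) * 69621) %% 2147483647)
}

log_prior_theta <- function(params, prior, model) {
  lp <- sum(stats::dnorm(params$beta, prior$beta_mean, prior$beta_sd, log = TRUE)) +
    sum(stats::dnorm(params$alpha, prior$alpha_mean, prior$alpha_sd, log = TRUE))
  if (model == "full" && !is.null(params$xi))
    lp <- lp + sum(stats::dnorm(params$xi, prior$xi_mean, prior$xi_sd, log = TRUE))
  if (params$sigma >= prior$sigma_max) return(-Inf)
  lp  # uniform sigma prior contributes a constant on (0, sigma_max)
}

#' Gibbs draw of the never-detected count n0
#'
#' The full conditional of n0 in the augmented likelihood is Poisson with
#' mean pi0 * Lambda(B).
#'
#' @inheritParams pi0
#' @param rfun Poisson sampler, default \code{stats::rpois} (injectable for
#'   testing).
#' @return a nonnegative integer draw.
#' @export
update_n0 <- function(params, domain, traps, schedule = NULL,
                      model = c("full", "restricted"), rfun = stats::rpois) {
  model <- match.arg(model)
  p0 <- pi0(params, domain, traps, schedule, model)
  Lam <- lambda_integral(params, domain)
  rfun(1L, p0 * Lam)
}

# data-driven starting values
default_inits <- function(survey, domain, schedule, model) {
  traps <- survey$traps
  n <- survey$n
  centers <- matrix(0, n, 2L)
  sig0 <- NULL
  for (i in seq_len(n)) {
    wk <- survey$y[i, ]
    centers[i, ] <- colSums(traps$xy * wk) / sum(wk)
    if (sum(wk > 0) > 1L) {
      mu <- centers[i, ]
      sig0 <- c(sig0, sqrt(sum(wk * ((traps$xy[, 1] - mu[1])^2 +
                                       (traps$xy[, 2] - mu[2])^2)) / sum(wk)))
    }
  }
  # snap any centroid that fell outside habitat to the nearest habitat cell
  ok <- in_habitat(domain, centers)
  if (any(!ok)) {
    cellsU <- domain$centers[domain$mask, , drop = FALSE]
    for (i in which(!ok)) {
      d2 <- (cellsU[, 1] - centers[i, 1])^2 + (cellsU[, 2] - centers[i, 2])^2
      centers[i, ] <- cellsU[which.min(d2), ]
    }
  }
  diam <- sqrt(diff(domain$bounds[1:2])^2 + diff(domain$bounds[3:4])^2)
  sigma <- if (length(sig0)) max(stats::median(sig0), 1e-3) else diam / 10
  area <- domain_area(domain)
  beta <- c(log(max(n, 1) / area), rep(0, ncol(domain$V) - 1L))
  rate <- sum(survey$y) / max(1, n * mean(traps$T))
  alpha <- c(log(max(rate, 1e-4)), rep(0, ncol(traps$W) - 1L))
  xi <- if (model == "full" && !is.null(schedule)) rep(0, schedule$q) else NULL
  list(params = scr_params(beta, alpha, sigma, xi),
       latent = scr_latent(centers, n0 = max(1L, round(n / 4))))
}

#' Fit a continuous-time SCR model by MCMC
#'
#' Metropolis-within-Gibbs sampler for the posterior of the full
#' (time-inhomogeneous) or restricted (time-homogeneous) model. Each
#' iteration updates, in order: the parameter blocks beta, alpha, xi (full
#' model only) and log sigma by random-walk Metropolis against the observed-
#' data log-likelihood plus log prior; the n observed individuals' activity
#' centers by per-individual Gaussian random-walk Metropolis (proposals
#' landing outside habitat are rejected); and n0 by an exact Gibbs draw from
#' Poisson(pi0 * Lambda(B)).
#'
#' @param survey an \code{scr_survey}.
#' @param domain an \code{scr_domain}.
#' @param schedule an \code{scr_schedule} (required for the full model unless
#'   a constant-gamma fit is intended; ignored by the restricted model).
#' @param prior an \code{scr_prior}.
#' @param config an \code{scr_mcmc_config}.
#' @param model "full" or "restricted".
#' @param inits optional list(params =, latent =) starting state; defaults
#'   are data-driven (detection centroids, moment-matched sigma and rates).
#' @return An object of class \code{scr_chain}: list with \code{draws} (a
#'   data frame of retained iterations: theta columns and n0), \code{centers}
#'   (n x 2 x retained array), \code{acceptance} (post-burn-in rates),
#'   \code{model}, \code{config}, \code{prior}, \code{par_names}.
#' @export
run_chain <- function(survey, domain, schedule = NULL, prior = scr_prior(),
                      config = scr_mcmc_config(),
                      model = c("full", "restricted"), inits = NULL) {
  model <- match.arg(model)
  traps <- survey$traps
  if (model == "restricted") schedule <- NULL
  if (is.na(prior$sigma_max)) {
    diam <- sqrt(diff(domain$bounds[1:2])^2 + diff(domain$bounds[3:4])^2)
    prior$sigma_max <- diam / 2
  }
  e <- build_lik_env(survey, domain, schedule)
  if (is.null(inits)) inits <- default_inits(survey, domain, schedule, model)
  params <- inits$params
  centers <- inits$latent$centers
  n0 <- inits$latent$n0
  n <- survey$n
  use_xi <- model == "full" && !is.null(params$xi)

  blocks <- c("beta", "alpha", if (use_xi) "xi", "logsigma")
  scales <- config$scale_theta
  sc_centers <- if (is.na(config$scale_centers)) params$sigma else config$scale_centers
  target <- function(b) if (b %in% c("logsigma")) 0.44 else 0.25
  acc_n <- stats::setNames(numeric(length(blocks)), blocks)
  acc_d <- acc_n
  acc_centers <- c(0, 0)

  nkeep <- config$iterations - config$burn_in
  pnames <- c(paste0("beta", seq_along(params$beta) - 1L),
              paste0("alpha", seq_along(params$alpha) - 1L),
              if (use_xi) paste0("xi", seq_along(params$xi) - (length(params$xi) == 1L)),
              "sigma")
  if (use_xi && length(params$xi) == 1L) pnames[pnames == "xi0"] <- "xi"
  draws <- matrix(NA_real_, nkeep, length(pnames) + 1L,
                  dimnames = list(NULL, c(pnames, "n0")))
  kept_centers <- array(NA_real_, c(n, 2L, nkeep))

  curll <- loglik_core(e, params, centers, n0, model)
  if (!is.finite(curll)) stop("non-finite log-posterior at the initial state")
  psiGam <- function(p) {
    psi <- exp(drop(traps$W %*% p$alpha))
    Gam <- if (model == "full") schedule_gamma_integral(e$schedule, p$xi, traps)
           else traps$T
    psi * Gam
  }

  for (it in seq_len(config$iterations)) {
    set.seed(iter_seed(config$seed, it))
    adapting <- config$adapt && it <= config$burn_in

    # -- theta blocks ---------------------------------------------------
    curll <- loglik_core(e, params, centers, n0, model)
    curlp <- curll + log_prior_theta(params, prior, model)
    for (b in blocks) {
      prop <- params
      if (b == "beta") prop$beta <- prop$beta + stats::rnorm(length(prop$beta), 0, scales$beta)
      if (b == "alpha") prop$alpha <- prop$alpha + stats::rnorm(length(prop$alpha), 0, scales$alpha)
      if (b == "xi") prop$xi <- prop$xi + stats::rnorm(length(prop$xi), 0, scales$xi)
      if (b == "logsigma") prop$sigma <- exp(log(prop$sigma) + stats::rnorm(1, 0, scales$logsigma))
      lpr <- log_prior_theta(prop, prior, model)
      lr <- -Inf
      if (is.finite(lpr)) {
        pll <- loglik_core(e, prop, centers, n0, model)
        # log-scale walk on sigma: Jacobian d sigma / d log sigma = sigma
        jac <- if (b == "logsigma") log(prop$sigma) - log(params$sigma) else 0
        lr <- pll + lpr + jac - curlp
      }
      acc <- is.finite(lr) && log(stats::runif(1)) < lr
      if (acc) { params <- prop; curlp <- pll + lpr; curll <- pll }
      if (it > config$burn_in) { acc_n[b] <- acc_n[b] + acc; acc_d[b] <- acc_d[b] + 1 }
      if (adapting)
        scales[[b]] <- scales[[b]] * exp((as.numeric(acc) - target(b)) / sqrt(it))
    }

    # -- activity centers (vectorized per-individual MH) ----------------
    if (n > 0) {
      pg <- psiGam(params)
      s2 <- 2 * params$sigma^2
      propc <- centers + matrix(stats::rnorm(2L * n, 0, sc_centers), n, 2L)
      okp <- in_habitat(domain, propc)
      D2cur <- sq_dist_mat(centers, traps$xy)
      D2prp <- sq_dist_mat(propc, traps$xy)
      icur <- cell_index(domain, centers)
      lamcur <- drop(domain$V[icur, , drop = FALSE] %*% params$beta)
      lamprp <- rep(-Inf, n)
      iprp <- cell_index(domain, propc)
      lamprp[okp] <- drop(domain$V[iprp[okp], , drop = FALSE] %*% params$beta)
      delta <- (lamprp - lamcur) -
        drop((exp(-D2prp / s2) - exp(-D2cur / s2)) %*% pg) -
        (rowSums(e$y * D2prp) - rowSums(e$y * D2cur)) / s2
      accv <- okp & log(stats::runif(n)) < delta
      centers[accv, ] <- propc[accv, ]
      rate <- mean(accv)
      if (it > config$burn_in) acc_centers <- acc_centers + c(sum(accv), n)
      if (adapting)
        sc_centers <- sc_centers * exp((rate - 0.25) / sqrt(it))
    }

    # -- n0 Gibbs draw ---------------------------------------------------
    lamU <- exp(drop(e$Vu %*% params$beta))
    Lam <- sum(lamU) * e$area
    G <- lik_env_kernel(e, params$sigma)
    PhiTot <- drop(G %*% psiGam(params))
    p0 <- sum(lamU * exp(-PhiTot)) * e$area / Lam
    n0 <- stats::rpois(1L, p0 * Lam)

    if (it > config$burn_in) {
      j <- it - config$burn_in
      draws[j, ] <- c(params$beta, params$alpha, if (use_xi) params$xi,
                      params$sigma, n0)
      kept_centers[, , j] <- centers
    }
  }

  acc_rates <- ifelse(acc_d > 0, acc_n / acc_d, NA_real_)
  structure(list(
    draws = as.data.frame(draws),
    centers = kept_centers,
    acceptance = c(as.list(acc_rates),
                   centers = if (acc_centers[2] > 0) acc_centers[1] / acc_centers[2] else NA_real_),
    model = model, config = config, prior = prior,
    par_names = pnames, n = n,
    final_scales = c(scales, centers = sc_centers)),
    class = "scr_chain")
}

#' @export
print.scr_chain <- function(x, ...) {
  cat(sprintf("scr_chain (%s model): %d retained iterations, %d individuals\n",
              x$model, nrow(x$draws), x$n))
  print(summarize_chain(x))
  invisible(x)
}

#' Posterior summaries of a chain
#'
#' Mean, empirical 2.5/97.5 percentiles, and Monte Carlo standard error of
#' the mean by the batch-means method with floor(sqrt(m)) batches.
#'
#' @param chain an \code{scr_chain}, or a data frame / matrix of draws.
#' @return data frame with columns parameter, mean, q2.5, q97.5, mcse.
#' @export
summarize_chain <- function(chain) {
  d <- if (inherits(chain, "scr_chain")) chain$draws else as.data.frame(chain)
  m <- nrow(d)
  if (m < 10L) stop("chain too short to summarize (need >= 10 draws)")
  nb <- floor(sqrt(m))
  bsize <- floor(m / nb)
  res <- lapply(names(d), function(p) {
    v <- d[[p]]
    bm <- vapply(seq_len(nb), function(b)
      mean(v[((b - 1L) * bsize + 1L):(b * bsize)]), 0)
    mcse <- if (stats::sd(v) == 0) 0 else stats::sd(bm) / sqrt(nb)
    data.frame(parameter = p, mean = mean(v),
               q2.5 = unname(stats::quantile(v, 0.025, type = 7)),
               q97.5 = unname(stats::quantile(v, 0.975, type = 7)),
               mcse = mcse)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
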