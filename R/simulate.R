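# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded smooth covariate surface
#'
#' Generates a smooth spatial covariate as a random low-frequency cosine
#' field, standardized to mean 0 and standard deviation 1 across the grid
#' cells. Deterministic given the seed. This is the package's stand-in for
#' externally supplied covariate rasters: it reproduces the qualitative
#' structure (smooth spatial variation on the scale of the region) used in
#' the package's simulation experiments.
#'
#' @param domain an \code{scr_domain}.
#' @param seed integer seed controlling the field.
#' @param n_basis number of cosine components (default 12).
#' @param max_wavenumber largest integer wavenumber per axis (default 3);
#'   smaller values give smoother fields.
#' @return numeric vector of per-cell covariate values, with attribute
#'   \code{fun}: a function(points) evaluating the same standardized surface
#'   at arbitrary coordinates (e.g. trap locations).
#' @export
gen_covariate_surface <- function(domain, seed, n_basis = 12L,
                                  max_wavenumber = 3L) {
  Lx <- diff(domain$bounds[1:2]); Ly <- diff(domain$bounds[3:4])
  basis <- with_local_seed(seed, {
    kx <- sample(0:max_wavenumber, n_basis, replace = TRUE)
    ky <- sample(0:max_wavenumber, n_basis, replace = TRUE)
    zero <- kx == 0 & ky == 0
    kx[zero] <- 1L
    amp <- stats::rnorm(n_basis) / (1 + kx^2 + ky^2)
    ph <- stats::runif(n_basis, 0, 2 * pi)
    list(kx = kx, ky = ky, amp = amp, ph = ph)
  })
  raw <- function(pts) {
    out <- numeric(nrow(pts))
    for (j in seq_len(n_basis))
      out <- out + basis$amp[j] *
        cos(2 * pi * (basis$kx[j] * (pts[, 1] - domain$bounds[1]) / Lx +
                        basis$ky[j] * (pts[, 2] - domain$bounds[3]) / Ly) +
              basis$ph[j])
    out
  }
  v <- raw(domain$centers)
  mu <- mean(v[domain$mask]); sdv <- stats::sd(v[domain$mask])
  if (sdv == 0) sdv <- 1
  std <- (v - mu) / sdv
  fun <- function(pts) (raw(as.matrix(pts)) - mu) / sdv
  structure(std, fun = fun)
}

#' Simulation configuration
#'
#' Defaults encode the package's reference simulation experiment: a square
#' region holding a centered 10 x 10 array of evenly spaced traps operating
#' for 30 time units with equal day/night split; activity-center density
#' lambda(s) = exp(1.4 + 0.8 v(s)) over a smooth seeded covariate surface
#' v; trap baseline rate psi_k = exp(-0.7 + 1.0 w(x_k)) over a second
#' surface w; daytime detection-rate multiplier exp(xi) with xi = -1; and
#' movement scale sigma = 0.4. The region side (5.2 units at trap spacing
#' 0.5) makes the expected abundance Lambda(B) about 150 under the default
#' density surface.
#'
#' @param beta,alpha,xi,sigma generating parameters.
#' @param side region side length; the region is (0, side)^2.
#' @param resolution quadrature-grid cell side.
#' @param traps_side,trap_spacing square trap-array dimensions; the array is
#'   centered in the region.
#' @param T_op operating duration of every trap (time units).
#' @param day_fraction fraction of each time unit that is daytime.
#' @param density_surface_seed,detection_surface_seed seeds of the two
#'   covariate surfaces (fixed across replicates by default).
#' @return object of class \code{scr_sim_config}.
#' @export
sim_config <- function(beta = c(1.4, 0.8), alpha = c(-0.7, 1.0), xi = -1,
                       sigma = 0.4, side = 5.2, resolution = 0.1,
                       traps_side = 10L, trap_spacing = 0.5, T_op = 30,
                       day_fraction = 0.5,
                       density_surface_seed = 101L,
                       detection_surface_seed = 202L) {
  stopifnot(T_op > 0, day_fraction >= 0, day_fraction <= 1, sigma > 0)
  structure(as.list(environment()), class = "scr_sim_config")
}

#' Build the domain, trap array and schedule of a simulation configuration
#'
#' @param config an \code{scr_sim_config}.
#' @return list(domain, traps, schedule, params) where params holds the
#'   generating \code{scr_params}; the domain carries the density covariate
#'   and the traps the detection covariate.
#' @export
sim_design <- function(config) {
  bounds <- c(0, config$side, 0, config$side)
  base <- build_grid(bounds, config$resolution)
  vsurf <- gen_covariate_surface(base, config$density_surface_seed)
  wsurf <- gen_covariate_surface(base, config$detection_surface_seed)
  vfun <- attr(vsurf, "fun")
  domain <- build_grid(bounds, config$resolution,
                       covariate_fields = function(p) cbind(v = vfun(p)))
  span <- (config$traps_side - 1L) * config$trap_spacing
  off <- (config$side - span) / 2
  g <- seq(0, span, by = config$trap_spacing) + off
  xy <- cbind(rep(g, times = config$traps_side), rep(g, each = config$traps_side))
  wfun <- attr(wsurf, "fun")
  traps <- scr_traps(xy, durations = config$T_op,
                     covariates = cbind(w = wfun(xy)))
  schedule <- equal_split_schedule(traps, config$day_fraction)
  params <- scr_params(config$beta, config$alpha, config$sigma, config$xi)
  list(domain = domain, traps = traps, schedule = schedule, params = params)
}

#' Simulate activity centers from the spatial Poisson process
#'
#' N ~ Poisson(Lambda(B)); centers are iid with cell probabilities
#' proportional to lambda_m, uniformly jittered within the drawn cell.
#'
#' @param params an \code{scr_params}.
#' @param domain an \code{scr_domain}.
#' @return N x 2 matrix of centers (N random).
#' @export
simulate_population <- function(params, domain) {
  lamU <- exp(drop(domain$V[domain$mask, , drop = FALSE] %*% params$beta))
  Lam <- sum(lamU) * domain$cell_area
  N <- stats::rpois(1L, Lam)
  if (N == 0L) return(matrix(numeric(0), 0L, 2L))
  cellsU <- domain$centers[domain$mask, , drop = FALSE]
  idx <- sample.int(nrow(cellsU), N, replace = TRUE, prob = lamU)
  half <- domain$resolution / 2
  cellsU[idx, , drop = FALSE] + matrix(stats::runif(2L * N, -half, half), N, 2L)
}

#' Simulate detection histories for a set of activity centers
#'
#' For each (individual, trap) pair the detection process is an
#' inhomogeneous Poisson process with rate
#' psi_k gamma(z(t)) exp(-d^2 / (2 sigma^2)). With the default exact
#' sampler, a total count is drawn as Poisson(Phi_ik), detections are
#' allocated to schedule segments with probabilities proportional to
#' exp(xi' z_seg) * segment length, and times are uniform within their
#' segment (exact for piecewise-constant z). The thinning sampler draws a
#' dominating homogeneous process at the maximum segment rate and keeps each
#' point with probability gamma(t)/gamma_max; it is exact for any
#' piecewise-constant path and is provided as a cross-check and for general
#' use.
#'
#' Individuals never detected at any trap are dropped (they are part of the
#' latent N - n).
#'
#' @param params generating \code{scr_params}.
#' @param centers N x 2 matrix of activity centers.
#' @param traps an \code{scr_traps}.
#' @param schedule an \code{scr_schedule} (NULL for a homogeneous process).
#' @param method "exact" or "thinning".
#' @return list(survey = \code{scr_survey} of the observed individuals,
#'   observed = integer indices into \code{centers} of those individuals).
#' @export
simulate_detections <- function(params, centers, traps, schedule = NULL,
                                method = c("exact", "thinning")) {
  method <- match.arg(method)
  N <- nrow(centers)
  K <- traps$K
  psi <- exp(drop(traps$W %*% params$alpha))
  Gam <- schedule_gamma_integral(schedule, params$xi, traps)
  if (N == 0L) {
    sv <- scr_survey(traps, matrix(0L, 0L, K), list())
    return(list(survey = sv, observed = integer(0)))
  }
  D2 <- sq_dist_mat(centers, traps$xy)
  kern <- exp(-D2 / (2 * params$sigma^2))
  base <- kern * rep(psi, each = N)           # psi_k * kernel, per (i, k)
  times <- NULL
  if (method == "exact") {
    Phi <- base * rep(Gam, each = N)
    y <- matrix(stats::rpois(N * K, Phi), N, K)
    times <- vector("list", N)
    for (i in seq_len(N)) times[[i]] <- rep(list(numeric(0)), K)
    nz <- which(y > 0L, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      i <- nz[r, 1L]; k <- nz[r, 2L]
      if (is.null(schedule)) {
        tt <- sort(stats::runif(y[i, k], 0, traps$T[k]))
      } else {
        seg <- schedule$segments[[k]]
        len <- seg$end - seg$start
        w <- len * if (is.null(params$xi)) 1 else exp(drop(seg$Z %*% params$xi))
        sidx <- sample.int(length(len), y[i, k], replace = TRUE, prob = w)
        tt <- sort(seg$start[sidx] + stats::runif(y[i, k]) * len[sidx])
      }
      times[[i]][[k]] <- tt
    }
  } else {
    y <- matrix(0L, N, K)
    times <- vector("list", N)
    for (i in seq_len(N)) times[[i]] <- rep(list(numeric(0)), K)
    for (k in seq_len(K)) {
      gmax <- if (is.null(schedule) || is.null(params$xi)) 1 else
        max(exp(drop(schedule$segments[[k]]$Z %*% params$xi)))
      for (i in seq_len(N)) {
        rate <- base[i, k] * gmax
        m <- stats::rpois(1L, rate * traps$T[k])
        if (m == 0L) next
        tt <- sort(stats::runif(m, 0, traps$T[k]))
        keep <- if (is.null(schedule) || is.null(params$xi)) {
          rep(TRUE, m)
        } else {
          g <- exp(drop(schedule_z_at(schedule, k, tt) %*% params$xi))
          stats::runif(m) < g / gmax
        }
        tt <- tt[keep]
        y[i, k] <- length(tt)
        times[[i]][[k]] <- tt
      }
    }
  }
  obs <- which(rowSums(y) > 0L)
  sv <- scr_survey(traps, y[obs, , drop = FALSE], times[obs])
  list(survey = sv, observed = obs)
}

#' Simulate a complete replicate survey
#'
#' Draws a population and its detection histories under a simulation
#' configuration. Covariate surfaces are fixed by the configuration's
#' surface seeds; the replicate seed drives the population and detection
#' randomness, so distinct replicate seeds give independent data sets on a
#' common design.
#'
#' @param config an \code{scr_sim_config}.
#' @param seed replicate seed.
#' @param design optional precomputed \code{sim_design(config)} (saves
#'   rebuilding the grid across replicates).
#' @return list(survey, domain, traps, schedule, truth) where truth records
#'   the generating params, N, all centers, and the observed indices.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L, design = NULL) {
  if (is.null(design)) design <- sim_design(config)
  res <- with_local_seed(seed, {
    centers <- simulate_population(design$params, design$domain)
    det <- simulate_detections(design$params, centers, design$traps,
                               design$schedule)
    list(centers = centers, det = det)
  })
  list(survey = res$det$survey,
       domain = design$domain, traps = design$traps,
       schedule = design$schedule,
       truth = list(params = design$params, N = nrow(res$centers),
                    centers = res$centers, observed = res$det$observed,
                    seed = seed))
}

#' Multi-replicate parameter-recovery experiment
#'
#' Simulates replicate surveys from a common design, fits the full and/or
#' restricted model to each by MCMC, and tabulates for every parameter the
#' average posterior mean across replicates and the coverage of 95% credible
#' intervals (the proportion of replicates whose interval contains the
#' generating value).
#'
#' @param n_reps number of replicate surveys.
#' @param config an \code{scr_sim_config}.
#' @param models character vector, subset of c("full", "restricted").
#' @param iterations,burn_in MCMC protocol per fit.
#' @param seed master seed; replicate r uses seed + r for data and fits.
#' @param prior an \code{scr_prior}.
#' @param verbose print per-replicate progress.
#' @return list with elements per model: list(summaries = per-replicate
#'   summary tables, table = data.frame(parameter, truth, average, coverage)),
#'   plus \code{truth} and \code{n_obs} (observed individuals per replicate).
#' @export
recover_study <- function(n_reps = 10L, config = sim_config(),
                          models = c("full", "restricted"),
                          iterations = 1200L, burn_in = 200L, seed = 1L,
                          prior = scr_prior(), verbose = FALSE) {
  design <- sim_design(config)
  truth <- design$params
  out <- list(truth = truth, n_obs = integer(n_reps))
  for (mdl in models) out[[mdl]] <- list(summaries = vector("list", n_reps))
  for (r in seq_len(n_reps)) {
    rep_seed <- iter_seed(seed, 7919L * r)
    sim <- simulate_study(config, seed = rep_seed, design = design)
    out$n_obs[r] <- sim$survey$n
    for (mdl in models) {
      cfg <- scr_mcmc_config(iterations = iterations, burn_in = burn_in,
                             seed = iter_seed(rep_seed, match(mdl, c("full", "restricted"))))
      ch <- run_chain(sim$survey, sim$domain,
                      schedule = if (mdl == "full") sim$schedule else NULL,
                      prior = prior, config = cfg, model = mdl)
      out[[mdl]]$summaries[[r]] <- summarize_chain(ch)
      if (verbose)
        message(sprintf("replicate %d/%d (%s): n = %d", r, n_reps, mdl,
                        sim$survey$n))
    }
  }
  for (mdl in models) {
    sums <- out[[mdl]]$summaries
    pn <- setdiff(sums[[1]]$parameter, "n0")
    truth_named <- c(
      stats::setNames(truth$beta, paste0("beta", seq_along(truth$beta) - 1L)),
      stats::setNames(truth$alpha, paste0("alpha", seq_along(truth$alpha) - 1L)),
      if (!is.null(truth$xi))
        stats::setNames(truth$xi,
                        if (length(truth$xi) == 1L) "xi"
                        else paste0("xi", seq_along(truth$xi))),
      sigma = truth$sigma)
    tab <- do.call(rbind, lapply(pn, function(p) {
      if (!p %in% names(truth_named)) return(NULL)
      means <- vapply(sums, function(s) s$mean[s$parameter == p], 0)
      lo <- vapply(sums, function(s) s$q2.5[s$parameter == p], 0)
      hi <- vapply(sums, function(s) s$q97.5[s$parameter == p], 0)
      tv <- truth_named[[p]]
      data.frame(parameter = p, truth = tv, average = mean(means),
                 mcse = stats::sd(means) / sqrt(length(means)),
                 coverage = mean(lo <= tv & tv <= hi))
    }))
    rownames(tab) <- NULL
    out[[mdl]]$table <- tab
  }
  out
}
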