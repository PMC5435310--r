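#' Model parameters
#'
#' Parameter vector theta = (beta, alpha, xi, sigma) of the continuous-time
#' SCR model. \code{beta} are log-scale coefficients of the activity-center
#' density surface log lambda(s) = beta' v(s); \code{alpha} are log-scale
#' coefficients of the trap baseline rate log psi_k = alpha' w_k; \code{xi}
#' are the temporal-covariate effects log gamma(t) = xi' z(t) (empty or NULL
#' in the restricted, time-homogeneous model); \code{sigma} (> 0) is the
#' Gaussian movement-scale in coordinate units.
#'
#' @param beta,alpha numeric coefficient vectors (first entry multiplies the
#'   intercept regressor 1).
#' @param sigma positive movement scale.
#' @param xi temporal effects, or NULL for the restricted model.
#' @return object of class \code{scr_params}.
#' @export
scr_params <- function(beta, alpha, sigma, xi = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !(sigma > 0))
    stop("sigma must be a positive scalar")
  if (!is.null(xi) && length(xi) == 0L) xi <- NULL
  structure(list(beta = as.numeric(beta), alpha = as.numeric(alpha),
                 xi = if (is.null(xi)) NULL else as.numeric(xi),
                 sigma = as.numeric(sigma)),
            class = "scr_params")
}

#' @export
print.scr_params <- function(x, ...) {
  cat("scr_params:\n")
  cat("  beta :", paste(signif(x$beta, 4), collapse = ", "), "\n")
  cat("  alpha:", paste(signif(x$alpha, 4), collapse = ", "), "\n")
  if (!is.null(x$xi)) cat("  xi   :", paste(signif(x$xi, 4), collapse = ", "), "\n")
  cat("  sigma:", signif(x$sigma, 4), "\n")
  invisible(x)
}

#' Latent state: activity centers of observed individuals and n0
#'
#' @param centers n x 2 matrix of activity centers for the n observed
#'   individuals.
#' @param n0 nonnegative count of never-detected individuals (data
#'   augmentation variable).
#' @export
scr_latent <- function(centers, n0) {
  centers <- matrix(as.numeric(centers), ncol = 2L)
  n0 <- as.integer(n0)
  if (is.na(n0) || n0 < 0L) stop("n0 must be a nonnegative integer")
  structure(list(centers = centers, n0 = n0), class = "scr_latent")
}

#' Survey data: detection counts and detection times
#'
#' @param traps an \code{scr_traps}.
#' @param y n x K matrix of detection counts (nonnegative integers).
#' @param times list of length n; element i is a list of length K of sorted
#'   numeric vectors, \code{times[[i]][[k]]} holding the y[i,k] detection
#'   times of individual i at trap k on that trap's clock (0, T_k].
#' @param id optional individual identifiers.
#' @details Tied detection times are permitted (real camera data contain
#'   duplicate timestamps even though the Poisson process assigns ties
#'   probability zero); a warning is issued when ties are present.
#' @return object of class \code{scr_survey} with fields \code{traps},
#'   \code{y}, \code{times}, \code{n}, \code{id}.
#' @export
scr_survey <- function(traps, y, times, id = NULL) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n > 0 && ncol(y) != traps$K) stop("y must have one column per trap")
  if (any(y < 0) || any(y != round(y))) stop("y must contain nonnegative integers")
  storage.mode(y) <- "integer"
  if (length(times) != n) stop("times must have one element per individual")
  ties <- FALSE
  for (i in seq_len(n)) {
    if (length(times[[i]]) != traps$K) stop("times[[i]] must have one entry per trap")
    for (k in seq_len(traps$K)) {
      tk <- times[[i]][[k]]
      if (length(tk) != y[i, k])
        stop(sprintf("individual %d, trap %d: %d times but y = %d",
                     i, k, length(tk), y[i, k]))
      if (length(tk)) {
        if (any(tk <= 0) || any(tk > traps$T[k] + 1e-9))
          stop(sprintf("individual %d, trap %d: time outside (0, T_k]", i, k))
        if (is.unsorted(tk)) times[[i]][[k]] <- sort(tk)
        if (anyDuplicated(tk)) ties <- TRUE
      }
    }
  }
  if (ties) warning("tied detection times present; density product keeps them")
  if (is.null(id)) id <- seq_len(n)
  structure(list(traps = traps, y = y, times = times, n = n, id = id),
            class = "scr_survey")
}

#' @export
print.scr_survey <- function(x, ...) {
  cat(sprintf("scr_survey: %d individuals, %d traps, %d detections\n",
              x$n, x$traps$K, sum(x$y)))
  invisible(x)
}

#' Expected density surface lambda(s)
#'
#' Evaluates lambda_m = exp(beta' v(c_m)) at every grid-cell center; masked
#' cells are returned as NA (they take no part in any integral).
#'
#' @param params an \code{scr_params}.
#' @param domain an \code{scr_domain}.
#' @return numeric vector, one value per grid cell.
#' @export
density_surface <- function(params, domain) {
  if (length(params$beta) != ncol(domain$V))
    stop("beta dimension does not match the domain's density covariates")
  lam <- exp(drop(domain$V %*% params$beta))
  lam[!domain$mask] <- NA_real_
  lam
}

#' Expected abundance Lambda(B)
#'
#' Midpoint-rule integral of the density surface over the habitat:
#' Lambda(B) = sum over unmasked cells of lambda_m times the cell area.
#'
#' @inheritParams density_surface
#' @return positive scalar.
#' @export
lambda_integral <- function(params, domain) {
  lam <- density_surface(params, domain)
  sum(lam[domain$mask]) * domain$cell_area
}

#' Multiplicative temporal effect gamma = exp(xi' z)
#'
#' @param params an \code{scr_params}.
#' @param z temporal covariate value(s) (length q), or a matrix with q
#'   columns for several time points.
#' @return gamma, positive; identically 1 when xi is NULL (restricted model).
#' @export
temporal_effect <- function(params, z) {
  if (is.null(params$xi)) {
    nz <- if (is.matrix(z)) nrow(z) else 1L
    return(rep(1, nz))
  }
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  if (ncol(zm) != length(params$xi))
    stop("z dimension does not match xi")
  exp(drop(zm %*% params$xi))
}

#' Detection-rate intensity phi(t, s, x_k)
#'
#' The instantaneous detection rate of an individual with activity center s
#' at trap k: phi = psi_k * gamma(z(t)) * exp(-||s - x_k||^2 / (2 sigma^2)),
#' with baseline psi_k = exp(alpha' w_k).
#'
#' @param params an \code{scr_params} (sigma > 0 enforced at construction).
#' @param traps an \code{scr_traps}.
#' @param k trap index.
#' @param s length-2 activity-center coordinates.
#' @param z temporal covariate value at the evaluation time (NULL for the
#'   homogeneous case gamma = 1).
#' @return nonnegative scalar rate (detections per unit time).
#' @export
detection_intensity <- function(params, traps, k, s, z = NULL) {
  if (length(params$alpha) != ncol(traps$W))
    stop("alpha dimension does not match trap covariates")
  psi <- exp(sum(params$alpha * traps$W[k, ]))
  g <- if (is.null(z)) 1 else temporal_effect(params, z)
  d2 <- sum((as.numeric(s) - traps$xy[k, ])^2)
  psi * g * exp(-d2 / (2 * params$sigma^2))
}

#' Expected number of detections Phi(T_k, s, x_k)
#'
#' Time integral of the detection intensity over a trap's operating window.
#' For a piecewise-constant temporal covariate path the integral is exact:
#' Phi = psi_k exp(-d^2 / (2 sigma^2)) * sum over segments of
#' exp(xi' z_seg) * segment length. With constant gamma it reduces to
#' T_k * phi. A quadrature fallback for an arbitrary covariate path z(t) is
#' available via \code{zfun}.
#'
#' @inheritParams detection_intensity
#' @param schedule an \code{scr_schedule}, or NULL for the homogeneous case.
#' @param zfun optional function of time returning the covariate vector, for
#'   non-piecewise paths; integrated numerically with
#'   \code{stats::integrate}.
#' @return nonnegative scalar.
#' @export
expected_count <- function(params, traps, k, s, schedule = NULL, zfun = NULL) {
  psi <- exp(sum(params$alpha * traps$W[k, ]))
  d2 <- sum((as.numeric(s) - traps$xy[k, ])^2)
  kern <- exp(-d2 / (2 * params$sigma^2))
  if (!is.null(zfun)) {
    gfun <- function(t) {
      vapply(t, function(ti) temporal_effect(params, zfun(ti)), 0)
    }
    # panel-wise adaptive quadrature: robust when gamma(t) has jumps
    edges <- seq(0, traps$T[k], by = min(0.25, traps$T[k]))
    if (edges[length(edges)] < traps$T[k]) edges <- c(edges, traps$T[k])
    gi <- sum(vapply(seq_len(length(edges) - 1L), function(j)
      stats::integrate(gfun, edges[j], edges[j + 1L], rel.tol = 1e-9,
                       subdivisions = 200L)$value, 0))
    return(psi * kern * gi)
  }
  if (is.null(schedule) || is.null(params$xi)) return(psi * kern * traps$T[k])
  seg <- schedule$segments[[k]]
  psi * kern * sum((seg$end - seg$start) * exp(drop(seg$Z %*% params$xi)))
}

#' Log joint density of a count and its detection times, [y_ik, t_ik | s_i]
#'
#' log of (1 / y!) exp(-Phi) prod_j phi(t_j); for y = 0 this is -Phi.
#'
#' @inheritParams expected_count
#' @param y detection count at trap k.
#' @param times the y sorted detection times on (0, T_k].
#' @return log density (real).
#' @export
log_joint_obs_density <- function(params, traps, k, y, times, s,
                                  schedule = NULL) {
  if (length(times) != y) stop("length(times) must equal y")
  if (y > 0 && (any(times <= 0) || any(times > traps$T[k] + 1e-9)))
    stop("detection time outside (0, T_k]")
  Phi <- expected_count(params, traps, k, s, schedule)
  if (y == 0L) return(-Phi)
  lphi <- vapply(times, function(tt) {
    z <- if (is.null(schedule) || is.null(params$xi)) NULL
         else drop(schedule_z_at(schedule, k, tt))
    log(detection_intensity(params, traps, k, s, z))
  }, 0)
  -Phi + sum(lphi) - lfactorial(y)
}

#' Probability that an individual in B is never detected
#'
#' pi0 = (1 / Lambda(B)) * sum over unmasked cells of
#' lambda_m * exp(-sum_k Phi(T_k, c_m, x_k)) * cell area.
#'
#' @inheritParams expected_count
#' @param domain an \code{scr_domain}.
#' @param model "full" (uses the schedule) or "restricted" (gamma = 1).
#' @return scalar in (0, 1]; equals 1 when there are no traps.
#' @export
pi0 <- function(params, domain, traps = NULL, schedule = NULL,
                model = c("full", "restricted")) {
  model <- match.arg(model)
  lamU <- exp(drop(domain$V[domain$mask, , drop = FALSE] %*% params$beta))
  Lam <- sum(lamU) * domain$cell_area
  if (is.null(traps) || traps$K == 0L)
    return(1)
  D2 <- sq_dist_mat(domain$centers[domain$mask, , drop = FALSE], traps$xy)
  psi <- exp(drop(traps$W %*% params$alpha))
  Gam <- if (model == "full") schedule_gamma_integral(schedule, params$xi, traps)
         else traps$T
  PhiTot <- drop(exp(-D2 / (2 * params$sigma^2)) %*% (psi * Gam))
  sum(lamU * exp(-PhiTot)) * domain$cell_area / Lam
}

# ---- precomputed likelihood workspace ---------------------------------------

# Bundles everything that is constant across likelihood evaluations: unmasked
# covariates, cell-trap squared distances, per-pair count/time summaries
# (sum of z over each pair's detection times), and a kernel cache keyed on
# sigma. Used by the samplers; the exported loglik functions build one on the
# fly for one-off evaluations.
build_lik_env <- function(survey, domain, schedule = NULL) {
  traps <- survey$traps
  e <- new.env(parent = emptyenv())
  e$traps <- traps
  e$domain <- domain
  e$schedule <- schedule
  e$Vu <- domain$V[domain$mask, , drop = FALSE]
  e$cellsU <- domain$centers[domain$mask, , drop = FALSE]
  e$area <- domain$cell_area
  e$D2cells <- sq_dist_mat(e$cellsU, traps$xy)
  e$y <- survey$y
  n <- survey$n; K <- traps$K
  q <- if (is.null(schedule)) 0L else schedule$q
  # SZ[[j]][i, k] = sum of covariate j over the detection times of pair (i, k)
  e$SZ <- if (q > 0L) {
    lapply(seq_len(q), function(j) {
      m <- matrix(0, n, K)
      for (i in seq_len(n)) for (k in seq_len(K)) {
        tk <- survey$times[[i]][[k]]
        if (length(tk)) m[i, k] <- sum(schedule_z_at(schedule, k, tk)[, j])
      }
      m
    })
  } else NULL
  e$sum_lfact_y <- sum(lfactorial(survey$y))
  e$sum_y_logT <- if (n > 0) sum(sweep(survey$y, 2L, log(traps$T), "*")) else 0
  e$cache_sigma <- NA_real_
  e$Gcells <- NULL
  e
}

# cell kernel exp(-d^2 / 2 sigma^2), cached on sigma
lik_env_kernel <- function(e, sigma) {
  if (!isTRUE(e$cache_sigma == sigma)) {
    e$Gcells <- exp(-e$D2cells / (2 * sigma^2))
    e$cache_sigma <- sigma
  }
  e$Gcells
}

# core observed-data log-likelihood given a workspace; model = "full" uses
# detection times and the schedule, "restricted" uses counts only (Poisson
# pmf with mean T_k * phi).
loglik_core <- function(e, params, centers, n0, model = "full") {
  traps <- e$traps
  lamU <- exp(drop(e$Vu %*% params$beta))
  Lam <- sum(lamU) * e$area
  psi <- exp(drop(traps$W %*% params$alpha))
  Gam <- if (model == "full")
    schedule_gamma_integral(e$schedule, params$xi, traps)
  else traps$T
  G <- lik_env_kernel(e, params$sigma)
  PhiTotCells <- drop(G %*% (psi * Gam))
  p0 <- sum(lamU * exp(-PhiTotCells)) * e$area / Lam
  n <- nrow(e$y)
  ll <- -Lam - lgamma(n0 + 1)
  if (n0 > 0) ll <- ll + n0 * log(p0 * Lam)
  if (n > 0) {
    idx <- cell_index(e$domain, centers)
    if (anyNA(idx) || !all(e$domain$mask[idx]))
      stop("activity center outside the habitat")
    ll <- ll + sum(drop(e$domain$V[idx, , drop = FALSE] %*% params$beta))
    D2c <- sq_dist_mat(centers, traps$xy)
    sumPhi <- sum(exp(-D2c / (2 * params$sigma^2)) %*% (psi * Gam))
    logpsi_y <- sum(sweep(e$y, 2L, log(psi), "*"))
    ll <- ll - sumPhi + logpsi_y - sum(e$y * D2c) / (2 * params$sigma^2) -
      e$sum_lfact_y
    if (model == "full") {
      if (!is.null(params$xi))
        for (j in seq_along(params$xi))
          ll <- ll + params$xi[j] * sum(e$SZ[[j]])
    } else {
      ll <- ll + e$sum_y_logT
    }
  }
  ll
}

#' Observed-data log-likelihood of the full (continuous-time) model
#'
#' log of the joint density of the observed counts, detection times, latent
#' activity centers and n0:
#' -Lambda(B) + n0 log(pi0 Lambda(B)) - log(n0!) + sum_i log lambda(s_i)
#' + sum_{i,k} log [y_ik, t_ik | s_i].
#'
#' @param params an \code{scr_params} (xi required unless the schedule is
#'   NULL).
#' @param latent an \code{scr_latent}.
#' @param survey an \code{scr_survey}.
#' @param domain an \code{scr_domain}.
#' @param schedule an \code{scr_schedule} or NULL for constant gamma.
#' @return log-likelihood value.
#' @export
full_loglik <- function(params, latent, survey, domain, schedule = NULL) {
  e <- build_lik_env(survey, domain, schedule)
  loglik_core(e, params, latent$centers, latent$n0, model = "full")
}

#' Observed-data log-likelihood of the restricted (time-homogeneous) model
#'
#' Counts-only likelihood: detection times carry no information when gamma is
#' constant, so each y_ik is Poisson with mean T_k * phi(s_i, x_k). The
#' temporal effect gamma is absorbed into the baseline intercept alpha_0 and
#' is not separately identifiable, so \code{params$xi} must be NULL. At
#' xi = 0 the full and restricted log-likelihoods differ by the constant
#' sum_{ik} y_ik log T_k (detection times are then Uniform(0, T_k)).
#'
#' @inheritParams full_loglik
#' @export
restricted_loglik <- function(params, latent, survey, domain) {
  if (!is.null(params$xi))
    stop("restricted model: xi cannot be identified from alpha_0; set xi = NULL")
  e <- build_lik_env(survey, domain, schedule = NULL)
  loglik_core(e, params, latent$centers, latent$n0, model = "restricted")
}
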