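#' Sample activity centers of never-detected individuals
#'
#' Draws from the conditional density of a center given no detections,
#' [s | y = 0] proportional to lambda(s) * prod_k exp(-Phi(T_k, s, x_k)),
#' discretized to the quadrature grid: a cell is drawn with probability
#' proportional to lambda_m * exp(-sum_k Phi_mk) * cell area, then the point
#' is jittered uniformly within the cell. This matches the discretization
#' used for pi0 exactly.
#'
#' @param params an \code{scr_params}.
#' @param n0 number of centers to draw.
#' @param domain an \code{scr_domain}.
#' @param traps an \code{scr_traps} or NULL (no thinning by traps:
#'   draws follow lambda alone).
#' @param schedule an \code{scr_schedule} or NULL.
#' @param model "full" or "restricted".
#' @return n0 x 2 matrix of coordinates.
#' @export
sample_unobserved_centers <- function(params, n0, domain, traps = NULL,
                                      schedule = NULL,
                                      model = c("full", "restricted")) {
  model <- match.arg(model)
  if (n0 == 0L) return(matrix(numeric(0), 0L, 2L))
  w <- unobserved_center_weights(params, domain, traps, schedule, model)
  if (all(w == 0)) stop("degenerate distribution: all center weights are zero")
  cellsU <- domain$centers[domain$mask, , drop = FALSE]
  idx <- sample.int(nrow(cellsU), n0, replace = TRUE, prob = w)
  half <- domain$resolution / 2
  cellsU[idx, , drop = FALSE] +
    matrix(stats::runif(2L * n0, -half, half), n0, 2L)
}

# unnormalized per-unmasked-cell weights lambda_m exp(-sum_k Phi_mk) * area
unobserved_center_weights <- function(params, domain, traps = NULL,
                                      schedule = NULL, model = "full") {
  lamU <- exp(drop(domain$V[domain$mask, , drop = FALSE] %*% params$beta))
  w <- lamU * domain$cell_area
  if (!is.null(traps) && traps$K > 0L) {
    D2 <- sq_dist_mat(domain$centers[domain$mask, , drop = FALSE], traps$xy)
    psi <- exp(drop(traps$W %*% params$alpha))
    Gam <- if (model == "full")
      schedule_gamma_integral(schedule, params$xi, traps)
    else traps$T
    w <- w * exp(-drop(exp(-D2 / (2 * params$sigma^2)) %*% (psi * Gam)))
  }
  w
}

#' Posterior abundance map over a grid
#'
#' For each retained MCMC iteration, places the sampled activity centers of
#' the n observed individuals together with a fresh draw of the n0 centers of
#' never-detected individuals, counts centers per map cell
#' (N(B_m) = number of centers in cell m), and summarizes counts across
#' iterations. Every iteration's counts sum exactly to n + n0 for that
#' iteration.
#'
#' @param chain an \code{scr_chain} from \code{run_chain}.
#' @param domain the \code{scr_domain} the model was fitted on.
#' @param traps,schedule the survey design (used to thin unobserved-center
#'   draws away from well-sampled areas).
#' @param map_resolution cell side of the output map; must be an integer
#'   multiple of the domain resolution (default: the domain resolution).
#' @param seed optional seed for the unobserved-center draws.
#' @return object of class \code{scr_abundance_map}: data frame with columns
#'   cell_id, x, y, mean, lo, hi plus attributes (map grid geometry).
#' @export
abundance_map <- function(chain, domain, traps = NULL, schedule = NULL,
                          map_resolution = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map_resolution)) map_resolution <- domain$resolution
  ratio <- map_resolution / domain$resolution
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1 - 1e-9)
    stop("map grid not nested in domain: map_resolution must be a multiple of the domain resolution")
  map <- build_grid(domain$bounds, map_resolution)
  M <- nrow(map$centers)
  draws <- chain$draws
  m <- nrow(draws)
  counts <- matrix(0L, m, M)
  use_xi <- chain$model == "full" && any(startsWith(names(draws), "xi"))
  xin <- grep("^xi", names(draws), value = TRUE)
  bn <- grep("^beta", names(draws), value = TRUE)
  an <- grep("^alpha", names(draws), value = TRUE)
  for (j in seq_len(m)) {
    p <- scr_params(beta = as.numeric(draws[j, bn]),
                    alpha = as.numeric(draws[j, an]),
                    sigma = draws$sigma[j],
                    xi = if (use_xi) as.numeric(draws[j, xin]) else NULL)
    pts <- chain$centers[, , j, drop = FALSE]
    pts <- matrix(pts, ncol = 2L)
    n0j <- draws$n0[j]
    if (n0j > 0L)
      pts <- rbind(pts, sample_unobserved_centers(p, n0j, domain, traps,
                                                  schedule, chain$model))
    idx <- cell_index(map, pts)
    tab <- tabulate(idx, nbins = M)
    counts[j, ] <- tab
  }
  out <- data.frame(
    cell_id = seq_len(M),
    x = map$centers[, 1], y = map$centers[, 2],
    mean = colMeans(counts),
    lo = apply(counts, 2L, stats::quantile, probs = 0.025),
    hi = apply(counts, 2L, stats::quantile, probs = 0.975))
  structure(out, class = c("scr_abundance_map", "data.frame"),
            map_resolution = map_resolution, counts_dim = dim(counts))
}

#' Posterior density of individuals per unit area
#'
#' Per retained iteration, (n + n0) / |B| scaled to \code{area_unit};
#' summarized by posterior mean and 95% credible interval.
#'
#' @param chain an \code{scr_chain}.
#' @param domain the fitted \code{scr_domain} (|B| = habitat area).
#' @param area_unit report density per this many squared coordinate units
#'   (e.g. 100 for individuals per 100 km^2 with km coordinates).
#' @return named vector c(mean, lo, hi).
#' @export
density_estimate <- function(chain, domain, area_unit = 1) {
  stopifnot(area_unit > 0)
  N <- chain$n + chain$draws$n0
  dens <- N / domain_area(domain) * area_unit
  c(mean = mean(dens),
    lo = unname(stats::quantile(dens, 0.025)),
    hi = unname(stats::quantile(dens, 0.975)))
}

#' Home-range area from the Gaussian movement kernel
#'
#' Area of the circle containing a given probability mass of a bivariate
#' Gaussian with scale sigma: pi * sigma^2 * q, where q is the chi-square
#' quantile with 2 degrees of freedom at the requested level.
#'
#' @param sigma positive movement scale (coordinate units).
#' @param quantile probability level in (0, 1) (default 0.95).
#' @return area in squared coordinate units.
#' @examples
#' home_range_area(1.70)  # ~54 squared units at the 95% level
#' @export
home_range_area <- function(sigma, quantile = 0.95) {
  stopifnot(sigma > 0, quantile > 0, quantile < 1)
  pi * sigma^2 * stats::qchisq(quantile, df = 2)
}
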