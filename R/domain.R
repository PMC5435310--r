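#' Build a quadrature grid over a rectangular spatial domain
#'
#' Discretizes a rectangular region \eqn{B} into square cells of side
#' \code{resolution}. The grid carries an optional habitat mask and per-cell
#' density covariates; all spatial integrals in the package (the expected
#' abundance \eqn{\Lambda(B)} and the never-detected probability \eqn{\pi_0})
#' are midpoint-rule sums over the unmasked cells of this grid.
#'
#' Coordinates are planar (projected) units, e.g. km; no geographic CRS
#' handling is attempted because the model is metric-Euclidean.
#'
#' @param bounds numeric vector \code{c(xmin, xmax, ymin, ymax)}.
#' @param resolution positive cell side length, in the same units as
#'   \code{bounds}. The rectangle is tiled with \code{ceiling} cell counts, so
#'   the grid may overshoot a rectangle whose side is not a multiple of
#'   \code{resolution}.
#' @param mask_predicate optional function taking a two-column matrix of cell
#'   centers and returning a logical vector; \code{TRUE} marks habitat cells.
#'   Masked (non-habitat) cells are excluded from every integral and from all
#'   activity-center proposals and predictions.
#' @param covariate_fields optional function taking a two-column matrix of
#'   cell centers and returning a matrix of density covariates (one row per
#'   cell). An intercept column of ones is always prepended as the first
#'   regressor.
#' @return An object of class \code{scr_domain}: a list with elements
#'   \code{centers} (M x 2 matrix of cell midpoints), \code{cell_area},
#'   \code{mask} (logical, habitat = TRUE), \code{V} (M x p covariate matrix,
#'   first column 1), \code{bounds}, \code{resolution}, and grid dimensions
#'   \code{nx}, \code{ny}.
#' @examples
#' dom <- build_grid(c(0, 1, 0, 1), resolution = 0.5)
#' sum(dom$mask) * dom$cell_area  # total habitat area = 1
#' @export
build_grid <- function(bounds, resolution, mask_predicate = NULL,
                       covariate_fields = NULL) {
  stopifnot(is.numeric(bounds), length(bounds) == 4L)
  if (!(resolution > 0)) stop("resolution must be positive")
  xmin <- bounds[1]; xmax <- bounds[2]; ymin <- bounds[3]; ymax <- bounds[4]
  if (!(xmax > xmin && ymax > ymin)) stop("bounds are degenerate")
  nx <- max(1L, as.integer(ceiling((xmax - xmin) / resolution - 1e-9)))
  ny <- max(1L, as.integer(ceiling((ymax - ymin) / resolution - 1e-9)))
  cx <- xmin + (seq_len(nx) - 0.5) * resolution
  cy <- ymin + (seq_len(ny) - 0.5) * resolution
  centers <- cbind(x = rep(cx, times = ny), y = rep(cy, each = nx))
  mask <- if (is.null(mask_predicate)) rep(TRUE, nrow(centers)) else {
    m <- mask_predicate(centers)
    if (!is.logical(m) || length(m) != nrow(centers))
      stop("mask_predicate must return one logical per cell")
    m & !is.na(m)
  }
  if (!any(mask)) stop("domain-empty: mask excludes every grid cell")
  V <- matrix(1, nrow(centers), 1L)
  if (!is.null(covariate_fields)) {
    cv <- covariate_fields(centers)
    cv <- as.matrix(cv)
    if (nrow(cv) != nrow(centers)) stop("covariate_fields must return one row per cell")
    V <- cbind(1, cv)
  }
  dimnames(V) <- list(NULL, paste0("v", seq_len(ncol(V)) - 1L))
  structure(
    list(centers = centers, cell_area = resolution^2, mask = mask, V = V,
         bounds = c(xmin, xmax, ymin, ymax), resolution = resolution,
         nx = nx, ny = ny),
    class = "scr_domain")
}

#' @export
print.scr_domain <- function(x, ...) {
  cat(sprintf("scr_domain: %d x %d grid (%d cells, %d habitat), resolution %g\n",
              x$nx, x$ny, nrow(x$centers), sum(x$mask), x$resolution))
  cat(sprintf("  bounds [%g, %g] x [%g, %g]; habitat area %g; %d density covariate(s)\n",
              x$bounds[1], x$bounds[2], x$bounds[3], x$bounds[4],
              sum(x$mask) * x$cell_area, ncol(x$V)))
  invisible(x)
}

#' Total habitat area of a domain
#' @param domain an \code{scr_domain}.
#' @return sum of unmasked cell areas.
#' @export
domain_area <- function(domain) sum(domain$mask) * domain$cell_area

#' Construct a trap array
#'
#' @param locations K x 2 matrix (or data frame) of trap coordinates, in the
#'   same planar units as the domain.
#' @param durations positive operating duration \eqn{T_k} for each trap; a
#'   scalar is recycled. Detection times at trap k live on \eqn{(0, T_k]},
#'   each trap's own clock starting at its deployment.
#' @param covariates optional K x p matrix of baseline-rate covariates
#'   \eqn{w_k}; an intercept column of ones is always prepended.
#' @param id optional trap identifiers (default \code{1:K}).
#' @return An object of class \code{scr_traps}: list with \code{xy},
#'   \code{T}, \code{W} (first column 1), \code{id}, \code{K}.
#' @export
scr_traps <- function(locations, durations, covariates = NULL, id = NULL) {
  xy <- as.matrix(locations)
  if (ncol(xy) != 2L) stop("trap locations must have two columns")
  storage.mode(xy) <- "double"
  K <- nrow(xy)
  if (K < 1L) stop("need at least one trap")
  Tk <- rep_len(as.numeric(durations), K)
  if (any(!is.finite(Tk)) || any(Tk <= 0)) stop("all trap durations must be positive")
  W <- matrix(1, K, 1L)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != K) stop("one covariate row per trap required")
    W <- cbind(1, cv)
  }
  dimnames(W) <- list(NULL, paste0("w", seq_len(ncol(W)) - 1L))
  if (is.null(id)) id <- seq_len(K)
  structure(list(xy = xy, T = Tk, W = W, id = id, K = K), class = "scr_traps")
}

#' @export
print.scr_traps <- function(x, ...) {
  cat(sprintf("scr_traps: %d traps, durations in [%g, %g], %d baseline covariate(s)\n",
              x$K, min(x$T), max(x$T), ncol(x$W)))
  invisible(x)
}

#' Squared Euclidean distances between grid cells and traps
#'
#' @param domain an \code{scr_domain} (all cells, masked included).
#' @param traps an \code{scr_traps}, or a two-column coordinate matrix.
#' @return M x K matrix with entry (m, k) = squared distance from cell center
#'   m to trap k.
#' @export
squared_distances <- function(domain, traps) {
  pts <- if (inherits(domain, "scr_domain")) domain$centers else as.matrix(domain)
  txy <- if (inherits(traps, "scr_traps")) traps$xy else as.matrix(traps)
  sq_dist_mat(pts, txy)
}

# squared-distance kernel between two point sets, vectorized
sq_dist_mat <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}

#' Locate points on the domain grid
#'
#' Maps continuous coordinates to the index of the grid cell containing them
#' (used to read density covariates at activity-center locations).
#'
#' @param domain an \code{scr_domain}.
#' @param pts n x 2 coordinate matrix.
#' @return integer vector of cell indices; NA for points outside the bounds.
#' @export
cell_index <- function(domain, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  res <- domain$resolution
  ix <- ceiling((pts[, 1] - domain$bounds[1]) / res - 1e-12)
  iy <- ceiling((pts[, 2] - domain$bounds[3]) / res - 1e-12)
  ix <- pmax(ix, 1L); iy <- pmax(iy, 1L)
  bad <- ix > domain$nx | iy > domain$ny |
    pts[, 1] < domain$bounds[1] | pts[, 2] < domain$bounds[3]
  idx <- (iy - 1L) * domain$nx + ix
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Test whether points lie in habitat (unmasked) cells
#' @inheritParams cell_index
#' @return logical vector.
#' @export
in_habitat <- function(domain, pts) {
  idx <- cell_index(domain, pts)
  ok <- !is.na(idx)
  ok[ok] <- domain$mask[idx[ok]]
  ok
}

#' Quadrature self-check under grid refinement
#'
#' Recomputes \eqn{\Lambda(B)} on a grid refined 2x and warns when the value
#' moves by more than \code{tol} relative — a sign that the quadrature
#' resolution is too coarse for the density surface.
#'
#' @param params an \code{scr_params}.
#' @param domain an \code{scr_domain} built with known covariate/mask rules.
#' @param mask_predicate,covariate_fields the rules used to build
#'   \code{domain} (needed to evaluate the refined grid).
#' @param tol relative tolerance (default 0.005).
#' @return invisibly, c(coarse, fine) values of Lambda(B).
#' @export
check_quadrature <- function(params, domain, mask_predicate = NULL,
                             covariate_fields = NULL, tol = 0.005) {
  fine <- build_grid(domain$bounds, domain$resolution / 2,
                     mask_predicate = mask_predicate,
                     covariate_fields = covariate_fields)
  l1 <- lambda_integral(params, domain)
  l2 <- lambda_integral(params, fine)
  if (abs(l2 - l1) / abs(l1) > tol)
    warning(sprintf(
      "Lambda(B) moves by %.2f%% under 2x refinement; consider a finer grid",
      100 * abs(l2 - l1) / abs(l1)))
  invisible(c(coarse = l1, fine = l2))
}
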