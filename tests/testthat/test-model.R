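test_that("density surface is log-linear in the covariates", {
  d <- build_grid(c(0, 2, 0, 2), 0.5)
  p <- scr_params(beta = log(2), alpha = 0, sigma = 1)
  expect_equal(unname(density_surface(p, d)), rep(2, 16))
  expect_equal(lambda_integral(p, d), 2 * 4)  # constant integrand: exact

  dv <- build_grid(c(0, 2, 0, 2), 0.5,
                   covariate_fields = function(pts) cbind(v = as.numeric(pts[, 1] > 1)))
  pv <- scr_params(beta = c(0, -5), alpha = 0, sigma = 1)
  lam <- density_surface(pv, dv)
  expect_equal(lam[dv$V[, 2] == 1][1] / lam[dv$V[, 2] == 0][1], exp(-5))
  expect_error(density_surface(p, dv), "dimension")
})

test_that("masked cells are excluded from Lambda(B)", {
  dm <- build_grid(c(0, 2, 0, 2), 0.5,
                   mask_predicate = function(pts) pts[, 1] < 1)
  p <- scr_params(beta = log(3), alpha = 0, sigma = 1)
  expect_equal(lambda_integral(p, dm), 3 * 2)
  expect_true(all(is.na(density_surface(p, dm)[!dm$mask])))
})

test_that("temporal effect gamma = exp(xi'z)", {
  p <- tiny_params(xi = -1)
  expect_equal(temporal_effect(p, 1), exp(-1))   # day rate ~37% of night
  expect_equal(temporal_effect(p, 0), 1)
  p0 <- tiny_params(xi = 0)
  expect_equal(temporal_effect(p0, 1), 1)
  p2 <- scr_params(0, 0, 1, xi = c(2, 3))
  expect_equal(temporal_effect(p2, c(0, 0)), 1)
  expect_equal(unname(temporal_effect(p2, rbind(c(1, 0), c(0, 1)))),
               c(exp(2), exp(3)))
  expect_equal(temporal_effect(scr_params(0, 0, 1, xi = NULL), 1), 1)
})

test_that("detection intensity has the Gaussian distance-decay form", {
  tr <- scr_traps(rbind(c(0, 0)), durations = 10)
  p <- scr_params(beta = 0, alpha = 0, sigma = 0.4)
  expect_equal(detection_intensity(p, tr, 1, c(0, 0)), 1)  # psi = gamma = 1, d = 0
  expect_equal(detection_intensity(p, tr, 1, c(0.4, 0)), exp(-0.5))
  pw <- scr_params(0, c(-0.4, 0.8), 0.7)
  trw <- tiny_traps()
  expect_equal(detection_intensity(pw, trw, 1, trw$xy[1, ]),
               exp(-0.4 + 0.8 * 0.2))
  expect_error(scr_params(0, 0, sigma = -1), "positive")
})

test_that("expected count: closed form, homogeneous reduction, quadrature oracle", {
  tr <- scr_traps(rbind(c(0, 0)), durations = 10)
  # homogeneous: Phi = T * phi
  p <- scr_params(beta = 0, alpha = log(0.3), sigma = 1)
  expect_equal(expected_count(p, tr, 1, c(0, 0)), 3.0)

  # day/night closed form at d = 0: exp(-0.7) * (15 + 15 exp(-1))
  tr30 <- scr_traps(rbind(c(0, 0)), durations = 30)
  sch <- equal_split_schedule(tr30)
  pf <- scr_params(0, -0.7, sigma = 0.4, xi = -1)
  expect_equal(expected_count(pf, tr30, 1, c(0, 0), sch),
               exp(-0.7) * (15 + 15 * exp(-1)), tolerance = 1e-12)
  # against adaptive numerical integration of the intensity
  zfun <- function(t) as.numeric(t - floor(t) < 0.5 & t <= 30)
  expect_equal(expected_count(pf, tr30, 1, c(0.3, -0.2), sch),
               expected_count(pf, tr30, 1, c(0.3, -0.2), zfun = zfun),
               tolerance = 1e-8)
  # the quadrature fallback reduces to the closed form for constant gamma
  p1 <- scr_params(0, log(0.3), sigma = 1, xi = 0.7)
  expect_equal(expected_count(p1, tr, 1, c(0.2, 0.1), zfun = function(t) 1),
               detection_intensity(p1, tr, 1, c(0.2, 0.1), z = 1) * 10,
               tolerance = 1e-8)
})

test_that("closed-form Phi equals numerical integration on random configurations", {
  set.seed(11)
  for (r in 1:100) {
    Tk <- runif(1, 1, 6)
    tr <- scr_traps(rbind(runif(2, -1, 1)), durations = Tk)
    nseg <- sample(1:5, 1)
    br <- sort(c(0, runif(nseg - 1, 0, Tk), Tk))
    z <- rbinom(nseg, 1, 0.5)
    sch <- scr_schedule(list(data.frame(start = br[-length(br)],
                                        end = br[-1], z = z)), tr)
    p <- scr_params(0, runif(1, -1, 0.5), sigma = runif(1, 0.2, 1),
                    xi = runif(1, -2, 1))
    s <- runif(2, -1.5, 1.5)
    # adaptive quadrature of the intensity, segment by segment
    numer <- 0
    for (j in seq_len(nseg)) {
      f <- function(t) vapply(t, function(ti)
        detection_intensity(p, tr, 1, s, z = z[j]), 0)
      numer <- numer + stats::integrate(f, br[j], br[j + 1],
                                        rel.tol = 1e-10)$value
    }
    closed <- expected_count(p, tr, 1, s, sch)
    expect_equal(closed, numer, tolerance = 1e-8)
  }
})

test_that("log joint density of counts and times factorizes correctly", {
  tr <- scr_traps(rbind(c(0, 0)), durations = 10)
  p <- scr_params(0, log(0.3), sigma = 1)
  # y = 0: just -Phi
  expect_equal(log_joint_obs_density(p, tr, 1, 0L, numeric(0), c(0, 0)), -3)
  # y = 2 homogeneous closed form: -Phi + 2 log phi - log 2!
  expect_equal(log_joint_obs_density(p, tr, 1, 2L, c(1.2, 7.5), c(0, 0)),
               -3 + 2 * log(0.3) - log(2))
  # day/night: equals Poisson count density times conditional time densities
  tr4 <- scr_traps(rbind(c(0.1, 0)), durations = 4)
  sch <- equal_split_schedule(tr4)
  pf <- scr_params(0, -0.2, sigma = 0.5, xi = -1)
  s <- c(0.4, 0.3)
  tt <- c(0.25, 1.7, 3.1)
  Phi <- expected_count(pf, tr4, 1, s, sch)
  phis <- vapply(tt, function(ti)
    detection_intensity(pf, tr4, 1, s, z = drop(schedule_z_at(sch, 1, ti))), 0)
  # [y] * prod(phi / Phi) equals (1/y!) exp(-Phi) prod(phi)
  oracle <- dpois(3, Phi, log = TRUE) + sum(log(phis / Phi))
  expect_equal(log_joint_obs_density(pf, tr4, 1, 3L, tt, s, sch), oracle)
  expect_error(log_joint_obs_density(pf, tr4, 1, 1L, 5.2, s, sch), "outside")
})

test_that("pi0 is a proper never-detected probability", {
  d <- tiny_domain()
  p <- tiny_params()
  expect_equal(pi0(p, d, traps = NULL), 1)  # no traps: empty product

  tr <- tiny_traps()
  sch <- tiny_schedule(tr)
  # brute-force oracle over cells
  lam <- exp(drop(d$V %*% p$beta))
  w <- numeric(nrow(d$centers))
  for (m in seq_len(nrow(d$centers))) {
    tot <- 0
    for (k in 1:tr$K)
      tot <- tot + expected_count(p, tr, k, d$centers[m, ], sch)
    w[m] <- lam[m] * exp(-tot)
  }
  expect_equal(pi0(p, d, tr, sch), sum(w) / sum(lam))

  # saturating baseline rate drives pi0 to zero
  phot <- scr_params(p$beta, alpha = c(8, 0), sigma = 5, xi = -1)
  expect_lt(pi0(phot, d, tr, sch), 1e-6)
  # monotone nonincreasing in T_k
  trlong <- tiny_traps(T_op = c(4, 6))
  expect_lte(pi0(p, d, trlong, tiny_schedule(trlong)), pi0(p, d, tr, sch))
  expect_gt(pi0(p, d, tr, sch), 0)
  expect_lte(pi0(p, d, tr, sch), 1)
})

test_that("full log-likelihood matches an independent transcription", {
  d <- tiny_domain()
  p <- tiny_params()
  tr <- tiny_traps()
  sch <- tiny_schedule(tr)
  sv <- tiny_survey(tr)
  lat <- scr_latent(rbind(c(1.2, 0.8), c(2.1, 2.4)), n0 = 3L)
  expect_equal(full_loglik(p, lat, sv, d, sch),
               oracle_full_loglik(p, lat, sv, d, sch), tolerance = 1e-12)

  # empty survey: likelihood reduces to -Lambda(B)
  sv0 <- scr_survey(tr, matrix(0L, 0, 2), list())
  lat0 <- scr_latent(matrix(numeric(0), 0, 2), 0L)
  expect_equal(full_loglik(p, lat0, sv0, d, sch), -lambda_integral(p, d))

  # invariance under relabeling individuals and traps
  perm_tr <- scr_traps(tr$xy[2:1, ], tr$T[2:1], covariates = tr$W[2:1, -1])
  perm_sv <- scr_survey(perm_tr, sv$y[2:1, 2:1],
                        list(rev(sv$times[[2]]), rev(sv$times[[1]])))
  perm_sch <- scr_schedule(list(
    data.frame(start = sch$segments[[2]]$start, end = sch$segments[[2]]$end,
               z = sch$segments[[2]]$Z[, 1]),
    data.frame(start = sch$segments[[1]]$start, end = sch$segments[[1]]$end,
               z = sch$segments[[1]]$Z[, 1])), perm_tr)
  perm_lat <- scr_latent(lat$centers[2:1, ], 3L)
  expect_equal(full_loglik(p, perm_lat, perm_sv, d, perm_sch),
               full_loglik(p, lat, sv, d, sch), tolerance = 1e-12)

  # a center in a masked cell is a domain error
  dm <- build_grid(c(0, 3, 0, 3), 1, mask_predicate = function(pts) pts[, 1] > 2)
  expect_error(full_loglik(p, lat, sv, dm, sch), "habitat")
})

test_that("restricted likelihood: counts-only Poisson form and xi = 0 identity", {
  d <- tiny_domain()
  tr <- tiny_traps()
  sv <- tiny_survey(tr)
  lat <- scr_latent(rbind(c(1.2, 0.8), c(2.1, 2.4)), n0 = 2L)
  pr <- scr_params(c(0.3, 0.5), c(-0.4, 0.8), 0.7, xi = NULL)
  expect_error(restricted_loglik(tiny_params(xi = -1), lat, sv, d),
               "cannot be identified")

  # single individual, never detected: contribution is -sum_k T_k phi_k
  sv1 <- scr_survey(tr, matrix(0L, 1, 2), list(rep(list(numeric(0)), 2)))
  lat1 <- scr_latent(rbind(c(1.5, 1.5)), 0L)
  base <- -lambda_integral(pr, d) +
    log(density_surface(pr, d)[cell_index(d, rbind(c(1.5, 1.5)))])
  phis <- vapply(1:2, function(k)
    detection_intensity(pr, tr, k, c(1.5, 1.5)), 0)
  expect_equal(restricted_loglik(pr, lat1, sv1, d),
               base - sum(tr$T * phis), tolerance = 1e-12)

  # y = 2, T = 10, phi = 0.3: Poisson count term -3 + 2 log 3 - log 2
  tr1 <- scr_traps(rbind(c(0, 0)), durations = 10)
  sv2 <- scr_survey(tr1, matrix(2L, 1, 1), list(list(c(1, 2))))
  p03 <- scr_params(0, log(0.3), sigma = 1)
  d0 <- build_grid(c(-2, 2, -2, 2), 1)
  lat2 <- scr_latent(rbind(c(0.0001, 0.0001)), 0L)
  got <- restricted_loglik(p03, lat2, sv2, d0)
  # strip the spatial terms to isolate the count density
  spatial <- -lambda_integral(p03, d0) + 0  # log lambda = 0
  phi <- detection_intensity(p03, tr1, 1, c(0.0001, 0.0001))
  expect_equal(got - spatial, -10 * phi + 2 * log(10 * phi) - log(2),
               tolerance = 1e-12)

  # at xi = 0 the full model differs by the constant sum y_ik log T_k
  p0 <- scr_params(c(0.3, 0.5), c(-0.4, 0.8), 0.7, xi = 0)
  sch <- tiny_schedule(tr)
  lat <- scr_latent(rbind(c(1.2, 0.8), c(2.1, 2.4)), n0 = 5L)
  offset <- sum(sweep(sv$y, 2, log(tr$T), "*"))
  expect_equal(full_loglik(p0, lat, sv, d, sch) + offset,
               restricted_loglik(pr, lat, sv, d), tolerance = 1e-10)
})

test_that("xi = 0 identity holds on randomly generated surveys", {
  set.seed(21)
  cfg <- small_config(xi = 0)
  des <- sim_design(cfg)
  for (r in 1:5) {
    sim <- simulate_study(cfg, seed = 100 + r, design = des)
    if (sim$survey$n == 0) next
    lat <- scr_latent(sim$truth$centers[sim$truth$observed, , drop = FALSE],
                      n0 = sim$truth$N - sim$survey$n)
    pfull <- des$params
    prest <- scr_params(pfull$beta, pfull$alpha, pfull$sigma, xi = NULL)
    offset <- sum(sweep(sim$survey$y, 2, log(sim$traps$T), "*"))
    expect_equal(full_loglik(pfull, lat, sim$survey, sim$domain, sim$schedule) +
                   offset,
                 restricted_loglik(prest, lat, sim$survey, sim$domain),
                 tolerance = 1e-10)
  }
})

test_that("survey validation enforces count/time consistency", {
  tr <- tiny_traps()
  expect_error(scr_survey(tr, rbind(c(1L, 0L)), list(list(numeric(0), numeric(0)))),
               "times but y")
  expect_error(scr_survey(tr, rbind(c(1L, 0L)), list(list(3.5, numeric(0)))),
               "outside")
  expect_warning(scr_survey(tr, rbind(c(2L, 0L)), list(list(c(1, 1), numeric(0)))),
                 "tied")
})
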