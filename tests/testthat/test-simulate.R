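test_that("covariate surfaces are seeded, standardized and seed-independent", {
  d <- build_grid(c(0, 5.2, 0, 5.2), 0.1)
  v1 <- gen_covariate_surface(d, seed = 5)
  v2 <- gen_covariate_surface(d, seed = 5)
  expect_equal(as.numeric(v1), as.numeric(v2))
  expect_equal(mean(v1), 0, tolerance = 1e-12)
  expect_equal(sd(v1), 1, tolerance = 1e-12)
  # the attached evaluator reproduces the cell values
  expect_equal(attr(v1, "fun")(d$centers), as.numeric(v1), tolerance = 1e-12)
  # surfaces from different seeds are uncorrelated on average
  rs <- vapply(1:20, function(i)
    cor(as.numeric(gen_covariate_surface(d, seed = 100 + 2 * i)),
        as.numeric(gen_covariate_surface(d, seed = 101 + 2 * i))), 0)
  expect_lt(abs(mean(rs)), 0.2)
  # generating a surface does not disturb the caller's RNG stream
  set.seed(42); a <- runif(1)
  set.seed(42); invisible(gen_covariate_surface(d, seed = 9)); b <- runif(1)
  expect_identical(a, b)
})

test_that("population sizes are Poisson(Lambda) and centers follow lambda", {
  d <- build_grid(c(0, 3, 0, 3), 0.5,
                  covariate_fields = function(p) cbind(v = p[, 2] - 1.5))
  p <- scr_params(c(1.2, 0.6), 0, sigma = 0.5)
  Lam <- lambda_integral(p, d)
  set.seed(8)
  Ns <- replicate(300, nrow(simulate_population(p, d)))
  expect_equal(mean(Ns), Lam, tolerance = 4 * sqrt(Lam / 300) / Lam)
  # doubling lambda doubles the expected population
  p2 <- scr_params(c(1.2 + log(2), 0.6), 0, sigma = 0.5)
  expect_equal(lambda_integral(p2, d), 2 * Lam)
  # cell occupancy matches the multinomial implied by lambda
  set.seed(9)
  pts <- do.call(rbind, replicate(60, simulate_population(p, d), simplify = FALSE))
  lam <- density_surface(p, d)
  gof <- stats::chisq.test(tabulate(cell_index(d, pts), nbins = nrow(d$centers)),
                           p = lam / sum(lam))
  expect_gt(gof$p.value, 0.001)
  expect_true(all(in_habitat(d, pts)))
})

test_that("detection counts have the Poisson(Phi) law pair by pair", {
  tr <- scr_traps(rbind(c(0, 0), c(1, 0)), durations = c(4, 6))
  sch <- equal_split_schedule(tr)
  p <- scr_params(0, -0.2, sigma = 0.6, xi = -1)
  s <- rbind(c(0.3, 0.2))
  PhiTrue <- vapply(1:2, function(k) expected_count(p, tr, k, s[1, ], sch), 0)
  set.seed(14)
  counts <- t(replicate(4000, {
    det <- simulate_detections(p, s, tr, sch)
    if (length(det$observed)) as.numeric(det$survey$y[1, ]) else c(0, 0)
  }))
  for (k in 1:2) {
    expect_equal(mean(counts[, k]), PhiTrue[k],
                 tolerance = 4 * sqrt(PhiTrue[k] / 4000) / PhiTrue[k])
    expect_equal(var(counts[, k]), PhiTrue[k], tolerance = 0.15)
  }

  # a vanishing movement scale kills off-trap detections
  p0 <- scr_params(0, -0.2, sigma = 1e-6, xi = -1)
  set.seed(15)
  det0 <- simulate_detections(p0, rbind(c(0.5, 0.5)), tr, sch)
  expect_equal(length(det0$observed), 0L)
})

test_that("detection times are uniform within schedule segments", {
  tr <- scr_traps(rbind(c(0, 0)), durations = 50)
  sch <- equal_split_schedule(tr)
  p <- scr_params(0, 1.2, sigma = 1, xi = -1)
  set.seed(16)
  det <- simulate_detections(p, rbind(c(0, 0)), tr, sch)
  tt <- det$survey$times[[1]][[1]]
  expect_gt(length(tt), 60)
  # position within the covering segment must be U(0, 1)
  seg <- sch$segments[[1]]
  j <- findInterval(tt - 1e-12, seg$start)
  u <- (tt - seg$start[j]) / (seg$end[j] - seg$start[j])
  ks <- stats::ks.test(u, "punif")
  expect_gt(ks$p.value, 0.001)
  # day/night totals reflect exp(xi) with equal durations
  zs <- drop(schedule_z_at(sch, 1, tt))
  set.seed(17)
  more <- replicate(50, {
    d2 <- simulate_detections(p, rbind(c(0, 0)), tr, sch)
    t2 <- d2$survey$times[[1]][[1]]
    z2 <- drop(schedule_z_at(sch, 1, t2))
    c(sum(z2 == 1), sum(z2 == 0))
  })
  ratio <- sum(more[1, ]) / sum(more[2, ])
  expect_equal(ratio, exp(-1), tolerance = 0.1)
})

test_that("exact and thinning samplers agree in distribution", {
  tr <- scr_traps(rbind(c(0.2, 0)), durations = 8)
  sch <- equal_split_schedule(tr)
  p <- scr_params(0, 0.5, sigma = 0.8, xi = -1.5)
  s <- rbind(c(0, 0.3))
  set.seed(18)
  ce <- replicate(3000, sum(simulate_detections(p, s, tr, sch)$survey$y))
  ct <- replicate(3000, sum(simulate_detections(p, s, tr, sch,
                                                method = "thinning")$survey$y))
  Phi <- expected_count(p, tr, 1, s[1, ], sch)
  expect_equal(mean(ce), Phi, tolerance = 0.1)
  expect_equal(mean(ct), Phi, tolerance = 0.1)
  expect_gt(suppressWarnings(stats::ks.test(ce, ct)$p.value), 0.001)
})

test_that("replicate surveys are reproducible and independent across seeds", {
  cfg <- small_config()
  s1 <- simulate_study(cfg, seed = 5)
  s2 <- simulate_study(cfg, seed = 5)
  expect_identical(s1$survey$y, s2$survey$y)
  expect_identical(s1$truth$centers, s2$truth$centers)
  s3 <- simulate_study(cfg, seed = 6)
  expect_false(identical(s1$survey$y, s3$survey$y))
  # truth record is complete for recovery scoring
  expect_true(all(c("params", "N", "centers", "observed") %in% names(s1$truth)))
  expect_equal(s1$survey$n, length(s1$truth$observed))
  expect_true(s1$truth$N >= s1$survey$n)
})

test_that("total detections match the truth-implied mean sum of Phi", {
  cfg <- small_config()
  des <- sim_design(cfg)
  set.seed(19)
  tots <- exps <- numeric(30)
  for (r in 1:30) {
    sim <- simulate_study(cfg, seed = 400 + r, design = des)
    tots[r] <- sum(sim$survey$y)
    cen <- sim$truth$centers
    if (nrow(cen) == 0) next
    D2 <- squared_distances(cen, des$traps$xy)
    psi <- exp(drop(des$traps$W %*% des$params$alpha))
    Gam <- schedule_gamma_integral(des$schedule, des$params$xi)
    exps[r] <- sum(exp(-D2 / (2 * des$params$sigma^2)) %*% (psi * Gam))
  }
  expect_equal(mean(tots), mean(exps), tolerance = 0.05)
})
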