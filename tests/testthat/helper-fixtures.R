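# shared fixtures: all tiny objects are built in code, no stored data

# 3 x 3 unit-resolution domain on (0,3)^2 with one density covariate
tiny_domain <- function(res = 1, covar = TRUE) {
  build_grid(c(0, 3, 0, 3), res,
             covariate_fields = if (covar)
               function(p) cbind(v = p[, 1] - 1.5) else NULL)
}

tiny_traps <- function(T_op = c(2, 3)) {
  scr_traps(rbind(c(1, 1), c(2, 2)), durations = T_op,
            covariates = cbind(w = c(0.2, -0.1)))
}

# alternating day/night schedule covering (0, T_k] in unit steps
tiny_schedule <- function(traps, day_fraction = 0.5) {
  equal_split_schedule(traps, day_fraction)
}

# hand-built survey: 2 individuals, 2 traps
tiny_survey <- function(traps = tiny_traps()) {
  y <- rbind(c(2L, 0L), c(1L, 3L))
  times <- list(
    list(c(0.4, 1.6), numeric(0)),
    list(c(0.9), c(0.2, 1.1, 2.75)))
  scr_survey(traps, y, times)
}

tiny_params <- function(xi = -1) {
  scr_params(beta = c(0.3, 0.5), alpha = c(-0.4, 0.8), sigma = 0.7, xi = xi)
}

# small end-to-end simulation design: 4 x 4 traps, short survey
small_config <- function(...) {
  sim_config(side = 3.2, traps_side = 4L, trap_spacing = 0.5, T_op = 5,
             resolution = 0.1, ...)
}

# independent slow transcription of the full-model log-likelihood, built
# only from the exported elementary operations (used as an oracle)
oracle_full_loglik <- function(params, latent, survey, domain, schedule) {
  lam <- density_surface(params, domain)
  Lam <- lambda_integral(params, domain)
  p0 <- pi0(params, domain, survey$traps, schedule, model = "full")
  ll <- -Lam - lgamma(latent$n0 + 1)
  if (latent$n0 > 0) ll <- ll + latent$n0 * log(p0 * Lam)
  for (i in seq_len(survey$n)) {
    ci <- cell_index(domain, latent$centers[i, , drop = FALSE])
    ll <- ll + log(lam[ci])
    for (k in seq_len(survey$traps$K))
      ll <- ll + log_joint_obs_density(params, survey$traps, k,
                                       survey$y[i, k], survey$times[[i]][[k]],
                                       latent$centers[i, ], schedule)
  }
  ll
}
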