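# msmr_core: design layout, fixed parameters, covariate alignment,
# transition kernel, likelihood and fitting.

test_that("layout counts coefficients as the formulas imply", {
  hlp <- function(phi, biomass = NULL) {
    spec <- model_spec(phi = phi, p = ~1, psi = ~1, fixed = NULL,
      biomass = biomass)
    build_layout(spec, 8)$classes$phi
  }
  expect_identical(ncol(hlp(~1)$X), 1L)
  expect_identical(ncol(hlp(~colony)$X), 2L)
  bm <- biomass_series(2013:2019, sardine = seq(700, 100, length.out = 7) * 1e3,
    anchovy = seq(1.5, 2.5, length.out = 7) * 1e6)
  expect_identical(ncol(hlp(~ sardine * colony, bm)$X), 4L)
  expect_error(model_spec(phi = ~ unknown_factor, fixed = NULL) |>
    build_layout(8), "unknown factor")
  expect_error(build_layout(model_spec(p = ~sardine, fixed = NULL,
    biomass = bm), 8), "detection occasions")
})

test_that("the general-model default fixed-cell list is realized exactly", {
  spec <- model_spec(phi = ~ state * time * colony, p = ~ state * time * colony,
    psi = ~ state * time * colony)
  lay <- build_layout(spec, 8)
  fx <- function(cl) {
    z <- lay$classes[[cl]]
    cells <- z$cells[!z$free, c("state", "index", "colony")]
    expect_true(all(z$fixed_val[!z$free] == 0))
    sprintf("%s:%s:%s", cells$state, cells$index, cells$colony)
  }
  want_phi <- c(outer(c("N", "P"), c("RobbenIsland", "StonyPoint"),
    function(s, c) sprintf("%s:1:%s", s, c)), "P:2:RobbenIsland")
  expect_setequal(fx("phi"), want_phi)
  expect_setequal(fx("psi"), want_phi)
  # p cells: internal index = occasion - 1
  want_p <- c(outer(c("N", "P"), c("RobbenIsland", "StonyPoint"),
    function(s, c) sprintf("%s:1:%s", s, c)), "P:2:RobbenIsland")
  expect_setequal(fx("p"), want_p)
})

test_that("covariates align November survey y with interval y -> y+1 and standardize", {
  bm <- biomass_series(2013:2019, sardine = c(5, 3, 8, 2, 9, 4, 6) * 1e5,
    anchovy = rep(2e6, 7))
  spec <- model_spec(phi = ~sardine, fixed = NULL, biomass = bm)
  lay <- build_layout(spec, 8)
  cells <- lay$classes$phi$cells
  z13 <- (5e5 - mean(c(5, 3, 8, 2, 9, 4, 6) * 1e5)) / sd(c(5, 3, 8, 2, 9, 4, 6) * 1e5)
  expect_equal(unique(cells$sardine[cells$index == 1]), z13)
  expect_equal(mean(unique(cells[, c("index", "sardine")])$sardine), 0)
  expect_equal(sd(unique(cells[, c("index", "sardine")])$sardine), 1)
  combo <- unique(cells[, c("index", "combined")])$combined
  raw <- c(5, 3, 8, 2, 9, 4, 6) * 1e5 + 2e6
  expect_equal(combo, (raw - mean(raw)) / sd(raw))
  short <- biomass_series(2013:2018, sardine = 1:6, anchovy = 1:6)
  expect_error(build_layout(model_spec(phi = ~sardine, fixed = NULL,
    biomass = short), 8), "missing survey year")
})

test_that("transition kernel: identity at Phi = 1 / stay, symmetry at beta 0, stochastic rows", {
  lay <- saturated_layout(3)
  beta <- qlogis(c(rep(1 - 1e-12, 3), rep(0.5, 3), rep(1e-12, 3)))
  k <- transition_kernel(beta, lay, 1, "C1")
  expect_equal(k$M[1, ], c(B = 1, N = 0, P = 0, dead = 0), tolerance = 1e-9)
  k0 <- transition_kernel(rep(0, lay$K), lay, 2, "C1")
  expect_equal(unname(diag(k0$M)[1:3]), rep(0.25, 3))
  expect_equal(unname(k0$M[cbind(1:3, c(2, 1, 1))]), rep(0.25, 3))
  expect_equal(unname(k0$M[, 4]), c(0.5, 0.5, 0.5, 1))
  set.seed(1)
  for (i in 1:1000) {
    kk <- transition_kernel(rnorm(lay$K, sd = 3), lay, sample(2, 1), 1)
    expect_equal(unname(rowSums(kk$M)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(kk$M >= 0))
  }
})

test_that("forward recursion equals brute-force path enumeration on random histories", {
  set.seed(4)
  for (T in 3:4) {
    lay <- saturated_layout(T)
    for (rep in 1:3) {
      beta <- rnorm(lay$K, sd = 1.5)
      real <- compute_real(beta, lay)
      for (draw in 1:20) {
        f <- sample(T - 1, 1)
        s <- sample(3, 1)
        codes <- c(rep(0L, f - 1L), s, sample(0:3, T - f, replace = TRUE))
        h <- new_histories("a", factor("C1"), matrix(codes, 1),
          seq(2013, length.out = T))
        expect_equal(exp(log_likelihood(h, beta, lay)),
          brute_force_history_prob(codes, 1L, real), tolerance = 1e-10)
      }
    }
  }
})

test_that("histories violating the encounter contract are rejected", {
  expect_error(new_histories("a", factor("C1"), matrix(c(0L, 0L), 1), 2013:2014),
    "at least one encounter")
  expect_error(new_histories("a", factor("C1"), matrix(c(1L, 5L), 1), 2013:2014),
    "codes must be in 0:3")
  h <- new_histories("a", factor("C1"), matrix(c(1L, 0L, 1L), 1), 2013:2015)
  lay <- saturated_layout(2)
  expect_error(log_likelihood(h, rep(0, lay$K), lay), "occasions")
})

test_that("constant-model fit recovers truth and likelihood invariances hold", {
  cfg <- recovery_config(n_year1 = 600L, seed = 61, n_occasions = 6L)
  h <- simulate_histories(cfg)
  fixed <- rbind(
    expand.grid(class = c("phi", "psi"), state = "P", index = 1:5,
      colony = "C1", value = 0.5, stringsAsFactors = FALSE),
    expand.grid(class = "p", state = "P", index = 2:6, colony = "C1",
      value = 0.5, stringsAsFactors = FALSE))
  spec <- model_spec(phi = ~1, p = ~ 0 + state, psi = ~ 0 + state, fixed = fixed)
  fit <- fit_msmr(spec, h, n_starts = 1)
  expect_true(fit$converged)
  est <- fit$real
  g <- function(cl, s, t1) est[est$class == cl & est$state == s &
    est$time == est$time[est$class == cl][t1], ][1, ]
  phi <- est[est$class == "phi" & est$state == "B", ][1, ]
  expect_lt(abs(phi$estimate - 0.8), 2 * phi$se)
  pb <- est[est$class == "p" & est$state == "B", ][1, ]
  expect_lt(abs(pb$estimate - 0.9), 2 * pb$se)
  # permutation invariance and dialect invariance
  set.seed(2)
  perm <- sample(length(h$id))
  f2 <- fit_msmr(spec, h[perm], n_starts = 1)
  expect_equal(f2$minus2loglik, fit$minus2loglik, tolerance = 1e-8)
  expect_equal(sort(f2$beta), sort(fit$beta), tolerance = 1e-5)
  tmp <- tempfile(fileext = ".inp")
  write_inp(h, tmp)
  f3 <- fit_msmr(spec, read_inp(tmp), n_starts = 1)
  expect_equal(f3$minus2loglik, fit$minus2loglik, tolerance = 1e-8)
})

test_that("fixing a free parameter at its MLE preserves the likelihood and drops K", {
  cfg <- recovery_config(n_year1 = 300L, seed = 71, n_occasions = 5L)
  h <- simulate_histories(cfg)
  fixP <- rbind(
    expand.grid(class = c("phi", "psi"), state = "P", index = 1:4,
      colony = "C1", value = 0.5, stringsAsFactors = FALSE),
    expand.grid(class = "p", state = "P", index = 2:5, colony = "C1",
      value = 0.5, stringsAsFactors = FALSE))
  spec <- model_spec(phi = ~1, p = ~ 0 + state, psi = ~ 0 + state, fixed = fixP)
  fit <- fit_msmr(spec, h, n_starts = 1)
  psi_n_hat <- fit$real$estimate[fit$real$class == "psi" &
    fit$real$state == "N"][1]
  fixN <- rbind(fixP, expand.grid(class = "psi", state = "N", index = 1:4,
    colony = "C1", value = psi_n_hat, stringsAsFactors = FALSE))
  fit2 <- fit_msmr(model_spec(phi = ~1, p = ~ 0 + state, psi = ~ 0 + state,
    fixed = fixN), h, n_starts = 1)
  expect_identical(fit2$K, fit$K - 1L)
  expect_equal(fit2$minus2loglik, fit$minus2loglik, tolerance = 1e-4)
})

test_that("terminal parameters of a fully time-dependent model are flagged confounded", {
  # single-state world (movement fixed 0): CJS identifiability limit
  cfg <- recovery_config(n_year1 = 400L, seed = 81, n_occasions = 5L,
    psi_bn = 0, p_b = 0.7)
  h <- simulate_histories(cfg)
  fixed <- rbind(
    expand.grid(class = c("phi", "psi"), state = c("N", "P"), index = 1:4,
      colony = "C1", value = 0, stringsAsFactors = FALSE),
    expand.grid(class = "p", state = c("N", "P"), index = 2:5, colony = "C1",
      value = 0, stringsAsFactors = FALSE),
    expand.grid(class = "psi", state = "B", index = 1:4, colony = "C1",
      value = 0, stringsAsFactors = FALSE))
  spec <- model_spec(phi = ~ 0 + time, p = ~ 0 + time, psi = ~1, fixed = fixed)
  fit <- fit_msmr(spec, h, n_starts = 1)
  est <- fit$real
  phiB <- est[est$class == "phi" & est$state == "B", ]
  pB <- est[est$class == "p" & est$state == "B", ]
  expect_true(phiB$inestimable[nrow(phiB)])
  expect_true(pB$inestimable[nrow(pB)])
  expect_false(phiB$inestimable[1])
})

test_that("delta-method SEs match a parametric-bootstrap oracle on a toy fit", {
  cfg <- recovery_config(n_year1 = 400L, seed = 91, n_occasions = 5L)
  h <- simulate_histories(cfg)
  fixP <- rbind(
    expand.grid(class = c("phi", "psi"), state = "P", index = 1:4,
      colony = "C1", value = 0.5, stringsAsFactors = FALSE),
    expand.grid(class = "p", state = "P", index = 2:5, colony = "C1",
      value = 0.5, stringsAsFactors = FALSE))
  spec <- model_spec(phi = ~1, p = ~ 0 + state, psi = ~ 0 + state, fixed = fixP)
  fit <- fit_msmr(spec, h, n_starts = 1)
  est <- fit$real
  phi_hat <- est$estimate[est$class == "phi"][1]
  se_delta <- est$se[est$class == "phi"][1]
  p_hat <- est$estimate[est$class == "p" & est$state == "B"][1]
  pn_hat <- est$estimate[est$class == "p" & est$state == "N"][1]
  mv_hat <- est$estimate[est$class == "psi" & est$state == "B"][1]
  nb_hat <- est$estimate[est$class == "psi" & est$state == "N"][1]
  boots <- vapply(1:200, function(b) {
    cb <- recovery_config(n_year1 = 400L, seed = 91000 + b, n_occasions = 5L,
      phi = phi_hat, p_b = p_hat, p_n = pn_hat, psi_bn = mv_hat,
      psi_nb = nb_hat)
    hb <- simulate_histories(cb)
    fb <- fit_msmr(spec, hb, n_starts = 1)
    fb$real$estimate[fb$real$class == "phi"][1]
  }, numeric(1))
  expect_lt(abs(sd(boots) / se_delta - 1), 0.10)
})

test_that("real_estimates predicts over a covariate grid and flags extrapolation", {
  bm <- biomass_series(2013:2019, sardine = c(5, 3, 8, 2, 9, 4, 6) * 1e5,
    anchovy = rep(2e6, 7))
  cfg <- sim_config(seed = 101)
  h <- simulate_histories(cfg)
  spec <- model_spec(phi = ~ sardine * colony, p = ~ state,
    psi = ~ state, biomass = bm)
  fit <- fit_msmr(spec, h, n_starts = 1)
  grid <- expand.grid(sardine = c(3e5, 6e5), colony = c("RobbenIsland", "StonyPoint"))
  pred <- real_estimates(fit, at = grid, class = "phi")
  expect_identical(nrow(pred), 4L)
  expect_true(all(pred$estimate > 0 & pred$estimate < 1))
  expect_false(any(pred$extrapolated))
  expect_warning(
    real_estimates(fit, at = data.frame(sardine = 5e6,
      colony = "RobbenIsland"), class = "phi"), "extrapolate")
})
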