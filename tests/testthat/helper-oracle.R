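# Shared test helpers: an independent brute-force likelihood oracle
# (explicit enumeration of latent state paths), enumeration of observation
# histories, and small fixture builders.

# Probability of one observed history by exhaustive enumeration of latent
# state sequences. Recomputed from the real-scale parameter arrays only;
# independent of the forward recursion in log_likelihood().
brute_force_history_prob <- function(codes, colony_index, real) {
  T <- length(codes)
  f <- which(codes != 0L)[1]
  dest <- c(2L, 1L, 1L) # B->N, N->B, P->B
  step_prob <- function(z, z2, t) {
    if (z == 4L) return(as.numeric(z2 == 4L))
    phi <- real$phi[z, t, colony_index]
    mv <- real$psimove[z, t, colony_index]
    if (z2 == 4L) return(1 - phi)
    if (z2 == z) return(phi * (1 - mv))
    if (z2 == dest[z]) return(phi * mv)
    0
  }
  obs_prob <- function(z2, y, t) {
    # t indexes the interval; detection applies at occasion t + 1
    if (y > 0L) {
      if (z2 != y) return(0)
      return(real$p[y, t, colony_index])
    }
    if (z2 == 4L) return(1)
    1 - real$p[z2, t, colony_index]
  }
  total <- 0
  n_steps <- T - f
  if (n_steps == 0L) return(1)
  grid <- expand.grid(rep(list(1:4), n_steps))
  for (r in seq_len(nrow(grid))) {
    z <- c(codes[f], as.integer(grid[r, ]))
    pr <- 1
    for (s in seq_len(n_steps)) {
      t <- f + s - 1L
      pr <- pr * step_prob(z[s], z[s + 1L], t) * obs_prob(z[s + 1L], codes[t + 1L], t)
      if (pr == 0) break
    }
    total <- total + pr
  }
  total
}

# All observation code sequences of length T with first capture at
# (occasion f, state s): codes are 0 before f, s at f, anything in 0:3 after.
enumerate_histories <- function(T, f, s) {
  n_after <- T - f
  if (n_after == 0L) return(matrix(c(rep(0L, f - 1L), s), 1L))
  tails <- as.matrix(expand.grid(rep(list(0:3), n_after)))
  cbind(matrix(rep(c(rep(0L, f - 1L), s), nrow(tails)), nrow(tails),
    byrow = TRUE), tails, deparse.level = 0)
}

# A saturated one-colony layout (identity state coding, no fixed cells) so
# beta maps 1:1 onto qlogis of the real parameters.
saturated_layout <- function(T, colonies = "C1") {
  spec <- model_spec(phi = ~ 0 + state, p = ~ 0 + state, psi = ~ 0 + state,
    fixed = NULL)
  build_layout(spec, T, colonies = colonies,
    years = seq(2013L, length.out = T))
}

# Fix every prebreeder cell so a two-state (B/N) simulation can be fitted
# with a full-rank constant model.
fix_prebreeders <- function(colonies, value = 0.5) {
  rbind(
    expand.grid(class = c("phi", "psi"), state = "P", index = 1:7,
      colony = colonies, value = value, stringsAsFactors = FALSE),
    expand.grid(class = "p", state = "P", index = 2:8, colony = colonies,
      value = value, stringsAsFactors = FALSE))
}

# Two-state constant-world simulation config used by the recovery tests:
# breeders marked in season 1 plus smaller later cohorts, no prebreeders.
recovery_config <- function(n_year1 = 2000L, seed = 1L, n_occasions = 8L,
                            phi = 0.80, p_b = 0.90, p_n = 0.55,
                            psi_bn = 0.20, psi_nb = 0.65) {
  sched <- array(0L, dim = c(1L, n_occasions, 3L),
    dimnames = list(colony = "C1", occasion = NULL, state = c("B", "N", "P")))
  sched[1, 1, 1] <- n_year1
  sim_config(n_occasions = n_occasions, colonies = "C1",
    marking_schedule = sched,
    true_phi = state_rate_array(phi, phi, phi, n_time = n_occasions - 1L,
      colonies = "C1"),
    true_p = state_rate_array(p_b, p_n, p_n, n_time = n_occasions,
      colonies = "C1"),
    true_psi = psi_table(psi_bn, psi_nb, 0.5,
      n_intervals = n_occasions - 1L, colonies = "C1"),
    seed = seed)
}
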