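# Three-state (plus dead) Arnason-Schwarz model: model specification, design
# layout with fixed parameters, forward-algorithm likelihood, maximum
# likelihood fitting and real-scale estimates.
#
# Links: logit for Phi and p. The psi row for each origin state is a
# multinomial logit with "stay" as the reference category; with the
# structural zeros psi(P->N) = psi(N->P) = psi(B->P) = 0 each origin has a
# single permitted non-stay destination, so the row reduces to one movement
# logit (B->N, N->B, P->B) and row sums to 1 hold by construction.

#' Annual spawner-biomass series
#'
#' November hydro-acoustic survey estimates of sardine and anchovy spawner
#' biomass by survey year. Survival over the nonbreeding season from breeding
#' season `y` to `y + 1` is related to the November `y` survey (the survey at
#' the start of that nonbreeding period).
#'
#' @param year integer survey years.
#' @param sardine,anchovy non-negative biomass (tonnes).
#' @return `data.frame` of class `biomass_series`.
#' @export
biomass_series <- function(year, sardine, anchovy) {
  .assert(length(year) == length(sardine) && length(year) == length(anchovy),
    "year, sardine, anchovy must have equal length")
  .assert(all(sardine >= 0) && all(anchovy >= 0), "biomass must be non-negative")
  .assert(!anyDuplicated(year), "duplicate survey years")
  structure(data.frame(year = as.integer(year), sardine = as.numeric(sardine),
    anchovy = as.numeric(anchovy)),
    class = c("biomass_series", "data.frame"))
}

#' @rdname biomass_series
#' @param path CSV with columns `year`, `sardine`, `anchovy`.
#' @export
read_biomass_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  biomass_series(df$year, df$sardine, df$anchovy)
}

#' Default fixed parameters
#'
#' The study design implies several known parameters that are fixed rather
#' than estimated: only breeders were marked in season 1, so nonbreeder and
#' prebreeder survival and transition over the first interval, and their
#' recapture at occasion 2, are 0 at both colonies; at the first colony no
#' prebreeders were marked in season 2 either, so prebreeder survival and
#' transition over interval 2 and recapture at occasion 3 are 0 there. The
#' structural-zero transitions are not listed here because the movement-logit
#' parameterization encodes them exactly.
#'
#' @param colonies colony names; `no_prebreeders_y2` names the colony that
#'   marked no new nonbreeding birds in season 2 (default the first).
#' @return `data.frame` with columns `class` (phi/p/psi), `state` (B/N/P),
#'   `index` (interval for phi/psi, occasion for p), `colony`, `value`.
#' @export
default_fixed_params <- function(colonies = .default_colonies,
                                 no_prebreeders_y2 = colonies[1]) {
  both <- expand.grid(class = c("phi", "psi"), state = c("N", "P"),
    index = 1L, colony = colonies, value = 0,
    stringsAsFactors = FALSE)
  p2 <- expand.grid(class = "p", state = c("N", "P"), index = 2L,
    colony = colonies, value = 0, stringsAsFactors = FALSE)
  extra <- data.frame(class = c("phi", "psi", "p"), state = "P",
    index = c(2L, 2L, 3L), colony = no_prebreeders_y2, value = 0)
  out <- rbind(both, p2, extra)
  rownames(out) <- NULL
  out
}

#' Model specification
#'
#' Symbolic structure for the three parameter classes. Formulas (or formula
#' strings) may use the factors `state`, `time`, `colony` and, for `phi` and
#' `psi`, the standardized interval covariates `sardine`, `anchovy` and
#' `combined` (sardine + anchovy), composed additively (`+`) or
#' interactively (`*`).
#'
#' @param phi,p,psi formulas or strings, e.g. `~ state + sardine * colony`.
#' @param fixed fixed-parameter table as from [default_fixed_params()]; use
#'   `NULL` for none.
#' @param biomass optional [biomass_series()] supplying the covariates.
#' @param label optional model label; auto-generated when `NULL`.
#' @return object of class `msmr_spec`.
#' @export
model_spec <- function(phi = ~1, p = ~1, psi = ~1,
                       fixed = default_fixed_params(), biomass = NULL,
                       label = NULL) {
  f <- lapply(list(phi = phi, p = p, psi = psi), function(x) {
    if (is.character(x)) x <- stats::as.formula(paste("~", sub("^~", "", x)))
    .assert(inherits(x, "formula"), "phi/p/psi must be formulas or strings")
    x
  })
  if (is.null(label)) {
    label <- sprintf("phi(%s) p(%s) psi(%s)",
      deparse(f$phi[[2]]), deparse(f$p[[2]]), deparse(f$psi[[2]]))
  }
  structure(list(phi = f$phi, p = f$p, psi = f$psi, fixed = fixed,
    biomass = biomass, label = label), class = "msmr_spec")
}

#' Attach a biomass covariate series to a model specification
#'
#' Aligns the series with the survival intervals (interval `i`, season
#' `years[i]` to `years[i+1]`, uses the November `years[i]` survey) and
#' records it on the spec; standardization (z-score over the supplied years)
#' happens when the design layout is built.
#'
#' @param spec an [model_spec()].
#' @param series a [biomass_series()].
#' @return the spec with covariates attached.
#' @export
attach_covariate <- function(spec, series) {
  .assert(inherits(spec, "msmr_spec"), "spec must be an msmr_spec")
  .assert(inherits(series, "biomass_series"), "series must be a biomass_series")
  spec$biomass <- series
  spec
}

#' @export
print.msmr_spec <- function(x, ...) {
  cat("Multistate model spec:", x$label, "\n")
  cat(sprintf("  fixed cells: %d; biomass covariates: %s\n",
    if (is.null(x$fixed)) 0L else nrow(x$fixed),
    if (is.null(x$biomass)) "none" else
      paste(range(x$biomass$year), collapse = "-")))
  invisible(x)
}

#' @noRd
.covariate_values <- function(biomass, years) {
  n_int <- length(years) - 1L
  need <- years[seq_len(n_int)]
  miss <- setdiff(need, biomass$year)
  if (length(miss)) {
    stop(sprintf(
      "biomass series missing survey year(s) %s needed for interval(s) %s",
      paste(miss, collapse = ", "),
      paste(which(need %in% miss), collapse = ", ")), call. = FALSE)
  }
  idx <- match(need, biomass$year)
  raw <- data.frame(sardine = biomass$sardine[idx],
    anchovy = biomass$anchovy[idx])
  raw$combined <- raw$sardine + raw$anchovy
  scale <- lapply(raw, function(v) c(mean = mean(v), sd = sd(v)))
  std <- as.data.frame(lapply(raw, function(v) {
    s <- sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }))
  list(raw = raw, std = std, scale = scale)
}

#' Build the parameter layout (design matrices, fixed masks, beta indexing)
#'
#' Realizes a [model_spec()] over a concrete study frame: `3 states x
#' (n_occasions - 1) intervals x colonies` cells for `phi` and `psi` (the psi
#' cell is the movement probability to the single permitted destination) and
#' `3 x (n_occasions - 1) x colonies` cells for `p` at occasions
#' `2..n_occasions`. Fixed cells are masked out of estimation; design columns
#' identified only by fixed cells are dropped, and `K` counts the remaining
#' estimated coefficients.
#'
#' @param spec an [model_spec()].
#' @param n_occasions number of occasions.
#' @param colonies colony names (order = factor levels).
#' @param years calendar labels for the occasions.
#' @return object of class `msmr_layout`.
#' @export
build_layout <- function(spec, n_occasions, colonies = .default_colonies,
                         years = seq(2013L, length.out = n_occasions)) {
  T <- as.integer(n_occasions)
  .assert(T >= 2L, "need at least 2 occasions")
  cov <- NULL
  uses_cov <- vapply(c("phi", "p", "psi"), function(cl) {
    any(all.vars(spec[[cl]]) %in% c("sardine", "anchovy", "combined"))
  }, logical(1))
  if (any(uses_cov)) {
    .assert(!is.null(spec$biomass),
      "formula uses biomass covariates but no biomass series is attached")
    .assert(!uses_cov[["p"]],
      "biomass covariates are defined for survival/transition intervals, not detection occasions")
    cov <- .covariate_values(spec$biomass, years)
  }
  int_label <- sprintf("%d-%02d", years[-T], years[-1] %% 100)
  occ_label <- as.character(years[-1])
  classes <- list()
  offset <- 0L
  for (cl in c("phi", "p", "psi")) {
    idx <- seq_len(T - 1L)
    tlab <- if (cl == "p") occ_label else int_label
    cells <- expand.grid(state = factor(.state_labels, levels = .state_labels),
      index = idx, colony = factor(colonies, levels = colonies),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cells$time <- factor(tlab[cells$index], levels = tlab)
    if (!is.null(cov) && cl != "p") {
      cells$sardine <- cov$std$sardine[cells$index]
      cells$anchovy <- cov$std$anchovy[cells$index]
      cells$combined <- cov$std$combined[cells$index]
    }
    form <- spec[[cl]]
    unknown <- setdiff(all.vars(form), names(cells))
    .assert(length(unknown) == 0L, "%s formula references unknown factor(s): %s",
      cl, paste(unknown, collapse = ", "))
    mf <- model.frame(form, cells)
    X <- model.matrix(form, mf)
    fixed_val <- rep(NA_real_, nrow(cells))
    fx <- spec$fixed
    if (!is.null(fx) && nrow(fx)) {
      fx_cl <- fx[fx$class == cl, , drop = FALSE]
      if (nrow(fx_cl)) {
        occ_index <- if (cl == "p") fx_cl$index - 1L else fx_cl$index
        m <- match(paste(fx_cl$state, occ_index, fx_cl$colony),
          paste(as.character(cells$state), cells$index,
            as.character(cells$colony)))
        bad <- which(is.na(m))
        .assert(length(bad) == 0L, "fixed %s cell not in layout: %s %s %s",
          cl, fx_cl$state[bad[1]], fx_cl$index[bad[1]], fx_cl$colony[bad[1]])
        .assert(all(fx_cl$value >= 0 & fx_cl$value <= 1),
          "fixed values must be in [0,1]")
        fixed_val[m] <- fx_cl$value
      }
    }
    free <- is.na(fixed_val)
    keep_col <- apply(X[free, , drop = FALSE], 2L, function(col) any(col != 0))
    X <- X[, keep_col, drop = FALSE]
    K_cl <- ncol(X)
    classes[[cl]] <- list(cells = cells, X = X, fixed_val = fixed_val,
      free = free, beta_idx = if (K_cl) offset + seq_len(K_cl) else integer(),
      terms = terms(mf), xlev = .getXlevels(terms(mf), mf))
    offset <- offset + K_cl
  }
  structure(list(classes = classes, K = offset, n_occasions = T,
    colonies = colonies, years = years, cov_scale = cov$scale,
    cov_range = if (!is.null(cov)) lapply(cov$raw, range),
    label = spec$label), class = "msmr_layout")
}

#' @noRd
.getXlevels <- function(Terms, m) stats::.getXlevels(Terms, m)

#' Real-scale parameter arrays for a beta vector
#'
#' @param beta coefficient vector of length `layout$K`.
#' @param layout an [build_layout()] result.
#' @return list of arrays `phi`, `p`, `psimove` with dims
#'   `3 x (n_occasions - 1) x n_colonies` (for `p`, column `t` is occasion
#'   `t + 1`); fixed cells hold their fixed values.
#' @export
compute_real <- function(beta, layout) {
  .assert(length(beta) == layout$K, "beta must have length %d", layout$K)
  out <- list()
  nT <- layout$n_occasions - 1L
  nc <- length(layout$colonies)
  for (cl in c("phi", "p", "psi")) {
    z <- layout$classes[[cl]]
    eta <- if (length(z$beta_idx)) drop(z$X %*% beta[z$beta_idx]) else
      rep(0, nrow(z$cells))
    eta <- pmin(pmax(eta, -35), 35)
    val <- plogis(eta)
    val[!z$free] <- z$fixed_val[!z$free]
    out[[cl]] <- array(val, dim = c(3L, nT, nc),
      dimnames = list(state = .state_labels, time = NULL,
        colony = layout$colonies))
  }
  names(out) <- c("phi", "p", "psimove")
  out
}

#' Transition kernel for one interval and colony
#'
#' Returns the 4x4 stochastic matrix over `{B, N, P, dead}` that combines
#' survival and state transition for one interval (row `s`:
#' `Phi_s * psi(s -> .)` over live destinations, `1 - Phi_s` to dead; dead is
#' absorbing), together with the state-wise detection probabilities at the
#' following occasion.
#'
#' @inheritParams compute_real
#' @param interval interval number (1 = first nonbreeding season).
#' @param colony colony name or index.
#' @param real optionally precomputed [compute_real()] output.
#' @return list with `M` (4x4 matrix, rows sum to 1) and `p_next` (length-4
#'   detection vector for occasion `interval + 1`; the dead entry is 0).
#' @export
transition_kernel <- function(beta, layout, interval, colony, real = NULL) {
  if (is.null(real)) real <- compute_real(beta, layout)
  k <- if (is.character(colony)) match(colony, layout$colonies) else colony
  .assert(!is.na(k) && k >= 1 && k <= length(layout$colonies),
    "unknown colony")
  .assert(interval >= 1 && interval <= layout$n_occasions - 1L,
    "interval out of range")
  M <- matrix(0, 4L, 4L,
    dimnames = list(c(.state_labels, "dead"), c(.state_labels, "dead")))
  for (s in 1:3) {
    phi <- real$phi[s, interval, k]
    mv <- real$psimove[s, interval, k]
    M[s, s] <- phi * (1 - mv)
    M[s, .move_dest[s]] <- M[s, .move_dest[s]] + phi * mv
    M[s, 4L] <- 1 - phi
  }
  M[4L, 4L] <- 1
  list(M = M, p_next = c(real$p[, interval, k], 0))
}

#' Multistate mark-recapture log-likelihood
#'
#' Forward recursion over the latent states `{B, N, P, dead}`, conditioned on
#' each individual's first capture (occasion and observed state). Per step the
#' state distribution is propagated by the interval's transition kernel and
#' then weighted by the event probability: detection in state `s` contributes
#' `p_s` on the matching latent state (observed states are assumed recorded
#' without misclassification), non-detection contributes `1 - p_s` for live
#' states and 1 for dead.
#'
#' @param histories an [msmr_histories]; its colony levels must match the
#'   layout's colonies.
#' @inheritParams compute_real
#' @return the total log-likelihood (a non-positive number).
#' @export
log_likelihood <- function(histories, beta, layout) {
  grp <- .group_histories(histories, layout)
  .ll_grouped(grp, beta, layout)
}

# Collapse histories to unique (colony, code pattern) groups with counts:
# the forward recursion then runs once per pattern, in lockstep over
# occasions, vectorized across patterns.
#' @noRd
.group_histories <- function(histories, layout) {
  .assert(is_histories(histories), "histories must be an msmr_histories")
  T <- layout$n_occasions
  .assert(ncol(histories$codes) == T,
    "histories have %d occasions but layout expects %d",
    ncol(histories$codes), T)
  kcol <- match(as.character(histories$colony), layout$colonies)
  .assert(!anyNA(kcol), "histories contain colonies unknown to the layout")
  key <- paste0(kcol, "|", apply(histories$codes, 1L, paste, collapse = ""))
  tab <- table(key)
  first_of <- match(names(tab), key)
  list(codes = histories$codes[first_of, , drop = FALSE],
    first = histories$first_occasion[first_of], kcol = kcol[first_of],
    cnt = as.integer(tab), T = T)
}

#' @noRd
.ll_grouped <- function(grp, beta, layout) {
  real <- compute_real(beta, layout)
  T <- grp$T
  U <- nrow(grp$codes)
  kern <- lapply(seq_along(layout$colonies), function(k)
    lapply(seq_len(T - 1L), function(t)
      transition_kernel(beta, layout, t, k, real = real)$M))
  kset <- sort(unique(grp$kcol))
  alpha <- matrix(0, U, 4L)
  for (t in seq_len(T)) {
    if (t > 1L) {
      started <- grp$first < t
      for (k in kset) {
        rows <- which(started & grp$kcol == k)
        if (length(rows)) {
          alpha[rows, ] <- alpha[rows, , drop = FALSE] %*% kern[[k]][[t - 1L]]
        }
      }
      pm <- matrix(real$p[, t - 1L, ], nrow = 3L)
      pu <- t(pm[, grp$kcol, drop = FALSE])
      y <- grp$codes[, t]
      det <- which(started & y > 0L)
      if (length(det)) {
        vals <- alpha[cbind(det, y[det])] * pu[cbind(det, y[det])]
        alpha[det, ] <- 0
        alpha[cbind(det, y[det])] <- vals
      }
      und <- which(started & y == 0L)
      if (length(und)) {
        alpha[und, 1:3] <- alpha[und, 1:3, drop = FALSE] *
          (1 - pu[und, , drop = FALSE])
      }
    }
    init <- which(grp$first == t)
    if (length(init)) alpha[cbind(init, grp$codes[init, t])] <- 1
  }
  sum(grp$cnt * log(pmax(rowSums(alpha), 1e-300)))
}

#' Effective sample size for QAICc
#'
#' Counted as release events: each occasion (other than the last) at which an
#' individual is encountered alive, and hence released back into the study,
#' contributes one.
#'
#' @param histories an [msmr_histories].
#' @return integer.
#' @export
effective_sample_size <- function(histories) {
  T <- ncol(histories$codes)
  sum(histories$codes[, seq_len(T - 1L), drop = FALSE] > 0L)
}

#' Fit a multistate mark-recapture model
#'
#' Maximizes [log_likelihood()] by quasi-Newton (BFGS) optimization with
#' numerical gradients and seeded multi-start (first start at the neutral
#' point beta = 0, further starts jittered). The covariance is the inverse
#' numerical Hessian; real-scale standard errors and 95% confidence intervals
#' come from the delta method on the logit scale, back-transformed.
#' Rank-deficient Hessians (boundary or confounded parameters, e.g. the
#' terminal survival x detection product of a fully time-dependent model) are
#' pseudo-inverted and the affected cells flagged inestimable.
#'
#' @param spec an [model_spec()].
#' @param histories an [msmr_histories].
#' @param n_starts number of optimizer starts (default 5).
#' @param seed seed for the start jitter.
#' @param maxit,reltol optimizer control.
#' @return object of class `msmr_fit`: `beta`, `vcov`, `minus2loglik`, `K`,
#'   `ess`, `real` (real-scale estimate table), `converged`, `label`,
#'   `layout`, `spec`, `starts` (per-start objective log).
#' @export
fit_msmr <- function(spec, histories, n_starts = 5L, seed = 1L,
                     maxit = 500L, reltol = 1e-10) {
  layout <- build_layout(spec, n_occasions = ncol(histories$codes),
    colonies = levels(histories$colony), years = histories$years)
  .assert(layout$K >= 1L, "model has no estimable coefficients")
  grp <- .group_histories(histories, layout)
  nll <- function(b) -.ll_grouped(grp, b, layout)
  set.seed(seed)
  starts <- matrix(rnorm(layout$K * n_starts, sd = 1.2), layout$K, n_starts)
  starts[, 1L] <- 0
  best <- NULL
  log <- data.frame(start = seq_len(n_starts), value = NA_real_,
    convergence = NA_integer_)
  for (j in seq_len(n_starts)) {
    o <- tryCatch(
      optim(starts[, j], nll, method = "BFGS",
        control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(o)) next
    log$value[j] <- o$value
    log$convergence[j] <- o$convergence
    if (is.null(best) || o$value < best$value - 1e-9) best <- o
  }
  if (is.null(best)) {
    stop("optimization failed from every start", call. = FALSE)
  }
  converged <- any(log$convergence == 0, na.rm = TRUE) &&
    is.finite(best$value)
  H <- tryCatch(optimHess(best$par, nll), error = function(e) NULL)
  V <- NULL
  flagged <- rep(FALSE, layout$K)
  if (!is.null(H)) {
    ev <- eigen(H, symmetric = TRUE)
    tol <- max(ev$values) * 1e-8
    ok <- ev$values > tol
    if (all(ok)) {
      V <- ev$vectors %*% (t(ev$vectors) / ev$values)
    } else {
      inv <- ifelse(ok, 1 / ev$values, 0)
      V <- ev$vectors %*% (t(ev$vectors) * inv)
      null_load <- abs(ev$vectors[, !ok, drop = FALSE])
      flagged <- apply(null_load, 1L, max) > 1e-4
    }
    dimnames(V) <- list(names(best$par), names(best$par))
  }
  real <- .real_table(best$par, V, layout, flagged)
  structure(list(beta = best$par, vcov = V, minus2loglik = 2 * best$value,
    K = layout$K, ess = effective_sample_size(histories), real = real,
    converged = converged, hessian_flagged = flagged, label = layout$label,
    layout = layout, spec = spec, starts = log, seed = seed),
    class = "msmr_fit")
}

#' @noRd
.real_table <- function(beta, V, layout, flagged) {
  out <- list()
  for (cl in c("phi", "p", "psi")) {
    z <- layout$classes[[cl]]
    eta <- if (length(z$beta_idx)) drop(z$X %*% beta[z$beta_idx]) else
      rep(0, nrow(z$cells))
    est <- plogis(eta)
    se <- se_eta <- rep(NA_real_, length(eta))
    inest <- rep(FALSE, length(eta))
    if (!is.null(V) && length(z$beta_idx)) {
      Vcl <- V[z$beta_idx, z$beta_idx, drop = FALSE]
      var_eta <- rowSums((z$X %*% Vcl) * z$X)
      var_eta[var_eta < 0] <- NA_real_
      se_eta <- sqrt(var_eta)
      se <- est * (1 - est) * se_eta
      inest <- apply(z$X[, flagged[z$beta_idx], drop = FALSE] != 0, 1L, any)
    }
    lcl <- plogis(eta - qnorm(0.975) * se_eta)
    ucl <- plogis(eta + qnorm(0.975) * se_eta)
    fixed <- !z$free
    est[fixed] <- z$fixed_val[fixed]
    se[fixed] <- 0
    lcl[fixed] <- ucl[fixed] <- z$fixed_val[fixed]
    inest[fixed] <- FALSE
    out[[cl]] <- data.frame(class = cl,
      state = as.character(z$cells$state),
      time = as.character(z$cells$time),
      colony = as.character(z$cells$colony),
      estimate = est, se = se, lcl = lcl, ucl = ucl,
      fixed = fixed, inestimable = inest)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.msmr_fit <- function(x, ...) {
  cat("Multistate mark-recapture fit:", x$label, "\n")
  cat(sprintf("  -2 log L = %.3f, K = %d, ESS = %d, converged: %s\n",
    x$minus2loglik, x$K, x$ess, x$converged))
  if (any(x$hessian_flagged)) {
    cat(sprintf("  %d coefficient(s) flagged confounded/inestimable\n",
      sum(x$hessian_flagged)))
  }
  invisible(x)
}

#' Real-scale estimates and predicted curves
#'
#' Without `at`, returns the per-cell real-scale estimate table of the fit
#' (fixed cells marked, psi reported both as the movement probability and the
#' by-subtraction "stay" probability). With `at`, predicts the named parameter
#' class over new covariate/factor values (e.g. a sardine grid per colony);
#' raw biomass values are standardized with the scaling stored at fit time,
#' and predictions beyond the observed covariate range are flagged
#' `extrapolated`.
#'
#' @param fit an [fit_msmr()] result.
#' @param at optional `data.frame` of predictor values (raw covariate scale).
#' @param class parameter class to predict when `at` is given.
#' @return a `data.frame` of estimates.
#' @export
real_estimates <- function(fit, at = NULL, class = "phi") {
  if (is.null(at)) {
    tab <- fit$real
    mv <- tab[tab$class == "psi", , drop = FALSE]
    if (nrow(mv)) {
      dest <- .state_labels[.move_dest[match(mv$state, .state_labels)]]
      mv$class <- "psi"
      mv$transition <- paste0(mv$state, "->", dest)
      stay <- mv
      stay$transition <- paste0(mv$state, "->", mv$state)
      stay$estimate <- 1 - mv$estimate
      stay$lcl <- 1 - mv$ucl
      stay$ucl <- 1 - mv$lcl
      rest <- tab[tab$class != "psi", , drop = FALSE]
      rest$transition <- NA_character_
      tab <- rbind(rest, mv, stay)
      rownames(tab) <- NULL
    }
    return(tab)
  }
  .assert(class %in% c("phi", "p", "psi"), "class must be phi, p or psi")
  z <- fit$layout$classes[[class]]
  at <- as.data.frame(at)
  extrap <- rep(FALSE, nrow(at))
  for (v in intersect(names(at), c("sardine", "anchovy", "combined"))) {
    rng <- fit$layout$cov_range[[v]]
    extrap <- extrap | at[[v]] < rng[1] | at[[v]] > rng[2]
    sc <- fit$layout$cov_scale[[v]]
    at[[v]] <- if (sc[["sd"]] == 0) at[[v]] - sc[["mean"]] else
      (at[[v]] - sc[["mean"]]) / sc[["sd"]]
  }
  Terms <- stats::delete.response(z$terms)
  mf <- model.frame(Terms, at, xlev = z$xlev)
  X <- model.matrix(Terms, mf)
  X <- X[, colnames(z$X), drop = FALSE]
  eta <- drop(X %*% fit$beta[z$beta_idx])
  se_eta <- rep(NA_real_, length(eta))
  if (!is.null(fit$vcov)) {
    Vcl <- fit$vcov[z$beta_idx, z$beta_idx, drop = FALSE]
    se_eta <- sqrt(pmax(rowSums((X %*% Vcl) * X), 0))
  }
  out <- cbind(at, data.frame(estimate = plogis(eta),
    se = plogis(eta) * (1 - plogis(eta)) * se_eta,
    lcl = plogis(eta - qnorm(0.975) * se_eta),
    ucl = plogis(eta + qnorm(0.975) * se_eta),
    extrapolated = extrap))
  if (any(extrap)) {
    warning("some predictions extrapolate beyond the observed covariate range")
  }
  out
}
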