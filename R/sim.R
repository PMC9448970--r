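# Synthetic-data generator: seeded detection records and encounter histories
# with known true parameters, emulating a two-colony PIT-tag study design
# (breeders-only marking in year 1, state-dependent detection, ground-reader
# ping streams inside the March-October breeding season).

#' Build a per-state probability array
#'
#' Helper to expand per-state scalars into the `state x interval/occasion x
#' colony` arrays used by [sim_config()].
#'
#' @param b,n,p probabilities for breeders, nonbreeders and prebreeders.
#' @param n_time number of intervals (survival/transition) or occasions
#'   (detection).
#' @param colonies character vector of colony names.
#' @return numeric array with dims `c(3, n_time, length(colonies))` and
#'   dimnames `state`, `time`, `colony`.
#' @export
state_rate_array <- function(b, n = b, p = b, n_time, colonies = .default_colonies) {
  arr <- array(rep(c(b, n, p), times = n_time * length(colonies)),
    dim = c(3L, n_time, length(colonies)),
    dimnames = list(state = .state_labels, time = NULL, colony = colonies)
  )
  arr
}

#' Build a transition-probability table with structural zeros
#'
#' Constructs the `origin x destination x interval x colony` transition table
#' from the three movement probabilities that remain free once the impossible
#' transitions psi(P->N), psi(N->P) and psi(B->P) are fixed to zero: each live
#' state either stays or moves to its single permitted alternative
#' (B->N, N->B, P->B).
#'
#' @param b_to_n,n_to_b,p_to_b movement probabilities, either scalars or
#'   vectors of length `length(colonies)` (recycled over intervals).
#' @param n_intervals number of survival intervals.
#' @param colonies colony names.
#' @return array with dims `c(3, 3, n_intervals, length(colonies))`; every row
#'   over destinations sums to 1.
#' @export
psi_table <- function(b_to_n, n_to_b, p_to_b, n_intervals,
                      colonies = .default_colonies) {
  nc <- length(colonies)
  mv <- rbind(rep(b_to_n, length.out = nc), rep(n_to_b, length.out = nc),
    rep(p_to_b, length.out = nc))
  arr <- array(0, dim = c(3L, 3L, n_intervals, nc),
    dimnames = list(from = .state_labels, to = .state_labels, NULL, colonies))
  for (k in seq_len(nc)) {
    for (t in seq_len(n_intervals)) {
      for (s in 1:3) {
        arr[s, s, t, k] <- 1 - mv[s, k]
        arr[s, .move_dest[s], t, k] <- mv[s, k]
      }
    }
  }
  arr
}

#' Default marking schedule
#'
#' Only breeders are marked in the first season; from the second season on,
#' both breeders and not-yet-breeding birds (prebreeders at marking) are
#' tagged. The second colony is given a larger cohort, and no prebreeders are
#' marked at the first colony in season 2, mirroring the study design that
#' motivates the default fixed parameters in [default_fixed_params()].
#'
#' @param n_occasions number of seasons.
#' @param colonies colony names.
#' @return integer array `colony x occasion x state` of newly marked counts.
#' @export
default_marking_schedule <- function(n_occasions = 8L,
                                     colonies = .default_colonies) {
  sched <- array(0L, dim = c(length(colonies), n_occasions, 3L),
    dimnames = list(colony = colonies, occasion = NULL, state = .state_labels))
  base_b <- c(60L, 80L)
  for (k in seq_along(colonies)) {
    sched[k, 1L, 1L] <- base_b[((k - 1L) %% 2L) + 1L]
    if (n_occasions >= 2L) {
      sched[k, 2:n_occasions, 1L] <- 25L
      sched[k, 2:n_occasions, 3L] <- 20L
    }
  }
  # colony 1 marks no nonbreeding birds in season 2
  if (n_occasions >= 2L) sched[1L, 2L, 3L] <- 0L
  sched
}

#' Simulation configuration
#'
#' Bundles the true demographic parameters and the observation process for the
#' synthetic-data generator. Defaults are set near field-realistic constant
#' estimates for a declining long-lived seabird (adult survival about 0.8,
#' breeder detection about 0.9, breeder-to-nonbreeder skipping 0.1-0.22).
#'
#' @param n_occasions number of breeding seasons (default 8, seasons
#'   `start_year` .. `start_year + n_occasions - 1`).
#' @param start_year first calendar season (default 2013).
#' @param colonies colony names.
#' @param marking_schedule integer array `colony x occasion x state` of newly
#'   marked individuals; default [default_marking_schedule()].
#' @param true_phi survival array `state x interval x colony` in \[0,1\].
#' @param true_p detection array `state x occasion x colony` in \[0,1\]
#'   (column 1 is unused: the marking capture is certain by conditioning).
#' @param true_psi transition array `origin x destination x interval x colony`;
#'   rows must sum to 1 and the structural zeros must be exactly 0.
#' @param ground_reader_rate named expected ping counts per season for
#'   `B`, `N`, `P` (the nonbreeder/prebreeder intensity is a free design
#'   choice; no published value exists for it).
#' @param nest_check_rate per-season probability that a breeding attempt is
#'   seen (with eggs/chicks) on nest inspections.
#' @param seed integer RNG seed recorded in the config and used by default by
#'   the generators.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_occasions = 8L, start_year = 2013L,
                       colonies = .default_colonies,
                       marking_schedule = default_marking_schedule(n_occasions, colonies),
                       true_phi = state_rate_array(0.80, 0.78, 0.75,
                         n_time = n_occasions - 1L, colonies = colonies),
                       true_p = state_rate_array(0.90, 0.55, 0.50,
                         n_time = n_occasions, colonies = colonies),
                       true_psi = psi_table(
                         b_to_n = c(0.22, 0.10), n_to_b = c(0.66, 0.69),
                         p_to_b = 0.5, n_intervals = n_occasions - 1L,
                         colonies = colonies),
                       ground_reader_rate = c(B = 20, N = 2, P = 2),
                       nest_check_rate = 0.7,
                       seed = 1L) {
  n_occasions <- as.integer(n_occasions)
  .assert(n_occasions >= 2L, "n_occasions must be >= 2")
  cfg <- structure(
    list(n_occasions = n_occasions, start_year = as.integer(start_year),
      colonies = colonies, marking_schedule = marking_schedule,
      true_phi = true_phi, true_p = true_p, true_psi = true_psi,
      ground_reader_rate = ground_reader_rate,
      nest_check_rate = nest_check_rate, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  T <- cfg$n_occasions
  nc <- length(cfg$colonies)
  .check_prob_array(cfg$true_phi, c(3L, T - 1L, nc), "true_phi")
  .check_prob_array(cfg$true_p, c(3L, T, nc), "true_p")
  .assert(identical(dim(cfg$true_psi), c(3L, 3L, T - 1L, nc)),
    "true_psi must have dim 3 x 3 x %d x %d", T - 1L, nc)
  bad <- which(cfg$true_psi < 0 | cfg$true_psi > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("true_psi[%s] outside [0,1]",
      paste(bad[1, ], collapse = ",")), call. = FALSE)
  }
  rs <- apply(cfg$true_psi, c(1, 3, 4), sum)
  off <- which(abs(rs - 1) > 1e-9, arr.ind = TRUE)
  if (nrow(off)) {
    stop(sprintf("true_psi row (from=%s, interval=%d, colony=%s) sums to %.6f, not 1",
      .state_labels[off[1, 1]], off[1, 2], cfg$colonies[off[1, 3]],
      rs[off[1, , drop = FALSE]]), call. = FALSE)
  }
  for (s in 1:3) {
    forb <- setdiff(1:3, c(s, .move_dest[s]))
    if (any(cfg$true_psi[s, forb, , ] != 0)) {
      stop(sprintf("structural zero violated: psi(%s->%s) must be exactly 0",
        .state_labels[s], .state_labels[forb]), call. = FALSE)
    }
  }
  .assert(all(cfg$marking_schedule >= 0), "marking_schedule counts must be non-negative")
  .assert(all(cfg$ground_reader_rate >= 0), "ground_reader_rate must be non-negative")
  .assert(cfg$nest_check_rate >= 0 && cfg$nest_check_rate <= 1,
    "nest_check_rate must be in [0,1]")
  cfg
}

#' @noRd
.check_prob_array <- function(x, dims, name) {
  .assert(identical(dim(x), dims), "%s must have dim %s", name,
    paste(dims, collapse = " x "))
  bad <- which(x < 0 | x > 1 | !is.finite(x), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s[%s] = %s is not a probability", name,
      paste(bad[1, ], collapse = ","), format(x[bad[1, , drop = FALSE]])),
      call. = FALSE)
  }
  invisible(x)
}

#' Simulate latent state trajectories
#'
#' Draws one latent trajectory per marked individual. Within each interval the
#' individual first survives with `Phi(state, interval, colony)` and then, if
#' alive, transitions by the corresponding `psi` row; death is absorbing and
#' emits nothing afterwards. States before first marking are `NA`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return object of class `msmr_truth`: list with `id`, `colony` (factor),
#'   `first_occasion`, `first_state`, `latent` (matrix individuals x occasions,
#'   codes 1=B, 2=N, 3=P, 4=dead, NA before marking) and `years`.
#' @export
simulate_latent <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  T <- config$n_occasions
  sched <- config$marking_schedule
  rows <- which(sched > 0, arr.ind = TRUE)
  n <- sum(sched)
  latent <- matrix(NA_integer_, n, T)
  colony <- integer(n)
  first_occ <- integer(n)
  first_state <- integer(n)
  id <- character(n)
  at <- 0L
  for (r in seq_len(nrow(rows))) {
    k <- rows[r, 1L]; m <- rows[r, 2L]; s <- rows[r, 3L]
    cnt <- sched[k, m, s]
    for (j in seq_len(cnt)) {
      at <- at + 1L
      colony[at] <- k
      first_occ[at] <- m
      first_state[at] <- s
      id[at] <- sprintf("%s-%02d%s-%04d", abbreviate(config$colonies[k], 3L),
        m, .state_labels[s], at)
      z <- s
      latent[at, m] <- z
      if (m < T) {
        for (t in m:(T - 1L)) {
          if (z != .dead) {
            if (runif(1) > config$true_phi[z, t, k]) {
              z <- .dead
            } else {
              z <- sample.int(3L, 1L, prob = config$true_psi[z, , t, k])
            }
          }
          latent[at, t + 1L] <- z
        }
      }
    }
  }
  structure(list(
    id = id, colony = factor(config$colonies[colony], levels = config$colonies),
    first_occasion = first_occ, first_state = first_state, latent = latent,
    years = config$start_year + 0:(T - 1L)),
    class = "msmr_truth")
}

#' @noRd
.season_window <- function(year) {
  c(as.Date(sprintf("%d-03-01", year)), as.Date(sprintf("%d-10-31", year)))
}

#' Emit detection records from a latent truth table
#'
#' Turns latent trajectories into dated detection records. For each alive
#' individual-season: latent breeders produce one nest-inspection record with
#' breeding evidence with probability `nest_check_rate`; every live state
#' produces a Poisson number of ground-reader pings with the state's
#' `ground_reader_rate`. Breeder records are dated uniformly within a
#' breeding-attempt window (`attempt_days`, default 110 days, placed uniformly
#' inside the March 1 - October 31 season) because breeders commute to the
#' colony for the duration of an attempt, not across the whole season;
#' nonbreeder and prebreeder pings are uniform over the full season. Records
#' never reveal the latent state (reader records carry no breeding evidence)
#' and dead individuals emit nothing.
#'
#' @inheritParams simulate_latent
#' @param truth output of [simulate_latent()].
#' @return `data.frame` with columns `individual_id`, `colony`, `date`
#'   (`Date`), `method` (`"nest"` or `"reader"`), `breeding_evidence` (0/1),
#'   sorted by individual and date.
#' @param attempt_days length (days) of the breeding-attempt window inside
#'   which a breeder's records are dated.
#' @export
emit_detections <- function(truth, config, seed = config$seed + 1L,
                            attempt_days = 110L) {
  set.seed(seed)
  T <- config$n_occasions
  rate <- config$ground_reader_rate[c("B", "N", "P")]
  out <- vector("list", length(truth$id) * 2L)
  oi <- 0L
  for (i in seq_along(truth$id)) {
    k <- as.integer(truth$colony[i])
    for (t in truth$first_occasion[i]:T) {
      z <- truth$latent[i, t]
      if (is.na(z) || z == .dead) next
      win <- .season_window(truth$years[t])
      days <- as.integer(win[2] - win[1])
      if (z == 1L) {
        # breeders attend the colony for one attempt, not the whole season
        w <- min(attempt_days, days)
        start <- win[1] + sample.int(days - w + 1L, 1L) - 1L
        day0 <- start
        span <- w
      } else {
        day0 <- win[1]
        span <- days
      }
      dates <- c()
      ev <- c()
      meth <- c()
      if (z == 1L && runif(1) < config$nest_check_rate) {
        dates <- day0 + sample.int(span + 1L, 1L) - 1L
        ev <- 1L
        meth <- "nest"
      }
      np <- rpois(1L, rate[[z]])
      if (np > 0L) {
        dates <- c(dates, day0 + sample.int(span + 1L, np, replace = TRUE) - 1L)
        ev <- c(ev, rep(0L, np))
        meth <- c(meth, rep("reader", np))
      }
      if (length(dates)) {
        oi <- oi + 1L
        out[[oi]] <- data.frame(
          individual_id = truth$id[i],
          colony = as.character(truth$colony[i]),
          date = as.Date(dates, origin = "1970-01-01"),
          method = meth, breeding_evidence = ev)
      }
    }
  }
  rec <- if (oi) do.call(rbind, out[seq_len(oi)]) else
    data.frame(individual_id = character(), colony = character(),
      date = as.Date(character()), method = character(),
      breeding_evidence = integer())
  rec <- rec[order(rec$individual_id, rec$date, rec$method), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Simulate encounter histories directly
#'
#' Shortcut generator at the history level, bypassing detection records: the
#' observation at each occasion after marking equals the latent state with
#' probability `p(state, occasion, colony)` and 0 (not seen) otherwise. The
#' marking occasion is observed with certainty (the capture is the marking),
#' matching the conditioning of the likelihood on first capture.
#'
#' @inheritParams simulate_latent
#' @param truth optionally a pre-simulated [simulate_latent()] truth table;
#'   drawn fresh from `config` when `NULL`.
#' @return an [msmr_histories] object.
#' @export
simulate_histories <- function(config, seed = config$seed, truth = NULL) {
  if (is.null(truth)) truth <- simulate_latent(config, seed = seed)
  set.seed(seed + 7L)
  T <- config$n_occasions
  codes <- matrix(0L, length(truth$id), T)
  for (i in seq_along(truth$id)) {
    k <- as.integer(truth$colony[i])
    f <- truth$first_occasion[i]
    codes[i, f] <- truth$latent[i, f]
    if (f < T) {
      for (t in (f + 1L):T) {
        z <- truth$latent[i, t]
        if (z %in% 1:3 && runif(1) < config$true_p[z, t, k]) codes[i, t] <- z
      }
    }
  }
  new_histories(id = truth$id, colony = truth$colony, codes = codes,
    years = truth$years)
}

#' Write detection records / truth / config to text files
#'
#' CSVs carry a `# seed: <n>` comment header line; [read_detections()] skips
#' comment lines.
#'
#' @param records data.frame from [emit_detections()].
#' @param path output file.
#' @param seed seed recorded in the header comment.
#' @export
write_detections <- function(records, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", seed), con)
  write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  rec <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  rec$date <- as.Date(rec$date)
  rec
}

#' @rdname write_detections
#' @param truth an `msmr_truth` object.
#' @export
write_truth <- function(truth, path, seed = NA) {
  df <- data.frame(individual_id = truth$id, colony = as.character(truth$colony),
    first_occasion = truth$first_occasion,
    first_state = .state_labels[truth$first_state])
  lat <- truth$latent
  colnames(lat) <- paste0("state_", truth$years)
  df <- cbind(df, as.data.frame(lat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", seed), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
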