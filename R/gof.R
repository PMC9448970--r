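# Goodness of fit for the general multistate model: contingency-table
# components in the spirit of the JMV omnibus test (Test3G on transitions of
# previously seen vs newly marked animals, TestM on immediate/longer-term
# encounter effects), overdispersion c-hat = chi2/df and QAICc.

#' Pearson chi-square with small-expectation pooling
#'
#' Computes the Pearson statistic of a contingency table after (a) dropping
#' all-zero rows/columns and (b) repeatedly merging the column containing the
#' smallest expected count below `min_expected` into its nearest neighbouring
#' column (then rows, if needed), decrementing the degrees of freedom
#' accordingly. Degenerate tables (fewer than 2 rows or columns after
#' pooling) contribute 0 on 0 df.
#'
#' @param tab numeric matrix of counts.
#' @param min_expected pooling threshold on expected counts (default 2).
#' @return list with `chi_square`, `df`, `table` (pooled).
#' @export
pooled_pearson <- function(tab, min_expected = 2) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  merge_dim <- function(tab, margin) {
    repeat {
      if (dim(tab)[margin] < 2L) return(tab)
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      small <- which(E < min_expected, arr.ind = TRUE)
      if (!nrow(small)) return(tab)
      cell <- small[which.min(E[small]), ]
      j <- cell[margin]
      jn <- if (j == 1L) 2L else j - 1L
      if (margin == 2L) {
        tab[, jn] <- tab[, jn] + tab[, j]
        tab <- tab[, -j, drop = FALSE]
      } else {
        tab[jn, ] <- tab[jn, ] + tab[j, ]
        tab <- tab[-j, , drop = FALSE]
      }
    }
  }
  tab <- merge_dim(tab, 2L)
  tab <- merge_dim(tab, 1L)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(chi_square = 0, df = 0L, table = tab))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi <- sum((tab - E)^2 / E)
  list(chi_square = chi, df = (nrow(tab) - 1L) * (ncol(tab) - 1L), table = tab)
}

#' @noRd
.gof_component <- function(name, tables) {
  tables <- Filter(function(tb) !is.null(tb) && sum(tb) > 0, tables)
  pooled <- lapply(tables, pooled_pearson)
  chi <- sum(vapply(pooled, `[[`, numeric(1), "chi_square"))
  df <- sum(vapply(pooled, `[[`, integer(1), "df"))
  list(name = name, chi_square = chi, df = df,
    p_value = if (df > 0) pchisq(chi, df, lower.tail = FALSE) else NA_real_,
    tables = pooled)
}

#' JMV-style goodness-of-fit components
#'
#' Contingency-table components of an omnibus goodness-of-fit test for the
#' general (time-, state- and colony-dependent) multistate model, computed
#' per colony and summed:
#' \describe{
#'   \item{Test3G.SR}{per occasion and state: newly marked vs previously seen
#'     animals cross-classified by whether they are ever re-encountered.}
#'   \item{Test3G.Sm}{per occasion and state, among previously seen animals
#'     re-encountered later: previous encounter immediately before vs
#'     earlier, against next encounter immediately after vs later.}
#'   \item{TestM.ITEC}{per occasion: animals encountered at `i` and known
#'     alive at `i + 1`, state at `i` against detected-at-`i+1` or not.}
#'   \item{TestM.LTEC}{per occasion: animals encountered at `i`, missed at
#'     `i + 1` but known alive at `i + 2`, state at `i` against
#'     detected-at-`i+2` or not.}
#' }
#' Cells with expected counts below 2 are pooled (see [pooled_pearson()]);
#' the omnibus statistic and df are the sums over components. With fewer than
#' 3 occasions the TestM components are empty (0 df).
#'
#' @param histories an [msmr_histories].
#' @return object of class `msmr_gof`: list of components plus `omnibus`
#'   (`chi_square`, `df`, `p_value`).
#' @export
jmv_components <- function(histories) {
  .assert(is_histories(histories), "histories must be an msmr_histories")
  T <- ncol(histories$codes)
  .assert(T >= 2L, "need at least 2 occasions")
  codes <- histories$codes
  first <- histories$first_occasion
  kcol <- as.integer(histories$colony)
  seen_after <- function(i, t) if (t >= T) rep(FALSE, length(i)) else
    rowSums(codes[i, (t + 1L):T, drop = FALSE] > 0L) > 0L
  tabs_sr <- list(); tabs_sm <- list(); tabs_itec <- list(); tabs_ltec <- list()
  for (k in sort(unique(kcol))) {
    for (t in 1:(T - 1L)) {
      for (s in 1:3) {
        at <- which(kcol == k & codes[, t] == s)
        if (!length(at)) next
        new <- first[at] == t
        again <- seen_after(at, t)
        if (t > 1L) {
          tabs_sr[[length(tabs_sr) + 1L]] <- table(
            factor(new, c(FALSE, TRUE)), factor(again, c(FALSE, TRUE)))
        }
        old_again <- at[!new & again]
        if (length(old_again) && t > 1L && t < T) {
          prev_imm <- codes[old_again, t - 1L] > 0L
          nxt_imm <- codes[old_again, t + 1L] > 0L
          tabs_sm[[length(tabs_sm) + 1L]] <- table(
            factor(prev_imm, c(FALSE, TRUE)), factor(nxt_imm, c(FALSE, TRUE)))
        }
      }
      # TestM strata: all animals seen at t, by state, on detection at t+1
      at <- which(kcol == k & codes[, t] > 0L)
      if (length(at)) {
        det_next <- codes[at, t + 1L] > 0L
        alive_next <- det_next | seen_after(at, t + 1L)
        sel <- at[alive_next]
        if (length(sel)) {
          tabs_itec[[length(tabs_itec) + 1L]] <- table(
            factor(.state_labels[codes[sel, t]], .state_labels),
            factor(codes[sel, t + 1L] > 0L, c(FALSE, TRUE)))
        }
        if (t <= T - 2L) {
          miss <- at[!det_next]
          if (length(miss)) {
            det_2 <- codes[miss, t + 2L] > 0L
            alive_2 <- det_2 | seen_after(miss, t + 2L)
            sel2 <- miss[alive_2]
            if (length(sel2)) {
              tabs_ltec[[length(tabs_ltec) + 1L]] <- table(
                factor(.state_labels[codes[sel2, t]], .state_labels),
                factor(codes[sel2, t + 2L] > 0L, c(FALSE, TRUE)))
            }
          }
        }
      }
    }
  }
  comps <- list(
    .gof_component("Test3G.SR", tabs_sr),
    .gof_component("Test3G.Sm", tabs_sm),
    .gof_component("TestM.ITEC", tabs_itec),
    .gof_component("TestM.LTEC", tabs_ltec))
  names(comps) <- vapply(comps, `[[`, character(1), "name")
  chi <- sum(vapply(comps, `[[`, numeric(1), "chi_square"))
  df <- sum(vapply(comps, `[[`, integer(1), "df"))
  structure(list(components = comps,
    omnibus = list(chi_square = chi, df = df,
      p_value = if (df > 0) pchisq(chi, df, lower.tail = FALSE) else NA_real_)),
    class = "msmr_gof")
}

#' @export
print.msmr_gof <- function(x, ...) {
  cat("Goodness of fit (JMV-style contingency components)\n")
  for (cm in x$components) {
    cat(sprintf("  %-11s chi2 = %8.3f  df = %3d  p = %s\n", cm$name,
      cm$chi_square, cm$df,
      if (is.na(cm$p_value)) "-" else format.pval(cm$p_value, digits = 3)))
  }
  cat(sprintf("  %-11s chi2 = %8.3f  df = %3d  p = %s\n", "omnibus",
    x$omnibus$chi_square, x$omnibus$df,
    if (is.na(x$omnibus$p_value)) "-" else
      format.pval(x$omnibus$p_value, digits = 3)))
  invisible(x)
}

#' @rdname jmv_components
#' @param gof an `msmr_gof` object.
#' @export
gof_table <- function(gof) {
  rows <- lapply(c(gof$components, list(c(list(name = "omnibus"), gof$omnibus))),
    function(cm) data.frame(component = cm$name, chi_square = cm$chi_square,
      df = cm$df, p_value = cm$p_value))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance inflation factor from a goodness-of-fit statistic
#'
#' `c-hat = chi2 / df`. Values below 1 indicate underdispersion and are
#' returned as-is with a message (set `floor_at_one = TRUE` to floor at 1).
#'
#' @param chi_square non-negative omnibus statistic.
#' @param df positive degrees of freedom.
#' @param floor_at_one floor the result at 1?
#' @return the variance inflation factor.
#' @export
chat_from_gof <- function(chi_square, df, floor_at_one = FALSE) {
  .assert(df > 0, "c-hat is undefined for df = 0")
  .assert(chi_square >= 0, "chi_square must be non-negative")
  chat <- chi_square / df
  if (chat < 1) {
    message(sprintf("c-hat = %.3f < 1 (underdispersion)%s", chat,
      if (floor_at_one) "; floored at 1" else ""))
    if (floor_at_one) chat <- 1
  }
  chat
}

#' QAICc
#'
#' Quasi-likelihood AIC with small-sample correction:
#' `(-2 lnL)/c-hat + 2K + 2K(K+1)/(ess - K - 1)`. Reduces to AICc at
#' `c-hat = 1`.
#'
#' @param minus2loglik -2 log-likelihood.
#' @param K number of estimated parameters.
#' @param ess effective sample size (must exceed `K + 1`).
#' @param chat variance inflation factor (> 0).
#' @return the QAICc value.
#' @export
qaicc <- function(minus2loglik, K, ess, chat = 1) {
  .assert(chat > 0, "chat must be positive")
  .assert(ess > K + 1,
    "effective sample size (%s) must exceed K + 1 (%s): small-sample correction undefined",
    ess, K + 1)
  minus2loglik / chat + 2 * K + 2 * K * (K + 1) / (ess - K - 1)
}

#' Model comparison table
#'
#' @param fits list of [fit_msmr()] results (one candidate set).
#' @param chat shared variance inflation factor.
#' @return `data.frame` with model, K, QDeviance, QAICc, delta, weight,
#'   sorted by QAICc.
#' @export
model_table <- function(fits, chat = 1) {
  rows <- lapply(fits, function(f) data.frame(model = f$label, K = f$K,
    minus2loglik = f$minus2loglik, qdeviance = f$minus2loglik / chat,
    QAICc = qaicc(f$minus2loglik, f$K, f$ess, chat),
    converged = f$converged))
  out <- do.call(rbind, rows)
  out <- out[order(out$QAICc), , drop = FALSE]
  out$delta <- out$QAICc - min(out$QAICc)
  w <- exp(-0.5 * out$delta)
  out$weight <- w / sum(w)
  rownames(out) <- NULL
  out
}

#' Parsimony rule on a model table
#'
#' Models within 2 QAICc units of the best are approximately equivalent; among
#' them the one with the fewest parameters is the most parsimonious, with ties
#' on `K` broken by the lower QAICc.
#'
#' @param tab a [model_table()] (columns `model`, `K`, `QAICc`, `delta`).
#' @return the label of the selected model.
#' @export
pick_parsimonious <- function(tab) {
  cand <- tab[tab$delta < 2, , drop = FALSE]
  cand <- cand[order(cand$K, cand$QAICc), , drop = FALSE]
  cand$model[1]
}

#' Stepwise QAICc model selection
#'
#' The selection procedure models recapture first, carries the best-supported
#' structure forward to survival, then transition. At each stage every
#' candidate formula for the focal class is fitted while the not-yet-selected
#' classes keep the general structure and already-selected classes keep their
#' winners; candidates are ranked by QAICc under a single shared `c-hat`
#' (estimated once from the general model's omnibus GOF, not per model).
#' Models within 2 QAICc units of the best are treated as equivalent and the
#' one with the fewest parameters wins. Non-converged candidates are excluded
#' with a logged reason.
#'
#' @param candidates named list with elements `p`, `phi`, `psi`, each a list
#'   of formulas/strings to try for that class.
#' @param histories an [msmr_histories].
#' @param chat shared variance inflation factor.
#' @param general named list of the general structures (defaults to
#'   `state * time * colony` for every class).
#' @param fixed,biomass passed to [model_spec()].
#' @param n_starts,seed passed to [fit_msmr()].
#' @return list with `table` (all stage fits), `chosen` (final
#'   [fit_msmr()]), `structures` (winning formula per class), `excluded`
#'   (non-converged candidates).
#' @export
select_stepwise <- function(candidates, histories, chat = 1,
                            general = list(phi = ~ state * time * colony,
                              p = ~ state * time * colony,
                              psi = ~ state * time * colony),
                            fixed = default_fixed_params(levels(histories$colony)),
                            biomass = NULL, n_starts = 2L, seed = 1L) {
  stages <- c("p", "phi", "psi")
  current <- general
  all_rows <- list()
  excluded <- data.frame(stage = character(), model = character(),
    reason = character())
  chosen_fit <- NULL
  for (st in stages) {
    cands <- candidates[[st]]
    .assert(!is.null(cands) && length(cands) >= 1L,
      "no candidates supplied for stage %s", st)
    fits <- list()
    for (cf in cands) {
      args <- current
      args[[st]] <- cf
      spec <- model_spec(phi = args$phi, p = args$p, psi = args$psi,
        fixed = fixed, biomass = biomass)
      f <- tryCatch(
        fit_msmr(spec, histories, n_starts = n_starts, seed = seed),
        error = function(e) e)
      if (inherits(f, "error") || !f$converged) {
        excluded <- rbind(excluded, data.frame(stage = st,
          model = if (inherits(f, "error")) deparse1(cf) else f$label,
          reason = if (inherits(f, "error")) conditionMessage(f) else
            "did not converge"))
        next
      }
      fits[[length(fits) + 1L]] <- f
    }
    .assert(length(fits) >= 1L, "every candidate failed at stage %s", st)
    tab <- model_table(fits, chat = chat)
    tab$stage <- st
    all_rows[[st]] <- tab
    winner <- pick_parsimonious(tab)
    wfit <- fits[[which(vapply(fits, `[[`, character(1), "label") == winner)[1]]]
    current[[st]] <- wfit$spec[[st]]
    chosen_fit <- wfit
  }
  list(table = do.call(rbind, all_rows), chosen = chosen_fit,
    structures = current, excluded = excluded)
}
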