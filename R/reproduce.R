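# Reproduction of the published study-scale results. The deposited encounter
# data are NOT bundled (no-download policy); obtain the Dryad deposit
# doi:10.5061/dryad.0rxwdbs3z manually, convert it to the .inp or CSV
# encounter-history dialect documented in write_inp(), and point this
# function (or the SKIPMARK_DRYAD_DIR environment variable, for the gated
# acceptance tests) at it.

#' Reproduce the study-scale analysis from deposited encounter data
#'
#' Runs the desk-scale checkpoints of the published analysis on a local copy
#' of the deposited data: filtered sample sizes by colony, the omnibus
#' goodness-of-fit statistic and c-hat, constant-model overall survival and
#' nonbreeder-to-breeder transition per colony, constant-model
#' breeder-to-nonbreeder skipping per colony, and (when a biomass series is
#' supplied) the sign of the sardine-survival slope per colony.
#'
#' @param histories_file path to the encounter histories (`.inp` dialect or
#'   the CSV mirror; see [write_inp()]).
#' @param biomass series CSV (`year`, `sardine`, `anchovy`) or `NULL` to
#'   skip the covariate model.
#' @param n_starts,seed passed to [fit_msmr()].
#' @return list with `n_individuals`, `n_by_colony`, `gof`, `chat`,
#'   `constant` (real-scale estimate table of the constant model) and,
#'   if biomass was supplied, `sardine_slopes` (named per colony, logit
#'   scale).
#' @export
reproduce_study_analysis <- function(histories_file, biomass = NULL,
                                     n_starts = 2L, seed = 1L) {
  histories <- if (grepl("\\.inp$", histories_file)) read_inp(histories_file)
    else read_histories_csv(histories_file)
  gof <- jmv_components(histories)
  chat <- if (gof$omnibus$df > 0) {
    suppressMessages(chat_from_gof(gof$omnibus$chi_square, gof$omnibus$df))
  } else 1
  fixed <- default_fixed_params(levels(histories$colony))
  const <- fit_msmr(model_spec(phi = ~colony, p = ~ state * colony,
    psi = ~ state * colony, fixed = fixed, label = "constant"),
    histories, n_starts = n_starts, seed = seed)
  out <- list(n_individuals = length(histories$id),
    n_by_colony = table(histories$colony),
    gof = gof, chat = chat, constant = real_estimates(const))
  if (!is.null(biomass)) {
    if (is.character(biomass)) biomass <- read_biomass_csv(biomass)
    sard <- fit_msmr(model_spec(phi = ~ sardine * colony,
      p = ~ state * colony, psi = ~ state * colony, fixed = fixed,
      biomass = biomass, label = "phi(sardine x colony)"),
      histories, n_starts = n_starts, seed = seed)
    b <- sard$beta
    z <- sard$layout$classes$phi
    nm <- colnames(z$X)
    slope_base <- b[z$beta_idx[match("sardine", nm)]]
    cols <- levels(histories$colony)
    slopes <- setNames(numeric(length(cols)), cols)
    slopes[1] <- slope_base
    for (kk in seq_along(cols)[-1]) {
      inter <- paste0("sardine:colony", cols[kk])
      j <- match(inter, nm)
      slopes[kk] <- slope_base + if (is.na(j)) 0 else b[z$beta_idx[j]]
    }
    out$sardine_slopes <- slopes
    out$sardine_fit <- sard
  }
  out
}
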