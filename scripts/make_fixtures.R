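#!/usr/bin/env Rscript
# Regenerates the bundled synthetic fixture under inst/extdata/synthetic/.
# All fixture content is synthetic (seeded generator output); the biomass
# series is an invented, field-plausible sequence, not survey data.
# Run from the repository root: Rscript scripts/make_fixtures.R

library(skipmark)

dir.create("inst/extdata/synthetic", recursive = TRUE, showWarnings = FALSE)

fixture_sim_config <- function() {
  colonies <- c("RobbenIsland", "StonyPoint")
  sched <- array(0L, dim = c(2, 8, 3),
    dimnames = list(colony = colonies, occasion = NULL, state = c("B", "N", "P")))
  sched[, 1, 1] <- c(6L, 8L)
  sched[, 2:8, 1] <- 2L
  sched[, 2:8, 3] <- 2L
  sched[1, 2, 3] <- 0L
  sim_config(marking_schedule = sched,
    ground_reader_rate = c(B = 6, N = 1.5, P = 1.5),
    nest_check_rate = 0.8, seed = 20130301)
}

cfg <- fixture_sim_config()
truth <- simulate_latent(cfg)
records <- emit_detections(truth, cfg)
message(sprintf("fixture: %d individuals, %d detection records",
  length(truth$id), nrow(records)))
write_detections(records, "inst/extdata/synthetic/detections.csv",
  seed = cfg$seed)
write_sim_config(cfg, "inst/extdata/synthetic/sim_config.json")

# synthetic biomass series (tonnes): sardine declining, anchovy fluctuating
bm <- data.frame(year = 2013:2019,
  sardine = c(680, 510, 420, 250, 310, 180, 140) * 1e3,
  anchovy = c(1.9, 2.4, 1.6, 2.1, 2.8, 1.7, 2.2) * 1e6)
con <- file("inst/extdata/synthetic/biomass.csv", "w")
writeLines("# synthetic spawner-biomass series (invented values, not survey data)", con)
write.csv(bm, con, row.names = FALSE)
close(con)

# reference output for the regression test: constant-model estimates from the
# full pipeline on this fixture
out <- tempfile("fixture-run")
config <- pipeline_config(
  detections_csv = "inst/extdata/synthetic/detections.csv",
  biomass_csv = "inst/extdata/synthetic/biomass.csv",
  candidates = list(p = "~ state", phi = c("~ 1", "~ colony"), psi = "~ state"),
  general = list(phi = "~ 1", p = "~ state", psi = "~ state"),
  n_starts = 1L, seed = 1L, out_dir = out)
run_pipeline(config)
file.copy(file.path(out, "constant_model_diagram.csv"),
  "inst/extdata/synthetic/reference_constant_estimates.csv", overwrite = TRUE)
message("reference written")
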