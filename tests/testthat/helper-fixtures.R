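# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- build()
  }
  .fixture_cache[[name]]
}

tiny_cfg <- function(...) {
  synth_config(n_positions = 16, n_tiles = 2, backgrounds_per_tile = 6, ...)
}

# exact (error-free) small study and its three-state fit
noiseless_study <- function() {
  fixture("noiseless_study", function() {
    synth_study(tiny_cfg(noise_frac = 0), seed = 7, noise = FALSE)
  })
}

noiseless_fit <- function() {
  fixture("noiseless_fit", function() {
    suppressWarnings(fit_energy_model(noiseless_study()$observations,
                                      n_states = 3))
  })
}

noisy_small_study <- function() {
  fixture("noisy_small_study", function() {
    synth_study(tiny_cfg(), seed = 17, noise = TRUE)
  })
}

# energy-estimate table emulating a fitted model: truth plus Gaussian
# estimation noise with known per-mutation SD
truth_estimates <- function(truth, sd = 0.15, seed = 1) {
  set.seed(seed)
  ddG <- truth$ddG
  tibble::tibble(
    mutation = ddG$mutation,
    position = ddG$position,
    ddGf_mean = ddG$ddGf + stats::rnorm(nrow(ddG), 0, sd),
    ddGf_sd = sd,
    ddGa_mean = ddG$ddGa + stats::rnorm(nrow(ddG), 0, sd),
    ddGa_sd = sd)
}

# two-residue PDB fixture with an altloc pair, a hydrogen and a ligand
pdb_fixture_lines <- function() {
  c(paste0("ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
           "  1.00  0.00           C"),
    paste0("ATOM      2  CB AALA A   1       1.000   0.000   0.000",
           "  1.00  0.00           C"),
    paste0("ATOM      3  CB BALA A   1       1.100   0.000   0.000",
           "  1.00  0.00           C"),
    paste0("ATOM      4  H   ALA A   1       0.500   0.500   0.000",
           "  1.00  0.00           H"),
    paste0("ATOM      5  CA  GLY A   2       3.000   4.000   0.000",
           "  1.00  0.00           C"),
    paste0("HETATM    6  C1  LIG A   3       2.000   2.000   2.000",
           "  1.00  0.00           C"),
    "END")
}
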