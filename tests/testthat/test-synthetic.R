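test_that("ground truth is deterministic for a fixed seed", {
  cfg <- tiny_cfg()
  t1 <- generate_truth(cfg, seed = 3)
  t2 <- generate_truth(cfg, seed = 3)
  expect_identical(t1$ddG, t2$ddG)
  expect_identical(t1$affine, t2$affine)
  expect_identical(ca_coords(t1$structure), ca_coords(t2$structure))
})

test_that("degenerate config: no allosteric effects outside the active site", {
  cfg <- tiny_cfg(frac_allosteric = 0, n_activating_sites = 0)
  tr <- generate_truth(cfg, seed = 5)
  outside <- tr$ddG[tr$ddG$site_class != "active_site", ]
  expect_true(all(outside$ddGa == 0))
})

test_that("invalid configs are rejected", {
  expect_error(synth_config(n_positions = 8, n_tiles = 5), "invalid config")
})

test_that("planted inhibitory decay is recovered by log-linear regression", {
  cfg <- synth_config(frac_allosteric = 0.5, n_activating_sites = 0,
                      allo_decay = -0.07)
  slopes <- vapply(1:5, function(s) {
    tr <- generate_truth(cfg, seed = 400 + s)
    pl <- tr$ddG[tr$ddG$site_class %in% c("allosteric", "active_site"), ]
    site_mean <- tapply(abs(pl$ddGa), pl$position, mean)
    d <- tr$site_class$distance[match(as.integer(names(site_mean)),
                                      tr$site_class$residue)]
    unname(stats::coef(stats::lm(log(site_mean) ~ d))[2])
  }, numeric(1))
  expect_equal(mean(slopes), -0.07, tolerance = 0.2)
})

test_that("truth covers all 19 substitutions per position in tiles", {
  tr <- generate_truth(tiny_cfg(), seed = 2)
  counts <- table(tr$ddG$position)
  expect_true(all(counts == 19))
  expect_equal(length(counts), 16)
  expect_true(all(tr$noise_sd$sd > 0))
})

test_that("library design: all singles in every background", {
  tr <- generate_truth(synth_config(n_positions = 10, n_tiles = 1,
                                    backgrounds_per_tile = 1), seed = 4)
  lib_wt <- generate_library(tr, backgrounds_per_tile = 1)
  # 1 tile x 10 positions, WT background only: 190 singles + WT
  expect_equal(nrow(lib_wt), 191)
  expect_equal(sum(lib_wt$order == 1), 190)
  expect_equal(sum(lib_wt$order == 0), 1)

  lib2 <- generate_library(tr, backgrounds_per_tile = 2)
  singles <- tr$ddG$mutation
  bg <- setdiff(unique(lib2$background_id), "WT")
  expect_length(bg, 1)
  # every single appears once per background (except at the bg position)
  bg_pos <- parse_mutation(bg)$position
  expected <- singles[parse_mutation(singles)$position != bg_pos]
  in_bg <- lib2[lib2$background_id == bg & lib2$order == 2, ]
  expect_setequal(
    setdiff(unlist(strsplit(in_bg$genotype, ";")), bg), expected)
  # a background that is itself a single makes its library doubles
  expect_true(all(lengths(strsplit(in_bg$genotype, ";")) == 2))
})

test_that("manual backgrounds outside their tile are rejected", {
  tr <- generate_truth(tiny_cfg(), seed = 4)
  far <- tr$ddG$mutation[tr$ddG$position == 16][1]
  expect_error(
    generate_library(tr, backgrounds = list(`1` = far,
                                            `2` = tr$ddG$mutation[300])),
    "outside tile")
})

test_that("observations: noiseless mode equals model predictions exactly", {
  tr <- generate_truth(tiny_cfg(noise_frac = 0), seed = 7)
  lib <- generate_library(tr)
  obs <- generate_observations(tr, lib, noise = FALSE)
  pred <- predict_fitness(obs, truth_model(tr))
  expect_equal(obs$fitness, pred$predicted, tolerance = 1e-12)
  # seeded determinism of noise draws
  o1 <- generate_observations(tr, lib, noise = TRUE, seed = 9)
  o2 <- generate_observations(tr, lib, noise = TRUE, seed = 9)
  expect_identical(o1$fitness, o2$fitness)
})

test_that("observation noise SD matches the configured value within 3%", {
  cfg <- synth_config(n_positions = 30, n_tiles = 2,
                      backgrounds_per_tile = 10)
  tr <- generate_truth(cfg, seed = 11)
  lib <- generate_library(tr)
  clean <- generate_observations(tr, lib, noise = FALSE)
  noisy <- generate_observations(tr, lib, noise = TRUE, seed = 12)
  expect_gt(nrow(noisy), 10000)
  z <- (noisy$fitness - clean$fitness) / noisy$sigma
  expect_equal(stats::sd(z), 1, tolerance = 0.03)
})

test_that("synthetic structures satisfy their geometric contract", {
  s <- generate_structure(40, seed = 9)
  ca <- ca_coords(s)
  consec <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(consec > 3 & consec < 4))
  site <- s$active_site
  dm <- as.matrix(stats::dist(ca[site, ]))
  expect_lt(max(dm), 12)
  # at least 4 heavy atoms per residue
  counts <- table(s$atoms$resSeq[s$atoms$record == "ATOM"])
  expect_true(all(counts >= 4))
  s2 <- generate_structure(40, seed = 9)
  expect_identical(s$atoms, s2$atoms)
})

test_that("study bundles are consistent and round-trip through TSV", {
  st <- noiseless_study()
  # observation count = genotypes x assays
  expect_equal(nrow(st$observations), 2 * nrow(st$genotypes))
  expect_true(all(st$observations$sigma > 0))
  # all genotype mutations exist in the truth
  muts <- unique(unlist(strsplit(st$genotypes$genotype[
    st$genotypes$order > 0], ";")))
  expect_true(all(muts %in% st$truth$ddG$mutation))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fitness_tsv(st$observations, path)
  back <- read_fitness_tsv(path)
  expect_equal(back$genotype, st$observations$genotype)
  expect_equal(back$fitness, st$observations$fitness, tolerance = 1e-9)
})

test_that("generator config round-trips through YAML", {
  cfg <- tiny_cfg(allo_decay = -0.05)
  path <- withr::local_tempfile(fileext = ".yml")
  write_synth_config(cfg, path)
  cfg2 <- read_synth_config(path)
  expect_equal(unclass(cfg)[order(names(cfg))],
               unclass(cfg2)[order(names(cfg2))])
})

test_that("single-substitution combinatorics", {
  expect_equal(count_possible_singles(1, 10), 190L)
  expect_equal(count_possible_singles(268, 536), 5111L)
})
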