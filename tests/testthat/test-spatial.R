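test_that("PDB parsing keeps the first altloc, drops hydrogens, keeps ligands", {
  s <- parse_pdb(pdb_fixture_lines())
  prot <- s$atoms[s$atoms$record == "ATOM", ]
  expect_equal(sort(unique(prot$resSeq)), c(1L, 2L))
  # altloc B and the hydrogen are gone
  expect_equal(nrow(prot[prot$resSeq == 1, ]), 2)
  expect_equal(nrow(prot[prot$resSeq == 2, ]), 1)
  lig <- s$atoms[s$atoms$record == "HETATM", ]
  expect_equal(lig$res_name, "LIG")
  # written and reparsed structures agree
  gen <- generate_structure(15, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(gen, path)
  back <- parse_pdb(path)
  expect_equal(nrow(back$atoms), nrow(gen$atoms))
  expect_equal(back$atoms$x, gen$atoms$x, tolerance = 1e-3)
})

test_that("malformed PDB records fail with a line number", {
  bad <- pdb_fixture_lines()
  bad[2] <- substr(bad[2], 1, 40)
  expect_error(parse_pdb(bad), "line 2")
})

test_that("minimum distances match brute force and conventions", {
  # two single-atom residues at (0,0,0) and (3,4,0): distance 5
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1L, 1L, 0, 0, 0),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            2L, 2L, 3, 4, 0))
  s <- parse_pdb(lines)
  d <- min_distance_to_active_site(s, residues = 1)
  expect_equal(d$distance[d$residue == 2], 5)
  # reference residues themselves sit at distance 0
  expect_equal(d$distance[d$residue == 1], 0)
  # brute-force oracle on a generated structure
  gen <- generate_structure(20, seed = 6)
  refs <- gen$active_site[1]
  dd <- min_distance_to_active_site(gen, ligands = "LIG", residues = refs)
  a <- gen$atoms
  ref_xyz <- as.matrix(a[(a$record == "HETATM" & a$res_name == "LIG") |
                           (a$record == "ATOM" & a$resSeq == refs),
                         c("x", "y", "z")])
  for (r in c(3, 11, 19)) {
    rx <- as.matrix(a[a$record == "ATOM" & a$resSeq == r,
                      c("x", "y", "z")])
    brute <- min(sqrt(outer(rowSums(rx^2), rep(1, nrow(ref_xyz))) +
                        outer(rep(1, nrow(rx)), rowSums(ref_xyz^2)) -
                        2 * rx %*% t(ref_xyz)))
    expect_equal(dd$distance[dd$residue == r], brute, tolerance = 1e-9)
  }
  expect_error(min_distance_to_active_site(gen, ligands = "ATP"),
               "ATP")
})

test_that("distances are invariant under rigid motion", {
  gen <- generate_structure(20, seed = 6)
  d0 <- min_distance_to_active_site(gen, ligands = "LIG")
  # rotate about z by 40 degrees and translate
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(gen$atoms[, c("x", "y", "z")]) %*% R +
    matrix(c(5, -3, 12), nrow(gen$atoms), 3, byrow = TRUE)
  rot <- gen
  rot$atoms$x <- xyz[, 1]; rot$atoms$y <- xyz[, 2]; rot$atoms$z <- xyz[, 3]
  d1 <- min_distance_to_active_site(rot, ligands = "LIG")
  expect_equal(d1$distance, d0$distance, tolerance = 1e-9)
})

test_that("exponential decay fits recover exact and degenerate inputs", {
  d <- seq(0, 30, length.out = 40)
  y <- 2.5 * exp(-0.07 * d)
  f <- fit_exponential_decay(d, y)
  expect_equal(f$amplitude, 2.5, tolerance = 1e-6)
  expect_equal(f$rate, -0.07, tolerance = 1e-6)
  expect_equal(f$d_half, log(2) / 0.07, tolerance = 1e-6)
  # every emitted fit satisfies d_half * |k| = ln 2
  expect_equal(f$d_half * abs(f$rate), log(2), tolerance = 1e-9)
  # constant response: rate 0, non-finite half-decay
  flat <- fit_exponential_decay(d, rep(1.3, 40))
  expect_equal(flat$rate, 0)
  expect_false(is.finite(flat$d_half))
  expect_error(fit_exponential_decay(d[1:2], y[1:2]), "3 points")
  expect_error(fit_exponential_decay(d, -y), "non-negative")
  expect_s3_class(autoplot(f), "ggplot")
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "rate"], f$rate)
  expect_equal(glance(f)$d_half, f$d_half)
})

test_that("decay confidence intervals cover the truth in noisy replicates", {
  covered <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    d <- stats::runif(250, 0, 40)
    y <- pmax(2 * exp(-0.06 * d) + stats::rnorm(250, 0, 0.05), 0)
    f <- fit_exponential_decay(d, y)
    covered <- covered +
      (f$ci95_rate[1] <= -0.06 && -0.06 <= f$ci95_rate[2])
  }
  expect_gte(covered / 20, 0.9)
})

test_that("half-decay distance follows ln2 over |k|", {
  expect_equal(half_decay(-0.6931), 1.00, tolerance = 1e-3)
  expect_equal(half_decay(0.1), half_decay(-0.1))
  expect_error(half_decay(0), "k = 0")
})

test_that("directional decay: degenerate slab reproduces the global fit", {
  st <- fixture("decay_truth", function() {
    generate_truth(synth_config(frac_allosteric = 0.5,
                                n_activating_sites = 0), seed = 21)
  })
  pl <- st$ddG[st$ddG$site_class %in% c("allosteric", "active_site"), ]
  sm <- tapply(abs(pl$ddGa), pl$position, mean)
  sv <- tibble::tibble(residue = as.integer(names(sm)),
                       value = as.numeric(sm))
  refs <- st$structure$active_site[1:2]
  global <- fit_exponential_decay(
    st$site_class$distance[match(sv$residue, st$site_class$residue)],
    sv$value)
  dir <- directional_decay(st$structure, sv, axis = "x", sign = "both",
                           slab = Inf, ligands = "LIG", residues = refs,
                           distance = "radial")
  expect_equal(dir$rate, global$rate, tolerance = 1e-6)
  expect_equal(dir$amplitude, global$amplitude, tolerance = 1e-6)
  expect_error(
    directional_decay(st$structure, sv[1:2, ], axis = "x", sign = "+",
                      ligands = "LIG", residues = refs), "fewer than 3")
})

test_that("directional decay detects planted single-axis anisotropy", {
  tr <- fixture("aniso_truth", function() {
    generate_truth(synth_config(frac_allosteric = 0.6,
                                n_activating_sites = 0,
                                anisotropy = c(x = -0.25, y = -0.05,
                                               z = -0.05)), seed = 21)
  })
  pl <- tr$ddG[tr$ddG$site_class %in% c("allosteric", "active_site"), ]
  sm <- tapply(abs(pl$ddGa), pl$position, mean)
  sv <- tibble::tibble(residue = as.integer(names(sm)),
                       value = as.numeric(sm))
  refs <- tr$structure$active_site[1:2]
  k <- vapply(c("x", "y", "z"), function(ax) {
    directional_decay(tr$structure, sv, axis = ax, sign = "both",
                      slab = 10, ligands = "LIG", residues = refs)$rate
  }, numeric(1))
  expect_gt(abs(k[["x"]]), abs(k[["y"]]))
  expect_gt(abs(k[["x"]]), abs(k[["z"]]))
})

test_that("matched subsampling is calibrated and detects planted contrasts", {
  # exchangeable case: activating set is a subsample of the inactivating
  ps <- vapply(1:40, function(s) {
    set.seed(s)
    d <- stats::runif(60, 0, 30)
    inact <- tibble::tibble(d = d, ddGa = stats::rlnorm(60, 0, 0.5))
    act <- inact[sample(60, 25), ]
    act$ddGa <- -act$ddGa
    matched_subsample_decay_test(inact, act, n_subsamples = 150,
                                 seed = 1000 + s)$p
  }, numeric(1))
  expect_equal(mean(ps), 0.5, tolerance = 0.05)
  # planted contrast: decaying inactivating vs flat activating
  set.seed(77)
  d_in <- stats::runif(150, 0, 35)
  inact <- tibble::tibble(d = d_in,
                          ddGa = 2 * exp(-0.1 * d_in) *
                            stats::rlnorm(150, 0, 0.2))
  d_ac <- stats::runif(40, 0, 35)
  act <- tibble::tibble(d = d_ac,
                        ddGa = -sample(inact$ddGa, 40))
  res <- matched_subsample_decay_test(inact, act, n_subsamples = 400,
                                      seed = 3)
  expect_lte(res$p, 0.01)
  # seeded determinism
  res2 <- matched_subsample_decay_test(inact, act, n_subsamples = 400,
                                       seed = 3)
  expect_identical(res$p, res2$p)
  # unfillable magnitude bins raise an informative error
  tiny <- tibble::tibble(d = c(1, 2, 3), ddGa = c(0.1, 0.1, 0.1))
  big <- tibble::tibble(d = c(1, 2, 3), ddGa = -c(10, 20, 30))
  expect_error(matched_subsample_decay_test(tiny, big), "bins")
})

test_that("site clustering test: degenerate, planted and null behaviour", {
  s <- fixture("cluster_structure", function() generate_structure(50, 3))
  all_res <- seq_len(50)
  # degenerate: sites = all residues, null equals observed
  expect_equal(site_clustering_test(all_res, s, n_random = 50, seed = 1)$p,
               1)
  # tightly planted cluster: the active site and its neighbours
  ca <- ca_coords(s)
  center <- s$active_site[1]
  tight <- order(sqrt(rowSums(sweep(ca, 2, ca[center, ])^2)))[1:8]
  expect_lte(site_clustering_test(tight, s, n_random = 400, seed = 2)$p,
             0.01)
  expect_lte(site_clustering_test(tight, s, n_random = 400,
                                  mode = "connectivity", seed = 2)$p, 0.01)
  expect_error(site_clustering_test(c(1, 99), s), "absent")
})

test_that("loess distance correction centres residuals and flags offsets", {
  set.seed(9)
  d <- stats::runif(200, 0, 30)
  y <- 2 * exp(-0.08 * d)
  res <- distance_corrected_effects(d, y)
  # exactly exponential input: residuals centred near zero per decile
  dec <- cut(d, stats::quantile(d, seq(0, 1, 0.1)), include.lowest = TRUE)
  expect_true(all(abs(tapply(res$residual, dec, stats::median)) < 0.02))
  expect_lt(abs(sum(res$residual)), 1e-6 * 200 * stats::sd(y) + 0.5)
  # a planted negative offset for one class shows up in its residuals
  klass <- rep(c("helix", "strand"), 100)
  y2 <- y + ifelse(klass == "strand", -0.3, 0) + stats::rnorm(200, 0, 0.02)
  res2 <- distance_corrected_effects(d, y2)
  expect_lt(stats::median(res2$residual[klass == "strand"]),
            stats::median(res2$residual[klass == "helix"]))
  expect_lt(stats::median(res2$residual[klass == "strand"]), 0)
  expect_error(distance_corrected_effects(d, y, span = 1.5), "span")
  expect_error(distance_corrected_effects(d[1:5], y[1:5]), "10 points")
})
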