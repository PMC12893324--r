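test_that("BH adjustment matches hand-computed values and preserves order", {
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  # hand-computed five-value case: p * n / rank with step-up monotonicity
  p <- c(0.003, 0.04, 0.02, 0.9, 0.25)
  expect_equal(bh_fdr(p), c(0.015, 0.0666666666666667, 0.05, 0.9, 0.3125),
               tolerance = 1e-12)
  # permutation invariance after restoring order
  set.seed(4)
  p2 <- stats::runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p2)[perm], bh_fdr(p2[perm]))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("z-test classification applies signed boundaries and thresholds", {
  est <- tibble::tibble(
    mutation = c("A1C", "A1D", "A1E", "A1F"),
    ddGf_mean = c(1.5, 0.4, 0, -1.5),
    ddGf_sd = c(0.25, 0.25, 0.1, 0.25),
    ddGa_mean = c(0, 0, 0, 0),
    ddGa_sd = rep(0.1, 4))
  cl <- classify_mutations(est)
  # mean 1.5, sd 0.25 vs +0.5 boundary: Z = -4, one-sided p ~ 3.17e-5
  p_raw <- stats::pnorm(-4)
  expect_equal(p_raw, 3.16712e-05, tolerance = 1e-4)
  expect_true(cl$destabilizing[1])
  # below threshold: never labelled regardless of sd
  expect_false(cl$destabilizing[2])
  expect_false(cl$stabilizing[2])
  expect_equal(cl$label_f[3], "none")
  expect_true(cl$stabilizing[4])
  # one mutation per family: fdr equals the raw one-sided p
  single <- classify_mutations(est[1, ])
  expect_equal(single$fdr_f, p_raw, tolerance = 1e-10)
})

test_that("zero-sd estimates classify by the point estimate", {
  est <- tibble::tibble(mutation = c("A1C", "A1D"),
                        ddGf_mean = c(2, 0.2), ddGf_sd = 0,
                        ddGa_mean = 0, ddGa_sd = 0.1)
  cl <- classify_mutations(est)
  expect_true(cl$destabilizing[1])
  expect_false(cl$destabilizing[2])
})

test_that("Fisher enrichment matches closed forms", {
  r <- fisher_enrichment(c(10, 10), c(10, 10))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  r2 <- fisher_enrichment(c(5, 0), c(0, 5))
  expect_equal(r2$odds_ratio, Inf)
  expect_equal(r2$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  r3 <- fisher_enrichment(c(20, 5), c(10, 40))
  expect_equal(r3$odds_ratio, 16)
  expect_error(fisher_enrichment(c(-1, 2), c(3, 4)), "negative")
})

test_that("Fisher p equals exact hypergeometric enumeration (sampled margins)", {
  # oracle: sum of dhyper probabilities <= the observed table's
  enum_p <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, n, k)
    sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(12)
  for (i in 1:300) {
    tot <- sample(4:30, 1)
    a <- sample(0:tot, 1)
    b <- sample(0:(tot - a), 1)
    c_ <- sample(0:(tot - a - b), 1)
    d <- tot - a - b - c_
    expect_equal(fisher_enrichment(c(a, b), c(c_, d))$p_value,
                 min(enum_p(a, b, c_, d), 1), tolerance = 1e-9,
                 info = paste(a, b, c_, d))
  }
})

test_that("group enrichment builds correct 2x2 tables", {
  muts <- tibble::tibble(position = rep(1:4, each = 5),
                         hit = c(rep(TRUE, 5), rep(FALSE, 15)))
  groups <- tibble::tibble(position = 1:4,
                           group = c("a", "a", "b", "b"))
  res <- group_enrichment(muts, groups, "hit")
  ga <- res[res$group == "a", ]
  expect_equal(ga$a, 5)
  expect_equal(ga$b, 5)
  expect_equal(ga$c, 0)
  expect_equal(ga$d, 10)
  expect_equal(res$fdr, bh_fdr(res$p_value))
})

test_that("major allosteric sites recover planted sites and obey exclusions", {
  st <- fixture("enrichment_study", function() {
    synth_study(synth_config(frac_allosteric = 0.25), seed = 31,
                noise = TRUE)
  })
  tr <- st$truth
  est <- truth_estimates(tr, sd = 0.15, seed = 5)
  cl <- classify_mutations(est)
  res <- major_allosteric_sites(cl, tr$structure$active_site)
  # planted sites with strong effects (the decay law attenuates distant
  # ones below the 0.5 kcal/mol call threshold)
  site_mean <- tapply(abs(tr$ddG$ddGa), tr$ddG$position, mean)
  strong <- intersect(
    tr$site_class$residue[tr$site_class$class == "allosteric"],
    as.integer(names(site_mean))[site_mean >= 1])
  expect_gte(length(strong), 3)
  found <- res$residue[res$major_site]
  # strong planted sites have 19 large-effect mutations: near-complete
  # recovery
  expect_gte(mean(strong %in% found), 0.9)
  planted <- tr$site_class$residue[tr$site_class$class == "allosteric"]
  # active-site residues are excluded even though enriched
  expect_false(any(tr$structure$active_site %in% found))
  # residues with zero significant mutations are never returned
  zero_sig <- res$residue[res$a == 0]
  expect_false(any(zero_sig %in% found))
  # inhibitory-only and activating variants run
  inh <- major_allosteric_sites(cl, tr$structure$active_site,
                                mode = "inhibitory")
  expect_true(all(inh$residue[inh$major_site] %in% res$residue))
  expect_warning(major_allosteric_sites(cl, integer()), "active-site")
})

test_that("per-site energy summaries use inverse-variance weights", {
  est <- tibble::tibble(mutation = c("A1C", "A1D"),
                        ddGa_mean = c(1, 3), ddGa_sd = c(0.1, 0.2))
  ss <- site_energy_summary(est)
  w <- 1 / c(0.1, 0.2)^2
  expect_equal(ss$weighted_mean_ddGa, sum(w * c(1, 3)) / sum(w))
  expect_equal(ss$mean_ddGa, 2)
  expect_equal(ss$mean_abs_ddGa, 2)
})
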