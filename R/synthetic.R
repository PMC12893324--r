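## Synthetic-study generator: ground-truth energies, mutagenesis library,
## fitness observations, toy structure, contacts, pockets, annotations.

#' Generator settings for a synthetic study
#'
#' Defaults describe a desk-scale study with the statistical structure the
#' downstream analysis assumes: a tiled deep mutagenesis library with
#' multiple genetic backgrounds per tile, a mostly-neutral surface, a
#' destabilized buried core, inhibitory activity effects that decay
#' exponentially with distance from a planted active site, and a small
#' number of distance-independent activating sites.
#'
#' @param n_positions Number of mutagenised positions (and structure
#'   residues).
#' @param n_tiles Number of library tiles (positions split contiguously).
#' @param backgrounds_per_tile Genetic backgrounds per tile (includes WT).
#' @param active_site_size Number of planted active-site residues.
#' @param frac_core Fraction of non-active-site positions treated as buried
#'   core (destabilising folding effects).
#' @param frac_stabilizing Fraction of surface positions carrying
#'   stabilising mutations (`ddGf = -|N(0, stabilizing_sd)|`), emulating
#'   the stabilising clusters real folding landscapes contain; these also
#'   give the background selection genuine dynamic range below the wild
#'   type.
#' @param stabilizing_sd Scale of stabilising folding effects (kcal/mol).
#' @param frac_allosteric Fraction of remaining positions planted as
#'   inhibitory allosteric sites.
#' @param n_activating_sites Number of planted activating sites
#'   (distance-independent negative ddGa).
#' @param neutral_f_sd SD (kcal/mol) of the neutral folding-effect spike.
#' @param neutral_a_sd SD (kcal/mol) of neutral activity effects (0 keeps
#'   non-planted ddGa exactly zero).
#' @param core_shape,core_scale Gamma parameters of destabilising ddGf added
#'   at core positions.
#' @param allo_amplitude Amplitude `a` (kcal/mol) of the planted inhibitory
#'   decay law `a * exp(k * d)`.
#' @param allo_decay Decay rate `k` (1/Angstrom, negative) of planted
#'   inhibitory effects.
#' @param allo_lnorm_sd sdlog of the mean-one lognormal scatter multiplying
#'   planted magnitudes.
#' @param anisotropy Optional named vector `c(x=,y=,z=)` of per-axis decay
#'   rates; when given, planted magnitudes follow
#'   `a * exp(kx|dx| + ky|dy| + kz|dz|)` in the structure frame.
#' @param activating_sd Scale of activating effects, `ddGa = -|N(0, sd)|`.
#' @param wt_dGf,wt_dGa Wild-type energies (kcal/mol).
#' @param noise_frac Per assay-block fitness noise SD as a fraction of the
#'   affine output span (|slope|).
#' @param sigma_floor Smallest recorded fitness error (keeps weights finite
#'   in the noiseless limit).
#' @param saturated_background Plant one activity-dead, unstable background
#'   in the last tile (narrow fitness range), to exercise background
#'   exclusion during fitting.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_positions = 50, n_tiles = 5,
                         backgrounds_per_tile = 10,
                         active_site_size = 5,
                         frac_core = 0.3, frac_allosteric = 0.15,
                         frac_stabilizing = 0.1, stabilizing_sd = 0.6,
                         n_activating_sites = 3,
                         neutral_f_sd = 0.1, neutral_a_sd = 0,
                         core_shape = 2.5, core_scale = 0.6,
                         allo_amplitude = 2, allo_decay = -0.07,
                         allo_lnorm_sd = 0.3,
                         anisotropy = NULL,
                         activating_sd = 1.25,
                         wt_dGf = -1.5, wt_dGa = 0,
                         noise_frac = 0.1, sigma_floor = 1e-3,
                         saturated_background = FALSE) {
  cfg <- as.list(environment())
  if (n_positions < 2 * n_tiles) {
    stop("invalid config: n_positions must be at least 2 x n_tiles")
  }
  structure(cfg, class = "synth_config")
}

tile_bounds_of <- function(n_positions, n_tiles) {
  cuts <- floor(seq(0, n_positions, length.out = n_tiles + 1))
  tibble::tibble(tile = seq_len(n_tiles),
                 start = cuts[-length(cuts)] + 1L, end = cuts[-1])
}

# mean-one lognormal scatter
rlnorm1 <- function(n, sdlog) stats::rlnorm(n, meanlog = -sdlog^2 / 2,
                                            sdlog = sdlog)

#' Generate ground-truth energies paired with a synthetic structure
#'
#' Assigns each position a class (active-site, core, allosteric, activating,
#' neutral) and draws per-mutation ddGf/ddGa from class-specific
#' distributions: neutral folding effects N(0, `neutral_f_sd`); Gamma
#' destabilisation at core positions; inhibitory ddGa at active-site and
#' allosteric positions whose expected magnitude follows
#' `a * exp(k * d)` against distance `d` from the active site in the paired
#' structure; and distance-independent activating ddGa at designated sites.
#' All 19 substitutions are covered at every position. Deterministic for a
#' fixed seed.
#'
#' @param config A [synth_config()].
#' @param seed Integer RNG seed.
#' @param structure Optional pre-built `structure_model`; generated from the
#'   same seed when omitted.
#' @return A list of class `ground_truth` (energies, affine layers, noise
#'   SDs, tile bounds, site classes, paired structure and distances).
#' @export
generate_truth <- function(config = synth_config(), seed,
                           structure = NULL) {
  stopifnot(inherits(config, "synth_config"), is.numeric(seed))
  n <- config$n_positions
  if (is.null(structure)) {
    structure <- generate_structure(n, seed = seed,
                                    active_site_size = config$active_site_size)
  }
  set.seed(seed + 1)
  atoms <- structure$atoms
  wt3 <- atoms$res_name[atoms$record == "ATOM" & atoms$atom_name == "CA"]
  wt_aa <- names(AA3)[match(wt3, AA3)]
  active_site <- structure$active_site

  refs_res <- active_site[seq_len(min(2, length(active_site)))]
  dist_tbl <- min_distance_to_active_site(structure, ligands = "LIG",
                                          residues = refs_res)
  d <- dist_tbl$distance[match(seq_len(n), dist_tbl$residue)]

  # position classes: active site, then most-buried core, then planted sites
  ca <- ca_coords(structure)
  burial <- sqrt(rowSums(sweep(ca, 2, colMeans(ca))^2))
  pool <- setdiff(seq_len(n), active_site)
  # core positions are the most buried within each tile: every tile of a
  # folded domain spans both buried core and surface
  tb0 <- tile_bounds_of(n, config$n_tiles)
  tile_of0 <- findInterval(seq_len(n), tb0$start)
  core <- unlist(lapply(split(pool, tile_of0[pool]), function(px) {
    px[order(burial[px])][seq_len(round(config$frac_core * length(px)))]
  }), use.names = FALSE)
  core <- sort(core)
  pool2 <- setdiff(pool, core)
  n_allo <- round(config$frac_allosteric * length(pool2))
  allo <- sort(sample(pool2, n_allo))
  pool3 <- setdiff(pool2, allo)
  # activating and stabilising positions are stratified across tiles so
  # that every tile can contribute backgrounds spanning weak-to-strong
  # effects on both energies (the design constraint the nonlinear fit
  # relies on)
  tb <- tile_bounds_of(n, config$n_tiles)
  tile_of <- findInterval(seq_len(n), tb$start)
  sample_stratified <- function(pool, k) {
    if (k <= 0 || !length(pool)) return(integer())
    by_tile <- split(pool, tile_of[pool])
    picked <- integer()
    ti <- rep_len(seq_along(by_tile), k)
    for (t in ti) {
      avail <- setdiff(by_tile[[t]], picked)
      if (!length(avail)) avail <- setdiff(pool, picked)
      if (!length(avail)) break
      picked <- c(picked, if (length(avail) == 1) avail else sample(avail, 1))
    }
    sort(picked)
  }
  act <- sample_stratified(pool3, if (config$n_activating_sites > 0)
    max(config$n_activating_sites, config$n_tiles) else 0L)
  pool4 <- setdiff(pool3, act)
  n_stab <- round(config$frac_stabilizing * length(pool))
  stab <- sample_stratified(pool4, if (n_stab > 0)
    max(n_stab, config$n_tiles) else 0L)
  klass <- rep("neutral", n)
  klass[core] <- "core"
  klass[allo] <- "allosteric"
  klass[act] <- "activating"
  klass[stab] <- "stabilizing"
  klass[active_site] <- "active_site"

  # per-mutation energies, 19 substitutions per position
  ddG <- tidyr::crossing(position = seq_len(n), mut_aa = AA_ALPHABET) |>
    dplyr::mutate(wt_aa = wt_aa[.data$position]) |>
    dplyr::filter(.data$mut_aa != .data$wt_aa) |>
    dplyr::mutate(mutation = mutation_id(.data$wt_aa, .data$position,
                                         .data$mut_aa),
                  site_class = klass[.data$position])
  m <- nrow(ddG)
  ddG$ddGf <- stats::rnorm(m, 0, config$neutral_f_sd)
  is_core <- ddG$site_class == "core"
  ddG$ddGf[is_core] <- ddG$ddGf[is_core] +
    stats::rgamma(sum(is_core), shape = config$core_shape,
                  scale = config$core_scale)
  is_stab <- ddG$site_class == "stabilizing"
  ddG$ddGf[is_stab] <- ddG$ddGf[is_stab] -
    abs(stats::rnorm(sum(is_stab), 0, config$stabilizing_sd))
  ddG$ddGa <- if (config$neutral_a_sd > 0) {
    stats::rnorm(m, 0, config$neutral_a_sd)
  } else rep(0, m)

  planted <- ddG$site_class %in% c("active_site", "allosteric")
  if (any(planted)) {
    dp <- d[ddG$position[planted]]
    mag <- if (!is.null(config$anisotropy)) {
      disp <- sweep(ca[ddG$position[planted], , drop = FALSE], 2,
                    active_site_centroid(structure, ligands = "LIG",
                                         residues = refs_res))
      k <- config$anisotropy[c("x", "y", "z")]
      config$allo_amplitude * exp(abs(disp) %*% cbind(as.numeric(k)))[, 1]
    } else {
      config$allo_amplitude * exp(config$allo_decay * dp)
    }
    ddG$ddGa[planted] <- mag * rlnorm1(sum(planted), config$allo_lnorm_sd)
  }
  is_act <- ddG$site_class == "activating"
  ddG$ddGa[is_act] <- -abs(stats::rnorm(sum(is_act), 0, config$activating_sd))

  affine <- tidyr::crossing(assay = c("activity", "abundance"),
                            block = seq_len(config$n_tiles)) |>
    dplyr::mutate(intercept = stats::runif(dplyr::n(), -0.2, 0.2),
                  slope = stats::runif(dplyr::n(), 0.8, 1.2))
  noise_sd <- affine |>
    dplyr::transmute(.data$assay, .data$block,
                     sd = pmax(config$noise_frac * abs(.data$slope),
                               config$sigma_floor))

  structure(list(
    wt_sequence = paste(wt_aa, collapse = ""),
    tile_bounds = tile_bounds_of(n, config$n_tiles),
    ddG = ddG[, c("mutation", "wt_aa", "position", "mut_aa",
                  "site_class", "ddGf", "ddGa")],
    wt_dGf = config$wt_dGf, wt_dGa = config$wt_dGa,
    affine = affine, noise_sd = noise_sd,
    site_class = tibble::tibble(residue = seq_len(n), class = klass,
                                distance = d),
    structure = structure, config = config, seed = seed),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nchar(x$wt_sequence), " positions, ",
      nrow(x$ddG), " mutations, ", nrow(x$tile_bounds), " tiles\n", sep = "")
  print(table(x$site_class$class))
  invisible(x)
}

#' Energy model of a ground truth
#'
#' @param truth A `ground_truth`.
#' @param const A [thermo_const()].
#' @return The generating three-state [energy_model()].
#' @export
truth_model <- function(truth, const = thermo_const()) {
  energy_model(truth$ddG[, c("mutation", "ddGf", "ddGa")],
               wt_dGf = truth$wt_dGf, wt_dGa = truth$wt_dGa,
               affine = truth$affine, n_states = 3, const = const)
}

join_genotype <- function(muts) {
  if (!length(muts)) return("")
  paste(muts[order(parse_mutation(muts)$position)], collapse = ";")
}

select_backgrounds <- function(singles, n_bg) {
  # deterministic quantile spacing of true effects on each energy
  if (n_bg <= 1) return(character())
  n_f <- ceiling((n_bg - 1) / 2)
  n_a <- (n_bg - 1) - n_f
  pick <- function(ord, k, taken) {
    if (k == 0) return(character())
    idx <- unique(round(stats::quantile(seq_along(ord),
                                        probs = seq(0.02, 0.98,
                                                    length.out = k))))
    out <- character(0)
    for (i in idx) {
      j <- i
      while (ord[j] %in% c(taken, out) && j < length(ord)) j <- j + 1
      out <- c(out, ord[j])
    }
    unique(out)
  }
  ord_f <- singles$mutation[order(singles$ddGf)]
  ord_a <- singles$mutation[order(singles$ddGa)]
  bg_f <- pick(ord_f, n_f, character())
  bg_a <- pick(ord_a, n_a, bg_f)
  unique(c(bg_f, bg_a))
}

#' Generate the tiled variant library
#'
#' For each tile: every single substitution introduced into every genetic
#' background of that tile. Backgrounds are the wild type plus single
#' mutants chosen by fixed quantile spacing of their true effects on each
#' energy (weak to strong), so the nonlinear fit is constrained over a wide
#' phenotype range. A background that is itself a single mutant turns the
#' tile's "singles" into double mutants.
#'
#' @param truth A `ground_truth`.
#' @param backgrounds_per_tile Number of backgrounds per tile (including
#'   WT); defaults to the generating configuration.
#' @param backgrounds Optional named list (tile id as name) of character
#'   vectors of background mutation ids overriding the automatic choice.
#' @return Tibble of genotypes: `genotype`, `background_id`, `tile`,
#'   `order`.
#' @export
generate_library <- function(truth,
                             backgrounds_per_tile =
                               truth$config$backgrounds_per_tile,
                             backgrounds = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  tb <- truth$tile_bounds
  out <- vector("list", nrow(tb))
  for (ti in seq_len(nrow(tb))) {
    singles <- truth$ddG[truth$ddG$position >= tb$start[ti] &
                           truth$ddG$position <= tb$end[ti], ]
    bg <- if (!is.null(backgrounds)) {
      b <- backgrounds[[as.character(tb$tile[ti])]]
      bp <- parse_mutation(b)$position
      if (any(bp < tb$start[ti] | bp > tb$end[ti])) {
        stop("background mutation outside tile ", tb$tile[ti], ": ",
             paste(b[bp < tb$start[ti] | bp > tb$end[ti]], collapse = ", "))
      }
      b
    } else {
      select_backgrounds(singles, backgrounds_per_tile)
    }
    if (isTRUE(truth$config$saturated_background) && ti == nrow(tb)) {
      dead <- singles$mutation[which.max(singles$ddGf + singles$ddGa)]
      bg <- unique(c(bg, dead))
    }
    bgs <- c("WT", bg)
    rows <- lapply(bgs, function(b) {
      bmut <- if (b == "WT") character() else b
      bpos <- if (length(bmut)) parse_mutation(bmut)$position else -1L
      sel <- singles$position != bpos
      tibble::tibble(
        genotype = c(join_genotype(bmut),
                     vapply(singles$mutation[sel],
                            function(s) join_genotype(c(bmut, s)),
                            character(1), USE.NAMES = FALSE)),
        background_id = b, tile = tb$tile[ti])
    })
    out[[ti]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  res$order <- genotype_order(res$genotype)
  res
}

#' Generate fitness observations from ground truth
#'
#' Predicts each genotype's activity and abundance fitness through the
#' generating three-state model and per assay-block affine layers, then adds
#' heteroscedastic Gaussian noise with the configured per assay-block SD.
#' The recorded `sigma` equals the generating noise SD (floored at
#' `sigma_floor`). With `noise = FALSE` observations equal the noiseless
#' predictions exactly.
#'
#' @param truth A `ground_truth`.
#' @param genotypes Library tibble from [generate_library()].
#' @param noise Add Gaussian noise?
#' @param seed RNG seed for the noise draws (defaults to `truth$seed + 1000`).
#' @return Tibble of observations: `genotype`, `background_id`, `tile`,
#'   `assay`, `block`, `construct`, `fitness`, `sigma`.
#' @export
generate_observations <- function(truth, genotypes, noise = TRUE,
                                  seed = truth$seed + 1000) {
  model <- truth_model(truth)
  obs <- tidyr::crossing(genotypes, assay = c("activity", "abundance")) |>
    dplyr::mutate(block = .data$tile, construct = "full_length")
  obs <- predict_fitness(obs, model)
  key <- paste(obs$assay, obs$block)
  sd_map <- truth$noise_sd
  sd_i <- sd_map$sd[match(key, paste(sd_map$assay, sd_map$block))]
  if (noise) {
    set.seed(seed)
    obs$fitness <- obs$predicted + stats::rnorm(nrow(obs), 0, sd_i)
  } else {
    obs$fitness <- obs$predicted
  }
  obs$sigma <- pmax(sd_i, truth$config$sigma_floor)
  obs$predicted <- NULL
  obs
}

#' Generate a complete synthetic study
#'
#' Bundles ground truth, structure, library, observations, state-specific
#' contact tables, overlapping pocket sets and per-residue annotations.
#'
#' @inheritParams generate_truth
#' @param noise Passed to [generate_observations()].
#' @return A list of class `synth_study`.
#' @export
synth_study <- function(config = synth_config(), seed, noise = TRUE) {
  truth <- generate_truth(config, seed)
  genotypes <- generate_library(truth)
  observations <- generate_observations(truth, genotypes, noise = noise)
  contacts <- generate_contact_tables(truth, seed = seed + 2)
  pockets <- generate_pockets(truth, seed = seed + 3)
  annotations <- generate_annotations(truth, seed = seed + 4)
  structure(list(truth = truth, structure = truth$structure,
                 genotypes = genotypes, observations = observations,
                 contacts_active = contacts$active,
                 contacts_inactive = contacts$inactive,
                 pockets = pockets, annotations = annotations,
                 seed = seed),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat("<synth_study> ", nrow(x$observations), " observations, ",
      nrow(x$genotypes), " genotypes, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# state-specific contact tables with planted dynamics:
# planted allosteric-site residues are biased into active-only and swapping
# contacts, mirroring conformation-specific interactions.
generate_contact_tables <- function(truth, seed) {
  set.seed(seed)
  s <- truth$structure
  ca <- ca_coords(s)
  n <- nrow(ca)
  dm <- as.matrix(stats::dist(ca))
  pairs <- which(upper.tri(dm) & dm < 8, arr.ind = TRUE)
  pairs <- pairs[abs(pairs[, 1] - pairs[, 2]) >= 3, , drop = FALSE]
  if (!nrow(pairs)) stop("structure too sparse to place contacts")
  types <- c("salt_bridge", "pi_cation", "hb_sidechain_sidechain",
             "hb_sidechain_backbone")
  allo <- truth$site_class$residue[truth$site_class$class %in%
                                     c("allosteric", "active_site")]
  w <- ifelse(pairs[, 1] %in% allo | pairs[, 2] %in% allo, 4, 1)
  k <- min(nrow(pairs), 3 * n)
  sel <- sample(nrow(pairs), k, prob = w)
  rec <- tibble::tibble(residue_a = pmin(pairs[sel, 1], pairs[sel, 2]),
                        residue_b = pmax(pairs[sel, 1], pairs[sel, 2]),
                        interaction_type = sample(types, k, replace = TRUE))
  allo_pair <- rec$residue_a %in% allo | rec$residue_b %in% allo
  fate <- ifelse(allo_pair,
                 sample(c("active", "swap", "static"), k, replace = TRUE,
                        prob = c(0.5, 0.3, 0.2)),
                 sample(c("active", "inactive", "static", "swap"), k,
                        replace = TRUE, prob = c(0.15, 0.35, 0.4, 0.1)))
  active <- rec[fate %in% c("active", "static"), ]
  inactive <- rec[fate %in% c("inactive", "static"), ]
  # swapping: same residue_a, partner shifts between states
  swp <- rec[fate == "swap", ]
  if (nrow(swp)) {
    alt <- ((swp$residue_b + 3 - 1) %% n) + 1
    ok <- alt != swp$residue_a
    inact_swp <- swp
    inact_swp$residue_b[ok] <- alt[ok]
    active <- dplyr::bind_rows(active, swp)
    inactive <- dplyr::bind_rows(inactive, inact_swp)
  }
  list(active = dplyr::mutate(active, state = "active"),
       inactive = dplyr::mutate(inactive, state = "inactive"))
}

# overlapping pocket sets across pseudo-structures, with one planted
# allosteric pocket, neutral decoys, and a low-druggability pocket
generate_pockets <- function(truth, seed, n_structures = 3) {
  set.seed(seed)
  sc <- truth$site_class
  n <- nrow(sc)
  allo <- sc$residue[sc$class == "allosteric"]
  neutral <- sc$residue[sc$class == "neutral"]
  rows <- list()
  pid <- 0
  for (st in seq_len(n_structures)) {
    sid <- paste0("S", st)
    pid <- pid + 1
    core_set <- allo[seq_len(min(8, length(allo)))]
    jitter <- sample(neutral, 1)
    rows[[length(rows) + 1]] <- tibble::tibble(
      structure_id = sid, pocket_id = paste0("P", pid),
      druggability = stats::runif(1, 8, 10),
      residues = list(sort(unique(c(core_set, jitter)))))
    for (j in 1:3) {
      pid <- pid + 1
      base <- sample(neutral, min(7, length(neutral)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        structure_id = sid, pocket_id = paste0("P", pid),
        druggability = stats::runif(1, 5, 9),
        residues = list(sort(base)))
    }
    pid <- pid + 1
    rows[[length(rows) + 1]] <- tibble::tibble(
      structure_id = sid, pocket_id = paste0("P", pid),
      druggability = stats::runif(1, 1, 4.9),
      residues = list(sort(sample(seq_len(n), 5))))
  }
  dplyr::bind_rows(rows)
}

generate_annotations <- function(truth, seed) {
  set.seed(seed)
  sc <- truth$site_class
  n <- nrow(sc)
  ca <- ca_coords(truth$structure)
  as_res <- truth$structure$active_site
  d_as <- apply(as.matrix(stats::dist(ca))[, as_res, drop = FALSE], 1, min)
  # secondary structure: repeating helix/strand/loop blocks along the chain
  blocks <- rep(c("helix", "strand", "loop"), times = c(8, 6, 4))
  sse_type <- rep_len(rep(blocks, 10), n)
  run <- cumsum(c(TRUE, sse_type[-1] != sse_type[-n]))
  sse_elem <- paste0(toupper(substr(sse_type, 1, 1)), run)
  tibble::tibble(
    residue = sc$residue,
    rSASA = ifelse(sc$class == "core", stats::runif(n, 0, 0.2),
                   stats::runif(n, 0.25, 1.1)),
    sse_type = sse_type, sse_element = sse_elem,
    region = ifelse(sc$residue <= n / 2, "N_lobe", "C_lobe"),
    active_site = sc$residue %in% as_res,
    second_shell = !(sc$residue %in% as_res) & d_as < 8)
}

#' Count possible single substitutions in a position range
#'
#' @param start_pos,end_pos 1-based inclusive residue range.
#' @param n_substitutions Substitutions per position (19 non-wild-type
#'   amino acids).
#' @return Integer count.
#' @examples
#' count_possible_singles(268, 536) # 5111
#' @export
count_possible_singles <- function(start_pos, end_pos, n_substitutions = 19) {
  stopifnot(end_pos >= start_pos)
  (end_pos - start_pos + 1L) * as.integer(n_substitutions)
}
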