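## Surface-pocket clustering by overlap coefficient and allosteric ranking.

#' Szymkiewicz-Simpson overlap coefficient
#'
#' `|A intersect B| / min(|A|, |B|)` for two non-empty sets.
#'
#' @param a,b Vectors treated as sets.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("overlap coefficient of an empty set")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Cluster per-structure pockets into unique pockets
#'
#' Filters out pockets below the druggability threshold, computes the
#' pairwise distance `1 - overlap coefficient` between the residue sets,
#' applies agglomerative hierarchical clustering, and cuts the dendrogram
#' at `cut_height`. Pockets are ordered canonically by
#' (structure_id, pocket_id) before clustering, so the result does not
#' depend on input order. Each member pocket belongs to exactly one unique
#' pocket; a unique pocket's residue set is the union of its members'.
#'
#' @param pockets Tibble with columns `structure_id`, `pocket_id`,
#'   `druggability` and a list-column `residues`.
#' @param druggability_min Pockets with scores below this are dropped
#'   before clustering.
#' @param linkage `hclust` agglomeration method.
#' @param cut_height Dendrogram cut on the overlap-distance scale.
#' @return Tibble of unique pockets: `unique_pocket`, `n_members`,
#'   `n_structures`, `druggability_median`, `druggability_max`,
#'   list-columns `residues` (union) and `members`.
#' @export
cluster_pockets <- function(pockets, druggability_min = 5,
                            linkage = "average", cut_height = 0.75) {
  p <- tibble::as_tibble(pockets)
  stopifnot(all(c("structure_id", "pocket_id", "druggability", "residues")
                %in% names(p)))
  p <- p[p$druggability >= druggability_min, ]
  if (!nrow(p)) stop("no pockets survive the druggability filter")
  p <- p[order(p$structure_id, p$pocket_id), ]
  n <- nrow(p)
  cl <- if (n == 1) 1L else {
    dm <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        dm[i, j] <- dm[j, i] <-
          1 - overlap_coefficient(p$residues[[i]], p$residues[[j]])
      }
    }
    stats::cutree(stats::hclust(stats::as.dist(dm), method = linkage),
                  h = cut_height)
  }
  p$cluster <- cl
  p |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_structures = length(unique(.data$structure_id)),
      druggability_median = stats::median(.data$druggability),
      druggability_max = max(.data$druggability),
      residues = list(sort(unique(unlist(.data$residues)))),
      members = list(paste(.data$structure_id, .data$pocket_id, sep = ":")),
      member_residues = list(.data$residues),
      .groups = "drop") |>
    dplyr::rename(unique_pocket = "cluster")
}

#' Score and rank unique pockets by allosteric activity
#'
#' For each member pocket of each unique pocket, computes the mean,
#' maximum and minimum of the per-site mean ddGa over the pocket residues,
#' and Fisher-exact enrichments of activating and inactivating mutations in
#' the pocket relative to the rest of the domain; per-member metrics are
#' aggregated as medians across members, enrichment p-values are
#' BH-adjusted across unique pockets, and the output is ranked by
#' inactivating enrichment.
#'
#' @param unique_pockets Output of [cluster_pockets()].
#' @param site_summary Output of [site_energy_summary()] (per-residue mean
#'   ddGa).
#' @param classified Output of [classify_mutations()] with a `position`
#'   column.
#' @return Tibble, one row per unique pocket, ranked by inactivating
#'   enrichment.
#' @export
score_pockets <- function(unique_pockets, site_summary, classified) {
  cl <- tibble::as_tibble(classified)
  if (!"position" %in% names(cl)) {
    cl$position <- parse_mutation(cl$mutation)$position
  }
  ss <- tibble::as_tibble(site_summary)
  member_scores <- function(res_set) {
    vals <- ss$mean_ddGa[ss$residue %in% res_set]
    inp <- cl$position %in% res_set
    f_act <- fisher_enrichment(c(sum(cl$activating & inp),
                                 sum(!cl$activating & inp)),
                               c(sum(cl$activating & !inp),
                                 sum(!cl$activating & !inp)))
    f_inh <- fisher_enrichment(c(sum(cl$inactivating & inp),
                                 sum(!cl$inactivating & inp)),
                               c(sum(cl$inactivating & !inp),
                                 sum(!cl$inactivating & !inp)))
    tibble::tibble(
      mean_ddGa = if (length(vals)) mean(vals) else NA_real_,
      max_ddGa = if (length(vals)) max(vals) else NA_real_,
      min_ddGa = if (length(vals)) min(vals) else NA_real_,
      or_activating = f_act$odds_ratio, p_activating = f_act$p_value,
      or_inactivating = f_inh$odds_ratio, p_inactivating = f_inh$p_value)
  }
  up <- tibble::as_tibble(unique_pockets)
  agg <- purrr::map_dfr(seq_len(nrow(up)), function(i) {
    per_member <- purrr::map_dfr(up$member_residues[[i]], member_scores)
    dplyr::summarise(per_member,
                     dplyr::across(dplyr::everything(),
                                   ~ stats::median(.x, na.rm = TRUE)))
  })
  out <- dplyr::bind_cols(
    up[, c("unique_pocket", "n_members", "n_structures",
           "druggability_median", "druggability_max", "residues")], agg)
  out$fdr_activating <- bh_fdr(out$p_activating)
  out$fdr_inactivating <- bh_fdr(out$p_inactivating)
  out$covered <- vapply(out$residues,
                        function(r) any(r %in% ss$residue), logical(1))
  # enriched pockets (OR > 1) rank first by significance; significantly
  # depleted pockets must not outrank them
  dplyr::arrange(out, dplyr::desc(.data$or_inactivating > 1),
                 .data$p_inactivating,
                 dplyr::desc(.data$or_inactivating))
}
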