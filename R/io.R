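## Tabular readers/writers for fitness, energy, contact and pocket tables.

genotype_to_pipe <- function(genotype) {
  vapply(split_genotype(genotype), function(m) {
    if (!length(m)) return("")
    p <- parse_mutation(m)
    paste(paste(p$wt_aa, p$position, p$mut_aa, sep = "|"), collapse = ";")
  }, character(1))
}

pipe_to_genotype <- function(pipe) {
  vapply(strsplit(ifelse(is.na(pipe), "", pipe), ";", fixed = TRUE),
         function(m) {
           m <- m[nzchar(m)]
           if (!length(m)) return("")
           parts <- stringr::str_split_fixed(m, stringr::fixed("|"), 3)
           join_genotype(mutation_id(parts[, 1], as.integer(parts[, 2]),
                                     parts[, 3]))
         }, character(1))
}

#' Write / read a fitness observation table
#'
#' TSV with columns `genotype` (pipe-encoded, `wt|pos|mut;...`, empty for
#' wild type), `background_id`, `tile`, `assay`, `block`, `fitness`,
#' `sigma`.
#'
#' @param observations Observation tibble.
#' @param path File path.
#' @return `path` / the observation tibble.
#' @export
write_fitness_tsv <- function(observations, path) {
  out <- tibble::as_tibble(observations)
  out$genotype <- genotype_to_pipe(out$genotype)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_fitness_tsv
#' @export
read_fitness_tsv <- function(path) {
  obs <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           genotype = readr::col_character()))
  obs$genotype[is.na(obs$genotype)] <- ""
  obs$genotype <- pipe_to_genotype(obs$genotype)
  obs
}

#' Write / read an energy table
#'
#' TSV with columns `mutation`, `ddGf_mean`, `ddGf_sd`, `ddGa_mean`,
#' `ddGa_sd` (kcal/mol).
#'
#' @param estimates Energy tibble (missing SD columns written as NA).
#' @param path File path.
#' @export
write_energy_tsv <- function(estimates, path) {
  e <- tibble::as_tibble(estimates)
  if (!"ddGf_mean" %in% names(e) && "ddGf" %in% names(e)) {
    e <- dplyr::rename(e, ddGf_mean = "ddGf", ddGa_mean = "ddGa")
  }
  for (col in c("ddGf_sd", "ddGa_sd")) {
    if (!col %in% names(e)) e[[col]] <- NA_real_
  }
  readr::write_tsv(e[, c("mutation", "ddGf_mean", "ddGf_sd",
                         "ddGa_mean", "ddGa_sd")], path)
  invisible(path)
}

#' @rdname write_energy_tsv
#' @export
read_energy_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a contact table in the getcontacts tab-separated dialect
#'
#' Rows `frame`, type code (`sb`, `pc`, `hbss`, `hbsb`), and two atoms as
#' `chain:resname:resid:atom`.
#'
#' @param records Contact tibble (`interaction_type`, `residue_a`,
#'   `residue_b`).
#' @param path File path.
#' @param res_names Optional named vector residue -> 3-letter name.
#' @export
write_contacts_tsv <- function(records, path, res_names = NULL) {
  r <- tibble::as_tibble(records)
  code <- names(CONTACT_CODES)[match(r$interaction_type, CONTACT_CODES)]
  nm <- function(res) {
    if (is.null(res_names)) rep("ALA", length(res))
    else unname(res_names[as.character(res)])
  }
  lines <- c("# total_frames:1 beg:0 end:0",
             "# frame\tinteraction_type\tatom_1\tatom_2",
             sprintf("0\t%s\tA:%s:%d:CB\tA:%s:%d:CB",
                     code, nm(r$residue_a), r$residue_a,
                     nm(r$residue_b), r$residue_b))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a pocket table
#'
#' TSV with columns `structure_id`, `pocket_id`, `druggability`,
#' `residues` (comma-joined residue numbers).
#'
#' @param pockets Pocket tibble with a `residues` list-column.
#' @param path File path.
#' @export
write_pockets_tsv <- function(pockets, path) {
  p <- tibble::as_tibble(pockets)
  p$residues <- vapply(p$residues, paste, character(1), collapse = ",")
  readr::write_tsv(p, path)
  invisible(path)
}

#' @rdname write_pockets_tsv
#' @export
read_pockets_tsv <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         residues = readr::col_character()))
  p$residues <- lapply(strsplit(p$residues, ",", fixed = TRUE), as.integer)
  p
}

#' Write / read generator settings
#'
#' Structured YAML round-trip of a [synth_config()].
#'
#' @param config A `synth_config`.
#' @param path File path.
#' @export
write_synth_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  do.call(synth_config, yaml::read_yaml(path))
}

#' Write ground-truth energy and class tables
#'
#' @param truth A `ground_truth`.
#' @param path File path.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth$ddG, path)
  invisible(path)
}
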