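## Structure handling: synthetic backbones, minimal PDB I/O, distances.

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

new_structure_model <- function(atoms, active_site = integer()) {
  structure(list(atoms = tibble::as_tibble(atoms),
                 active_site = as.integer(active_site)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  n_res <- length(unique(x$atoms$resSeq[x$atoms$record == "ATOM"]))
  ligs <- unique(x$atoms$res_name[x$atoms$record == "HETATM"])
  cat("<structure_model> ", n_res, " residues, ", nrow(x$atoms), " heavy atoms",
      if (length(ligs)) paste0(", ligands: ", paste(ligs, collapse = ",")),
      "\n", sep = "")
  if (length(x$active_site)) {
    cat("  active site:", paste(x$active_site, collapse = ","), "\n")
  }
  invisible(x)
}

# Calpha coordinate matrix (rows named by resSeq)
ca_coords <- function(s) {
  a <- s$atoms[s$atoms$record == "ATOM" & s$atoms$atom_name == "CA", ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resSeq
  m
}

unit_vec <- function(v) v / sqrt(sum(v^2))

#' Generate a synthetic protein structure
#'
#' Builds a compact self-avoiding 3-D backbone (consecutive Calpha atoms
#' 3.8 A apart, no two non-adjacent Calpha closer than 4 A) with five heavy
#' atoms per residue (N, CA, C, O, CB), selects a spatially clustered set of
#' active-site residues, and places a small heteroatom ligand group (`LIG`)
#' at the active-site centroid as the nucleotide stand-in. Coordinates in
#' Angstrom. Deterministic for a fixed seed.
#'
#' @param n_residues Number of residues (>= 10).
#' @param seed Integer RNG seed.
#' @param wt_sequence Optional amino-acid string of length `n_residues`;
#'   sampled uniformly when omitted.
#' @param active_site_size Number of active-site residues (clustered within
#'   12 A of each other).
#' @return A `structure_model` with an `active_site` residue vector.
#' @export
generate_structure <- function(n_residues, seed, wt_sequence = NULL,
                               active_site_size = 5) {
  stopifnot(n_residues >= 10)
  set.seed(seed)
  if (is.null(wt_sequence)) {
    wt_sequence <- paste(sample(AA_ALPHABET, n_residues, replace = TRUE),
                         collapse = "")
  }
  aa <- strsplit(wt_sequence, "")[[1]]
  stopifnot(length(aa) == n_residues)

  # compact self-avoiding walk for the Calpha trace
  ca <- matrix(NA_real_, n_residues, 3)
  ca[1, ] <- c(0, 0, 0)
  for (i in 2:n_residues) {
    centroid <- colMeans(ca[1:(i - 1), , drop = FALSE])
    placed <- FALSE
    bias <- 0.6
    for (try in 1:500) {
      dir <- stats::rnorm(3)
      pull <- centroid - ca[i - 1, ]
      if (sqrt(sum(pull^2)) > 1e-6) dir <- dir + bias * unit_vec(pull)
      cand <- ca[i - 1, ] + 3.8 * unit_vec(dir)
      if (i == 2) {
        ca[i, ] <- cand; placed <- TRUE; break
      }
      dmin <- min(sqrt(rowSums(sweep(ca[1:(i - 2), , drop = FALSE], 2,
                                     cand)^2)))
      if (dmin >= 4.0) {
        ca[i, ] <- cand; placed <- TRUE; break
      }
      if (try %% 50 == 0) bias <- bias * 0.5 # loosen the compactness pull
    }
    if (!placed) stop("failed to place residue ", i, " in self-avoiding walk")
  }

  # decorate each residue with N, C, O, CB pseudo-atoms
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    offs <- matrix(stats::rnorm(12), 4, 3)
    offs <- offs / sqrt(rowSums(offs^2)) * c(1.45, 1.52, 2.4, 1.53)
    xyz <- rbind(ca[i, ],
                 ca[i, ] + offs[1, ], ca[i, ] + offs[2, ],
                 ca[i, ] + offs[3, ], ca[i, ] + offs[4, ])
    rows[[i]] <- tibble::tibble(
      record = "ATOM", chain = "A", resSeq = i, res_name = unname(AA3[aa[i]]),
      atom_name = c("CA", "N", "C", "O", "CB"),
      element = c("C", "N", "C", "O", "C"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  atoms <- dplyr::bind_rows(rows)

  # active site: the most buried residue and its nearest spatial neighbours
  dmat <- as.matrix(stats::dist(ca))
  center <- which.max(rowSums(dmat < 8))
  site <- order(dmat[center, ])[seq_len(active_site_size)]
  stopifnot(max(dmat[site, site]) < 12)

  lig_center <- colMeans(ca[site, , drop = FALSE])
  lig_off <- matrix(stats::rnorm(9), 3, 3)
  lig_off <- lig_off / sqrt(rowSums(lig_off^2)) * 1.2
  lig <- tibble::tibble(
    record = "HETATM", chain = "A", resSeq = n_residues + 1L,
    res_name = "LIG", atom_name = c("C1", "N1", "P1"),
    element = c("C", "N", "P"),
    x = lig_center[1] + c(0, lig_off[, 1][1:2]),
    y = lig_center[2] + c(0, lig_off[, 2][1:2]),
    z = lig_center[3] + c(0, lig_off[, 3][1:2]))

  new_structure_model(dplyr::bind_rows(atoms, lig), sort(site))
}

#' Write a structure as a minimal PDB file
#'
#' Emits fixed-column ATOM/HETATM records (single chain, 1-based resSeq).
#'
#' @param s A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$record, seq_len(nrow(a)),
    ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
    " ", a$res_name, a$chain, a$resSeq, " ", a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Parse a PDB file or text into a structure model
#'
#' Reads fixed-column ATOM/HETATM records, retaining only alternate-location
#' indicators `' '` or `'A'` and dropping hydrogens. HETATM groups are kept
#' and exposed under their residue names (ligands).
#'
#' @param x Path to a PDB file, or a character vector of PDB lines.
#' @param active_site Optional integer vector of active-site residues to
#'   attach to the returned model.
#' @return A `structure_model`.
#' @export
parse_pdb <- function(x, active_site = integer()) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  keep <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM/HETATM records found")
  recs <- lines[idx]
  short <- nchar(recs) < 54
  if (any(short)) {
    stop("malformed PDB record at line ", idx[which(short)[1]],
         ": record shorter than coordinate columns")
  }
  fld <- function(a, b) substr(recs, a, b)
  xyz <- suppressWarnings(cbind(as.numeric(fld(31, 38)),
                                as.numeric(fld(39, 46)),
                                as.numeric(fld(47, 54))))
  bad <- which(rowSums(is.na(xyz)) > 0)
  if (length(bad)) {
    stop("malformed PDB record at line ", idx[bad[1]],
         ": non-numeric coordinates")
  }
  res_seq <- suppressWarnings(as.integer(fld(23, 26)))
  if (anyNA(res_seq)) {
    stop("malformed PDB record at line ", idx[which(is.na(res_seq))[1]],
         ": bad residue number")
  }
  atoms <- tibble::tibble(
    record = trimws(fld(1, 6)), chain = fld(22, 22),
    resSeq = res_seq, res_name = trimws(fld(18, 20)),
    atom_name = trimws(fld(13, 16)), altloc = fld(17, 17),
    element = trimws(fld(77, 78)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  # infer element from the atom name when the element column is blank
  blank <- atoms$element == ""
  atoms$element[blank] <- substr(gsub("[0-9]", "", atoms$atom_name[blank]), 1, 1)
  atoms <- atoms[atoms$altloc %in% c(" ", "A"), ]
  atoms <- atoms[atoms$element != "H", ]
  atoms$altloc <- NULL
  new_structure_model(atoms, active_site)
}

resolve_reference_atoms <- function(s, ligands = character(),
                                    residues = integer()) {
  a <- s$atoms
  sel <- rep(FALSE, nrow(a))
  for (lg in ligands) {
    hit <- a$record == "HETATM" & a$res_name == lg
    if (!any(hit)) stop("reference ligand not found in structure: ", lg)
    sel <- sel | hit
  }
  for (r in residues) {
    hit <- a$record == "ATOM" & a$resSeq == r
    if (!any(hit)) stop("reference residue not found in structure: ", r)
    sel <- sel | hit
  }
  if (!any(sel)) stop("no reference atoms selected")
  a[sel, ]
}

#' Minimum heavy-atom distance from each residue to the active site
#'
#' For every residue, the minimum Euclidean distance over all of its heavy
#' atoms to all heavy atoms of the reference selections (ligand groups
#' and/or reference residues). Residues that are themselves part of the
#' reference selection are assigned distance 0, anchoring the decay fits at
#' the active site.
#'
#' @param s A `structure_model`.
#' @param ligands Character vector of HETATM residue names to use as
#'   reference points (e.g. a bound nucleotide).
#' @param residues Integer vector of reference residue numbers (e.g. a
#'   catalytic residue).
#' @return Tibble with columns `residue` and `distance` (Angstrom).
#' @export
min_distance_to_active_site <- function(s, ligands = character(),
                                        residues = integer()) {
  refs <- resolve_reference_atoms(s, ligands, residues)
  ref_m <- as.matrix(refs[, c("x", "y", "z")])
  prot <- s$atoms[s$atoms$record == "ATOM", ]
  out <- prot |>
    dplyr::group_by(residue = .data$resSeq) |>
    dplyr::summarise(distance = {
      m <- cbind(.data$x, .data$y, .data$z)
      # min over all atom pairs residue x reference
      cross <- outer(rowSums(m^2), rep(1, nrow(ref_m))) +
        outer(rep(1, nrow(m)), rowSums(ref_m^2)) - 2 * m %*% t(ref_m)
      sqrt(max(0, min(cross)))
    }, .groups = "drop")
  out$distance[out$residue %in% residues] <- 0
  out
}

# centroid of the reference selection's heavy atoms (origin for signed axes)
active_site_centroid <- function(s, ligands = character(),
                                 residues = integer()) {
  refs <- resolve_reference_atoms(s, ligands, residues)
  colMeans(as.matrix(refs[, c("x", "y", "z")]))
}
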