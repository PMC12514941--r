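# Synthetic fixture generators: ideal peptides built from internal
# coordinates, seeded jitter "trajectories", and minimal toy systems with
# exactly prescribed hydrogen-bond / salt-bridge geometry.  Everything is
# deterministic under a fixed seed so the full test suite runs offline.
#
# Sidechains are placed with idealized extended rotamers; fixtures are
# geometric test articles, not physically relaxed conformers.

# Sidechain templates: one row per heavy atom, placed by NeRF from three
# previously placed atoms of the same residue.  Columns: atom name, element,
# frame atoms p1/p2/p3, bond length, bond angle, torsion, number of
# hydrogens to attach.  `closures` lists ring-closing bonds.
.sc_row <- function(name, el, p1, p2, p3, b, a, t, nh)
  list(name = name, el = el, p1 = p1, p2 = p2, p3 = p3,
       bond = b, angle = a, torsion = t, nh = nh)

.CB <- function(nh) .sc_row("CB", "C", "N", "C", "CA", 1.53, 110.4, -122.6, nh)

.SIDECHAINS <- list(
  GLY = list(atoms = list(), closures = NULL),
  ALA = list(atoms = list(.CB(3)), closures = NULL),
  SER = list(atoms = list(.CB(2),
    .sc_row("OG", "O", "N", "CA", "CB", 1.42, 110.8, 180, 1)), closures = NULL),
  CYS = list(atoms = list(.CB(2),
    .sc_row("SG", "S", "N", "CA", "CB", 1.81, 113.8, 180, 1)), closures = NULL),
  THR = list(atoms = list(.CB(1),
    .sc_row("OG1", "O", "N", "CA", "CB", 1.43, 109.3, 180, 1),
    .sc_row("CG2", "C", "N", "CA", "CB", 1.52, 110.5, -60, 3)), closures = NULL),
  VAL = list(atoms = list(.CB(1),
    .sc_row("CG1", "C", "N", "CA", "CB", 1.52, 110.5, 180, 3),
    .sc_row("CG2", "C", "N", "CA", "CB", 1.52, 110.5, 60, 3)), closures = NULL),
  LEU = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.53, 116.3, 180, 1),
    .sc_row("CD1", "C", "CA", "CB", "CG", 1.52, 110.7, 180, 3),
    .sc_row("CD2", "C", "CA", "CB", "CG", 1.52, 110.7, 60, 3)), closures = NULL),
  ILE = list(atoms = list(.CB(1),
    .sc_row("CG1", "C", "N", "CA", "CB", 1.53, 110.4, 180, 2),
    .sc_row("CG2", "C", "N", "CA", "CB", 1.54, 110.5, -60, 3),
    .sc_row("CD1", "C", "CA", "CB", "CG1", 1.51, 113.8, 180, 3)), closures = NULL),
  MET = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.52, 114.1, 180, 2),
    .sc_row("SD", "S", "CA", "CB", "CG", 1.80, 112.7, 180, 0),
    .sc_row("CE", "C", "CB", "CG", "SD", 1.79, 100.2, 180, 3)), closures = NULL),
  PRO = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.49, 104.5, -20, 2),
    .sc_row("CD", "C", "CA", "CB", "CG", 1.51, 106.0, 10, 2)),
    closures = list(c("CD", "N"))),
  PHE = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.50, 113.8, 180, 0),
    .sc_row("CD1", "C", "CA", "CB", "CG", 1.39, 120.8, 90, 1),
    .sc_row("CD2", "C", "CA", "CB", "CG", 1.39, 120.8, -90, 1),
    .sc_row("CE1", "C", "CB", "CG", "CD1", 1.39, 120.8, 180, 1),
    .sc_row("CE2", "C", "CB", "CG", "CD2", 1.39, 120.8, 180, 1),
    .sc_row("CZ", "C", "CG", "CD1", "CE1", 1.39, 120.0, 0, 1)),
    closures = list(c("CZ", "CE2"))),
  TYR = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.50, 113.8, 180, 0),
    .sc_row("CD1", "C", "CA", "CB", "CG", 1.39, 120.8, 90, 1),
    .sc_row("CD2", "C", "CA", "CB", "CG", 1.39, 120.8, -90, 1),
    .sc_row("CE1", "C", "CB", "CG", "CD1", 1.39, 120.8, 180, 1),
    .sc_row("CE2", "C", "CB", "CG", "CD2", 1.39, 120.8, 180, 1),
    .sc_row("CZ", "C", "CG", "CD1", "CE1", 1.39, 120.0, 0, 0),
    .sc_row("OH", "O", "CD1", "CE1", "CZ", 1.38, 120.0, 180, 1)),
    closures = list(c("CZ", "CE2"))),
  TRP = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.50, 114.0, 180, 0),
    .sc_row("CD1", "C", "CA", "CB", "CG", 1.37, 127.0, 90, 1),
    .sc_row("CD2", "C", "CA", "CB", "CG", 1.43, 126.6, -90, 0),
    .sc_row("NE1", "N", "CB", "CG", "CD1", 1.38, 110.0, 180, 1),
    .sc_row("CE2", "C", "CB", "CG", "CD2", 1.41, 107.0, 180, 0),
    .sc_row("CE3", "C", "CB", "CG", "CD2", 1.40, 133.9, 0, 1),
    .sc_row("CZ2", "C", "CG", "CD2", "CE2", 1.40, 122.4, 180, 1),
    .sc_row("CZ3", "C", "CG", "CD2", "CE3", 1.39, 118.6, 180, 1),
    .sc_row("CH2", "C", "CD2", "CE2", "CZ2", 1.37, 117.5, 0, 1)),
    closures = list(c("NE1", "CE2"), c("CZ3", "CH2"))),
  ASP = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.52, 112.6, 180, 0),
    .sc_row("OD1", "O", "CA", "CB", "CG", 1.25, 118.5, -30, 0),
    .sc_row("OD2", "O", "CA", "CB", "CG", 1.25, 118.5, 150, 0)), closures = NULL),
  ASN = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.52, 112.6, 180, 0),
    .sc_row("OD1", "O", "CA", "CB", "CG", 1.23, 120.8, -30, 0),
    .sc_row("ND2", "N", "CA", "CB", "CG", 1.33, 116.4, 150, 2)), closures = NULL),
  GLU = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.52, 114.0, 180, 2),
    .sc_row("CD", "C", "CA", "CB", "CG", 1.52, 112.6, 180, 0),
    .sc_row("OE1", "O", "CB", "CG", "CD", 1.25, 118.5, -30, 0),
    .sc_row("OE2", "O", "CB", "CG", "CD", 1.25, 118.5, 150, 0)), closures = NULL),
  GLN = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.52, 114.0, 180, 2),
    .sc_row("CD", "C", "CA", "CB", "CG", 1.52, 112.6, 180, 0),
    .sc_row("OE1", "O", "CB", "CG", "CD", 1.23, 120.8, -30, 0),
    .sc_row("NE2", "N", "CB", "CG", "CD", 1.33, 116.4, 150, 2)), closures = NULL),
  LYS = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.52, 114.0, 180, 2),
    .sc_row("CD", "C", "CA", "CB", "CG", 1.52, 111.3, 180, 2),
    .sc_row("CE", "C", "CB", "CG", "CD", 1.52, 111.3, 180, 2),
    .sc_row("NZ", "N", "CG", "CD", "CE", 1.49, 112.0, 180, 3)), closures = NULL),
  ARG = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.52, 114.0, 180, 2),
    .sc_row("CD", "C", "CA", "CB", "CG", 1.52, 111.3, 180, 2),
    .sc_row("NE", "N", "CB", "CG", "CD", 1.46, 112.0, 180, 1),
    .sc_row("CZ", "C", "CG", "CD", "NE", 1.33, 124.2, 180, 0),
    .sc_row("NH1", "N", "CD", "NE", "CZ", 1.33, 120.0, 0, 2),
    .sc_row("NH2", "N", "CD", "NE", "CZ", 1.33, 120.0, 180, 2)), closures = NULL),
  HIS = list(atoms = list(.CB(2),
    .sc_row("CG", "C", "N", "CA", "CB", 1.49, 113.8, 180, 0),
    .sc_row("ND1", "N", "CA", "CB", "CG", 1.38, 122.7, 90, 0),
    .sc_row("CD2", "C", "CA", "CB", "CG", 1.36, 131.0, -90, 1),
    .sc_row("CE1", "C", "CB", "CG", "ND1", 1.32, 109.0, 180, 1),
    .sc_row("NE2", "N", "CB", "CG", "CD2", 1.37, 107.0, 180, 1)),
    closures = list(c("CE1", "NE2")))
)

.H_BOND_LEN <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)

#' Build an ideal peptide from internal coordinates
#'
#' The backbone is constructed from ideal bond lengths and angles with the
#' requested dihedrals (helix: phi = -57, psi = -47; strand: phi = -135,
#' psi = 135; or custom per-residue vectors).  Hydrogens are placed with
#' ideal geometry and all covalent bonds are recorded, so fixtures round-trip
#' through [write_ensemble()] / [load_ensemble()].
#'
#' @param sequence 1-letter amino-acid string, e.g. `"AAAAAAAAAAAAAAA"`.
#' @param conformation `"helix"`, `"strand"`, or `"custom"` with `phi`/`psi`.
#' @param phi,psi optional per-residue dihedral vectors (degrees, recycled).
#' @param chain chain identifier.
#' @param variant_id label for the resulting ensemble.
#' @return a single-frame `structure_ensemble`.
#' @export
build_ideal_peptide <- function(sequence,
                                conformation = c("helix", "strand", "custom"),
                                phi = NULL, psi = NULL, chain = "A",
                                variant_id = "peptide") {
  conformation <- match.arg(conformation)
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (any(is.na(match(seq1, .AA1))))
    stop("unknown residue in sequence: ",
         paste(setdiff(seq1, .AA1), collapse = ","))
  nres <- length(seq1)
  if (conformation == "helix") { phi <- -57; psi <- -47 }
  if (conformation == "strand") { phi <- -135; psi <- 135 }
  if (is.null(phi) || is.null(psi))
    stop("custom conformation requires phi and psi")
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)

  res <- vector("list", nres)      # named coordinate lists
  put <- function(i, nm, xyz) res[[i]][[nm]] <<- xyz
  get <- function(i, nm) res[[i]][[nm]]
  bonds_nm <- list()               # (res_i, name_i, res_j, name_j)
  link <- function(i, a, j, b) bonds_nm[[length(bonds_nm) + 1]] <<- list(i, a, j, b)

  for (i in seq_len(nres)) {
    if (i == 1) {
      th <- 111.2 * pi / 180
      put(1, "N", c(0, 0, 0))
      put(1, "CA", c(1.458, 0, 0))
      put(1, "C", c(1.458, 0, 0) + 1.525 * c(-cos(th), sin(th), 0))
    } else {
      put(i, "N", place_atom(get(i - 1, "N"), get(i - 1, "CA"), get(i - 1, "C"),
                             1.329, 116.2, psi[i - 1]))
      put(i, "CA", place_atom(get(i - 1, "CA"), get(i - 1, "C"), get(i, "N"),
                              1.458, 121.7, 180))
      put(i, "C", place_atom(get(i - 1, "C"), get(i, "N"), get(i, "CA"),
                             1.525, 111.2, phi[i]))
      link(i - 1, "C", i, "N")
    }
    put(i, "O", place_atom(get(i, "N"), get(i, "CA"), get(i, "C"),
                           1.231, 120.5, psi[i] + 180))
    link(i, "N", i, "CA"); link(i, "CA", i, "C"); link(i, "C", i, "O")
    tmpl <- .SIDECHAINS[[aa_123(seq1[i])]]
    for (row in tmpl$atoms) {
      put(i, row$name, place_atom(get(i, row$p1), get(i, row$p2), get(i, row$p3),
                                  row$bond, row$angle, row$torsion))
      link(i, row$p3, i, row$name)
    }
    for (cl in tmpl$closures) link(i, cl[1], i, cl[2])
  }
  .assemble_peptide(res, seq1, bonds_nm, chain, variant_id)
}

# Turn the per-residue coordinate lists into an ensemble, appending hydrogens.
#' @keywords internal
.assemble_peptide <- function(res, seq1, bonds_nm, chain, variant_id) {
  nres <- length(res)
  # hydrogen targets per residue: backbone + sidechain template counts
  h_spec <- function(i) {
    aa <- seq1[i]
    out <- list()
    if (aa != "P" || i == 1) out[["N"]] <- 1L
    out[["CA"]] <- if (aa == "G") 2L else 1L
    for (row in .SIDECHAINS[[aa_123(aa)]]$atoms)
      if (row$nh > 0) out[[row$name]] <- as.integer(row$nh)
    out
  }

  # flatten heavy atoms
  names_all <- character(0); el_all <- character(0)
  resno_all <- integer(0); coords <- NULL
  index_of <- list()   # index_of[[i]][[name]]
  for (i in seq_len(nres)) {
    index_of[[i]] <- list()
    for (nm in names(res[[i]])) {
      names_all <- c(names_all, nm)
      el_all <- c(el_all, substr(gsub("[0-9]", "", nm), 1, 1))
      resno_all <- c(resno_all, i)
      coords <- rbind(coords, res[[i]][[nm]])
      index_of[[i]][[nm]] <- length(names_all)
    }
  }
  bonds <- do.call(rbind, lapply(bonds_nm, function(b)
    c(index_of[[b[[1]]]][[b[[2]]]], index_of[[b[[3]]]][[b[[4]]]])))

  # neighbor lookup over heavy atoms
  nb_of <- function(idx) {
    hit <- bonds[bonds[, 1] == idx | bonds[, 2] == idx, , drop = FALSE]
    setdiff(as.vector(hit), idx)
  }

  h_names <- character(0); h_coords <- NULL; h_parent <- integer(0)
  h_res <- integer(0)
  for (i in seq_len(nres)) {
    spec <- h_spec(i)
    for (nm in names(spec)) {
      p_idx <- index_of[[i]][[nm]]
      hp <- .place_hydrogens(coords, bonds, p_idx, spec[[nm]],
                             el_all[p_idx], nb_of(p_idx))
      base <- if (nm == "N") "H" else paste0("H", substring(nm, 2))
      for (k in seq_len(nrow(hp))) {
        lbl <- if (nm == "N") {
          "H"
        } else if (nm == "CA") {
          if (spec[[nm]] == 1L) "HA" else c("HA2", "HA3")[k]
        } else {
          paste0(base, k)
        }
        h_names <- c(h_names, lbl)
        h_coords <- rbind(h_coords, hp[k, ])
        h_parent <- c(h_parent, p_idx)
        h_res <- c(h_res, i)
      }
    }
  }
  n_heavy <- nrow(coords)
  all_names <- c(names_all, h_names)
  all_el <- c(el_all, rep("H", length(h_names)))
  all_resno <- c(resno_all, h_res)
  all_coords <- rbind(coords, h_coords)
  h_bonds <- cbind(h_parent, n_heavy + seq_along(h_parent))
  if (length(h_parent) > 0) bonds <- rbind(bonds, h_bonds)

  # heavy atoms first, then hydrogens, within each residue
  ord <- order(all_resno, seq_along(all_resno) > n_heavy,
               seq_along(all_resno))
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
  atoms <- data.frame(name = all_names[ord], element = all_el[ord],
                      resno = all_resno[ord],
                      resname = aa_123(seq1)[all_resno[ord]],
                      chain = chain, stringsAsFactors = FALSE)
  bonds <- cbind(remap[bonds[, 1]], remap[bonds[, 2]])
  structure_ensemble(atoms, bonds, list(all_coords[ord, , drop = FALSE]),
                     variant_id = variant_id)
}

# Generic geometric hydrogen placement on a heavy atom.
#' @keywords internal
.place_hydrogens <- function(coords, bonds, p_idx, n_h, element, nb) {
  P <- coords[p_idx, ]
  blen <- .H_BOND_LEN[[element]]
  if (is.null(blen)) blen <- 1.0
  k <- length(nb)
  if (k == 0) stop("cannot place hydrogens on an unbonded atom")
  u <- lapply(nb, function(j) unit(coords[j, ] - P))
  if (k >= 3) {
    d <- -unit(Reduce(`+`, u))
    return(matrix(P + blen * d, nrow = 1))
  }
  if (k == 2) {
    b <- -unit(u[[1]] + u[[2]])
    if (n_h == 1) return(matrix(P + blen * b, nrow = 1))
    p <- unit(pracma_cross(u[[1]], u[[2]]))
    half <- 54.75 * pi / 180
    return(rbind(P + blen * (b * cos(half) + p * sin(half)),
                 P + blen * (b * cos(half) - p * sin(half))))
  }
  # k == 1: need a reference atom bonded to the single neighbor
  nbj <- nb[1]
  hit <- bonds[bonds[, 1] == nbj | bonds[, 2] == nbj, , drop = FALSE]
  ref <- setdiff(as.vector(hit), c(nbj, p_idx))[1]
  R <- if (is.na(ref)) P + c(1, 0, 0) + 0.1 else coords[ref, ]
  ang <- if (n_h == 2) 120 else 109.5
  tors <- switch(as.character(n_h), "1" = 180,
                 "2" = c(0, 180), "3" = c(60, 180, -60))
  do.call(rbind, lapply(tors, function(t)
    place_atom(R, coords[nbj, ], P, blen, ang, t)))
}

#' Add seeded Gaussian jitter frames to a structure
#'
#' Every atom of residue `i` is displaced, independently per frame and per
#' coordinate, by Gaussian noise with standard deviation `amplitude[i]`
#' (Angstrom).  For large frame counts the per-atom RMSF about the mean
#' converges to `amplitude * sqrt(3)`.
#'
#' @param ens a `structure_ensemble` (frame 1 is the reference geometry).
#' @param n_frames number of frames to generate.
#' @param amplitude per-residue noise sd (Angstrom), recycled over residues.
#' @param seed integer seed (generation is reproducible).
#' @param n_replicates split the frames evenly into this many replicates.
#' @return a `structure_ensemble` with `n_frames` frames.
#' @export
jitter_trajectory <- function(ens, n_frames, amplitude, seed = 1L,
                              n_replicates = 1L) {
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  set.seed(seed)
  ref <- ens$frames[[1]]
  resno <- ens$atoms$resno
  res_levels <- unique(resno)
  amp <- rep_len(amplitude, length(res_levels))
  atom_amp <- amp[match(resno, res_levels)]
  frames <- lapply(seq_len(n_frames), function(f)
    ref + matrix(stats::rnorm(length(ref), 0, rep(atom_amp, 3)),
                 ncol = 3))
  ends <- unique(round(seq_len(n_replicates) * n_frames / n_replicates))
  structure_ensemble(ens$atoms, ens$bonds, frames, as.integer(ends),
                     variant_id = paste0(ens$variant_id, "_jitter"))
}

#' Toy system realizing an exact hydrogen-bond geometry
#'
#' Builds a minimal donor-hydrogen-acceptor(-neighbor) system with the
#' requested hydrogen-acceptor distance, donor-hydrogen-acceptor angle, and
#' acceptor-neighbor angle, for exact-value energy tests.
#'
#' @param dist_HA hydrogen-acceptor distance (Angstrom).
#' @param angle_DHA donor-hydrogen-acceptor angle (degrees).
#' @param angle_HAX hydrogen-acceptor-neighbor angle (degrees); `NULL` for an
#'   acceptor without covalent neighbors.
#' @param neighbor_is_hydrogen whether the acceptor neighbor is a hydrogen.
#' @return a single-frame `structure_ensemble`.
#' @export
build_hbond_toy <- function(dist_HA = 2.0, angle_DHA = 180,
                            angle_HAX = 120, neighbor_is_hydrogen = FALSE) {
  if (dist_HA <= 0) stop("dist_HA must be positive")
  if (angle_DHA < 0 || angle_DHA > 180 ||
      (!is.null(angle_HAX) && (angle_HAX < 0 || angle_HAX > 180)))
    stop("angles must lie in [0, 180]")
  aD <- angle_DHA * pi / 180
  H <- c(0, 0, 0)
  A <- c(dist_HA, 0, 0)
  D <- 1.01 * c(cos(aD), sin(aD), 0)
  if (vnorm(D - A) < 0.5) stop("unrealizable geometry: donor overlaps acceptor")
  atoms <- data.frame(
    name = c("ND2", "HD21", "O"),
    element = c("N", "H", "O"),
    resno = c(1L, 1L, 2L),
    resname = c("ASN", "ASN", "ALA"),
    chain = "A", stringsAsFactors = FALSE)
  coords <- rbind(D, H, A)
  bonds <- rbind(c(1L, 2L))
  if (!is.null(angle_HAX)) {
    aX <- angle_HAX * pi / 180
    r <- if (neighbor_is_hydrogen) 0.96 else 1.40
    X <- A + r * c(-cos(aX), sin(aX), 0)
    atoms <- rbind(atoms, data.frame(
      name = if (neighbor_is_hydrogen) "HX" else "C",
      element = if (neighbor_is_hydrogen) "H" else "C",
      resno = 2L, resname = "ALA", chain = "A", stringsAsFactors = FALSE))
    coords <- rbind(coords, X)
    bonds <- rbind(bonds, c(3L, 4L))
  }
  rownames(coords) <- NULL
  structure_ensemble(atoms, bonds, list(coords), variant_id = "hbond_toy")
}

#' Toy bifurcated hydrogen bond
#'
#' One donor hydrogen engages two acceptors simultaneously, both with the
#' requested hydrogen-acceptor distance and donor-hydrogen-acceptor angle
#' (default within the saturated ideal zone) and unhindered acceptor
#' neighbors, for testing the bifurcation energy cap.
#'
#' @param dist_HA hydrogen-acceptor distance for both bonds (Angstrom).
#' @param angle_DHA donor-hydrogen-acceptor angle for both bonds (degrees).
#' @return a single-frame `structure_ensemble`.
#' @export
build_bifurcated_toy <- function(dist_HA = 2.0, angle_DHA = 170) {
  H <- c(0, 0, 0)
  uD <- c(0, 1, 0)
  D <- 1.01 * uD
  alpha <- (180 - angle_DHA) * pi / 180
  atoms <- data.frame(name = c("ND2", "HD21"), element = c("N", "H"),
                      resno = 1L, resname = "ASN", chain = "A",
                      stringsAsFactors = FALSE)
  coords <- rbind(D, H)
  bonds <- rbind(c(1L, 2L))
  for (k in 1:2) {
    az <- if (k == 1) 0 else pi
    dir <- c(sin(alpha) * cos(az), -cos(alpha), sin(alpha) * sin(az))
    A <- dist_HA * dir
    w <- unit(A - H)
    v <- unit(pracma_cross(w, c(0, 0, 1)))
    X <- A + 1.23 * (-cos(120 * pi / 180) * w + sin(120 * pi / 180) * v)
    atoms <- rbind(atoms, data.frame(
      name = c("O", "C"), element = c("O", "C"), resno = k + 1L,
      resname = "ALA", chain = "A", stringsAsFactors = FALSE))
    coords <- rbind(coords, A, X)
    bonds <- rbind(bonds, c(nrow(coords) - 1L, nrow(coords)))
  }
  rownames(coords) <- NULL
  structure_ensemble(atoms, bonds, list(coords), variant_id = "bifurcated_toy")
}

#' Toy water bridging two protein acceptors
#'
#' A single water donates one hydrogen bond to each of two protein carbonyl
#' oxygens, both with the requested hydrogen-acceptor distance and linear
#' donor-hydrogen-acceptor geometry (acceptor neighbors at the unhindered
#' 120 degrees).
#'
#' @param dist_HA hydrogen-acceptor distance for both bonds (Angstrom).
#' @param n_acceptors 1 or 2 protein acceptors.
#' @return a single-frame `structure_ensemble` containing the water.
#' @export
build_water_bridge_toy <- function(dist_HA = 2.0, n_acceptors = 2) {
  OW <- c(0, 0, 0)
  dirs <- list(c(1, 0, 0),
               c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0))
  atoms <- NULL; coords <- NULL; bonds <- NULL
  add <- function(nm, el, resno, resname, xyz) {
    atoms <<- rbind(atoms, data.frame(name = nm, element = el, resno = resno,
                                      resname = resname, chain = "A",
                                      stringsAsFactors = FALSE))
    coords <<- rbind(coords, xyz)
    nrow(coords)
  }
  iow <- add("O", "O", 10L, "HOH", OW)
  for (k in seq_len(2)) {
    u <- dirs[[k]]
    ih <- add(paste0("H", k), "H", 10L, "HOH", 0.96 * u)
    bonds <- rbind(bonds, c(iow, ih))
    if (k <= n_acceptors) {
      ia <- add("O", "O", k, "ALA", (0.96 + dist_HA) * u)
      # carbonyl carbon at 120 degrees from the incoming hydrogen
      v <- unit(pracma_cross(u, c(0, 0, 1)))
      aX <- 120 * pi / 180
      ic <- add("C", "C", k, "ALA",
                coords[ia, ] + 1.23 * (-cos(aX) * u + sin(aX) * v))
      bonds <- rbind(bonds, c(ia, ic))
    }
  }
  rownames(coords) <- NULL
  structure_ensemble(atoms, bonds, list(coords), variant_id = "water_bridge_toy")
}

#' Toy aspartate-lysine salt bridge at a prescribed distance
#'
#' Minimal Asp and Lys sidechain fragments with the carboxylate OD1 to amine
#' NZ distance set exactly to `distance`.
#'
#' @param distance O-N distance in Angstrom.
#' @param n_frames replicate the geometry over this many frames.
#' @param bridge_frames number of leading frames in which the contact is at
#'   `distance`; remaining frames move the pair 10 Angstrom apart.
#' @return a `structure_ensemble`.
#' @export
build_salt_bridge_toy <- function(distance = 3.5, n_frames = 1L,
                                  bridge_frames = n_frames) {
  if (distance <= 0) stop("distance must be positive")
  atoms <- data.frame(
    name = c("CG", "OD1", "OD2", "CE", "NZ", "HZ1", "HZ2", "HZ3"),
    element = c("C", "O", "O", "C", "N", "H", "H", "H"),
    resno = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    resname = c("ASP", "ASP", "ASP", "LYS", "LYS", "LYS", "LYS", "LYS"),
    chain = "A", stringsAsFactors = FALSE)
  base <- function(off) {
    NZ <- c(distance + off, 0, 0)
    rbind(c(-1.25, 0.3, 0),          # CG
          c(0, 0, 0),                # OD1
          c(-1.9, 1.35, 0),          # OD2
          NZ + c(1.49, 0, 0),        # CE
          NZ,
          NZ + 1.01 * c(-0.33, 0.9, 0.28),
          NZ + 1.01 * c(-0.33, -0.2, -0.92),
          NZ + 1.01 * c(-0.33, -0.7, 0.64))
  }
  bonds <- rbind(c(1L, 2L), c(1L, 3L), c(4L, 5L),
                 c(5L, 6L), c(5L, 7L), c(5L, 8L))
  frames <- lapply(seq_len(n_frames), function(f)
    base(if (f <= bridge_frames) 0 else 10))
  structure_ensemble(atoms, bonds, frames, variant_id = "salt_bridge_toy")
}

#' Draw synthetic benchmark samples
#'
#' Generates a per-residue sample table of sidechain RMSF and hydrophobic
#' SASA values from log-normal distributions, covering the requested amino
#' acids and exposure classes, for building benchmark curves without
#' structural input.  Exposure classes shift the RMSF location upward
#' (exposed sidechains fluctuate more), mirroring what curve collections
#' from real ensembles look like.
#'
#' @param aa 1-letter amino-acid codes to cover.
#' @param classes exposure classes to cover.
#' @param n samples per (amino acid, class) category.
#' @param meanlog_rmsf named per-class location of log RMSF.
#' @param sdlog log-sd for both properties.
#' @param seed integer seed.
#' @return data.frame with columns `aa`, `exposure`, `sidechain_rmsf`,
#'   `hydrophobic_sasa`.
#' @export
build_benchmark_samples <- function(aa = .AA1,
                                    classes = c("buried", "partial", "exposed"),
                                    n = 50,
                                    meanlog_rmsf = c(buried = -0.7,
                                                     partial = -0.35,
                                                     exposed = 0.0),
                                    sdlog = 0.4, seed = 1L) {
  if (n < 2) stop("need at least 2 samples per category")
  set.seed(seed)
  out <- expand.grid(aa = aa, exposure = classes, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(out)), function(i) {
    cls <- out$exposure[i]
    data.frame(aa = out$aa[i], exposure = cls,
               sidechain_rmsf = stats::rlnorm(n, meanlog_rmsf[[cls]], sdlog),
               hydrophobic_sasa = stats::rlnorm(n, log(40), sdlog),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
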