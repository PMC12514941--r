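# Core domain types: the structure ensemble (topology + coordinate frames),
# mutations, atom selections at three granularities, and frame averaging.

#' Construct a structure ensemble
#'
#' A structure ensemble bundles a topology (atom table + covalent bonds) with
#' one or more coordinate frames, e.g. snapshots from molecular dynamics.
#' Coordinates are in Angstrom throughout; residue numbering is taken from the
#' topology and never re-indexed.
#'
#' @param atoms data.frame with columns `name`, `element`, `resno`, `resname`,
#'   `chain`, and optionally `is_backbone`, `is_water` (derived from atom and
#'   residue names when absent).
#' @param bonds two-column integer matrix of covalent bonds (atom indices).
#' @param frames list of `n_atoms x 3` coordinate matrices (Angstrom).
#' @param replicate_ends integer vector of cumulative frame counts marking
#'   the end of each replicate; defaults to a single replicate.
#' @param variant_id character label for the variant.
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, bonds, frames, replicate_ends = NULL,
                               variant_id = "variant") {
  if (is.null(atoms$is_water))
    atoms$is_water <- atoms$resname %in% .WATER_NAMES
  if (is.null(atoms$is_backbone))
    atoms$is_backbone <- !atoms$is_water & atoms$name %in% .BACKBONE_NAMES
  atoms$name <- as.character(atoms$name)
  atoms$element <- toupper(as.character(atoms$element))
  atoms$resname <- toupper(as.character(atoms$resname))
  atoms$chain <- as.character(atoms$chain)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (!is.list(frames)) frames <- list(frames)
  if (is.null(replicate_ends)) replicate_ends <- length(frames)
  ens <- structure(list(atoms = atoms, bonds = bonds, frames = frames,
                        replicate_ends = as.integer(replicate_ends),
                        variant_id = variant_id),
                   class = "structure_ensemble")
  validate_ensemble(ens)
}

#' @keywords internal
validate_ensemble <- function(ens) {
  n <- nrow(ens$atoms)
  if (length(ens$frames) < 1) stop("ensemble must contain at least one frame")
  ok <- vapply(ens$frames, function(f) is.matrix(f) && nrow(f) == n &&
                 ncol(f) == 3 && all(is.finite(f)), logical(1))
  if (!all(ok))
    stop("every frame must supply exactly one finite coordinate triple per atom")
  if (nrow(ens$bonds) > 0 &&
      (min(ens$bonds) < 1 || max(ens$bonds) > n))
    stop("bond indices reference non-existing atoms")
  if (utils::tail(ens$replicate_ends, 1) != length(ens$frames))
    stop("replicate boundaries do not partition the frames")
  ens
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble '%s': %d atoms, %d bonds, %d frames, %d replicate(s)>\n",
              x$variant_id, nrow(x$atoms), nrow(x$bonds),
              length(x$frames), length(x$replicate_ends)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens a `structure_ensemble`.
#' @return integer.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Indices of protein (non-water) atoms
#' @param ens a `structure_ensemble`.
#' @return integer vector.
#' @export
protein_atoms <- function(ens) which(!ens$atoms$is_water)

# ---------------------------------------------------------------------------
# Multi-model PDB input/output.  ATOM/coordinate parsing is delegated to
# bio3d; CONECT records and the replicate-boundary REMARK (which bio3d does
# not expose) are read from the raw lines.

#' Load a structure ensemble from PDB files
#'
#' Reads a topology (multi-model PDB with CONECT bond records; every model
#' becomes one frame) plus optional additional trajectory files.  Each extra
#' file is treated as one replicate and must contain the same atoms as the
#' topology; frames are concatenated in input order and replicate boundaries
#' recorded.  Binary DCD trajectories are accepted via bio3d; waters are
#' retained and flagged.  No periodic-boundary imaging is performed: inputs
#' are assumed whole-molecule.
#'
#' @param topology_source path to a PDB file carrying CONECT records.
#' @param trajectory_sources optional character vector of trajectory files
#'   (multi-model PDB or DCD), one replicate each.
#' @param frame_stride keep every `frame_stride`-th frame (default 1).
#' @param variant_id label; defaults to the topology file name.
#' @return a `structure_ensemble`.
#' @export
load_ensemble <- function(topology_source, trajectory_sources = NULL,
                          frame_stride = 1L, variant_id = NULL) {
  if (is.null(variant_id))
    variant_id <- sub("\\.[^.]*$", "", basename(topology_source))
  pdb <- bio3d::read.pdb(topology_source, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(name = pdb$atom$elety,
                      element = .element_of(pdb$atom),
                      resno = pdb$atom$resno,
                      resname = pdb$atom$resid,
                      chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
                      stringsAsFactors = FALSE)
  n <- nrow(atoms)
  raw <- readLines(topology_source)
  bonds <- .parse_conect(raw, pdb$atom$eleno)
  if (nrow(bonds) == 0)
    stop("topology carries no bond records; provide a bond-bearing input ",
         "(PDB with CONECT records)")
  frames <- .xyz_to_frames(pdb$xyz, n)
  rep_ends <- .parse_replicate_remark(raw)
  if (is.null(rep_ends)) rep_ends <- length(frames)
  if (utils::tail(rep_ends, 1) != length(frames)) rep_ends <- length(frames)

  for (tr in trajectory_sources) {
    if (grepl("\\.dcd$", tr, ignore.case = TRUE)) {
      xyz <- bio3d::read.dcd(tr, verbose = FALSE)
    } else {
      xyz <- bio3d::read.pdb(tr, multi = TRUE, verbose = FALSE)$xyz
    }
    if (ncol(as.matrix(xyz)) != 3 * n)
      stop(sprintf("trajectory '%s' has %d atoms but the topology has %d",
                   tr, ncol(as.matrix(xyz)) / 3, n))
    frames <- c(frames, .xyz_to_frames(xyz, n))
    rep_ends <- c(rep_ends, length(frames))
  }
  if (frame_stride > 1L) {
    keep <- seq(1L, length(frames), by = as.integer(frame_stride))
    rep_ends <- vapply(rep_ends, function(e) sum(keep <= e), integer(1))
    rep_ends <- unique(rep_ends[rep_ends > 0])
    frames <- frames[keep]
  }
  structure_ensemble(atoms, bonds, frames, rep_ends, variant_id)
}

#' @keywords internal
.element_of <- function(atom_df) {
  el <- toupper(trimws(atom_df$elesy))
  miss <- is.na(el) | el == ""
  # fall back to the leading letter of the atom name
  el[miss] <- substr(gsub("^[0-9]*", "", atom_df$elety[miss]), 1, 1)
  el
}

#' @keywords internal
.xyz_to_frames <- function(xyz, n) {
  m <- as.matrix(xyz)
  if (is.null(dim(m)) || ncol(m) != 3 * n)
    stop("coordinate block does not match the topology atom count")
  lapply(seq_len(nrow(m)), function(i) matrix(m[i, ], ncol = 3, byrow = TRUE))
}

#' @keywords internal
.parse_conect <- function(lines, serials) {
  con <- grep("^CONECT", lines, value = TRUE)
  out <- list()
  for (ln in con) {
    flds <- suppressWarnings(as.integer(
      substring(ln, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) >= 2) {
      a <- match(flds[1], serials)
      bs <- match(flds[-1], serials)
      for (b in bs[!is.na(bs)])
        if (!is.na(a)) out[[length(out) + 1]] <- sort(c(a, b))
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, out))
}

#' @keywords internal
.parse_replicate_remark <- function(lines) {
  rem <- grep("^REMARK 285 REPLICATE_ENDS", lines, value = TRUE)
  if (length(rem) == 0) return(NULL)
  as.integer(strsplit(trimws(sub("^REMARK 285 REPLICATE_ENDS", "", rem[1])),
                      "\\s+")[[1]])
}

#' Write a structure ensemble as multi-model PDB
#'
#' Emits every frame as one MODEL, all CONECT bonds, and a
#' `REMARK 285 REPLICATE_ENDS` line so replicate boundaries survive a
#' write/load round trip.
#'
#' @param ens a `structure_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  a <- ens$atoms
  n <- nrow(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("REMARK 285 REPLICATE_ENDS",
                   paste(ens$replicate_ends, collapse = " ")), con)
  fmt_name <- function(nm) {
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  rec <- ifelse(a$is_water, "HETATM", "ATOM  ")
  nm <- fmt_name(a$name)
  for (f in seq_along(ens$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens$frames[[f]]
    writeLines(sprintf("%s%5d %s%-1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rec, seq_len(n), nm, "", a$resname, a$chain, a$resno,
                       xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                       sprintf("%2s", a$element)), con)
    writeLines("ENDMDL", con)
  }
  if (nrow(ens$bonds) > 0) {
    writeLines(sprintf("CONECT%5d%5d", ens$bonds[, 1], ens$bonds[, 2]), con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Mutations and selections

#' Parse a mutation specifier
#'
#' Mutations are written `"CHAIN:WposM"`, e.g. `"A:N92K"` for asparagine 92
#' of chain A mutated to lysine.
#'
#' @param x character specifier (or an already-parsed mutation).
#' @return object of class `mutation` with fields `chain`, `pos`, `wt`, `mut`.
#' @export
parse_mutation <- function(x) {
  if (inherits(x, "mutation")) return(x)
  m <- regmatches(x, regexec("^([A-Za-z0-9]+):([A-Z])([0-9]+)([A-Z])$", x))[[1]]
  if (length(m) != 5)
    stop(sprintf("cannot parse mutation '%s'; expected 'CHAIN:WposM'", x))
  if (m[3] == m[5])
    stop("wild-type and mutant residue must differ")
  structure(list(chain = m[2], wt = m[3], pos = as.integer(m[4]), mut = m[5]),
            class = "mutation")
}

#' @export
format.mutation <- function(x, ...)
  sprintf("%s:%s%d%s", x$chain, x$wt, x$pos, x$mut)

#' @export
print.mutation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @keywords internal
.mutation_site_atoms <- function(ens, mutation, check_wt = TRUE) {
  mut <- parse_mutation(mutation)
  idx <- which(ens$atoms$chain == mut$chain & ens$atoms$resno == mut$pos &
                 !ens$atoms$is_water)
  if (length(idx) == 0)
    stop(sprintf("position %s:%d not found in topology", mut$chain, mut$pos))
  if (check_wt) {
    res <- unique(ens$atoms$resname[idx])[1]
    if (!is.na(aa_321(res)) && !aa_321(res) %in% c(mut$wt, mut$mut))
      stop(sprintf("topology holds %s at %s:%d, mutation says %s",
                   res, mut$chain, mut$pos, mut$wt))
  }
  idx
}

#' Select atoms at one of the three granularities
#'
#' `"residue"` returns the atoms of the mutated residue, `"surrounding"`
#' every protein residue with at least one atom within `radius` of any atom
#' of the mutated residue in the given frame (the mutated residue included),
#' and `"whole_protein"` all protein atoms.  Waters are never part of a
#' selection; they enter the metrics only through water-bridge logic.
#' Surrounding membership is dynamic: it is recomputed for the frame asked.
#'
#' @param ens a `structure_ensemble`.
#' @param mutation mutation specifier (`"A:N92K"`) or `mutation` object.
#' @param level one of `"residue"`, `"surrounding"`, `"whole_protein"`.
#' @param frame frame index used for the surrounding distance test.
#' @param radius surrounding cutoff radius in Angstrom (default 8).
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(ens, mutation, level = c("residue", "surrounding",
                                                  "whole_protein"),
                         frame = 1L, radius = 8.0) {
  level <- match.arg(level)
  if (radius <= 0) stop("radius must be positive")
  prot <- protein_atoms(ens)
  if (level == "whole_protein") return(prot)
  site <- .mutation_site_atoms(ens, mutation)
  if (level == "residue") return(site)
  xyz <- ens$frames[[frame]]
  site_xyz <- xyz[site, , drop = FALSE]
  # squared distance of every protein atom to the nearest site atom
  d2 <- rep(Inf, length(prot))
  px <- xyz[prot, , drop = FALSE]
  for (k in seq_len(nrow(site_xyz))) {
    dd <- (px[, 1] - site_xyz[k, 1])^2 + (px[, 2] - site_xyz[k, 2])^2 +
      (px[, 3] - site_xyz[k, 3])^2
    d2 <- pmin(d2, dd)
  }
  near <- prot[d2 <= radius^2]
  keys <- paste(ens$atoms$chain, ens$atoms$resno)
  sel_res <- unique(keys[near])
  prot[keys[prot] %in% sel_res]
}

#' Average a per-frame series
#'
#' Arithmetic mean with equal weight per frame across all replicates.
#'
#' @param per_frame_values numeric vector, one value per frame.
#' @return scalar mean.
#' @export
frame_average <- function(per_frame_values) {
  if (length(per_frame_values) == 0)
    stop("frame_average requires at least one value")
  mean(per_frame_values)
}
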