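# Hydrogen-bond detection and energetics: lenient geometric detection, a
# ramp-based energy estimate (25 kJ/mol ideal), an energy filter, bifurcation
# capping, water bridges with an entropic desolvation penalty, and the
# unsatisfied donor/acceptor count.

# Detection cutoffs (deliberately lenient; the energy filter removes
# unrealistic bonds afterwards).
.HB_DIST_DA <- 3.5     # donor-acceptor distance cutoff, Angstrom
.HB_ANGLE_DHA <- 100   # donor-hydrogen-acceptor angle cutoff, degrees
.HB_E_MIN <- 6.25      # kJ/mol, bonds at or below are discarded
.HB_E_CAP <- 15        # kJ/mol cap on additional bonds of a bifurcated atom
.HB_WATER_PENALTY <- 32.2  # kJ/mol entropic cost of removing a water

#' Hydrogen-bond energy from geometry
#'
#' Estimates the bond energy as `25 * S_HA * S_DHA * S_HAX` kJ/mol, where the
#' three factors are saturated ramps in the hydrogen-acceptor distance, the
#' donor-hydrogen-acceptor angle, and the steric hindrance from atoms
#' covalently bound to the acceptor.  An ideal interaction (short, linear,
#' unhindered) scores 25 kJ/mol.  Hydrogen neighbors of the acceptor hinder
#' less than heavy ones, so a softer ramp applies; with several neighbors the
#' lowest factor is used, and an acceptor without covalent neighbors is
#' unhindered.
#'
#' @param dist_HA hydrogen-acceptor distance (Angstrom).
#' @param angle_DHA donor-hydrogen-acceptor angle (degrees).
#' @param neighbor_angles hydrogen-acceptor-neighbor angles (degrees) over
#'   the acceptor's covalent neighbors.
#' @param neighbor_is_h logical, parallel to `neighbor_angles`.
#' @return energy in kJ/mol, in \[0, 25\].
#' @export
hbond_energy <- function(dist_HA, angle_DHA,
                         neighbor_angles = numeric(0),
                         neighbor_is_h = logical(0)) {
  if (dist_HA <= 0) stop("dist_HA must be positive")
  if (angle_DHA < 0 || angle_DHA > 180) stop("angle_DHA outside [0, 180]")
  clamp01 <- function(x) pmin(1, pmax(0, x))
  s_ha <- clamp01((2.6 - max(dist_HA, 2.1)) / (2.6 - 2.1))
  s_dha <- clamp01((min(angle_DHA, 165) - 100) / (165 - 100))
  s_hax <- 1
  if (length(neighbor_angles) > 0) {
    lo <- ifelse(neighbor_is_h, 75, 85)
    hi <- ifelse(neighbor_is_h, 85, 95)
    s_hax <- min(clamp01((pmin(neighbor_angles, hi) - lo) / (hi - lo)))
  }
  25 * s_ha * s_dha * s_hax
}

#' @keywords internal
.bond_neighbors <- function(ens) {
  n <- nrow(ens$atoms)
  nb <- vector("list", n)
  b <- ens$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b[k, 1]]] <- c(nb[[b[k, 1]]], b[k, 2])
    nb[[b[k, 2]]] <- c(nb[[b[k, 2]]], b[k, 1])
  }
  nb
}

#' Detect candidate hydrogen bonds in one frame
#'
#' Candidates are all donor-hydrogen-acceptor triples with donor and acceptor
#' among N, O, S atoms, a donor-acceptor distance of at most 3.5 Angstrom and
#' a donor-hydrogen-acceptor angle of at least 100 degrees.  Donors must
#' carry a covalently bound hydrogen; atoms covalently bound to each other
#' are never partners.  Energies are left unset.
#'
#' @param ens a `structure_ensemble` (hydrogens required).
#' @param frame frame index.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `dist_HA`, `dist_DA`, `angle_DHA`, `water` (either end is
#'   water), `energy` (`NA`).
#' @export
detect_candidate_hbonds <- function(ens, frame = 1L) {
  a <- ens$atoms
  if (!any(a$element == "H"))
    stop("topology contains no hydrogens; hydrogen-bond analysis requires ",
         "an explicitly protonated input")
  xyz <- ens$frames[[frame]]
  nb <- .bond_neighbors(ens)
  polar <- which(a$element %in% c("N", "O", "S"))
  donors <- polar[vapply(polar, function(i)
    any(a$element[nb[[i]]] == "H"), logical(1))]
  acceptors <- polar
  out <- list()
  for (d in donors) {
    hyd <- nb[[d]][a$element[nb[[d]]] == "H"]
    dd <- (xyz[acceptors, 1] - xyz[d, 1])^2 +
      (xyz[acceptors, 2] - xyz[d, 2])^2 + (xyz[acceptors, 3] - xyz[d, 3])^2
    cand <- acceptors[dd <= .HB_DIST_DA^2]
    cand <- setdiff(cand, c(d, nb[[d]]))
    for (acc in cand) {
      for (h in hyd) {
        if (acc %in% nb[[h]]) next
        ang <- angle3(xyz[d, ], xyz[h, ], xyz[acc, ])
        if (ang >= .HB_ANGLE_DHA) {
          out[[length(out) + 1]] <- data.frame(
            donor = d, hydrogen = h, acceptor = acc,
            dist_HA = vnorm(xyz[acc, ] - xyz[h, ]),
            dist_DA = vnorm(xyz[acc, ] - xyz[d, ]),
            angle_DHA = ang,
            water = a$is_water[d] || a$is_water[acc],
            energy = NA_real_)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), dist_HA = numeric(0),
                      dist_DA = numeric(0), angle_DHA = numeric(0),
                      water = logical(0), energy = numeric(0)))
  do.call(rbind, out)
}

#' Fill in energies for detected candidate bonds
#'
#' @param ens a `structure_ensemble`.
#' @param bonds candidate table from [detect_candidate_hbonds()].
#' @param frame frame index (geometry source for acceptor neighbors).
#' @return the table with the `energy` column populated (kJ/mol).
#' @export
score_hbonds <- function(ens, bonds, frame = 1L) {
  if (nrow(bonds) == 0) return(bonds)
  xyz <- ens$frames[[frame]]
  nb <- .bond_neighbors(ens)
  el <- ens$atoms$element
  bonds$energy <- vapply(seq_len(nrow(bonds)), function(k) {
    acc <- bonds$acceptor[k]; h <- bonds$hydrogen[k]
    nbrs <- setdiff(nb[[acc]], h)
    angs <- vapply(nbrs, function(x) angle3(xyz[h, ], xyz[acc, ], xyz[x, ]),
                   numeric(1))
    hbond_energy(bonds$dist_HA[k], bonds$angle_DHA[k], angs, el[nbrs] == "H")
  }, numeric(1))
  bonds
}

#' Energy-filter and bifurcation-cap a scored bond set
#'
#' Bonds with energy at or below 6.25 kJ/mol are discarded.  A bond is
#' bifurcated when its hydrogen or its acceptor participates in two or more
#' retained bonds; for each such sharing atom the highest-energy bond keeps
#' its energy and every additional bond is capped at 15 kJ/mol.  (A donor
#' heavy atom engaging through two distinct hydrogens is not bifurcated.)
#' Ties are broken by atom-index order (donor, then hydrogen, then
#' acceptor), so the result is deterministic.
#'
#' @param bonds scored bond table.
#' @return the retained bond table (capped energies).
#' @export
filter_and_cap <- function(bonds) {
  if (nrow(bonds) == 0) return(bonds)
  if (any(is.na(bonds$energy))) stop("bonds must be scored before filtering")
  bonds <- bonds[bonds$energy > .HB_E_MIN, , drop = FALSE]
  if (nrow(bonds) <= 1) return(bonds)
  ord <- order(-bonds$energy, bonds$donor, bonds$hydrogen, bonds$acceptor)
  for (atom in sort(unique(c(bonds$hydrogen, bonds$acceptor)))) {
    member <- which(bonds$hydrogen == atom | bonds$acceptor == atom)
    if (length(member) < 2) next
    member <- member[order(match(member, ord))]
    extra <- member[-1]
    bonds$energy[extra] <- pmin(bonds$energy[extra], .HB_E_CAP)
  }
  bonds
}

#' Identify water bridges among retained protein-water bonds
#'
#' A water engaged in two or more retained hydrogen bonds with the protein
#' forms a bridge; its energy is the sum of the member bond energies minus a
#' 32.2 kJ/mol entropic penalty for removing the water from solution,
#' floored at zero.
#'
#' @param ens a `structure_ensemble`.
#' @param retained retained bond table (after [filter_and_cap()]).
#' @return data.frame with columns `water_key` (chain/resno of the water),
#'   `energy` (kJ/mol) and a list-column `members` of row indices into
#'   `retained`.
#' @export
find_water_bridges <- function(ens, retained) {
  a <- ens$atoms
  empty <- data.frame(water_key = character(0), energy = numeric(0))
  empty$members <- list()
  if (nrow(retained) == 0) return(empty)
  dw <- a$is_water[retained$donor]
  aw <- a$is_water[retained$acceptor]
  pw <- which(xor(dw, aw))            # protein-water bonds only
  if (length(pw) == 0) return(empty)
  watom <- ifelse(dw[pw], retained$donor[pw], retained$acceptor[pw])
  key <- paste(a$chain[watom], a$resno[watom])
  keys <- names(which(table(key) >= 2))
  if (length(keys) == 0) return(empty)
  rows <- lapply(keys, function(k) {
    mem <- pw[key == k]
    data.frame(water_key = k,
               energy = max(0, sum(retained$energy[mem]) - .HB_WATER_PENALTY))
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(keys, function(k) pw[key == k])
  out
}

#' @keywords internal
.hbond_partner_set <- function(ens, definition = c("polar", "strict")) {
  definition <- match.arg(definition)
  a <- ens$atoms
  nb <- .bond_neighbors(ens)
  prot <- which(!a$is_water)
  if (definition == "polar") {
    heavy <- prot[a$element[prot] %in% c("N", "O", "S")]
    hs <- unlist(lapply(heavy, function(i) nb[[i]][a$element[nb[[i]]] == "H"]))
    sort(unique(c(heavy, hs)))
  } else {
    # all oxygens plus nitrogens without bound hydrogens
    ox <- prot[a$element[prot] == "O"]
    ni <- prot[a$element[prot] == "N"]
    ni <- ni[vapply(ni, function(i) !any(a$element[nb[[i]]] == "H"),
                    logical(1))]
    sort(unique(c(ox, ni)))
  }
}

#' Count unsatisfied hydrogen-bond partners in a selection
#'
#' Counts atoms of the selection that are potential partners (by default all
#' protein N, O, S atoms plus the hydrogens bound to them) yet appear in no
#' retained bond.  Membership in a water-mediated bond satisfies an atom.
#' The alternative `"strict"` definition restricts partners to oxygens plus
#' hydrogen-free nitrogens.
#'
#' @param ens a `structure_ensemble`.
#' @param retained retained bond table for the frame.
#' @param selection atom indices to evaluate.
#' @param definition `"polar"` (default) or `"strict"`.
#' @return integer count.
#' @export
unsatisfied_count <- function(ens, retained, selection,
                              definition = c("polar", "strict")) {
  partners <- .hbond_partner_set(ens, definition)
  engaged <- unique(c(retained$donor, retained$hydrogen, retained$acceptor))
  sum(selection %in% setdiff(partners, engaged))
}

#' Per-frame hydrogen-bond summary for a selection
#'
#' Runs detection, scoring, filtering/capping and water-bridge assembly on
#' one frame, then totals (a) the energies of retained protein-protein bonds
#' touching the selection plus the energies of water bridges anchored in the
#' selection and (b) the unsatisfied-partner count within the selection.
#'
#' @param ens a `structure_ensemble`.
#' @param frame frame index.
#' @param selection atom indices.
#' @param definition partner-set definition for the unsatisfied count.
#' @return list with `energy` (kJ/mol), `unsatisfied` (count), and the
#'   retained bond table.
#' @export
frame_hbond_summary <- function(ens, frame, selection,
                                definition = "polar") {
  cand <- detect_candidate_hbonds(ens, frame)
  ret <- filter_and_cap(score_hbonds(ens, cand, frame))
  pp <- ret[!ret$water, , drop = FALSE]
  touch <- pp$donor %in% selection | pp$hydrogen %in% selection |
    pp$acceptor %in% selection
  e_total <- sum(pp$energy[touch])
  bridges <- find_water_bridges(ens, ret)
  if (nrow(bridges) > 0) {
    iswat <- ens$atoms$is_water
    for (b in seq_len(nrow(bridges))) {
      mem <- bridges$members[[b]]
      anchor <- unlist(lapply(mem, function(m)
        Filter(function(i) !iswat[i],
               c(ret$donor[m], ret$hydrogen[m], ret$acceptor[m]))))
      if (any(anchor %in% selection)) e_total <- e_total + bridges$energy[b]
    }
  }
  list(energy = e_total,
       unsatisfied = unsatisfied_count(ens, ret, selection, definition),
       retained = ret, bridges = bridges)
}

#' Hydrogen-bond metric deltas between mutant and wild type
#'
#' For each variant the per-frame selection-restricted totals (bond energy
#' including water bridges; unsatisfied count) are frame-averaged, and the
#' mutant-minus-wild-type differences returned.  The surrounding selection is
#' recomputed per frame.
#'
#' @param mut_ens,wt_ens mutant and wild-type ensembles.
#' @param mutation mutation specifier.
#' @param level selection level.
#' @param radius surrounding radius (Angstrom).
#' @param definition partner-set definition.
#' @return named numeric: `d_energy` (kJ/mol), `d_unsatisfied` (count).
#' @export
hbond_metric_deltas <- function(mut_ens, wt_ens, mutation,
                                level = "surrounding", radius = 8.0,
                                definition = "polar") {
  per_variant <- function(ens) {
    vals <- vapply(seq_len(n_frames(ens)), function(f) {
      sel <- select_atoms(ens, mutation, level, frame = f, radius = radius)
      s <- frame_hbond_summary(ens, f, sel, definition)
      c(s$energy, s$unsatisfied)
    }, numeric(2))
    c(frame_average(vals[1, ]), frame_average(vals[2, ]))
  }
  m <- per_variant(mut_ens)
  w <- per_variant(wt_ens)
  c(d_energy = m[1] - w[1], d_unsatisfied = m[2] - w[2])
}
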