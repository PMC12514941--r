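# Solvent-accessible surface area (Shrake-Rupley sphere sampling) and the
# hydrophobic-exposure metric.
#
# Coordinates are first moved into a canonical frame (centered, aligned to
# the principal axes with deterministic sign conventions) before the sphere
# grid is applied, so the computed areas are invariant under rigid-body
# motion of the input rather than merely approximately so.

.SASA_PROBE <- 1.4     # probe radius, Angstrom
.SASA_POINTS <- 100    # sphere sample points per atom

#' @keywords internal
.sphere_points <- function(n) {
  # deterministic golden-spiral point set on the unit sphere
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' @keywords internal
.canonical_frame <- function(coords) {
  ctr <- colMeans(coords)
  x <- sweep(coords, 2, ctr)
  cv <- crossprod(x) / nrow(x)
  ev <- eigen(cv, symmetric = TRUE)$vectors
  # rotation-equivariant sign convention: orient the first two axes by the
  # coordinate skewness along them, take the third as their cross product
  for (k in 1:2) {
    if (sum((x %*% ev[, k])^3) < 0) ev[, k] <- -ev[, k]
  }
  ev[, 3] <- pracma_cross(ev[, 1], ev[, 2])
  x %*% ev
}

#' Per-atom solvent-accessible surface area of one frame
#'
#' Shrake-Rupley sphere sampling with a 1.4 Angstrom probe over Bondi van
#' der Waals radii; hydrogens carry their own spheres.  Water atoms are
#' excluded from the calculation (they are solvent, not surface).
#'
#' @param ens a `structure_ensemble`.
#' @param frame frame index.
#' @param probe probe radius (Angstrom).
#' @param n_points sphere sample points per atom.
#' @return numeric vector of per-atom SASA (Angstrom^2), 0 for waters.
#' @export
sasa_atoms <- function(ens, frame = 1L, probe = .SASA_PROBE,
                       n_points = .SASA_POINTS) {
  a <- ens$atoms
  idx <- which(!a$is_water)
  coords <- .canonical_frame(ens$frames[[frame]][idx, , drop = FALSE])
  radii <- vdw_radius(a$element[idx]) + probe
  n <- length(idx)
  pts <- .sphere_points(n_points)
  d2 <- as.matrix(stats::dist(coords))^2
  out <- numeric(nrow(a))
  for (i in seq_len(n)) {
    nbrs <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)
    sp <- sweep(pts * radii[i], 2, coords[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nbrs) {
      if (!any(free)) break
      dd <- (sp[, 1] - coords[j, 1])^2 + (sp[, 2] - coords[j, 2])^2 +
        (sp[, 3] - coords[j, 3])^2
      free <- free & dd >= radii[j]^2
    }
    out[idx[i]] <- 4 * pi * radii[i]^2 * mean(free)
  }
  out
}

#' Relative solvent exposure per residue
#'
#' Trajectory-mean residue SASA divided by the reference SASA of the free
#' amino acid, in percent, plus the derived exposure class.
#'
#' @param ens a `structure_ensemble`.
#' @param ref_sasa named reference table (see [reference_sasa()]).
#' @param frames frame indices to average over (default all).
#' @param n_points sphere sample points per atom.
#' @return data.frame with chain, resno, resname, rel_exposure (percent),
#'   exposure.
#' @export
residue_exposure <- function(ens, ref_sasa = reference_sasa(),
                             frames = seq_len(n_frames(ens)),
                             n_points = .SASA_POINTS) {
  a <- ens$atoms
  prot <- which(!a$is_water)
  key <- paste(a$chain[prot], a$resno[prot])
  ukey <- unique(key)
  per_frame <- vapply(frames, function(f) {
    s <- sasa_atoms(ens, f, n_points = n_points)
    as.numeric(tapply(s[prot], factor(key, levels = ukey), sum))
  }, numeric(length(ukey)))
  mean_sasa <- rowMeans(as.matrix(per_frame))
  meta <- a[prot, ][match(ukey, key), ]
  refv <- ref_sasa[meta$resname]
  if (any(is.na(refv)))
    stop("no reference SASA for residue type(s): ",
         paste(unique(meta$resname[is.na(refv)]), collapse = ","))
  rel <- 100 * mean_sasa / refv
  data.frame(chain = meta$chain, resno = meta$resno, resname = meta$resname,
             rel_exposure = unname(rel),
             exposure = exposure_class(unname(rel)),
             stringsAsFactors = FALSE)
}

#' Hydrophobic solvent-accessible surface per residue
#'
#' Sums the per-atom SASA over each residue's hydrophobic moieties: atoms
#' engaged in a C-C or C-H bond, i.e. all carbons and the hydrogens bound to
#' carbon.  Averaged over the requested frames.
#'
#' @param ens a `structure_ensemble` (bond information required).
#' @param frames frame indices to average over (default all).
#' @param n_points sphere sample points per atom.
#' @return data.frame with chain, resno, resname, hydrophobic_sasa.
#' @export
hydrophobic_sasa <- function(ens, frames = seq_len(n_frames(ens)),
                             n_points = .SASA_POINTS) {
  a <- ens$atoms
  if (nrow(ens$bonds) == 0)
    stop("hydrophobic SASA requires bond information")
  nb <- .bond_neighbors(ens)
  prot <- which(!a$is_water)
  hydrophobic <- vapply(prot, function(i) {
    if (a$element[i] == "C") return(TRUE)
    if (a$element[i] == "H")
      return(any(a$element[nb[[i]]] == "C"))
    FALSE
  }, logical(1))
  key <- paste(a$chain[prot], a$resno[prot])
  ukey <- unique(key)
  per_frame <- vapply(frames, function(f) {
    s <- sasa_atoms(ens, f, n_points = n_points)
    sh <- ifelse(hydrophobic, s[prot], 0)
    as.numeric(tapply(sh, factor(key, levels = ukey), sum))
  }, numeric(length(ukey)))
  meta <- a[prot, ][match(ukey, key), ]
  data.frame(chain = meta$chain, resno = meta$resno, resname = meta$resname,
             hydrophobic_sasa = rowMeans(as.matrix(per_frame)),
             stringsAsFactors = FALSE)
}

#' Benchmark-normalized hydrophobic-exposure score
#'
#' Same interpolation/clamping contract as [sidechain_score()], with curves
#' keyed by amino acid only.
#'
#' @param sasa observed hydrophobic SASA (Angstrom^2).
#' @param aa 1-letter amino-acid code.
#' @param curves a SASA curve set.
#' @return score in \[0, 1\].
#' @export
exposure_score <- function(sasa, aa, curves) {
  cv <- curves[[aa]]
  if (is.null(cv))
    stop(sprintf("no benchmark curve for category '%s'", aa))
  stats::approx(cv$x, cv$y, xout = sasa, rule = 2)$y
}
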