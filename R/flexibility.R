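# Backbone and sidechain flexibility: RMSF after least-squares superposition,
# exposure classification, and the benchmark-normalized sidechain score.

#' @keywords internal
.frames_to_xyz <- function(frames) {
  t(vapply(frames, function(m) as.vector(t(m)), numeric(3 * nrow(frames[[1]]))))
}

#' @keywords internal
.xyz_row_to_frame <- function(row) matrix(row, ncol = 3, byrow = TRUE)

# Superpose all frames on the subset `fit_atoms` (atom indices), reference
# frame 1; returns the list of fitted frames.  Delegated to bio3d's
# least-squares fitting.
#' @keywords internal
.superpose <- function(ens, fit_atoms) {
  xyz <- .frames_to_xyz(ens$frames)
  inds <- as.vector(t(outer(fit_atoms, 1:3, function(i, k) 3 * (i - 1) + k)))
  fitted <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                           fixed.inds = inds, mobile.inds = inds)
  lapply(seq_len(nrow(fitted)), function(i) .xyz_row_to_frame(fitted[i, ]))
}

#' @keywords internal
.rmsf_of <- function(frames, atom_idx) {
  # per-atom root-mean-square deviation from the mean position
  vapply(atom_idx, function(i) {
    pts <- t(vapply(frames, function(f) f[i, ], numeric(3)))
    mu <- colMeans(pts)
    sqrt(mean(rowSums(sweep(pts, 2, mu)^2)))
  }, numeric(1))
}

#' Backbone RMSF per residue
#'
#' Frames are globally superposed on all protein C-alpha atoms
#' (least-squares) and the per-residue RMSF of each C-alpha about its mean
#' position is computed, together with the mean over the residues of a
#' selection.
#'
#' @param ens a `structure_ensemble` with at least two frames.
#' @param selection optional atom indices; the `mean` entry averages over
#'   residues having at least one atom in the selection (default: all).
#' @return list with `residues` (data.frame chain, resno, rmsf) and `mean`.
#' @export
backbone_rmsf <- function(ens, selection = NULL) {
  if (n_frames(ens) < 2)
    stop("RMSF is undefined for a single frame")
  a <- ens$atoms
  ca <- which(!a$is_water & a$name == "CA")
  if (length(ca) == 0) stop("no C-alpha atoms present")
  fitted <- .superpose(ens, ca)
  vals <- .rmsf_of(fitted, ca)
  res <- data.frame(chain = a$chain[ca], resno = a$resno[ca], rmsf = vals,
                    stringsAsFactors = FALSE)
  if (is.null(selection)) selection <- protein_atoms(ens)
  keys <- paste(a$chain, a$resno)
  sel_res <- unique(keys[selection])
  list(residues = res, mean = mean(res$rmsf[paste(res$chain, res$resno) %in%
                                              sel_res]))
}

#' Sidechain RMSF of one residue
#'
#' Frames are superposed locally on the backbone heavy atoms of the residue
#' and its two sequence neighbors (truncated at chain ends) so backbone drift
#' does not dominate; the RMSF is then averaged over the residue's
#' non-backbone atoms.  Glycine (no sidechain atoms) returns 0 with
#' attribute `no_sidechain`.
#'
#' @param ens a `structure_ensemble` with at least two frames.
#' @param resno residue number; `chain` chain id.
#' @return scalar RMSF (Angstrom).
#' @export
sidechain_rmsf <- function(ens, resno, chain = "A") {
  if (n_frames(ens) < 2) stop("RMSF is undefined for a single frame")
  a <- ens$atoms
  own <- which(a$chain == chain & a$resno == resno & !a$is_water)
  if (length(own) == 0) stop(sprintf("residue %s:%d not found", chain, resno))
  sc <- own[!a$is_backbone[own]]
  if (length(sc) == 0)
    return(structure(0, no_sidechain = TRUE))
  nbhood <- which(a$chain == chain & a$resno %in% (resno + (-1:1)) &
                    !a$is_water & a$is_backbone &
                    a$name %in% c("N", "CA", "C", "O"))
  fitted <- .superpose(ens, nbhood)
  mean(.rmsf_of(fitted, sc))
}

#' Classify residue solvent exposure
#'
#' The trajectory-mean residue SASA divided by the reference SASA of the
#' free amino acid gives a relative exposure; residues are `buried` at 0%,
#' `partial` in (0, 20\]%, and `exposed` above 20%.
#'
#' @param rel_exposure relative exposure in percent.
#' @return factor level as character: `"buried"`, `"partial"`, `"exposed"`.
#' @export
exposure_class <- function(rel_exposure) {
  ifelse(rel_exposure <= 1e-9, "buried",
         ifelse(rel_exposure <= 20, "partial", "exposed"))
}

#' Benchmark-normalized sidechain flexibility score
#'
#' Linear interpolation on the stored monotone curve for the residue's
#' (amino acid, exposure class) category; outside the stored range the score
#' clamps to the nearest endpoint.  Low RMSF (at or below the distribution
#' mode) scores 1; unusually high flexibility is penalized towards 0.
#'
#' @param rmsf observed sidechain RMSF (Angstrom).
#' @param aa 1-letter amino-acid code.
#' @param exposure exposure class.
#' @param curves an RMSF curve set from [build_benchmark_curves()] or
#'   [load_curves()].
#' @return score in \[0, 1\].
#' @export
sidechain_score <- function(rmsf, aa, exposure, curves) {
  key <- paste0(aa, "_", exposure)
  cv <- curves[[key]]
  if (is.null(cv))
    stop(sprintf("no benchmark curve for category '%s'", key))
  stats::approx(cv$x, cv$y, xout = rmsf, rule = 2)$y
}
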