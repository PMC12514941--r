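# Benchmark curves: per-category monotone score curves built from a sample
# collection via Gaussian KDE (Silverman bandwidth) and a suffix-maximum
# envelope, plus CSV serialization.

.KDE_GRID_N <- 512

#' Collect benchmark samples from a set of ensembles
#'
#' One row per protein residue per ensemble: amino acid, exposure class
#' (from the trajectory-mean relative SASA), sidechain RMSF, and hydrophobic
#' SASA.  Glycine rows carry a zero sidechain RMSF and are flagged.
#'
#' @param ensembles list of `structure_ensemble`s (each needs >= 2 frames
#'   for the RMSF part).
#' @param ref_sasa reference SASA table.
#' @param n_points SASA sphere sample points per atom.
#' @return data.frame with columns `variant`, `chain`, `resno`, `aa`,
#'   `exposure`, `sidechain_rmsf`, `hydrophobic_sasa`, `no_sidechain`.
#' @export
collect_samples <- function(ensembles, ref_sasa = reference_sasa(),
                            n_points = .SASA_POINTS) {
  if (length(ensembles) < 1) stop("need at least one ensemble")
  rows <- lapply(ensembles, function(ens) {
    expo <- residue_exposure(ens, ref_sasa, n_points = n_points)
    hyd <- hydrophobic_sasa(ens, n_points = n_points)
    key <- paste(expo$chain, expo$resno)
    hkey <- paste(hyd$chain, hyd$resno)
    sc <- vapply(seq_len(nrow(expo)), function(i)
      as.numeric(sidechain_rmsf(ens, expo$resno[i], expo$chain[i])),
      numeric(1))
    data.frame(variant = ens$variant_id, chain = expo$chain,
               resno = expo$resno, aa = aa_321(expo$resname),
               exposure = expo$exposure, sidechain_rmsf = sc,
               hydrophobic_sasa = hyd$hydrophobic_sasa[match(key, hkey)],
               no_sidechain = aa_321(expo$resname) == "G",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit a monotone benchmark curve for one category
#'
#' A Gaussian KDE with Silverman's rule-of-thumb bandwidth is evaluated on a
#' uniform 512-point grid over \[0, max(sample) + 3 bandwidths\], scaled to a
#' maximum of 1, and made non-increasing by the suffix-maximum envelope
#' `y'_i = max(y_j, j >= i)` (filling in local minima so only unusually
#' large values are penalized, never small ones).
#'
#' @param x numeric samples (RMSF or hydrophobic SASA values).
#' @param category category label (for error messages and serialization).
#' @return object of class `benchmark_curve`: list(category, x, y).
#' @export
fit_curve <- function(x, category = "curve") {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2 || stats::sd(x) == 0)
    stop(sprintf("category '%s' needs >= 2 distinct sample values", category))
  h <- stats::bw.nrd0(x)
  d <- stats::density(x, bw = h, kernel = "gaussian",
                      from = 0, to = max(x) + 3 * h, n = .KDE_GRID_N)
  y <- d$y / max(d$y)
  y <- rev(cummax(rev(y)))
  structure(list(category = category, x = d$x, y = y),
            class = "benchmark_curve")
}

#' Build the full benchmark curve sets
#'
#' Fits one sidechain-RMSF curve per populated (amino acid, exposure class)
#' category (up to 60) and one hydrophobic-SASA curve per amino acid (up to
#' 20), from a sample table ([collect_samples()] or
#' [build_benchmark_samples()]).  Glycine RMSF categories are skipped (no
#' sidechain).  A manifest reports populated and skipped categories.
#'
#' @param samples sample table with columns `aa`, `exposure`,
#'   `sidechain_rmsf`, `hydrophobic_sasa`.
#' @return list with `rmsf` (curves keyed `"<aa>_<class>"`), `sasa` (keyed
#'   `"<aa>"`), and `manifest` (data.frame category/kind/status).
#' @export
build_benchmark_curves <- function(samples) {
  rmsf <- list(); sasa <- list(); man <- list()
  note <- function(cat, kind, status)
    man[[length(man) + 1]] <<- data.frame(category = cat, kind = kind,
                                          status = status)
  for (aa in intersect(.AA1, unique(samples$aa))) {
    for (cls in c("buried", "partial", "exposed")) {
      key <- paste0(aa, "_", cls)
      xs <- samples$sidechain_rmsf[samples$aa == aa &
                                     samples$exposure == cls &
                                     !(samples$no_sidechain %||% FALSE)]
      if (aa == "G" || length(unique(xs[is.finite(xs)])) < 2) {
        note(key, "rmsf", "missing")
      } else {
        rmsf[[key]] <- fit_curve(xs, key)
        note(key, "rmsf", "fitted")
      }
    }
    xh <- samples$hydrophobic_sasa[samples$aa == aa]
    if (length(unique(xh[is.finite(xh)])) < 2) {
      note(aa, "sasa", "missing")
    } else {
      sasa[[aa]] <- fit_curve(xh, aa)
      note(aa, "sasa", "fitted")
    }
  }
  list(rmsf = rmsf, sasa = sasa, manifest = do.call(rbind, man))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a curve set as CSV
#'
#' The on-disk format is a plain CSV with columns `category`, `x`, `y` —
#' the compatibility surface for externally generated benchmark files.
#' Loading validates the curve invariants (scores in \[0,1\] peaking at 1,
#' non-increasing, strictly ascending x).
#'
#' @param curves named list of `benchmark_curve`s (e.g. the `rmsf` or
#'   `sasa` element of [build_benchmark_curves()]).
#' @param path CSV file path.
#' @return `path` (save) or the curve list (load).
#' @export
save_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(category = cv$category, x = cv$x, y = cv$y))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_curves
#' @export
load_curves <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed curve CSV: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0 || !all(c("category", "x", "y") %in% names(df)))
    stop("curve CSV must have columns category, x, y and at least one row")
  out <- list()
  for (cat in unique(df$category)) {
    sub <- df[df$category == cat, ]
    ln <- which(df$category == cat)[1] + 1  # +1 for the header line
    if (any(diff(sub$x) <= 0))
      stop(sprintf("curve '%s' (near line %d): x not strictly ascending",
                   cat, ln))
    if (any(sub$y < 0 | sub$y > 1) || abs(max(sub$y) - 1) > 1e-9)
      stop(sprintf("curve '%s' (near line %d): scores must lie in [0,1] with max 1",
                   cat, ln))
    if (any(diff(sub$y) > 1e-12))
      stop(sprintf("curve '%s' (near line %d): scores must be non-increasing",
                   cat, ln))
    out[[cat]] <- structure(list(category = cat, x = sub$x, y = sub$y),
                            class = "benchmark_curve")
  }
  out
}
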