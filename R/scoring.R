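# Per-mutation metric assembly, normalization, sign adjustment, and the
# composite score used to rank mutations.
#
# All metrics are frame-averaged per variant and reported as mutant minus
# wild type, so an unchanged property gives 0.  Whole-protein columns are
# opt-in (they converge slowly on short trajectories); salt bridges are the
# exception and are always assessed on the whole protein.

# Sign ledger: +1 when a raw increase is stabilizing.  Binary check columns
# (currently the capping flag) bypass the standard-deviation normalization
# and enter the composite as 0 / -1.
.METRIC_POLARITY <- c(
  hbond_energy = +1, sidechain_score = +1, hydrophobic_score = +1,
  salt_bridges = +1, disulfides = +1,
  unsatisfied = -1, backbone_rmsf = -1, helix_propensity = -1,
  capping_disrupted = -1)
.BINARY_METRICS <- "capping_disrupted"

#' Metric polarity ledger
#'
#' @return named vector mapping metric to +1 (raw increase is stabilizing)
#'   or -1 (raw increase is destabilizing).
#' @export
metric_polarity <- function() .METRIC_POLARITY

#' @keywords internal
.residue_level_scores <- function(ens, residues, curves, expo, hyd) {
  # benchmark-normalized sidechain and hydrophobic scores for given residues
  ekey <- paste(expo$chain, expo$resno)
  hkey <- paste(hyd$chain, hyd$resno)
  sc <- hs <- numeric(0)
  for (key in residues) {
    i <- match(key, ekey)
    aa <- aa_321(expo$resname[i])
    if (aa == "G") {
      sc <- c(sc, 1)          # no sidechain: nothing to penalize
    } else {
      r <- sidechain_rmsf(ens, expo$resno[i], expo$chain[i])
      sc <- c(sc, sidechain_score(as.numeric(r), aa, expo$exposure[i],
                                  curves$rmsf))
    }
    hs <- c(hs, exposure_score(hyd$hydrophobic_sasa[match(key, hkey)], aa,
                               curves$sasa))
  }
  c(sidechain = mean(sc), hydrophobic = mean(hs))
}

#' Evaluate all metrics for one mutation
#'
#' Computes the raw mutant-minus-wild-type delta of every metric at the
#' residue and surrounding levels (whole-protein opt-in); salt bridges,
#' helix checks and disulfides are whole-protein by nature.  Selections for
#' trajectory-level metrics (RMSF, benchmark scores) use frame-1 surrounding
#' membership; per-frame metrics (hydrogen bonding) recompute it per frame.
#'
#' @param mut_ens,wt_ens mutant and wild-type ensembles.
#' @param mutation mutation specifier, e.g. `"A:N92K"`.
#' @param curves benchmark curve sets (list with `rmsf` and `sasa`).
#' @param selections levels to evaluate (`"residue"`, `"surrounding"`, and
#'   optionally `"whole_protein"`).
#' @param radius surrounding radius (Angstrom).
#' @param ref_sasa reference SASA table.
#' @param n_points SASA sphere points per atom.
#' @param hbond_definition partner-set definition for unsatisfied counting.
#' @return named numeric vector of raw metric deltas
#'   (`<metric>.<selection>` plus the whole-protein-only checks).
#' @export
evaluate_mutation <- function(mut_ens, wt_ens, mutation, curves,
                              selections = c("residue", "surrounding"),
                              radius = 8.0, ref_sasa = reference_sasa(),
                              n_points = .SASA_POINTS,
                              hbond_definition = "polar") {
  mut <- parse_mutation(mutation)
  if (nrow(mut_ens$atoms[!mut_ens$atoms$is_water, ]) > 0 &&
      !setequal(unique(wt_ens$atoms$chain), unique(mut_ens$atoms$chain)))
    stop("mutant and wild-type topologies are not comparable")
  out <- c()
  a_w <- wt_ens$atoms; a_m <- mut_ens$atoms
  bb_w <- backbone_rmsf(wt_ens)
  bb_m <- backbone_rmsf(mut_ens)
  expo_w <- residue_exposure(wt_ens, ref_sasa, n_points = n_points)
  expo_m <- residue_exposure(mut_ens, ref_sasa, n_points = n_points)
  hyd_w <- hydrophobic_sasa(wt_ens, n_points = n_points)
  hyd_m <- hydrophobic_sasa(mut_ens, n_points = n_points)
  for (lev in selections) {
    hb <- hbond_metric_deltas(mut_ens, wt_ens, mut, lev, radius,
                              hbond_definition)
    sel_w <- select_atoms(wt_ens, mut, lev, frame = 1, radius = radius)
    sel_m <- select_atoms(mut_ens, mut, lev, frame = 1, radius = radius)
    res_w <- unique(paste(a_w$chain, a_w$resno)[sel_w])
    res_m <- unique(paste(a_m$chain, a_m$resno)[sel_m])
    rmsf_w <- mean(bb_w$residues$rmsf[
      paste(bb_w$residues$chain, bb_w$residues$resno) %in% res_w])
    rmsf_m <- mean(bb_m$residues$rmsf[
      paste(bb_m$residues$chain, bb_m$residues$resno) %in% res_m])
    sco_w <- .residue_level_scores(wt_ens, res_w, curves, expo_w, hyd_w)
    sco_m <- .residue_level_scores(mut_ens, res_m, curves, expo_m, hyd_m)
    tag <- function(m) paste0(m, ".", lev)
    out[tag("hbond_energy")] <- unname(hb["d_energy"])
    out[tag("unsatisfied")] <- unname(hb["d_unsatisfied"])
    out[tag("backbone_rmsf")] <- rmsf_m - rmsf_w
    out[tag("sidechain_score")] <- unname(sco_m["sidechain"] - sco_w["sidechain"])
    out[tag("hydrophobic_score")] <- unname(sco_m["hydrophobic"] - sco_w["hydrophobic"])
  }
  out["salt_bridges"] <- salt_bridge_count(mut_ens) - salt_bridge_count(wt_ens)
  helices <- assign_helices(wt_ens)
  out["helix_propensity"] <- propensity_delta(mut, helices)
  out["capping_disrupted"] <- as.numeric(capping_check(mut, helices))
  out["disulfides"] <- disulfide_count(mut_ens) - disulfide_count(wt_ens)
  out
}

#' Normalize and sign-adjust a raw metric table
#'
#' Each raw column is divided by its population standard deviation over the
#' mutation set (no centering, so 0 stays the wild-type reference) and
#' multiplied by the metric polarity, yielding z-score-like values where
#' positive means predicted stabilizing.  Binary check columns bypass the SD
#' division.  Optional primary-predictor scores are normalized the same way
#' and appended (`predictor_polarity = -1` suits ddG-style scores where
#' lower is better).  Zero-SD columns are dropped from the composite with a
#' warning.
#'
#' @param raw data.frame or matrix of raw deltas, rownames = mutation ids,
#'   colnames `<metric>.<selection>` or whole-protein metric names.
#' @param predictor optional named numeric of primary-predictor scores.
#' @param predictor_polarity sign for the predictor column.
#' @return object of class `metric_table`: list with `raw`, `scaled`
#'   (data.frame), `dropped` (character).
#' @export
scale_table <- function(raw, predictor = NULL, predictor_polarity = -1) {
  raw <- as.data.frame(raw)
  if (nrow(raw) < 2)
    stop("normalization needs at least two mutations (SD undefined)")
  if (!is.null(predictor)) {
    if (is.null(names(predictor)) || !all(rownames(raw) %in% names(predictor)))
      stop("predictor scores must be named by mutation id")
    raw$predictor <- unname(predictor[rownames(raw)])
  }
  pol <- function(col) {
    if (col == "predictor") return(predictor_polarity)
    base <- sub("\\..*$", "", col)
    p <- .METRIC_POLARITY[base]
    if (is.na(p)) stop(sprintf("unknown metric column '%s'", col))
    unname(p)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  scaled <- raw
  dropped <- character(0)
  for (col in names(raw)) {
    base <- sub("\\..*$", "", col)
    if (base %in% .BINARY_METRICS) {
      scaled[[col]] <- raw[[col]] * pol(col)
      next
    }
    s <- pop_sd(raw[[col]])
    if (s == 0) {
      dropped <- c(dropped, col)
      scaled[[col]] <- NULL
      next
    }
    scaled[[col]] <- raw[[col]] / s * pol(col)
  }
  if (length(dropped) > 0)
    warning("dropped zero-variance column(s): ", paste(dropped, collapse = ", "))
  structure(list(raw = raw, scaled = scaled, dropped = dropped),
            class = "metric_table")
}

#' Composite score and ranking
#'
#' The composite score is the arithmetic mean of all scaled metric columns;
#' mutations are ranked by descending composite, ties broken
#' lexicographically by mutation id (rank 1 = best).
#'
#' @param tab a `metric_table` from [scale_table()].
#' @return data.frame with `mutation`, the scaled columns, `composite`,
#'   `rank`, sorted by rank.
#' @export
composite_and_rank <- function(tab) {
  if (!inherits(tab, "metric_table")) stop("expected a metric_table")
  sc <- tab$scaled
  if (ncol(sc) == 0) stop("no scaled columns left to combine")
  comp <- rowMeans(as.matrix(sc))
  ids <- rownames(sc)
  ord <- order(-comp, ids)
  out <- data.frame(mutation = ids[ord], sc[ord, , drop = FALSE],
                    composite = comp[ord], rank = seq_along(ord),
                    row.names = NULL, check.names = FALSE)
  out
}

#' Score and rank a set of mutations against the wild type
#'
#' Convenience wrapper: evaluates every mutation with [evaluate_mutation()],
#' normalizes with [scale_table()], and ranks with [composite_and_rank()].
#'
#' @param ensembles named list of mutant ensembles (names = mutation specs).
#' @param wt_ens wild-type ensemble.
#' @param curves benchmark curve sets.
#' @param ... passed to [evaluate_mutation()] and [scale_table()].
#' @param predictor optional named predictor scores.
#' @return ranked data.frame (see [composite_and_rank()]).
#' @export
rank_mutations <- function(ensembles, wt_ens, curves, predictor = NULL, ...) {
  rows <- lapply(names(ensembles), function(id)
    evaluate_mutation(ensembles[[id]], wt_ens, id, curves, ...))
  raw <- do.call(rbind, rows)
  rownames(raw) <- names(ensembles)
  composite_and_rank(scale_table(raw, predictor = predictor))
}
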