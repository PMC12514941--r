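# Ranking evaluation: ROC / AUC, the stability-weighted ROC in which each
# true positive's step is proportional to its share of the total melting-
# temperature gain, combinatorial AUC bounds for partially untested mutation
# sets, and the fraction-sweep estimator.

#' Build a labeled ranking
#'
#' Labels derive from the melting-temperature change: stabilizing iff
#' `dtm > threshold` (strictly; neutral mutations count as unsuccessful),
#' not stabilizing otherwise, and untested where `dtm` is `NA`.
#'
#' @param id mutation identifiers.
#' @param score predictor scores (higher = predicted more stabilizing).
#' @param dtm melting-temperature changes (degrees C), `NA` = untested.
#' @param threshold stabilizing threshold (default 0, strict).
#' @return data.frame of class `labeled_ranking`, sorted by descending score.
#' @export
labeled_ranking <- function(id, score, dtm, threshold = 0) {
  stopifnot(length(id) == length(score), length(score) == length(dtm))
  label <- ifelse(is.na(dtm), "untested",
                  ifelse(dtm > threshold, "pos", "neg"))
  out <- data.frame(id = as.character(id), score = score, dtm = dtm,
                    label = label, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$id), ]
  rownames(out) <- NULL
  class(out) <- c("labeled_ranking", "data.frame")
  out
}

# Core step construction shared by the plain and weighted ROC: processes
# tied scores as one block (diagonal segment), with per-positive weights.
#' @keywords internal
.roc_points <- function(score, is_pos, pos_weight = NULL) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs at least one positive and one negative")
  if (is.null(pos_weight)) pos_weight <- rep(1, length(score))
  w_tot <- sum(pos_weight[is_pos])
  ord <- order(-score)
  score <- score[ord]; is_pos <- is_pos[ord]; pw <- pos_weight[ord]
  fpr <- 0; tpr <- 0
  pts <- matrix(c(0, 0), ncol = 2)
  for (s in unique(score)) {
    blk <- which(score == s)
    tpr <- tpr + sum(pw[blk][is_pos[blk]]) / w_tot
    fpr <- fpr + sum(!is_pos[blk]) / n_neg
    pts <- rbind(pts, c(fpr, tpr))
  }
  colnames(pts) <- c("fpr", "tpr")
  pts
}

#' @keywords internal
.trapezoid_auc <- function(pts) {
  sum(diff(pts[, "fpr"]) * (utils::head(pts[, "tpr"], -1) +
                              utils::tail(pts[, "tpr"], -1)) / 2)
}

#' ROC curve and AUC of a ranking
#'
#' Standard ROC by descending score, ties processed as one block (diagonal
#' segment), AUC by the trapezoid rule.  Untested entries are not allowed
#' here; see [auc_bounds()] and [fraction_sweep()] for those.
#'
#' @param ranking a `labeled_ranking` (without untested rows).
#' @return list of class `roc_result`: `points` (fpr/tpr matrix), `auc`,
#'   `weighted = FALSE`.
#' @export
roc <- function(ranking) {
  r <- ranking[ranking$label != "untested", ]
  pts <- .roc_points(r$score, r$label == "pos")
  structure(list(points = pts, auc = .trapezoid_auc(pts), weighted = FALSE),
            class = "roc_result")
}

#' Stability-weighted ROC curve and AUC
#'
#' Each stabilizing mutation's true-positive-rate step is its share of the
#' total melting-temperature increase (`dtm_i / sum(dtm_pos)`); negatives
#' step uniformly (true negatives are not scaled).  Rewards predictors that
#' put highly stabilizing mutations first.
#'
#' @param ranking a `labeled_ranking`; every positive needs a `dtm`.
#' @return `roc_result` with `weighted = TRUE`.
#' @export
weighted_roc <- function(ranking) {
  r <- ranking[ranking$label != "untested", ]
  is_pos <- r$label == "pos"
  if (any(is_pos & is.na(r$dtm)))
    stop("weighted ROC requires a dtm for every positive")
  w <- ifelse(is_pos, r$dtm, 0)
  pts <- .roc_points(r$score, is_pos, pos_weight = w)
  structure(list(points = pts, auc = .trapezoid_auc(pts), weighted = TRUE),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<%s ROC: AUC = %.4f, %d points>\n",
              if (x$weighted) "weighted" else "plain",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' Combinatorial AUC bounds over untested mutations
#'
#' For every assumed number `k = 0..U` of truly stabilizing mutations among
#' the `U` untested ones, the upper bound flips the `k` best-ranked untested
#' to positive and the lower bound the `k` worst-ranked; untested mutations
#' not flipped count as negatives.  Global bounds are the max/min over `k`.
#'
#' @param ranking a `labeled_ranking` with at least one untested row.
#' @param dtm_flip `dtm` assigned to flipped positives in the weighted case;
#'   `NULL` (default) computes unweighted AUCs.
#' @return list with `per_k` (data.frame k, lower, upper), `lower`, `upper`.
#' @export
auc_bounds <- function(ranking, dtm_flip = NULL) {
  unk <- which(ranking$label == "untested")
  U <- length(unk)
  auc_with <- function(flip_idx) {
    lab <- ranking$label
    lab[unk] <- "neg"
    lab[flip_idx] <- "pos"
    pts <- .roc_points(ranking$score, lab == "pos")
    .trapezoid_auc(pts)
  }
  ks <- 0:U
  # untested are already in rank order since the ranking is score-sorted
  upper <- vapply(ks, function(k) auc_with(unk[seq_len(k)]), numeric(1))
  lower <- vapply(ks, function(k)
    auc_with(rev(unk)[seq_len(k)]), numeric(1))
  list(per_k = data.frame(k = ks, lower = lower, upper = upper),
       lower = min(lower, upper), upper = max(lower, upper))
}

#' Mean AUC as a function of the stabilizing fraction among untested
#'
#' For each fraction `f`, `round(f * U)` of the `U` untested mutations are
#' sampled uniformly as positives (the rest count negative), the AUC is
#' computed, and the mean over `reps` draws reported.
#'
#' @param ranking a `labeled_ranking` with untested rows.
#' @param fractions numeric fractions in \[0, 1\].
#' @param reps random draws per fraction (default 1000).
#' @param seed integer seed; results are reproducible.
#' @return data.frame with `fraction`, `mean_auc`.
#' @export
fraction_sweep <- function(ranking, fractions, reps = 1000, seed = 1L) {
  unk <- which(ranking$label == "untested")
  U <- length(unk)
  if (U == 0) stop("no untested mutations to sweep over")
  set.seed(seed)
  mean_auc <- vapply(fractions, function(f) {
    k <- round(f * U)
    lab0 <- ranking$label
    lab0[unk] <- "neg"
    if (k == 0) {
      pts <- .roc_points(ranking$score, lab0 == "pos")
      return(.trapezoid_auc(pts))
    }
    mean(vapply(seq_len(reps), function(r) {
      lab <- lab0
      lab[unk[sample.int(U, k)]] <- "pos"
      .trapezoid_auc(.roc_points(ranking$score, lab == "pos"))
    }, numeric(1)))
  }, numeric(1))
  data.frame(fraction = fractions, mean_auc = mean_auc)
}
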