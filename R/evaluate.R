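# Cell-level evaluation. Detection quality is the fraction of ground-truth
# cells matched one-to-one by predicted patches under an
# intersection-over-union criterion — the standard cell-detection
# convention; both the threshold and the matching are parameters so
# alternative readings can be tested.

#' Match predicted patches to ground-truth cells
#'
#' Computes all pairwise overlap fractions `|pred n gt| / |pred u gt|`
#' (IoU), then matches greedily by descending overlap, one-to-one; pairs
#' below `min_overlap` stay unmatched. Cell-level accuracy is the matched
#' fraction of ground-truth cells; precision is the matched fraction of
#' predictions.
#'
#' @param pred Integer label matrix of predicted patches.
#' @param gt Integer label matrix of ground-truth cells (same shape).
#' @param min_overlap Minimum IoU for a match.
#' @return An object of class `hma_match`: list with `n_gt`, `n_pred`,
#'   `matches` (data frame: gt, pred, overlap), `accuracy`, `precision`,
#'   `recall`.
#' @examples
#' gt <- matrix(0L, 16, 16); gt[2:6, 2:6] <- 1L; gt[10:14, 10:14] <- 2L
#' match_cells(gt, gt)$accuracy
#' @export
match_cells <- function(pred, gt, min_overlap = 0.5) {
  if (!all(dim(pred) == dim(gt)))
    stop("prediction and ground truth shapes differ", call. = FALSE)
  n_gt <- max(gt, 0L); n_pred <- max(pred, 0L)
  matches <- data.frame(gt = integer(0), pred = integer(0), overlap = numeric(0))
  if (n_gt > 0L && n_pred > 0L) {
    joint <- pred > 0L & gt > 0L
    if (any(joint)) {
      inter <- table(pred = pred[joint], gt = gt[joint])
      a_pred <- tabulate(pred[pred > 0L], nbins = n_pred)
      a_gt <- tabulate(gt[gt > 0L], nbins = n_gt)
      pi <- as.integer(rownames(inter))[row(inter)]
      gi <- as.integer(colnames(inter))[col(inter)]
      ov <- as.vector(inter) /
        (a_pred[as.integer(rownames(inter))[row(inter)]] +
         a_gt[as.integer(colnames(inter))[col(inter)]] - as.vector(inter))
      cand <- data.frame(pred = as.vector(pi), gt = as.vector(gi),
                         overlap = as.vector(ov))
      cand <- cand[cand$overlap >= min_overlap, , drop = FALSE]
      cand <- cand[order(-cand$overlap, cand$gt, cand$pred), , drop = FALSE]
      used_p <- logical(n_pred); used_g <- logical(n_gt)
      for (i in seq_len(nrow(cand))) {
        p <- cand$pred[i]; g <- cand$gt[i]
        if (!used_p[p] && !used_g[g]) {
          used_p[p] <- TRUE; used_g[g] <- TRUE
          matches <- rbind(matches,
                           data.frame(gt = g, pred = p, overlap = cand$overlap[i]))
        }
      }
    }
  }
  m <- nrow(matches)
  structure(list(n_gt = n_gt, n_pred = n_pred, matches = matches,
                 accuracy = if (n_gt > 0) m / n_gt else NA_real_,
                 precision = if (n_pred > 0) m / n_pred else NA_real_,
                 recall = if (n_gt > 0) m / n_gt else NA_real_),
            class = "hma_match")
}

#' Average cell-level accuracy over a sequence
#'
#' @param reports List of `hma_match` reports (at least 1).
#' @return Unweighted mean of the per-frame accuracies.
#' @export
sequence_accuracy <- function(reports) {
  if (length(reports) < 1) stop("need at least one report", call. = FALSE)
  mean(vapply(reports, function(r) r$accuracy, 0))
}

#' @exportS3Method base::print
print.hma_match <- function(x, ...) {
  cat("cell-level match:", nrow(x$matches), "of", x$n_gt,
      "ground-truth cells matched by", x$n_pred, "predictions;",
      sprintf("accuracy %.3f, precision %.3f\n", x$accuracy, x$precision))
  invisible(x)
}
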