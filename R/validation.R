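# Decoy-based FDR control and the relaxed-specificity ROC for cross-link
# site assignment.

#' Score threshold at a target false discovery rate
#'
#' Targets and decoys come from separate searches of the forward and the
#' reversed-sequence database. The FDR at threshold t is
#' `#decoys >= t / max(1, #targets >= t)`; the function returns the smallest
#' threshold achieving `FDR <= alpha`, together with monotone q-values for
#' the target scores (cumulative minimum over decreasing thresholds, so
#' q never increases with score).
#'
#' @param targets Numeric target scores.
#' @param decoys Numeric decoy scores.
#' @param alpha Accepted FDR, in (0, 1) (default 0.05).
#' @return List of class `xl_fdr`: `threshold` (`Inf`, with a warning, when
#'   no threshold reaches `alpha`), `alpha`, `n_accepted`, and a data.frame
#'   `table` of candidate thresholds with `fdr` and `qvalue`.
#' @export
#' @examples
#' fdr_threshold(c(5, 4, 3), 4.5, alpha = 0.05)$threshold  # 5
fdr_threshold <- function(targets, decoys, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (!length(targets)) {
    warning("no target scores")
    return(structure(list(threshold = Inf, alpha = alpha, n_accepted = 0L,
                          table = data.frame(threshold = numeric(0),
                                             fdr = numeric(0),
                                             qvalue = numeric(0))),
                     class = "xl_fdr"))
  }
  thr <- sort(unique(c(targets, decoys)))
  n_t <- vapply(thr, function(t) sum(targets >= t), 0L)
  n_d <- vapply(thr, function(t) sum(decoys >= t), 0L)
  fdr <- n_d / pmax(1L, n_t)
  # q-value at threshold t: best FDR achievable at any threshold >= t
  qvalue <- rev(cummin(rev(fdr)))
  ok <- which(fdr <= alpha)
  if (!length(ok)) {
    warning(sprintf("no threshold achieves FDR <= %g", alpha))
    threshold <- Inf; n_accepted <- 0L
  } else {
    threshold <- thr[ok[1L]]
    n_accepted <- n_t[ok[1L]]
  }
  structure(list(threshold = threshold, alpha = alpha,
                 n_accepted = n_accepted,
                 table = data.frame(threshold = thr, fdr = fdr,
                                    qvalue = qvalue)),
            class = "xl_fdr")
}

#' @export
print.xl_fdr <- function(x, ...) {
  cat(sprintf("<FDR> threshold %s at alpha %.3g (%d accepted)\n",
              format(x$threshold), x$alpha, x$n_accepted))
  invisible(x)
}

#' Relaxed-specificity ROC curve for cross-link site assignment
#'
#' Validation of site localization with a residue-specific cross-linker
#' searched as if non-specific: localized sites inside the known
#' specificity (e.g. Lys for an amine-reactive linker) are positives, sites
#' outside it false positives. The ROC sweeps the score threshold; ties are
#' grouped, which yields the standard half-credit diagonal segments, and the
#' AUC is computed by the trapezoid rule (equal to the Mann-Whitney
#' pair-comparison statistic with half weight for ties).
#'
#' @param scores Numeric match scores.
#' @param within_specificity Logical, same length: `TRUE` when the localized
#'   site is a known-reactive residue.
#' @return List of class `xl_roc`: `points` (data.frame `fpr`, `tpr`, from
#'   (0,0) to (1,1)) and `auc`.
#' @export
relaxed_specificity_roc <- function(scores, within_specificity) {
  if (length(scores) != length(within_specificity))
    stop("'scores' and 'within_specificity' lengths differ")
  pos <- as.logical(within_specificity)
  if (anyNA(pos) || anyNA(scores)) stop("missing values not allowed")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined: need both within- and outside-specificity sites")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  grp <- cumsum(!duplicated(s))      # tie groups share one ROC vertex
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "xl_roc")
}

#' @export
print.xl_roc <- function(x, ...) {
  cat(sprintf("<ROC> AUC %.4f (%d positives, %d negatives, %d vertices)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @export
plot.xl_roc <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate (site outside specificity)",
       ylab = "True positive rate (site within specificity)", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.4f", x$auc))
  invisible(x)
}

#' Flag localized sites as within a cross-linker's known specificity
#'
#' Helper for the relaxed-specificity analysis: given result rows carrying
#' the localized residue on the relaxed (wildcard) end, returns whether each
#' site is a residue the specific reagent could actually have targeted.
#'
#' @param sequence Chain sequence of each identification.
#' @param site Localized 1-based position on that chain (0 = protein
#'   N-terminus token).
#' @param residues Residues of the true specificity (default `"K"`).
#' @param nterm Does the true specificity include the protein N-terminus?
#' @param start Protein coordinate of the chain's first residue (needed for
#'   `nterm`).
#' @return Logical vector.
#' @export
site_within_specificity <- function(sequence, site, residues = "K",
                                    nterm = TRUE, start = 1L) {
  mapply(function(sq, st, s0) {
    if (st == 0L) return(nterm && s0 == 1L)
    substr(sq, st, st) %in% residues
  }, sequence, site, rep_len(start, length(sequence)), USE.NAMES = FALSE)
}
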