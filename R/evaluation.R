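#' Confusion counts between an inferred and a gold-standard network
#'
#' Counts over all `choose(n, 2)` unordered gene pairs: present in both
#' networks = TP, inferred only = FP, absent from both = TN, gold only = FN.
#' Both networks must share the same gene universe.
#'
#' @param inferred,gold [gene_network()] objects over the same genes.
#' @return named integer vector `c(TP, FP, TN, FN)` of class
#'   `"confusion_counts"`; the four counts always sum to `choose(n, 2)`.
#' @export
confusion <- function(inferred, gold) {
  stopifnot(inherits(inferred, "gene_network"), inherits(gold, "gene_network"))
  if (!setequal(inferred$gene_ids, gold$gene_ids))
    stop("networks are defined over different gene sets")
  g <- lex_sort(inferred$gene_ids)
  ai <- inferred$adjacency[g, g][upper.tri(diag(length(g)))]
  ag <- gold$adjacency[g, g][upper.tri(diag(length(g)))]
  out <- c(TP = sum(ai & ag), FP = sum(ai & !ag),
           TN = sum(!ai & !ag), FN = sum(!ai & ag))
  structure(as.integer(out), names = names(out), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' Binary-classification metrics of network recovery
#'
#' Standard confusion-matrix summaries:
#' \deqn{TPR = TP/(TP+FN),\quad FPR = FP/(FP+TN),\quad PPV = TP/(TP+FP),}
#' \deqn{ACC = (TP+TN)/(TP+FP+TN+FN),\quad
#'       MCC = \frac{TP \cdot TN - FP \cdot FN}
#'                  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' A metric whose denominator is zero is reported as `NA` (undefined), except
#' MCC, which is set to 0 by the usual convention when any factor of its
#' denominator vanishes (a message notes this).
#'
#' @param counts a `confusion_counts` vector (or any named numeric with
#'   entries TP, FP, TN, FN).
#' @return named numeric vector `c(TPR, FPR, PPV, ACC, MCC)`.
#' @examples
#' grn_metrics(c(TP = 9, FP = 1, TN = 34, FN = 1))
#' @export
grn_metrics <- function(counts) {
  cc <- as.numeric(counts[c("TP", "FP", "TN", "FN")])
  if (any(is.na(cc)) || any(cc < 0)) stop("counts must contain TP, FP, TN, FN >= 0")
  TP <- cc[1]; FP <- cc[2]; TN <- cc[3]; FN <- cc[4]
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  fac <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc <- if (any(fac == 0)) {
    message("MCC denominator has a zero factor; reporting 0 by convention")
    0
  } else (TP * TN - FP * FN) / sqrt(prod(fac))
  c(TPR = rat(TP, TP + FN), FPR = rat(FP, FP + TN), PPV = rat(TP, TP + FP),
    ACC = rat(TP + TN, TP + FP + TN + FN), MCC = mcc)
}

#' ROC curve by threshold sweep
#'
#' Re-runs the full inference ([rpni()]) at each threshold in `thetas`,
#' scores the resulting binary network against the gold standard, and
#' assembles the (FPR, TPR) operating points into a ROC curve anchored at
#' (0, 0) and (1, 1).  This mirrors the method's own evaluation protocol --
#' the curve traces the algorithm's binary decisions as `theta` ranges from
#' near 0 to infinity -- and is not a ranking ROC (see [ranking_auc()] for
#' that, separately labeled, variant).
#'
#' AUC is computed by the trapezoid rule over unique FPR values, keeping the
#' maximal TPR per FPR.
#'
#' @param expr expression data passed to [rpni()].
#' @param gold gold-standard [gene_network()].
#' @param thetas numeric vector of thresholds (`>= 0`).
#' @param ... further arguments to [rpni()] (e.g. `fallback`, `measure`).
#' @return object of class `"rpni_roc"`: list with `points` (data frame
#'   `theta`, `FPR`, `TPR`, threshold points only), `curve` (with anchors),
#'   and `auc`.
#' @export
roc_sweep <- function(expr, gold, thetas, ...) {
  if (!length(thetas) || any(thetas < 0)) stop("'thetas' must be nonnegative and nonempty")
  pts <- lapply(thetas, function(th) {
    fit <- tryCatch(rpni(expr, theta = th, ...), error = function(e) {
      warning(sprintf("inference failed at theta = %g: %s", th,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(fit)) return(NULL)
    # only FPR/TPR are consumed: the MCC zero-factor note is irrelevant here
    m <- suppressMessages(grn_metrics(confusion(fit$network, gold)))
    data.frame(theta = th, FPR = m[["FPR"]], TPR = m[["TPR"]])
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || !nrow(pts)) stop("no threshold produced a usable operating point")
  roc_from_points(pts)
}

# assemble a ROC object from raw operating points (theta, FPR, TPR)
roc_from_points <- function(pts) {
  pts <- pts[stats::complete.cases(pts[, c("FPR", "TPR")]), , drop = FALSE]
  curve <- rbind(data.frame(theta = Inf, FPR = 0, TPR = 0),
                 pts[, c("theta", "FPR", "TPR")],
                 data.frame(theta = 0, FPR = 1, TPR = 1))
  curve <- curve[order(curve$FPR, curve$TPR), ]
  structure(list(points = pts, curve = curve, auc = trapezoid_auc(curve)),
            class = "rpni_roc")
}

# trapezoid AUC over unique FPR values, max TPR per FPR
trapezoid_auc <- function(curve) {
  fpr <- curve$FPR; tpr <- curve$TPR
  ufpr <- sort(unique(fpr))
  utpr <- vapply(ufpr, function(f) max(tpr[fpr == f]), numeric(1))
  sum(diff(ufpr) * (utpr[-1] + utpr[-length(utpr)]) / 2)
}

#' @export
print.rpni_roc <- function(x, ...) {
  cat(sprintf("ROC (threshold sweep): %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.rpni_roc <- function(x, ...) {
  plot(x$curve$FPR, x$curve$TPR, type = "b", pch = 16,
       xlab = "FPR", ylab = "TPR", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Ranking AUC over pairwise mutual information
#'
#' A conventional ranking ROC/AUC in which all gene pairs are ordered by
#' their marginal Gaussian mutual information and swept as a score.  This is
#' *not* the package's evaluation protocol (which sweeps the algorithm's
#' decision threshold, [roc_sweep()]); it is provided as a separately labeled
#' baseline.
#'
#' @inheritParams roc_sweep
#' @return numeric AUC in `[0, 1]`.
#' @export
ranking_auc <- function(expr, gold) {
  em <- as_expression_matrix(expr)
  S <- gene_covariance(em)
  prs <- gene_pairs(gene_ids(em))
  score <- mapply(function(a, b) mi_cov(S, a, b), prs$gene_a, prs$gene_b)
  truth <- mapply(function(a, b) gold$adjacency[a, b], prs$gene_a, prs$gene_b)
  if (!any(truth) || all(truth)) stop("gold standard has no pairs of both classes")
  # probability a random true pair outranks a random false pair (ties = 1/2)
  r <- rank(score)
  (sum(r[truth]) - sum(truth) * (sum(truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
}
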