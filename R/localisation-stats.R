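#' Distinguishability of resected from spared tissue (D_RS)
#'
#' Normalised Mann-Whitney U statistic over regional abnormality scores:
#' the probability that a randomly chosen spared region is more abnormal
#' than a randomly chosen resected one, counting ties as 1/2. A value of 0
#' means the largest abnormalities all lie in the resected regions (the
#' favourable case for surgery); 1 means they were all spared.
#'
#' @param scores Numeric abnormality scores, one per region (larger = more
#'   abnormal).
#' @param resected Logical flags, `TRUE` for resected regions.
#' @return D_RS in [0, 1].
#' @export
compute_drs <- function(scores, resected) {
  if (length(scores) != length(resected))
    stop("scores and resected flags differ in length")
  ok <- is.finite(scores) & !is.na(resected)
  scores <- scores[ok]
  resected <- as.logical(resected[ok])
  n_r <- sum(resected)
  n_s <- sum(!resected)
  if (n_r == 0L) stop("no resected regions with finite scores")
  if (n_s == 0L) stop("no spared regions with finite scores")
  r <- rank(scores)
  # pairs (spared, resected) with spared > resected, ties counted 1/2
  u_s <- sum(r[!resected]) - n_s * (n_s + 1) / 2
  u_s / (n_r * n_s)
}

#' Linear-SVM separability of resected and spared abnormalities
#'
#' Fits a linear-kernel support vector machine (large fixed penalty
#' C = 1e4, unscaled features) to the per-region points
#' (iEEG abnormality B, connectivity abnormality score), labelled resected
#' or spared. A patient's abnormality space is "separable" when the
#' trained classifier misclassifies no region. The maximal-abnormality
#' point is the componentwise maximum over the patient's regions; when the
#' space is separable, `maximal_resected` records whether that corner
#' falls in the resected zone.
#'
#' @param ieeg_b Numeric iEEG abnormalities (implanted regions only).
#' @param conn Numeric connectivity abnormality scores, same regions.
#' @param resected Logical resection flags.
#' @param cost SVM penalty (default 1e4, near-hard-margin).
#' @return Object of class `svm_separation`: `evaluable`, `separable`,
#'   `maximal_resected` (`NA` unless separable), `maximal_point`,
#'   `boundary` (weights `w` and offset `b` of w.x + b = 0), `zones`
#'   (per-region predicted class).
#' @export
svm_separation <- function(ieeg_b, conn, resected, cost = 1e4) {
  resected <- as.logical(resected)
  ok <- is.finite(ieeg_b) & is.finite(conn) & !is.na(resected)
  x <- cbind(ieeg = ieeg_b[ok], conn = conn[ok])
  y <- factor(ifelse(resected[ok], "resected", "spared"),
              levels = c("resected", "spared"))
  if (min(table(y)) < 2L)
    return(structure(list(evaluable = FALSE, separable = NA,
                          maximal_resected = NA, maximal_point = NULL,
                          boundary = NULL, zones = NULL),
                     class = "svm_separation"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  pred <- stats::predict(fit, x)
  separable <- all(pred == y)
  maximal <- c(ieeg = max(x[, 1]), conn = max(x[, 2]))
  max_res <- if (separable)
    unname(stats::predict(fit, rbind(maximal)) == "resected") else NA
  w <- drop(t(fit$coefs) %*% fit$SV)
  structure(list(evaluable = TRUE, separable = separable,
                 maximal_resected = max_res, maximal_point = maximal,
                 boundary = list(w = w, b = -fit$rho),
                 zones = as.character(pred)),
            class = "svm_separation")
}

#' Chi-squared association test for a 2x2 table
#'
#' Pearson chi-squared with Yates continuity correction (the default for
#' 2x2 tables in base R), 1 degree of freedom.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List: `statistic`, `p.value`, `df`.
#' @export
association_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("a 2x2 count table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in the 2x2 table")
  ct <- stats::chisq.test(table, correct = TRUE)
  list(statistic = unname(ct$statistic), p.value = ct$p.value,
       df = unname(ct$parameter))
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = ad/(bc) for the table ((a,b),(c,d)), with the Woolf (log-normal)
#' interval exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). Any zero cell
#' triggers the Haldane-Anscombe correction (0.5 added to every cell),
#' flagged in the result.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `or`, `ci` (length 2), `conf_level`, `haldane`.
#' @export
odds_ratio <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("a 2x2 count table is required")
  if (any(table < 0)) stop("counts must be non-negative")
  haldane <- any(table == 0)
  if (haldane) table <- table + 0.5
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se),
       conf_level = conf_level, haldane = haldane)
}

#' Outcome discrimination of D_RS: ROC AUC and Mann-Whitney test
#'
#' AUC is the probability that a randomly chosen poor-outcome patient has
#' a higher D_RS than a randomly chosen good-outcome patient (ties 1/2):
#' higher D_RS (abnormalities spared) should predict continued seizures.
#' The p-value comes from the two-sided Mann-Whitney U test by default.
#'
#' @param drs Numeric D_RS values.
#' @param good_outcome Logical, `TRUE` = seizure-free (ILAE 1-2).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return List: `auc`, `p.value`, `n_good`, `n_poor`.
#' @export
outcome_auc <- function(drs, good_outcome, alternative = "two.sided") {
  good_outcome <- as.logical(good_outcome)
  ok <- is.finite(drs) & !is.na(good_outcome)
  drs <- drs[ok]; good_outcome <- good_outcome[ok]
  n_g <- sum(good_outcome); n_p <- sum(!good_outcome)
  if (n_g == 0L || n_p == 0L)
    stop("both outcome groups must be non-empty")
  r <- rank(drs)
  auc <- (sum(r[!good_outcome]) - n_p * (n_p + 1) / 2) / (n_g * n_p)
  p <- suppressWarnings(
    stats::wilcox.test(drs[!good_outcome], drs[good_outcome],
                       alternative = alternative)$p.value)
  list(auc = auc, p.value = p, n_good = n_g, n_poor = n_p)
}

# -- constrained depth-two decision tree --------------------------------------

# midpoints between consecutive sorted unique values, with the local gap
# (used as the margin of a cut placed at that midpoint)
cut_candidates <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L)
    return(data.frame(threshold = numeric(0), gap = numeric(0)))
  data.frame(threshold = (u[-1] + u[-length(u)]) / 2, gap = diff(u))
}

majority_label <- function(good) {
  n_g <- sum(good); n_p <- sum(!good)
  if (n_g == n_p) TRUE else n_g > n_p   # ties labelled good (seizure-free)
}

tree_predict_raw <- function(tree, ieeg, conn) {
  root <- if (tree$root_var == "ieeg") ieeg else conn
  second <- if (tree$root_var == "ieeg") conn else ieeg
  in_split <- if (tree$split_child == "low") root <= tree$root_threshold
              else root > tree$root_threshold
  pred <- rep(tree$leaf_other, length(root))
  pred[in_split & second <= tree$second_threshold] <- tree$leaf_split_low
  pred[in_split & second > tree$second_threshold] <- tree$leaf_split_high
  pred
}

#' Predict outcomes from a constrained decision tree
#' @param object A `constrained_tree` from [constrained_decision_tree()].
#' @param ieeg_drs,conn_drs New patients' D_RS values.
#' @param ... Unused.
#' @return Logical vector of predicted good-outcome flags.
#' @export
predict.constrained_tree <- function(object, ieeg_drs, conn_drs, ...) {
  tree_predict_raw(object, ieeg_drs, conn_drs)
}

#' Constrained depth-two decision tree on paired D_RS values
#'
#' Classifies patients as seizure-free or not from their two D_RS values
#' using a tree constrained to exactly one cut per modality: a root cut on
#' one modality and a second cut on the other modality inside one of the
#' root's children (the other child is a leaf). All candidate cut
#' placements (midpoints between consecutive sorted unique values), both
#' root modalities and both child positions are searched exhaustively;
#' leaves take the majority class of their training points. The tree with
#' maximal training accuracy wins; ties are broken by the larger minimum
#' margin at the chosen cuts, then by an iEEG root, then by lower
#' thresholds.
#'
#' @param ieeg_drs,conn_drs Numeric D_RS values per patient.
#' @param good_outcome Logical, `TRUE` = seizure-free.
#' @return Object of class `constrained_tree`: the cut structure
#'   (`root_var`, `root_threshold`, `split_child`, `second_threshold`,
#'   leaf labels), `accuracy`, `n_correct`, `n`.
#' @export
constrained_decision_tree <- function(ieeg_drs, conn_drs, good_outcome) {
  good <- as.logical(good_outcome)
  n <- length(good)
  stopifnot(length(ieeg_drs) == n, length(conn_drs) == n)
  if (length(unique(good)) == 1L) {
    warning("single-class input; returning a trivial tree")
    tree <- structure(list(root_var = "ieeg", root_threshold = Inf,
                           split_child = "low", second_threshold = Inf,
                           leaf_split_low = good[1], leaf_split_high = good[1],
                           leaf_other = good[1],
                           accuracy = 1, n_correct = n, n = n),
                      class = "constrained_tree")
    return(tree)
  }
  vars <- list(ieeg = ieeg_drs, conn = conn_drs)
  best <- NULL
  for (root_var in c("ieeg", "conn")) {
    root <- vars[[root_var]]
    second <- vars[[setdiff(c("ieeg", "conn"), root_var)]]
    c1 <- cut_candidates(root)
    c2 <- cut_candidates(second)
    if (nrow(c1) == 0L || nrow(c2) == 0L) next
    for (i in seq_len(nrow(c1))) {
      t1 <- c1$threshold[i]
      side_low <- root <= t1
      for (child in c("low", "high")) {
        in_split <- if (child == "low") side_low else !side_low
        if (!any(in_split) || all(in_split)) next
        leaf_other <- majority_label(good[!in_split])
        for (k in seq_len(nrow(c2))) {
          t2 <- c2$threshold[k]
          lo <- in_split & second <= t2
          hi <- in_split & second > t2
          l_lo <- if (any(lo)) majority_label(good[lo]) else TRUE
          l_hi <- if (any(hi)) majority_label(good[hi]) else TRUE
          correct <- sum(good[lo] == l_lo) + sum(good[hi] == l_hi) +
            sum(good[!in_split] == leaf_other)
          cand <- list(root_var = root_var, root_threshold = t1,
                       split_child = child, second_threshold = t2,
                       leaf_split_low = l_lo, leaf_split_high = l_hi,
                       leaf_other = leaf_other,
                       n_correct = correct,
                       margin = min(c1$gap[i], c2$gap[k]))
          if (is.null(best) || tree_better(cand, best)) best <- cand
        }
      }
    }
  }
  best$accuracy <- best$n_correct / n
  best$n <- n
  best$margin <- NULL
  class(best) <- "constrained_tree"
  best
}

# deterministic preference order for tree candidates
tree_better <- function(a, b) {
  if (a$n_correct != b$n_correct) return(a$n_correct > b$n_correct)
  if (!isTRUE(all.equal(a$margin, b$margin))) return(a$margin > b$margin)
  if (a$root_var != b$root_var) return(a$root_var == "ieeg")
  if (a$root_threshold != b$root_threshold)
    return(a$root_threshold < b$root_threshold)
  a$second_threshold < b$second_threshold
}

#' @export
print.constrained_tree <- function(x, ...) {
  cat(sprintf("<constrained_tree> root: %s <= %.4g; second cut (%s child): %s <= %.4g; training accuracy %.3f (%d/%d)\n",
              x$root_var, x$root_threshold, x$split_child,
              setdiff(c("ieeg", "conn"), x$root_var), x$second_threshold,
              x$accuracy, x$n_correct, x$n))
  invisible(x)
}

#' Leave-one-out cross-validation of the constrained decision tree
#'
#' Each patient is predicted by a tree fitted on the remaining n-1.
#' Sensitivity is the correctly-predicted fraction of the good-outcome
#' (seizure-free) class; specificity that of the poor-outcome class. Folds
#' whose training set collapses to a single class predict the majority
#' class and are flagged.
#'
#' @param ieeg_drs,conn_drs,good_outcome As in
#'   [constrained_decision_tree()]; n >= 3.
#' @return List: `accuracy`, `sensitivity`, `specificity`, `predictions`
#'   (logical per patient), `n_degenerate_folds`.
#' @export
loocv_evaluate <- function(ieeg_drs, conn_drs, good_outcome) {
  good <- as.logical(good_outcome)
  n <- length(good)
  if (n < 3L) stop("leave-one-out requires n >= 3")
  preds <- logical(n)
  degen <- 0L
  for (i in seq_len(n)) {
    tr_good <- good[-i]
    if (length(unique(tr_good)) == 1L) {
      preds[i] <- tr_good[1]
      degen <- degen + 1L
      next
    }
    tree <- suppressWarnings(
      constrained_decision_tree(ieeg_drs[-i], conn_drs[-i], tr_good))
    preds[i] <- tree_predict_raw(tree, ieeg_drs[i], conn_drs[i])
  }
  list(accuracy = mean(preds == good),
       sensitivity = mean(preds[good]),
       specificity = mean(!preds[!good]),
       predictions = preds,
       n_degenerate_folds = degen)
}

#' Correlation between the two abnormality modalities
#'
#' Pearson (default) or Spearman correlation with its two-sided p-value,
#' for paired regional abnormalities within a patient or paired D_RS
#' values across a cohort.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `r`, `p.value`, `n`, `method`.
#' @export
modality_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("correlation requires >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one modality; correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x),
       method = method)
}
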