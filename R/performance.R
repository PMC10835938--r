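#' Orient biomarker scores for a classification task
#'
#' Each phenotype-vs-gNM task declares whether a low or a high biomarker
#' value indicates the target class (e.g. solanidine concentration is high in
#' impaired metabolizers but low in ultrarapid ones; metabolic ratios the
#' reverse). Orientation is made explicit rather than inferred, and `"low"`
#' simply negates the scores so that higher always means "more likely target"
#' downstream.
#'
#' @param scores Numeric biomarker values.
#' @param orientation `"high"` (default) if large scores indicate the target
#'   class, `"low"` if small scores do.
#' @return Oriented numeric scores.
#' @export
orient_scores <- function(scores, orientation = c("high", "low")) {
  orientation <- match.arg(orientation)
  if (orientation == "low") -scores else scores
}

check_score_labels <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (any(is.na(scores)) || any(is.na(labels)))
    stop("scores and labels must not contain missing values")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L)
    stop("both classes must be present (>= 1 positive and >= 1 negative)")
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability that
#' a random positive outranks a random negative, with half-credit for ties.
#' Scores must already be oriented so that the target class scores higher
#' (see [orient_scores()]).
#'
#' @param scores Oriented numeric scores.
#' @param labels Binary labels (1 = target class, 0 = reference).
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.4), c(1, 1, 0, 0))  # 1
#' @export
auroc <- function(scores, labels) {
  check_score_labels(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision) and baseline
#'
#' Non-interpolated average precision: thresholds sweep the distinct score
#' values from high to low; at each threshold the precision is weighted by
#' the recall increment it delivers. The no-skill baseline of a PR curve is
#' the positive-class prevalence.
#'
#' @inheritParams auroc
#' @return List with `auprc` and `baseline` (= prevalence of positives).
#' @examples
#' aupr(c(3, 2, 1), c(1, 0, 1))$auprc
#' @export
aupr <- function(scores, labels) {
  check_score_labels(scores, labels)
  n_pos <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each distinct-threshold block boundary
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  list(auprc = sum(precision * d_recall),
       baseline = n_pos / length(labels))
}

#' Maximum F1 score over all thresholds
#'
#' For every distinct score threshold (predict target when score >=
#' threshold), computes the harmonic mean of precision and recall, and
#' returns the maximum.
#'
#' @inheritParams auroc
#' @return F1max in \[0, 1\].
#' @examples
#' f1_max(c(3, 2, 1), c(1, 0, 1))  # 0.8
#' @export
f1_max <- function(scores, labels) {
  check_score_labels(scores, labels)
  n_pos <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  max(f1)
}

stratified_indices <- function(labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  c(sample(pos, length(pos), replace = TRUE),
    sample(neg, length(neg), replace = TRUE))
}

#' Stratified bootstrap confidence interval for a performance metric
#'
#' Percentile 95% (by default) interval over class-stratified resamples:
#' positives and negatives are resampled separately so every resample retains
#' both classes and the original prevalence. Reproducible given `seed`.
#'
#' @inheritParams auroc
#' @param metric Function `(scores, labels) -> numeric(1)`, e.g. [auroc()],
#'   `function(s, l) aupr(s, l)$auprc`, or [f1_max()].
#' @param B Number of bootstrap iterations (default 1000).
#' @param level Confidence level, default 0.95.
#' @param seed Integer seed for the resampling.
#' @return List with `estimate`, `ci_low`, `ci_high`, `B`, and the bootstrap
#'   `replicates`.
#' @export
bootstrap_ci <- function(scores, labels, metric = auroc, B = 1000,
                         level = 0.95, seed = 1L) {
  check_score_labels(scores, labels)
  stopifnot(B >= 1)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- stratified_indices(labels)
    metric(scores[idx], labels[idx])
  }, numeric(1L))
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(estimate = metric(scores, labels),
       ci_low = qs[1L], ci_high = qs[2L], B = B, replicates = reps)
}

#' Evaluate a biomarker on a phenotype-vs-reference task
#'
#' One-call evaluation: orients the scores, computes AUROC, AUPRC (with its
#' prevalence baseline) and F1max, and attaches stratified-bootstrap
#' percentile CIs for each.
#'
#' @param scores Numeric biomarker values (unoriented).
#' @param labels Binary labels (1 = target class, 0 = reference).
#' @param orientation `"high"` or `"low"`; see [orient_scores()].
#' @param B Bootstrap iterations for the CIs (default 1000).
#' @param seed Seed for the bootstrap.
#' @return Object of class `biomarker_perf`.
#' @export
evaluate_biomarker <- function(scores, labels, orientation = c("high", "low"),
                               B = 1000, seed = 1L) {
  orientation <- match.arg(orientation)
  s <- orient_scores(scores, orientation)
  check_score_labels(s, labels)
  pr <- aupr(s, labels)
  res <- list(
    orientation = orientation,
    auroc = auroc(s, labels),
    auprc = pr$auprc,
    baseline_auprc = pr$baseline,
    f1_max = f1_max(s, labels),
    n_pos = sum(labels == 1), n_neg = sum(labels == 0),
    ci = list(
      auroc = bootstrap_ci(s, labels, auroc, B = B, seed = seed),
      auprc = bootstrap_ci(s, labels, function(x, y) aupr(x, y)$auprc,
                           B = B, seed = seed),
      f1_max = bootstrap_ci(s, labels, f1_max, B = B, seed = seed)
    ))
  structure(res, class = "biomarker_perf")
}

#' @export
print.biomarker_perf <- function(x, ...) {
  cat(sprintf("Biomarker performance (%d positives vs %d negatives, orientation: %s)\n",
              x$n_pos, x$n_neg, x$orientation))
  for (m in c("auroc", "auprc", "f1_max")) {
    ci <- x$ci[[m]]
    cat(sprintf("  %-7s %.3f (95%% CI %.3f, %.3f)\n",
                toupper(sub("_", "", m)), x[[m]], ci$ci_low, ci$ci_high))
  }
  cat(sprintf("  baseline AUPRC (prevalence) %.4f\n", x$baseline_auprc))
  invisible(x)
}

# DeLong covariance machinery for correlated AUROCs on the same subjects.
# Placement values: V10[i] = P(neg < pos_i) + 0.5 P(neg = pos_i), etc.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(p) (sum(p > neg) + 0.5 * sum(p == neg)) / n,
                numeric(1L))
  v01 <- vapply(neg, function(q) (sum(pos > q) + 0.5 * sum(pos == q)) / m,
                numeric(1L))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Compare a candidate biomarker to a reference biomarker
#'
#' Paired comparison of two biomarkers measured on the same subjects, e.g. a
#' metabolic ratio versus parent solanidine. The delta (candidate minus
#' reference) for AUROC, AUPRC and F1max is bootstrapped with shared
#' stratified resample indices (preserving the within-subject pairing); the
#' AUROC difference additionally gets a correlated-ROC (DeLong) z-test
#' p-value. AUPRC differences are judged by their bootstrap CI only.
#'
#' @param cand_scores,ref_scores Oriented scores of candidate and reference
#'   on the same subjects (orient each with [orient_scores()] first).
#' @param labels Shared binary labels.
#' @param B Bootstrap iterations, default 1000.
#' @param level Confidence level, default 0.95.
#' @param seed Seed for the shared resampling.
#' @return Object of class `biomarker_comparison`: per metric, `delta`,
#'   `ci_low`, `ci_high`; plus `p_value_auroc` from the DeLong test.
#' @export
compare_to_reference <- function(cand_scores, ref_scores, labels,
                                 B = 1000, level = 0.95, seed = 1L) {
  check_score_labels(cand_scores, labels)
  check_score_labels(ref_scores, labels)
  if (length(cand_scores) != length(ref_scores))
    stop("candidate and reference must score the same subjects")

  metrics <- list(auroc = auroc,
                  auprc = function(s, l) aupr(s, l)$auprc,
                  f1_max = f1_max)
  point <- lapply(metrics, function(f)
    f(cand_scores, labels) - f(ref_scores, labels))

  set.seed(seed)
  deltas <- matrix(NA_real_, nrow = B, ncol = length(metrics),
                   dimnames = list(NULL, names(metrics)))
  for (b in seq_len(B)) {
    idx <- stratified_indices(labels)
    lb <- labels[idx]
    for (m in names(metrics))
      deltas[b, m] <- metrics[[m]](cand_scores[idx], lb) -
        metrics[[m]](ref_scores[idx], lb)
  }
  alpha <- (1 - level) / 2
  ci <- apply(deltas, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)

  # DeLong correlated-AUROC test
  pa <- delong_placements(cand_scores, labels)
  pb <- delong_placements(ref_scores, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d_auc <- pa$auc - pb$auc
  p_auroc <- if (var_delta <= 0) {
    if (abs(d_auc) < .Machine$double.eps^0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(d_auc) / sqrt(var_delta))
  }

  structure(list(
    delta = point,
    ci = list(auroc = ci[, "auroc"], auprc = ci[, "auprc"],
              f1_max = ci[, "f1_max"]),
    p_value_auroc = p_auroc, B = B, level = level),
    class = "biomarker_comparison")
}

#' @export
print.biomarker_comparison <- function(x, ...) {
  cat("Paired biomarker comparison (candidate - reference)\n")
  for (m in names(x$delta))
    cat(sprintf("  %-7s delta %+0.3f (95%% CI %+0.3f, %+0.3f)\n",
                toupper(sub("_", "", m)), x$delta[[m]],
                x$ci[[m]][1L], x$ci[[m]][2L]))
  cat(sprintf("  AUROC difference p (correlated-ROC) = %.4g\n", x$p_value_auroc))
  invisible(x)
}
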