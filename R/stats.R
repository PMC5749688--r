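#' Unweighted average recall (UAR)
#'
#' Mean over classes of the class-specific recall (fraction of instances of
#' each class that were predicted correctly), expressed as a percentage.
#' Classes absent from the truth vector are excluded from the mean, so a
#' classifier is never rewarded or punished for classes it was never shown.
#' UAR is the standard performance measure for unbalanced decoding problems:
#' unlike raw accuracy it is invariant to class prevalence.
#'
#' @param truth vector of true class labels.
#' @param pred vector of predicted labels, same length.
#' @return UAR in percent (0-100).
#' @export
#' @examples
#' uar(c("a", "a", "b", "b"), c("a", "a", "b", "a"))  # (100 + 50)/2 = 75
uar <- function(truth, pred) {
  if (length(truth) == 0L) stop2("uar: empty input")
  if (length(truth) != length(pred))
    stop2("uar: truth and pred lengths differ (", length(truth), " vs ", length(pred), ")")
  truth <- as.character(truth)
  pred <- as.character(pred)
  classes <- unique(truth)
  recalls <- vapply(classes, function(cl) {
    idx <- truth == cl
    mean(pred[idx] == cl)
  }, numeric(1))
  100 * mean(recalls)
}

#' Empirical chance level for a finite test set
#'
#' The theoretical chance level 100/n_classes assumes an infinite test set.
#' For a finite set of `n_test` instances, the accuracy threshold that must be
#' exceeded for decoding to be significant at level `alpha` is obtained from
#' the exact binomial cumulative distribution: the smallest number of correct
#' answers k such that `pbinom(k, n_test, 1/n_classes) >= 1 - alpha`, returned
#' as a percentage `100 * k / n_test`. No normal approximation is used.
#'
#' @param n_test number of test instances (>= 1).
#' @param n_classes number of classes (>= 2).
#' @param alpha significance level, default 0.05.
#' @return threshold in percent; always > 100/n_classes for finite n_test and
#'   non-increasing in n_test.
#' @export
#' @examples
#' empirical_chance(20, 2)   # 70: at least 14/20 correct needed
#' empirical_chance(296, 2)  # ~54.73
empirical_chance <- function(n_test, n_classes, alpha = 0.05) {
  stopifnot(n_test >= 1, n_classes >= 2, alpha > 0, alpha < 1)
  p <- 1 / n_classes
  k <- qbinom(1 - alpha, n_test, p)  # smallest k with CDF >= 1 - alpha
  100 * k / n_test
}

#' One-sample one-tailed significance of a UAR distribution against chance
#'
#' Tests H1: mean(UAR) > chance with a one-sample Student's t-test over the
#' per-test-set UAR values (the 3 fold test sets plus their bootstrap
#' resamples). Degenerate zero-variance input is handled by convention:
#' p = 0 if the common value exceeds chance, else p = 1.
#'
#' Note the statistical caveat: bootstrap resamples of a fold's test set are
#' not independent observations, so this test is anticonservative. It is
#' provided because it is the conventional report for this protocol; the
#' empirical chance threshold itself is the more honest yardstick.
#'
#' @param uars numeric vector of UAR percentages (length >= 2).
#' @param chance chance level in percent to test against.
#' @return list with `t`, `df`, `p` and `stars` ("" / "*" / "**" / "***").
#' @export
significance <- function(uars, chance) {
  if (length(uars) < 2L) stop2("significance: need at least 2 UAR values")
  n <- length(uars)
  m <- mean(uars)
  s <- sd(uars)
  df <- n - 1L
  if (s == 0) {
    tstat <- if (m > chance) Inf else if (m < chance) -Inf else 0
    p <- if (m > chance) 0 else 1
  } else {
    tstat <- (m - chance) / (s / sqrt(n))
    p <- pt(tstat, df = df, lower.tail = FALSE)
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(t = tstat, df = df, p = p, stars = stars)
}

#' Build an evaluation report from per-test-set predictions
#'
#' Aggregates the (truth, prediction) pairs emitted by [run_sicv()] into the
#' standard report: per-set UAR, mean +/- sd, empirical chance (computed per
#' fold from that fold's original test-set size, then averaged across folds
#' for the headline; the pooled-size value is also reported), diffUAR = mean
#' UAR - chance, and one-tailed significance.
#'
#' @param evals list of evaluations, each a list with `truth`, `pred`, `fold`,
#'   and logical `bootstrap` (as produced by [run_sicv()]).
#' @param n_classes number of classes in the task.
#' @param alpha significance level for the chance threshold (default 0.05).
#' @return object of class `eval_report`.
#' @export
eval_report <- function(evals, n_classes, alpha = 0.05) {
  stopifnot(length(evals) >= 1)
  uars <- vapply(evals, function(e) uar(e$truth, e$pred), numeric(1))
  folds <- vapply(evals, function(e) e$fold, integer(1))
  boot <- vapply(evals, function(e) isTRUE(e$bootstrap), logical(1))
  # per-fold original test sizes (bootstrap sets share the fold's size)
  fold_ids <- sort(unique(folds))
  n_per_fold <- vapply(fold_ids, function(f) {
    length(evals[[which(folds == f & !boot)[1]]]$truth)
  }, integer(1))
  chance_per_fold <- vapply(n_per_fold, empirical_chance,
                            numeric(1), n_classes = n_classes, alpha = alpha)
  chance <- mean(chance_per_fold)
  chance_pooled <- empirical_chance(sum(n_per_fold), n_classes, alpha)
  sig <- significance(uars, chance)
  structure(list(
    uars = uars, fold = folds, bootstrap = boot,
    mean_uar = mean(uars), sd_uar = sd(uars),
    n_test_per_fold = n_per_fold, n_classes = n_classes, alpha = alpha,
    empirical_chance = chance, chance_per_fold = chance_per_fold,
    chance_pooled = chance_pooled,
    diff_uar = mean(uars) - chance,
    t = sig$t, df = sig$df, p = sig$p, stars = sig$stars
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d test sets (%d folds)\n",
              length(x$uars), length(x$n_test_per_fold)))
  cat(sprintf("  UAR: %.1f +/- %.1f %%\n", x$mean_uar, x$sd_uar))
  cat(sprintf("  empirical chance: %.1f %% (per-fold mean; pooled %.1f %%)\n",
              x$empirical_chance, x$chance_pooled))
  cat(sprintf("  diffUAR: %.1f %%  t(%d) = %.2f, one-tailed p = %.3g %s\n",
              x$diff_uar, x$df, x$t, x$p, x$stars))
  invisible(x)
}
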