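#' Read a one-to-one orthologue pair list
#'
#' TSV with header columns `idA`, `idB` and optionally `pct_identity`.
#' When the identity column is present, pairs at or above `max_identity`
#' percent sequence identity are excluded (trivially similar orthologues
#' would inflate benchmark performance). The pairing must be one-to-one:
#' no identifier may occur twice.
#'
#' @param path TSV path.
#' @param max_identity exclusion threshold in percent (default 80;
#'   retained pairs satisfy `pct_identity < max_identity`).
#' @return an `ortholog_set` data.frame with columns `idA`, `idB` (and
#'   `pct_identity` when supplied).
#' @export
read_orthologs <- function(path, max_identity = 80) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("idA", "idB") %in% names(df)))
    stop_gofunsim("ortholog file '%s' must have header columns idA, idB", path)
  n0 <- nrow(df)
  if ("pct_identity" %in% names(df)) {
    df <- df[df$pct_identity < max_identity, , drop = FALSE]
    if (nrow(df) < n0)
      log_msg("read_orthologs: excluded %d pair(s) with >= %g%% sequence identity",
              n0 - nrow(df), max_identity)
  }
  if (anyDuplicated(df$idA) || anyDuplicated(df$idB))
    stop_gofunsim("ortholog pairs are not one-to-one (duplicated identifiers)")
  rownames(df) <- NULL
  structure(df, class = c("ortholog_set", "data.frame"))
}

#' Derangement controls for an orthologue benchmark
#'
#' Builds the matched negative class: the second-organism column of the
#' case pairs is permuted without fixed points (a derangement), so every
#' control gene is used exactly once and no orthologous pair survives
#' intact. Sampling is by rejection (reshuffle until fixed-point-free;
#' about e = 2.72 shuffles expected).
#'
#' @param cases an `ortholog_set` or data.frame with `idA`, `idB`;
#'   at least two pairs (no derangement exists for one).
#' @param seed optional integer seed.
#' @return data.frame with columns `idA`, `idB` holding the control pairs.
#' @export
make_controls <- function(cases, seed = NULL) {
  n <- nrow(cases)
  if (n < 2)
    stop_gofunsim("cannot build controls: no derangement exists for %d pair(s)", n)
  if (!is.null(seed)) set.seed(seed)
  perm <- derangement(n)
  data.frame(idA = cases$idA, idB = cases$idB[perm])
}

derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Optimal classification threshold and error rate
#'
#' Scans candidate thresholds h (midpoints of adjacent distinct observed
#' scores plus -Inf/+Inf sentinels), classifies a pair as orthologous
#' when its score >= h, and returns the threshold minimizing the error
#' rate (FP + FN) / (TP + FP + TN + FN). Midpoints are exact for the
#' step-constant empirical error curve. Ties in error are broken toward
#' the smallest h. On balanced classes the optimum never exceeds 0.5
#' (either extreme sentinel already achieves it).
#'
#' @param cases numeric scores of the positive class (orthologues).
#' @param controls numeric scores of the negative class.
#' @return list with `h_star`, `error_rate`, `tp`, `fp`, `tn`, `fn`.
#' @export
optimal_threshold <- function(cases, controls) {
  stopifnot(length(cases) > 0, length(controls) > 0,
            all(is.finite(cases)), all(is.finite(controls)))
  u <- sort(unique(c(cases, controls)))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sc <- sort(cases); sk <- sort(controls)
  fn <- findInterval(cand, sc)               # cases strictly below h
  fp <- length(sk) - findInterval(cand, sk)  # controls at or above h
  err <- (fp + fn) / (length(sc) + length(sk))
  i <- which.min(err)                        # first minimum = smallest h
  list(h_star = cand[i], error_rate = err[i],
       tp = length(sc) - fn[i], fp = fp[i],
       tn = length(sk) - fp[i], fn = fn[i])
}

#' Repeated orthology benchmark with resampled controls
#'
#' Scores the case pairs once, then over `R` repeats draws a fresh
#' derangement control set, scores it, and records the optimal threshold
#' and its error rate. Reports the mean error rate with a normal-theory
#' confidence interval of the mean (99% by default) and the mean optimal
#' threshold. When a background table is supplied the same procedure is
#' run in parallel on z-scores, enabling the raw-versus-z comparison.
#'
#' Case pairs unscorable under the scorer are excluded up front (before
#' control construction), so case and control sets stay equally sized;
#' any residual scorer failure inside a repeat drops that pair from the
#' repeat with a logged count.
#'
#' @param cases an `ortholog_set` (or data.frame with `idA`, `idB`).
#' @param scorer `function(idA, idB)` returning a numeric score or `NA`;
#'   typically [fs_scorer()].
#' @param R number of control resamples (default 225).
#' @param seed optional integer seed governing all derangements.
#' @param background optional `fs_background` covering the proteins of
#'   `cases`; enables the z-score arm.
#' @param conf_level confidence level of the CI of the mean error rate.
#' @return an `fs_benchmark`: list with elements `raw` and (optionally)
#'   `z`, each holding `errors`, `h_stars`, `mean_error`, `ci`,
#'   `mean_h_star`; plus `R`, `n_pairs`, `n_excluded`, `n_dropped`,
#'   `conf_level`.
#' @export
repeat_benchmark <- function(cases, scorer, R = 225, seed = NULL,
                             background = NULL, conf_level = 0.99) {
  stopifnot(nrow(cases) >= 2, R >= 1)
  if (!is.null(seed)) set.seed(seed)

  case_raw <- mapply(scorer, cases$idA, cases$idB)
  keep <- !is.na(case_raw)
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    log_msg("repeat_benchmark: excluded %d unscorable case pair(s)", n_excluded)
  cases <- cases[keep, , drop = FALSE]
  case_raw <- case_raw[keep]
  n <- nrow(cases)
  if (n < 2)
    stop_gofunsim("fewer than 2 scorable case pairs remain")

  use_z <- !is.null(background)
  case_z <- if (use_z) zscore_pairs(case_raw, cases$idA, cases$idB, background)

  arm_names <- c("raw", if (use_z) "z")
  errors <- h_stars <- stats::setNames(
    rep(list(numeric(R)), length(arm_names)), arm_names)
  n_dropped <- 0L

  for (r in seq_len(R)) {
    perm <- derangement(n)
    idB_ctrl <- cases$idB[perm]
    ctrl_raw <- mapply(scorer, cases$idA, idB_ctrl)
    ok <- !is.na(ctrl_raw)
    n_dropped <- n_dropped + sum(!ok)
    o <- optimal_threshold(case_raw[ok], ctrl_raw[ok])
    errors$raw[r] <- o$error_rate
    h_stars$raw[r] <- o$h_star
    if (use_z) {
      ctrl_z <- zscore_pairs(ctrl_raw, cases$idA, idB_ctrl, background)
      okz <- ok & !is.na(ctrl_z) & !is.na(case_z)
      oz <- optimal_threshold(case_z[okz], ctrl_z[okz])
      errors$z[r] <- oz$error_rate
      h_stars$z[r] <- oz$h_star
    }
  }
  if (n_dropped > 0)
    log_msg("repeat_benchmark: dropped %d control scoring(s) across repeats",
            n_dropped)

  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  arm <- function(e, h) {
    se <- stats::sd(e) / sqrt(R)
    list(errors = e, h_stars = h, mean_error = mean(e),
         ci = c(lo = mean(e) - zq * se, hi = mean(e) + zq * se),
         mean_h_star = mean(h))
  }
  out <- list(raw = arm(errors$raw, h_stars$raw),
              z = if (use_z) arm(errors$z, h_stars$z),
              R = R, n_pairs = n, n_excluded = n_excluded,
              n_dropped = n_dropped, conf_level = conf_level)
  class(out) <- "fs_benchmark"
  out
}

#' @export
print.fs_benchmark <- function(x, ...) {
  cat(sprintf("Orthology benchmark: %d case pairs, %d control resamples\n",
              x$n_pairs, x$R))
  fmt <- function(a, label)
    cat(sprintf("  %-3s mean error %.4f  %g%% CI [%.4f, %.4f]  mean h* %.4g\n",
                label, a$mean_error, 100 * x$conf_level,
                a$ci["lo"], a$ci["hi"], a$mean_h_star))
  fmt(x$raw, "raw")
  if (!is.null(x$z)) fmt(x$z, "z")
  if (x$n_excluded) cat(sprintf("  (%d unscorable case pair(s) excluded)\n",
                                x$n_excluded))
  invisible(x)
}

#' @export
summary.fs_benchmark <- function(object, ...) {
  arms <- Filter(Negate(is.null), object[c("raw", "z")])
  do.call(rbind, lapply(names(arms), function(nm) {
    a <- arms[[nm]]
    data.frame(scores = nm, mean_error = a$mean_error,
               ci_lo = unname(a$ci["lo"]), ci_hi = unname(a$ci["hi"]),
               mean_h_star = a$mean_h_star, R = object$R,
               n_pairs = object$n_pairs)
  }))
}

#' @export
plot.fs_benchmark <- function(x, ...) {
  if (is.null(x$z)) {
    graphics::hist(x$raw$errors, main = "Per-repeat error rates",
                   xlab = "error rate", ...)
  } else {
    rng <- range(c(x$raw$errors, x$z$errors))
    graphics::plot(x$raw$errors, x$z$errors, xlim = rng, ylim = rng,
                   xlab = "raw-score error rate",
                   ylab = "z-score error rate",
                   main = "Raw vs z-score error per repeat", ...)
    graphics::abline(0, 1, col = "grey")
  }
  invisible(x)
}

#' Paired corpus comparison of per-repeat error rates
#'
#' One-sided Wilcoxon signed-rank test comparing the per-repeat error
#' rates of the same measure under two annotation corpora (e.g. ALL
#' versus AOO). Significance is assessed at `alpha` after Bonferroni
#' adjustment for `n_tests` measure combinations (default 30 = six
#' semantic-similarity measures times five mixing strategies). When all
#' paired differences are zero the test statistic is undefined and the
#' result is reported non-significant with a degeneracy flag.
#'
#' @param errors_all,errors_aoo equal-length numeric vectors of per-repeat
#'   error rates under the two corpora.
#' @param n_tests Bonferroni family size (default 30).
#' @param alpha family significance level (default 0.01).
#' @param alternative passed to [stats::wilcox.test()]; the default
#'   `"greater"` tests whether AOO errors exceed ALL errors.
#' @return list with `statistic`, `p_value`, `significant`, `degenerate`,
#'   `alpha`, `n_tests`.
#' @export
compare_corpora <- function(errors_all, errors_aoo, n_tests = 30,
                            alpha = 0.01,
                            alternative = c("greater", "less")) {
  stopifnot(length(errors_all) == length(errors_aoo))
  alternative <- match.arg(alternative)
  d <- errors_aoo - errors_all
  if (all(d == 0))
    return(list(statistic = NA_real_, p_value = NA_real_,
                significant = FALSE, degenerate = TRUE,
                alpha = alpha, n_tests = n_tests))
  wt <- suppressWarnings(
    stats::wilcox.test(errors_aoo, errors_all, paired = TRUE,
                       alternative = alternative, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < alpha / n_tests, degenerate = FALSE,
       alpha = alpha, n_tests = n_tests)
}

#' Write a benchmark report row as TSV
#'
#' Machine-readable summary per (measure, mix, namespaces, corpus
#' filter): mean error, CI bounds, and mean optimal threshold for each
#' score arm.
#'
#' @param bench an `fs_benchmark`.
#' @param path output TSV path.
#' @param context named character vector prepended as columns (e.g.
#'   measure, mix, namespaces, iea).
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bench, path, context = character(0)) {
  df <- summary(bench)
  for (nm in rev(names(context)))
    df <- cbind(stats::setNames(data.frame(rep(context[[nm]], nrow(df))), nm), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
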