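# Case-control association statistics: 2x2 odds ratios with Woolf CIs and
# Fisher's exact p-values, ROC/AUROC, balanced-accuracy threshold scans,
# centiles, correlation/regression with prediction bands, and rank-based
# group comparison (Kruskal-Wallis omnibus + Dunn's pairwise post-test).

.check_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (length(cnt) != 4 || anyNA(cnt) || any(cnt < 0))
    stop("a 2x2 table needs four non-negative counts")
  if (sum(cnt) == 0) stop("2x2 table total must be positive")
  cnt
}

#' Odds ratio with Woolf confidence interval from a 2x2 table
#'
#' Convention: rows = category of interest vs rest, columns = outcome vs
#' rest, so `a` = in-category with outcome, `b` = in-category without,
#' `c` = rest with outcome, `d` = rest without; OR = (a d)/(b c).  With a
#' zero in any cross-product cell the OR is reported as undefined (`NA`,
#' the "—" convention) unless `haldane = TRUE` adds 0.5 to every cell.
#' The 95% CI is Woolf's: `exp(ln OR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' The p-value is the two-sided Fisher's exact probability.
#'
#' @param a,b,c,d non-negative counts.
#' @param conf_level confidence level, default 0.95.
#' @param haldane apply the Haldane-Anscombe +0.5 correction (default off).
#' @return one-row `data.frame`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @examples
#' oddsRatioFromCounts(56, 70, 94, 231)  # OR ~ 1.97
#' @export
oddsRatioFromCounts <- function(a, b, c, d, conf_level = 0.95,
                                haldane = FALSE) {
  cnt <- .check_2x2(a, b, c, d)
  p <- fisherExact2x2(a, b, c, d)
  if (haldane) cnt <- cnt + 0.5
  if (cnt[1] * cnt[4] == 0 || cnt[2] * cnt[3] == 0)
    return(data.frame(odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = p))
  or <- (cnt[1] * cnt[4]) / (cnt[2] * cnt[3])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cnt))
  data.frame(odds_ratio = or,
             ci_low = exp(log(or) - z * se),
             ci_high = exp(log(or) + z * se),
             p_value = p)
}

#' Odds ratio from case/control frequencies
#'
#' `OR = [p_case / (1 - p_case)] / [p_ctrl / (1 - p_ctrl)]`; undefined
#' (`NA`) when either frequency is 0 or 1.  When the numbers of sampled
#' alleles (or subjects, for subject-level categories) are supplied, the
#' underlying counts are reconstructed by rounding `freq * n` and used for
#' a Woolf confidence interval centred on the frequency-ratio OR and a
#' Fisher's exact p-value.  The reconstruction is approximate when
#' per-locus missingness altered the true denominators.
#'
#' @param p_case,p_ctrl frequencies in \[0, 1\].
#' @param n_case,n_ctrl total allele (or subject) counts; `NULL` skips
#'   CI and p.
#' @param conf_level confidence level, default 0.95.
#' @return one-row `data.frame`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value` (the latter three `NA` without counts).
#' @examples
#' oddsRatioFromFreqs(0.1542, 0.0734)                    # OR ~ 2.30
#' oddsRatioFromFreqs(0.1542, 0.0734, 2 * 478, 2 * 290)  # adds CI and p
#' @export
oddsRatioFromFreqs <- function(p_case, p_ctrl, n_case = NULL, n_ctrl = NULL,
                               conf_level = 0.95) {
  if (anyNA(c(p_case, p_ctrl)) ||
      any(c(p_case, p_ctrl) < 0 | c(p_case, p_ctrl) > 1))
    stop("frequencies must lie in [0, 1]")
  out <- data.frame(odds_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_)
  degenerate <- p_case %in% c(0, 1) || p_ctrl %in% c(0, 1)
  if (!degenerate)
    out$odds_ratio <- (p_case / (1 - p_case)) / (p_ctrl / (1 - p_ctrl))
  if (!is.null(n_case) && !is.null(n_ctrl)) {
    a <- round(p_case * n_case); b <- n_case - a
    cc <- round(p_ctrl * n_ctrl); d <- n_ctrl - cc
    out$p_value <- fisherExact2x2(a, b, cc, d)
    if (!degenerate && all(c(a, b, cc, d) > 0)) {
      z <- qnorm(1 - (1 - conf_level) / 2)
      se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
      out$ci_low <- exp(log(out$odds_ratio) - z * se)
      out$ci_high <- exp(log(out$odds_ratio) + z * se)
    }
  }
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' all tables no more probable than the observed one (the conventional
#' "small-p" two-sided rule; two-sided conventions differ, so the rule is
#' stated here).
#'
#' @param a,b,c,d non-negative counts (row 1: a, b; row 2: c, d).
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(56, 70, 94, 231)
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  .check_2x2(a, b, c, d)
  stats::fisher.test(matrix(c(a, c, b, d), 2, 2))$p.value
}

#' ROC curve and AUROC
#'
#' Classification direction is fixed: higher scores predict the positive
#' class (`score >= threshold` predicts a case); there is no automatic
#' flip.  Sensitivity/specificity are evaluated at every distinct score
#' (plus an all-negative sentinel) and the AUC is the trapezoidal area,
#' which equals the pair statistic P(case score > control score) + 1/2
#' P(tie) and is therefore invariant under strictly increasing transforms
#' of the scores.
#'
#' @param scores numeric scores.
#' @param labels binary labels (logical, 0/1, or a factor whose second
#'   level is the positive class); `TRUE`/1 = case.
#' @return list of class `"RocCurve"`: `thresholds`, `sens`, `spec`,
#'   `auc`, `n_case`, `n_control`.
#' @examples
#' rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
#' @export
rocAuc <- function(scores, labels) {
  lab <- .as_binary(labels)
  keep <- !is.na(scores) & !is.na(lab)
  scores <- scores[keep]; lab <- lab[keep]
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  # pair statistic via midranks (exact, ties counted half)
  r <- rank(scores)
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[lab] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!lab] < t), numeric(1))
  structure(list(thresholds = thr, sens = sens, spec = spec, auc = auc,
                 n_case = n1, n_control = n0),
            class = "RocCurve")
}

.as_binary <- function(labels) {
  if (is.factor(labels)) return(labels == levels(labels)[2])
  if (is.logical(labels)) return(labels)
  if (all(labels %in% c(0, 1, NA))) return(labels == 1)
  stop("labels must be logical, 0/1, or a two-level factor")
}

#' Balanced-accuracy threshold scan
#'
#' Balanced accuracy at a threshold t is
#' `[sens(t) + spec(t)] / 2` with `score >= t` predicting a case.  The
#' default grid places one threshold at the midpoint of every pair of
#' consecutive distinct scores, plus -Inf/+Inf sentinels - no threshold
#' between two adjacent scores can change any prediction, so this grid is
#' exhaustive.  `"observed"` evaluates at the observed scores instead.
#' Grid ties at the peak are broken toward the lower threshold.
#'
#' @param scores numeric scores.
#' @param labels binary labels; `TRUE`/1 = case.
#' @param grid_policy `"midpoints"` (default) or `"observed"`.
#' @return list of class `"ThresholdScan"`: `grid`, `balanced_accuracy`,
#'   `peak_threshold`, `peak_accuracy`, `sens_at_peak`, `spec_at_peak`.
#' @examples
#' balancedAccuracyScan(c(1, 2, 3, 4), c(0, 0, 1, 1))$peak_accuracy  # 1
#' @export
balancedAccuracyScan <- function(scores, labels,
                                 grid_policy = c("midpoints", "observed")) {
  grid_policy <- match.arg(grid_policy)
  lab <- .as_binary(labels)
  keep <- !is.na(scores) & !is.na(lab)
  scores <- scores[keep]; lab <- lab[keep]
  if (sum(lab) == 0 || sum(!lab) == 0)
    stop("balanced accuracy undefined: both classes must be present")
  u <- sort(unique(scores))
  grid <- if (grid_policy == "midpoints") {
    if (length(u) > 1) c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
    else c(-Inf, Inf)
  } else u
  ba <- vapply(grid, function(t) {
    (mean(scores[lab] >= t) + mean(scores[!lab] < t)) / 2
  }, numeric(1))
  peak <- which.max(ba)  # which.max takes the first, i.e. lowest, maximum
  structure(list(grid = grid, balanced_accuracy = ba,
                 peak_threshold = grid[peak], peak_accuracy = ba[peak],
                 sens_at_peak = mean(scores[lab] >= grid[peak]),
                 spec_at_peak = mean(scores[!lab] < grid[peak])),
            class = "ThresholdScan")
}

#' Score centiles, with the fraction of a second group above the median
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7; quantile conventions differ, so the choice
#' is stated).  When a second score vector is supplied, the fraction of it
#' lying above the reference 50th centile is reported alongside.
#'
#' @param scores reference scores (non-empty).
#' @param centiles centiles to report, default `c(25, 50, 75)`.
#' @param other optional second group of scores.
#' @return named list: `centiles` (named numeric) and, with `other`,
#'   `frac_above_median`.
#' @examples
#' scoreCentiles(1:100)$centiles[["50"]]  # 50.5
#' @export
scoreCentiles <- function(scores, centiles = c(25, 50, 75), other = NULL) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no scores supplied")
  q <- quantile(scores, probs = centiles / 100, type = 7, names = FALSE)
  out <- list(centiles = setNames(q, centiles))
  if (!is.null(other))
    out$frac_above_median <-
      mean(other > quantile(scores, 0.5, type = 7), na.rm = TRUE)
  out
}

#' Linear regression with Pearson correlation and a prediction band
#'
#' Ordinary least squares of score on age (or any x), the Pearson
#' correlation with its two-sided p-value, and a two-sided prediction band
#' `yhat ± t_{(1+level)/2, n-2} * s * sqrt(1 + 1/n + (x - xbar)^2 / Sxx)`.
#' Samples whose observed y falls below the lower band are flagged as low
#' outliers (the low-score flag used to question a clinical diagnosis).
#'
#' @param x,y numeric vectors (n >= 3, x non-constant).  Names of `y` (or
#'   of `x`) identify samples in `outlier_ids`.
#' @param band_level prediction-band level, default 0.99.
#' @return list of class `"RegressionFit"`: `slope`, `intercept`,
#'   `pearson_r`, `p_value`, `band_level`, `fitted`, `lower`, `upper`,
#'   `outlier_ids`, `n`.
#' @examples
#' fit <- regressionWithBand(1:20, 21:40 * 0.5)
#' fit$pearson_r  # 1
#' @export
regressionWithBand <- function(x, y, band_level = 0.99) {
  ids <- names(y); if (is.null(ids)) ids <- names(x)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (!is.null(ids)) ids <- ids[keep] else ids <- as.character(which(keep))
  if (length(x) < 3) stop("regression needs at least 3 complete pairs")
  if (sd(x) == 0) stop("degenerate fit: x is constant")
  fit <- lm(y ~ x)
  ct <- suppressWarnings(cor.test(x, y))
  # in-sample evaluation of the band is intentional here
  pred <- suppressWarnings(
    predict(fit, interval = "prediction", level = band_level))
  low <- y < pred[, "lwr"] - 1e-10 * (1 + abs(y))  # guard exact fits
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 band_level = band_level,
                 fitted = pred[, "fit"], lower = pred[, "lwr"],
                 upper = pred[, "upr"],
                 outlier_ids = ids[low],
                 n = length(x)),
            class = "RegressionFit")
}

#' Rank-based group comparison (Kruskal-Wallis + Dunn's post-test)
#'
#' Omnibus Kruskal-Wallis rank test across all groups, followed by Dunn's
#' pairwise z-tests on the shared ranks (with tie correction), two-sided.
#' The multiplicity adjustment of the pairwise p-values is a parameter;
#' the default, Bonferroni, matches the usual multiple-comparison
#' post-test convention.
#'
#' @param groups named list of numeric score vectors (>= 2 non-empty
#'   groups).
#' @param adjust a `p.adjust` method for the pairwise p-values, default
#'   `"bonferroni"`; `"none"` gives unadjusted Dunn p-values.
#' @return list: `omnibus_p`, `pairwise` (a `data.frame` with `group1`,
#'   `group2`, `z`, `p_value` rows for every pair).
#' @examples
#' rankGroupComparison(list(a = rnorm(20), b = rnorm(20) + 5))
#' @export
rankGroupComparison <- function(groups, adjust = "bonferroni") {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(!lengths(groups)))
    stop("need at least two non-empty groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  glab <- factor(rep(names(groups), lengths(groups)),
                 levels = names(groups))
  omnibus <- kruskal.test(values, glab)$p.value
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, glab, mean)
  n <- lengths(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(p) {
    v <- (N * (N + 1) / 12 - tie_corr) * (1 / n[[p[1]]] + 1 / n[[p[2]]])
    (rbar[[p[1]]] - rbar[[p[2]]]) / sqrt(v)
  })
  p_raw <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_value = p.adjust(p_raw, method = adjust)) -> pw
  list(omnibus_p = omnibus, pairwise = pw)
}
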