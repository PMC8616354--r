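#' Pixel-wise confusion between prediction and ground truth
#'
#' True negatives are excluded from the denominator by construction: the
#' fractions of true-positive, false-positive and false-negative pixels sum
#' to 1, and `iou = tp / (tp + fp + fn)` is the intersection over union of
#' the two foregrounds.
#'
#' @param pred,truth [binary_mask()]s (or logical matrices) of identical
#'   dimensions.
#' @return List with counts `tp`, `fp`, `fn`, fractions `tp_frac`,
#'   `fp_frac`, `fn_frac`, and `iou`.
#' @export
pixel_confusion <- function(pred, truth) {
  p <- as_pixels(pred); t <- as_pixels(truth)
  if (!identical(dim(p), dim(t)))
    stop("input error: mask dimensions differ")
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  denom <- tp + fp + fn
  list(tp = tp, fp = fp, fn = fn,
       tp_frac = if (denom > 0) tp / denom else NA_real_,
       fp_frac = if (denom > 0) fp / denom else NA_real_,
       fn_frac = if (denom > 0) fn / denom else NA_real_,
       iou = if (denom > 0) tp / denom else NA_real_)
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = x - y`; reports `mean(d)` and
#' `mean(d) +/- 1.96 * sd(d)` (sample SD, n - 1), plus the per-pair
#' (mean, difference) points for plotting.
#'
#' @param x,y paired measurement vectors of equal length >= 2.
#' @return List with `mean_diff`, `lower`, `upper`, `sd_diff`, and a
#'   `points` data frame (`avg`, `diff`).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("input error: unequal lengths")
  if (length(x) < 2) stop("input error: need at least 2 pairs")
  d <- x - y
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
       sd_diff = s, points = data.frame(avg = (x + y) / 2, diff = d))
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (>= 3, both non-constant).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("input error: unequal lengths")
  if (length(x) < 3) stop("input error: need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined: constant input has no correlation")
  cor(x, y, method = "pearson")
}

#' Dunn's test for non-parametric multiple comparisons
#'
#' Joint mid-rank ranking of all observations with tie-corrected variance;
#' for each pair of groups `z = (mean-rank difference) / SE` with
#' `SE = sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` and tie term
#' `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided normal p-values are
#' reported both raw and Holm-corrected over the family of pairs.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2
#'   observations); names are used as group labels.
#' @return Data frame: `group1`, `group2`, `z`, `p_raw`, `p_holm`.
#' @export
dunns_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("input error: need a list of >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("input error: every group needs >= 2 observations")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), sizes)
  N <- length(vals)
  r <- rank(vals, ties.method = "average")
  mean_ranks <- tapply(r, g, mean)
  tie_tab <- table(vals)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  combs <- utils::combn(names(groups), 2)
  out <- apply(combs, 2, function(pr) {
    ni <- sizes[[pr[1]]]; nj <- sizes[[pr[2]]]
    se <- sqrt(var_base * (1 / ni + 1 / nj))
    diff <- mean_ranks[[pr[1]]] - mean_ranks[[pr[2]]]
    z <- if (se == 0) 0 else diff / se
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p_raw = 2 * pnorm(-abs(z)))
  })
  out <- do.call(rbind, out)
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  rownames(out) <- NULL
  out
}
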