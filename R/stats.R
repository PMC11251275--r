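#' Median and interquartile range
#'
#' Quartiles by linear interpolation of order statistics (R's default
#' type-7 convention); documented because printed IQRs depend on it.
#'
#' @param values Numeric vector, n >= 1, no NAs.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @examples
#' median_iqr(1:5) # 3, 2, 4
#' @export
median_iqr <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("missing values", call. = FALSE)
  q <- quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

# midrank-based U statistic of x (number of (x, y) pairs with x > y,
# ties counted 1/2)
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test (two-sided)
#'
#' U with midranks for ties. The exact two-sided p-value (from the exact
#' null distribution of U, computed by the standard counting recursion) is
#' used when `nx * ny <= exact_max` and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections. `mode` can
#' force either route (forcing `"exact"` with ties is an error).
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param exact_max Largest `nx * ny` for which the exact distribution is
#'   used in `"auto"` mode.
#' @return List: `U` (statistic of `x`), `p_value`, `method`, `nx`, `ny`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal"),
                           exact_max = 400) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0L
  u <- u_statistic(x, y)

  if (length(unique(pooled)) == 1L) {
    warning("all pooled values identical; p = 1", call. = FALSE)
    return(list(U = u, p_value = 1, method = "degenerate",
                nx = nx, ny = ny))
  }
  use_exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = !ties && nx * ny <= exact_max
  )
  if (use_exact && ties)
    stop("exact mode requires tie-free data", call. = FALSE)

  if (use_exact) {
    # two-sided: double the smaller tail of the exact U distribution
    lo <- pwilcox(u, nx, ny)
    hi <- 1 - pwilcox(u - 1, nx, ny)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tab <- table(pooled)
    n <- nx + ny
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = u, p_value = p, method = method, nx = nx, ny = ny)
}

#' Kruskal-Wallis rank test
#'
#' H with tie correction; p from the chi-square approximation with
#' k - 1 degrees of freedom.
#'
#' @param groups List of >= 2 non-empty numeric vectors (named or not);
#'   the usual use is >= 3 groups (with 2 groups H is the square of the
#'   normal-approximation Mann-Whitney z).
#' @return List: `H`, `p_value`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need >= 2 groups", call. = FALSE)
  if (any(!lengths(groups))) stop("empty group", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (anyNA(vals)) stop("missing values", call. = FALSE)
  n <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  rsum <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (n + 1)
  tab <- table(vals)
  correction <- 1 - sum(tab^3 - tab) / (n^3 - n)
  if (correction <= 0) {
    warning("all values identical; H = 0", call. = FALSE)
    return(list(H = 0, p_value = 1, df = length(groups) - 1L, n = n))
  }
  h <- h / correction
  list(H = h, p_value = pchisq(h, df = length(groups) - 1L,
                               lower.tail = FALSE),
       df = length(groups) - 1L, n = n)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics from pooled midranks with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups. Two-sided p-values are
#' adjusted by the configured method (default Holm).
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param adjust `"holm"`, `"bonferroni"` or `"none"`.
#' @return Data.frame: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(groups, adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need >= 2 groups", call. = FALSE)
  if (any(!lengths(groups))) stop("empty group", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  if (anyNA(vals)) stop("missing values", call. = FALSE)
  n <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  tab <- table(vals)
  tie_sum <- sum(tab^3 - tab)
  var_base <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))

  pairs <- utils::combn(seq_along(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / lengths(groups)[i] +
                             1 / lengths(groups)[j]))
    z[k] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             z = z, p_value = pmin(1, p),
             p_adjusted = p.adjust(pmin(1, p), method = adjust),
             stringsAsFactors = FALSE)
}

#' Q10 temperature correction of a rate
#'
#' `rate * q10 ^ ((t_target - t_measured) / 10)`; with the conventional
#' Q10 of 2.2 for rubisco carboxylation, a rate measured at 20 degC is
#' roughly doubled when expressed at 30 degC.
#'
#' @param rate Rate (s^-1), >= 0.
#' @param t_measured,t_target Temperatures (degC).
#' @param q10 Fold change per 10 degC (default 2.2).
#' @return Corrected rate (s^-1).
#' @examples
#' q10_correct(3, 20, 30) # 6.6
#' @export
q10_correct <- function(rate, t_measured, t_target, q10 = 2.2) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  rate * q10^((t_target - t_measured) / 10)
}

box_stats <- function(v) {
  q <- median_iqr(v)
  iqr <- q[["q3"]] - q[["q1"]]
  lo <- q[["q1"]] - 1.5 * iqr
  hi <- q[["q3"]] + 1.5 * iqr
  list(median = q[["median"]], q1 = q[["q1"]], q3 = q[["q3"]],
       whisker_low = min(v[v >= lo]), whisker_high = max(v[v <= hi]),
       outliers = v[v < lo | v > hi], n = length(v))
}

compare_two <- function(panel, label_col, test_name) {
  groups <- split(panel$kcat, panel[[label_col]])
  if (length(groups) != 2L)
    stop("expected exactly 2 groups in ", label_col, call. = FALSE)
  mw <- mann_whitney_u(groups[[1]], groups[[2]])
  med <- vapply(groups, function(v) median_iqr(v)[["median"]], numeric(1))
  list(comparison = test_name, test = "mann_whitney_u",
       groups = names(groups), sizes = unname(lengths(groups)),
       summaries = lapply(groups, box_stats),
       statistic = mw$U, p_value = mw$p_value,
       fold_difference = max(med) / min(med),
       pairwise = NULL)
}

#' Group comparisons of carboxylation rates (box-plot analyses)
#'
#' Runs the three class-representative comparisons on a panel table:
#' trophic mode (Mann-Whitney), carboxysome association (Mann-Whitney) and
#' clade (Kruskal-Wallis followed by Dunn). Each comparison is restricted
#' to active variants carrying the matching `subset` flag (all active
#' variants when the panel has no subset column). Summaries are plot-ready
#' box/whisker data (whiskers at the most extreme values within 1.5 IQR of
#' the quartiles) plus the fold difference of group medians.
#'
#' @param panel A `panel_table` data.frame (see [simulate_panel()] /
#'   [read_panel()]).
#' @param comparisons Which comparisons to run.
#' @param adjust Dunn adjustment method.
#' @return Named list of comparison results; comparisons whose subset flag
#'   is absent are skipped with a warning.
#' @export
compare_figure2 <- function(panel,
                            comparisons = c("trophic", "carboxysome",
                                            "clade"),
                            adjust = "holm") {
  stopifnot(is.data.frame(panel))
  label_of <- c(trophic = "trophic_mode", carboxysome = "carboxysome",
                clade = "clade")
  out <- list()
  for (cmp in comparisons) {
    lab <- label_of[[cmp]]
    sub <- panel[panel$active & !is.na(panel$kcat), , drop = FALSE]
    if ("subset" %in% names(panel) && any(panel$subset %in% cmp)) {
      sub <- sub[sub$subset %in% cmp, , drop = FALSE]
    }
    if (!nrow(sub) || length(unique(sub[[lab]])) < 2L) {
      warning("comparison '", cmp, "' skipped: no usable subset",
              call. = FALSE)
      next
    }
    if (cmp == "clade") {
      groups <- split(sub$kcat, sub[[lab]])
      groups <- groups[lengths(groups) > 0]
      kw <- kruskal_wallis(groups)
      dn <- dunn_test(groups, adjust = adjust)
      med <- vapply(groups, function(v) median_iqr(v)[["median"]],
                    numeric(1))
      out[[cmp]] <- list(comparison = cmp,
                         test = "kruskal_wallis+dunn",
                         groups = names(groups),
                         sizes = unname(lengths(groups)),
                         summaries = lapply(groups, box_stats),
                         statistic = kw$H, p_value = kw$p_value,
                         fold_difference = max(med) / min(med),
                         pairwise = dn, adjust = adjust)
    } else {
      out[[cmp]] <- compare_two(sub, lab, cmp)
    }
  }
  out
}
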