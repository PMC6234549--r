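#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent groups. The exact null
#' distribution is used whenever the pooled sample size is at most
#' `exact_max` and there are no ties (with the usual two-sided doubling rule
#' `p = min(1, 2 min(P<=, P>=))`); otherwise the normal approximation with
#' tie correction and continuity correction is applied.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_max largest pooled sample size for which the exact
#'   distribution is used (default 25; small-study group comparisons demand
#'   exact tests, the approximation is kept for large simulations).
#' @return an object of class `comparison_result`: list with `statistic`
#'   (the U statistic for `x`), `p_value`, `method` and `n_per_group`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 25) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical; p = 1")
    return(comparison_result(length(x) * length(y) / 2, 1,
                             "mann_whitney_exact", c(length(x), length(y))))
  }
  exact <- !ties && (length(x) + length(y)) <= exact_max
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  comparison_result(unname(wt$statistic), wt$p.value,
                    if (exact) "mann_whitney_exact" else "mann_whitney_asymptotic",
                    c(length(x), length(y)))
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired test on a vector of differences. Zero differences are
#' dropped before ranking (Wilcoxon's rule, the default) or retained in the
#' ranking and then discarded (`zero_method = "pratt"`, normal approximation).
#' The exact distribution over all `2^n` sign assignments is used when the
#' number of nonzero differences is at most `exact_max` and their magnitudes
#' are tie-free.
#'
#' @param differences paired differences; at least one must be nonzero.
#' @param exact_max largest `n` for the exact distribution (default 20).
#' @param zero_method `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @return a `comparison_result` (statistic is `V`, the positive-rank sum).
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 20,
                                 zero_method = c("wilcoxon", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- differences[!is.na(differences)]
  if (all(d == 0)) stop("all differences are zero; the test is undefined")
  if (zero_method == "pratt") {
    # Pratt: rank |d| including zeros, then drop the zero ranks; normal
    # approximation with tie and zero corrections.
    r <- rank(abs(d))
    nz <- d != 0
    V <- sum(r[nz & d > 0])
    n <- length(d)
    n0 <- sum(!nz)
    mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
    tie_tab <- table(r[nz])
    sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu) / sqrt(sig2)
    return(comparison_result(V, min(1, 2 * pnorm(-abs(z))),
                             "wilcoxon_asymptotic", sum(nz)))
  }
  if (any(d == 0)) {
    warning(sprintf("%d zero difference(s) dropped", sum(d == 0)))
    d <- d[d != 0]
  }
  exact <- length(d) <= exact_max && anyDuplicated(abs(d)) == 0L
  wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  comparison_result(unname(wt$statistic), wt$p.value,
                    if (exact) "wilcoxon_exact" else "wilcoxon_asymptotic",
                    length(d))
}

comparison_result <- function(statistic, p_value, method, n_per_group) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n_per_group = n_per_group), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Regional ratio of group means
#'
#' For each region present in both groups, the ratio of the group-A mean to
#' the group-B mean, plus their mean across regions — the standard summary of
#' a multiplicative group effect measured region-wise.
#'
#' @param value_a,value_b values for groups A and B.
#' @param region_a,region_b region labels aligned with the values.
#' @return list with `table` (data frame: region, mean_a, mean_b, ratio, n_a,
#'   n_b) and `mean_ratio`. Regions with a zero denominator are dropped with a
#'   warning.
#' @export
ratio_of_group_means <- function(value_a, region_a, value_b, region_b) {
  stopifnot(length(value_a) == length(region_a),
            length(value_b) == length(region_b))
  regions <- intersect(unique(region_a), unique(region_b))
  if (length(regions) < 1L) stop("no region present in both groups")
  rows <- lapply(regions, function(rg) {
    a <- value_a[region_a == rg & !is.na(value_a)]
    b <- value_b[region_b == rg & !is.na(value_b)]
    data.frame(region = rg, mean_a = mean(a), mean_b = mean(b),
               ratio = mean(a) / mean(b), n_a = length(a), n_b = length(b))
  })
  tab <- do.call(rbind, rows)
  if (any(tab$mean_b == 0)) {
    warning("region(s) with zero denominator dropped: ",
            paste(tab$region[tab$mean_b == 0], collapse = ", "))
    tab <- tab[tab$mean_b != 0, , drop = FALSE]
  }
  list(table = tab, mean_ratio = mean(tab$ratio))
}

#' Paired ordinary least-squares regression
#'
#' Regresses paired region values (e.g. lesion on non-lesional white matter)
#' with a free intercept, reporting the slope, its standard error and R^2,
#' with optional exclusion of named outliers.
#'
#' @param x predictor values (one per subject).
#' @param y response values, aligned with `x`.
#' @param ids optional subject identifiers aligned with `x`.
#' @param exclude identifiers to exclude before fitting.
#' @return an object of class `regression_result`: list with `slope`,
#'   `slope_se`, `intercept`, `r_squared`, `n`, `outliers_excluded`.
#' @export
paired_regression <- function(x, y, ids = NULL, exclude = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(ids)) ids <- as.character(seq_along(x))
  keep <- !(ids %in% exclude) & !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("at least three pairs are required after exclusion")
  if (sd(x) == 0) stop("slope undefined: predictor is constant")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # silence the exact-fit notice
  structure(list(slope = unname(coef(fit)[2]),
                 slope_se = unname(sm$coefficients[2, 2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 n = length(x),
                 outliers_excluded = exclude %||% character()),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.3f +/- %.3f, intercept %.3f, R^2 = %.3f (n = %d%s)\n",
              x$slope, x$slope_se, x$intercept, x$r_squared, x$n,
              if (length(x$outliers_excluded))
                paste0(", excluded: ", paste(x$outliers_excluded, collapse = ","))
              else ""))
  invisible(x)
}

#' Genotype contrast from cohort fit results
#'
#' Regional HAB/MAB ratio of mean fitted values. For `BP_ND` the contrast is
#' computed on the healthy-control arm by default, because a disease effect
#' confined to one genotype would otherwise confound the genotype ratio; for
#' `V_T` all subjects are used (no disease effect on `V_T` is expected).
#'
#' @param results a [fit_cohort] data frame.
#' @param value column to contrast, `"vt"` or `"bpnd"`.
#' @param subjects `"auto"` (the defaults above), `"all"` or `"hc"`.
#' @return as [ratio_of_group_means].
#' @export
genotype_contrast <- function(results, value = c("vt", "bpnd"),
                              subjects = c("auto", "all", "hc")) {
  value <- match.arg(value)
  subjects <- match.arg(subjects)
  if (subjects == "auto") subjects <- if (value == "bpnd") "hc" else "all"
  df <- if (subjects == "hc") results[results$group == "HC", ] else results
  hab <- df[df$genotype == "HAB", ]
  mab <- df[df$genotype == "MAB", ]
  ratio_of_group_means(hab[[value]], hab$region, mab[[value]], mab$region)
}
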