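#' @include volumetry.R
NULL

#' Descriptive statistics of one group sample
#'
#' n, min, max, mean, sample SD (n - 1), median and the t-based 95%
#' confidence interval of the mean, as tabulated per treatment group for
#' the volumetric endpoints.
#'
#' @param values numeric vector of volumes (mm^3) or dimensionless
#'   fractions; NA values are dropped.
#' @param conf confidence level, default 0.95.
#' @return A one-row data.frame with columns \code{n}, \code{min},
#'   \code{max}, \code{mean}, \code{sd}, \code{median}, \code{ci_lo},
#'   \code{ci_hi}.
#' @export
#' @examples
#' descriptiveStats(c(1, 2, 3))  # CI (-0.484, 4.484)
descriptiveStats <- function(values, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L)
    stop("insufficient data: descriptive statistics need n >= 2, got ", n)
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  data.frame(n = n, min = min(values), max = max(values), mean = m,
             sd = s, median = stats::median(values),
             ci_lo = m - half, ci_hi = m + half)
}

#' Power-function transform
#'
#' Monotone normalizing map \eqn{v \to max(v, floor)^{power}} applied to
#' right-skewed volume data before ANOVA. The floor (default 1e-6 mm^3)
#' keeps near-zero volumes (reported as "<0.001") finite and stabilizes the
#' Shapiro-Wilk test on ties.
#'
#' @param values non-negative numeric vector.
#' @param power exponent in (0, 1].
#' @param floor lower clamp applied before exponentiation (mm^3).
#' @return Transformed vector (NA preserved).
#' @export
powerTransform <- function(values, power, floor = 1e-6) {
  if (power <= 0) stop("power must be > 0")
  if (any(values < 0, na.rm = TRUE))
    stop("domain error: negative values cannot be power-transformed")
  pmax(values, floor)^power
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the Royston (AS R94) implementation in
#' \code{stats::shapiro.test}, with the 3 <= n <= 5000 domain made
#' explicit.
#'
#' @param values numeric vector (NA dropped).
#' @return A list with \code{W} and \code{p}.
#' @export
shapiroWilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("domain error: Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = unname(ht$p.value))
}

#' Select a normalizing power over a grid
#'
#' Searches a grid of exponents for the power transform that maximizes the
#' minimum per-group Shapiro-Wilk p-value. Exponents whose minimum p is
#' within \code{tieTol} of the best are treated as ties and resolved toward
#' the larger exponent (the milder transform). A user-fixed power bypasses
#' the search.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @param grid candidate exponents, default \code{seq(0.025, 1, 0.025)}.
#' @param fixed optional fixed power returned as-is (with its per-group
#'   p-values).
#' @param floor transform floor, see \code{\link{powerTransform}}.
#' @param tieTol tie tolerance on the minimum p-value, default 0.05.
#' @return A list with \code{power}, \code{pValues} (per-group
#'   Shapiro-Wilk p at the selected power), and \code{allNormal} (TRUE when
#'   min p > 0.05; when no grid exponent achieves this a warning is issued
#'   and the best exponent is still returned).
#' @export
selectPower <- function(groups, grid = seq(0.025, 1, by = 0.025),
                        fixed = NULL, floor = 1e-6, tieTol = 0.05) {
  if (length(groups) < 2L) stop("at least 2 groups are required")
  swp <- function(power) vapply(groups, function(g)
    shapiroWilk(powerTransform(g, power, floor))$p, numeric(1))
  if (!is.null(fixed)) {
    pv <- swp(fixed)
    return(list(power = fixed, pValues = pv,
                allNormal = min(pv) > 0.05))
  }
  pmat <- vapply(grid, function(pw) swp(pw), numeric(length(groups)))
  minp <- if (length(groups) == 1L) pmat else apply(pmat, 2, min)
  best <- max(minp)
  sel <- max(which(minp >= best - tieTol))  # mildest transform among ties
  pv <- pmat[, sel]
  names(pv) <- names(groups)
  if (best <= 0.05)
    warning("no grid exponent renders all groups normal (best min ",
            "Shapiro-Wilk p = ", signif(best, 3), ")")
  list(power = grid[sel], pValues = pv, allNormal = minp[sel] > 0.05)
}

#' One-way ANOVA
#'
#' Standard fixed-effects one-way analysis of variance on (transformed)
#' group samples, via \code{stats::aov}.
#'
#' @param groups list of numeric vectors, k >= 2 groups with n >= 2 each
#'   (NA dropped).
#' @return An \linkS4class{AnovaResult}.
#' @export
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3, df (2, 6)
oneWayAnova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop("at least 2 groups are required")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs n >= 2")
  df <- data.frame(
    value = unlist(groups),
    group = factor(rep(seq_along(groups),
                       vapply(groups, length, 1L))))
  if (stats::var(df$value) == 0)
    stop("undefined F: zero variance within and between groups")
  tab <- summary(stats::aov(value ~ group, data = df))[[1]]
  Fv <- tab[1, "F value"]
  p <- tab[1, "Pr(>F)"]
  if (!is.finite(Fv)) {  # zero within-group variance, groups differ
    Fv <- Inf
    p <- .Machine$double.xmin
  }
  new("AnovaResult", F = Fv, dfBetween = as.integer(tab[1, "Df"]),
      dfWithin = as.integer(tab[2, "Df"]), p = min(1, max(p, 0)) )
}

#' Tukey HSD post-hoc test
#'
#' All-pairs comparison of (transformed) group means with family-wise
#' adjustment from the studentized range distribution (Tukey-Kramer for
#' unequal n), via \code{stats::TukeyHSD}.
#'
#' @param groups list of numeric vectors (optionally named), as in
#'   \code{\link{oneWayAnova}}.
#' @param alpha family-wise level used for flagging, default 0.05.
#' @return A \linkS4class{TukeyResult}; \code{pairs} has one row per
#'   unordered pair with the difference of means (group2 - group1) on the
#'   analysis scale and the adjusted p-value.
#' @export
tukeyHsd <- function(groups, alpha = 0.05) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  labs <- names(groups)
  if (is.null(labs)) labs <- as.character(seq_along(groups))
  df <- data.frame(
    value = unlist(groups),
    group = factor(rep(labs, vapply(groups, length, 1L)), levels = labs))
  hsd <- stats::TukeyHSD(stats::aov(value ~ group, data = df))$group
  cmp <- strsplit(rownames(hsd), "-", fixed = TRUE)
  pairs <- data.frame(
    group1 = vapply(cmp, `[`, "", 2),
    group2 = vapply(cmp, `[`, "", 1),
    difference = unname(hsd[, "diff"]),
    p_adj = unname(hsd[, "p adj"]),
    stringsAsFactors = FALSE)
  pairs$significant <- pairs$p_adj < alpha
  new("TukeyResult", pairs = pairs, alpha = alpha)
}

#' A-priori sample size (normal approximation)
#'
#' Per-group sample size for a two-group mean comparison at type-I error
#' \code{alpha} (two-sided) and power \code{power}: the standardized effect
#' size is d = meanDifference / sd (reported rounded to two decimals) and
#' n per group is \eqn{ceil(2 (z_{1-\alpha/2} + z_{1-\beta})^2 / d^2)}
#' using the unrounded d.
#'
#' @param meanDifference expected mean difference (same units as
#'   \code{sd}).
#' @param sd standard deviation.
#' @param alpha two-sided type-I error, default 0.05.
#' @param power target power (1 - beta), default 0.8.
#' @return A list with \code{d} (rounded to 2 decimals), \code{dExact},
#'   and \code{nPerGroup}.
#' @export
#' @examples
#' sampleSizeNormalApprox(0.006, 0.007)  # d = 0.86, n = 22
sampleSizeNormalApprox <- function(meanDifference, sd, alpha = 0.05,
                                   power = 0.8) {
  if (sd <= 0) stop("sd must be positive")
  d <- meanDifference / sd
  if (d == 0) stop("divergence: zero effect size, n is unbounded")
  n <- ceiling(2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 /
                 d^2)
  list(d = round(d, 2), dExact = d, nPerGroup = as.integer(n))
}

#' Transform-then-ANOVA analysis of one endpoint
#'
#' The complete group comparison for one volumetric endpoint: power
#' transform (fixed exponent or grid-selected), per-group Shapiro-Wilk
#' gating, one-way ANOVA, and Tukey HSD on the transformed scale.
#'
#' @param groups list of numeric vectors (optionally named by treatment);
#'   NA values (e.g. undefined dAV) are dropped per group.
#' @param power a fixed exponent, or \code{"auto"} for the grid search of
#'   \code{\link{selectPower}}.
#' @param alpha significance level, default 0.05.
#' @param floor transform floor, see \code{\link{powerTransform}}.
#' @return A list with \code{power}, \code{shapiroP} (per-group),
#'   \code{anova} (\linkS4class{AnovaResult}), \code{tukey}
#'   (\linkS4class{TukeyResult}).
#' @export
analyzeEndpoint <- function(groups, power = "auto", alpha = 0.05,
                            floor = 1e-6) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sel <- if (identical(power, "auto"))
    selectPower(groups, floor = floor)
  else selectPower(groups, fixed = power, floor = floor)
  tg <- lapply(groups, powerTransform, power = sel$power, floor = floor)
  list(power = sel$power, shapiroP = sel$pValues,
       anova = oneWayAnova(tg), tukey = tukeyHsd(tg, alpha = alpha))
}
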