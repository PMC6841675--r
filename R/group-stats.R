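## Classical group statistics, computed from their defining formulas so
## every downstream number is auditable: two-sample Student t, Fisher's
## exact test (probability-mass rule) and the Pearson chi-square on 2x2
## tables. One-way ANOVA + Tukey HSD go through stats::aov/TukeyHSD.

.as2x2 <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2L, 2L))) stop("a 2 x 2 table is required")
  if (any(t < 0) || any(t != round(t)))
    stop("counts must be non-negative integers")
  if (sum(t) == 0L) stop("empty table: all counts are zero")
  storage.mode(t) <- "double"
  t
}

#' Two-sample Student t-test from the pooled-variance formula
#'
#' Equal-variance (pooled) by default, as in the classical Student test;
#' Welch's unequal-variance form by flag. Two-sided p-value. With zero
#' pooled variance the test degenerates: equal means give `t = 0, p = 1`,
#' unequal means an infinite-t marker (`t = +/- Inf, p = 0`).
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param welch use Welch's unequal-variance form.
#' @return List with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
studentT <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  if (welch) {
    vx <- var(x) / nx; vy <- var(y) / ny
    se2 <- vx + vy
    df <- se2^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- nx + ny - 2
  }
  if (se2 == 0) {
    if (mx == my)
      return(list(t = 0, df = df, p = 1, mean_x = mx, mean_y = my))
    return(list(t = sign(mx - my) * Inf, df = df, p = 0,
                mean_x = mx, mean_y = my))
  }
  tt <- (mx - my) / sqrt(se2)
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df), mean_x = mx, mean_y = my)
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Exact two-sided p by the probability-mass rule: the sum of
#' hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table.
#' Odds ratio is the sample `(a d) / (b c)` with zero-cell conventions:
#' `Inf` when the denominator alone vanishes (including the degenerate
#' perfect-association table with `b = c = 0`), `NaN` when the ratio is
#' otherwise 0/0.
#'
#' @param t 2 x 2 matrix of counts (rows = condition, cols = outcome).
#' @return List with `odds_ratio` and `p`.
#' @examples
#' fisherExact2x2(matrix(c(12, 3, 5, 9), 2))
#' @export
fisherExact2x2 <- function(t) {
  t <- .as2x2(t)
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, r1, r2, c1)
  pObs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0 || (b == 0 && c == 0)) Inf else NaN
  list(odds_ratio = or, p = p)
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' `sum((O - E)^2 / E)` against chi-square with 1 df; optional Yates
#' continuity correction (off by default). All expected counts must be
#' positive.
#'
#' @param t 2 x 2 matrix of counts.
#' @param correction apply Yates' continuity correction.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chiSquare2x2 <- function(t, correction = FALSE) {
  t <- .as2x2(t)
  E <- outer(rowSums(t), colSums(t)) / sum(t)
  if (any(E == 0))
    stop("zero expected count: chi-square statistic undefined")
  dev <- abs(t - E)
  if (correction) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  list(statistic = stat, df = 1L, p = pchisq(stat, 1L, lower.tail = FALSE),
       expected = E)
}

#' Compare central-window signal between two groups of profiles
#'
#' Per profile, the mean intensity within `+/- centralHalfwidth` um of the
#' center is computed; the per-meristem means of the two groups are then
#' compared with the two-sided Student t-test (equal-variance by default).
#'
#' @param groupA,groupB lists of [RadialProfile-class] (>= 2 each).
#' @param cfg a [ProfileConfig-class] (uses `centralHalfwidth`).
#' @param welch use Welch's t-test instead of the pooled form.
#' @return List with `mean_a`, `mean_b` (group means of the per-profile
#'   central means), `t`, `df`, `p`, and the per-profile means
#'   `central_means_a` / `central_means_b`.
#' @export
centralWindowTest <- function(groupA, groupB, cfg = profileConfig(),
                              welch = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 profiles")
  ma <- vapply(groupA, centralMean, 0, halfwidth = cfg@centralHalfwidth)
  mb <- vapply(groupB, centralMean, 0, halfwidth = cfg@centralHalfwidth)
  tt <- studentT(ma, mb, welch = welch)
  list(mean_a = mean(ma), mean_b = mean(mb), t = tt$t, df = tt$df,
       p = tt$p, central_means_a = ma, central_means_b = mb)
}

#' One-way ANOVA with Tukey HSD across condition/time groups
#'
#' Used for central-zone signal time courses: per-meristem central means
#' grouped by condition x time are compared by one-way analysis of
#' variance, followed by Tukey's honest significant difference pairwise
#' comparisons (studentized range).
#'
#' @param groups named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @return List with `F`, `df` (between, within), `p`, and `tukey` (a
#'   data.frame of pairwise differences with adjusted p-values).
#' @export
centralZoneTimecourse <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("each group needs at least 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)),
                   levels = names(groups)))
  if (var(df$value) == 0)  # all observations identical: F := 0, p := 1
    return(list(F = 0, df = c(length(groups) - 1L,
                              nrow(df) - length(groups)),
                p = 1, tukey = NULL))
  fit <- aov(value ~ group, data = df)
  s <- summary(fit)[[1L]]
  tk <- as.data.frame(TukeyHSD(fit)$group)
  names(tk) <- c("diff", "lwr", "upr", "p_adj")
  tk$comparison <- rownames(tk)
  rownames(tk) <- NULL
  list(F = s[["F value"]][1L], df = s[["Df"]], p = s[["Pr(>F)"]][1L],
       tukey = tk[, c("comparison", "diff", "lwr", "upr", "p_adj")])
}
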