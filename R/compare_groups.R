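#' Exact Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U with a tie-aware exact p-value by enumeration of
#' all group assignments when the number of splits is small (total n <= 12
#' in the intended use; the implementation enumerates whenever
#' `choose(n+m, n)` <= `max_enumeration`), and a tie-corrected normal
#' approximation with continuity correction otherwise. U is reported for the
#' first sample (`U = #\{x_i > y_j\} + 0.5 #\{x_i = y_j\}`); two-sided
#' p-values count splits at least as far from the null center `nm/2`.
#'
#' @param x,y numeric samples.
#' @param max_enumeration largest number of splits to enumerate exactly.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, max_enumeration = 2e5) {
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  u_from_rsum <- function(rs) rs - n * (n + 1) / 2
  U <- u_from_rsum(sum(r[seq_len(n)]))
  center <- n * m / 2
  if (choose(n + m, n) <= max_enumeration) {
    splits <- combn(n + m, n)
    rsums <- colSums(matrix(r[splits], nrow = n))
    u_all <- u_from_rsum(rsums)
    p <- mean(abs(u_all - center) >= abs(U - center) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * m / 12 *
      ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    z <- (abs(U - center) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test with exact p by enumeration of all
#' 2^n sign assignments (tie-aware, zero differences dropped) for n <= 20,
#' normal approximation beyond.
#'
#' @param x,y paired numeric samples of equal length.
#' @return list with `W` (sum of positive-difference ranks), `p`, `method`.
#' @export
wilcoxon_signed <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must match in length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, p = 1, method = "degenerate (all ties)"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  center <- n * (n + 1) / 4
  if (n <= 20) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- mean(abs(w_all - center) >= abs(W - center) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(W - center) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- "normal approximation"
  }
  list(W = W, p = p, method = method)
}

#' Assumption-driven group comparison
#'
#' Reproduces the test-selection procedure of the behavioral analyses:
#' normality is checked per group with Shapiro-Wilk and variance homogeneity
#' with Levene's test (median-centered); when both hold a parametric test is
#' used (one-way ANOVA between subjects, repeated-measures ANOVA within
#' subjects, or a t test for two levels, Welch-corrected when variances are
#' unequal), otherwise the nonparametric counterpart (Kruskal-Wallis,
#' Friedman, Mann-Whitney U, or Wilcoxon signed-rank). Post hoc pairwise
#' comparisons are Benjamini-Hochberg adjusted. The branch taken is a pure
#' function of the assumption p-values and is recorded in the result.
#'
#' @param samples named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param paired are the groups repeated measures on the same subjects?
#'   Requires equal lengths with subjects aligned across groups.
#' @param assumption_alpha significance level for the assumption checks.
#' @param force `NULL` for automatic selection, or `"parametric"` /
#'   `"nonparametric"` to force a branch.
#' @return object of class `group_comparison`: list with `test_name`,
#'   `statistic`, `p`, `effect_size`, `assumptions` (Shapiro and Levene
#'   p-values), `path`, and for >= 3 groups a `posthoc` data.frame with
#'   BH-adjusted pairwise p-values.
#' @export
compare_groups <- function(samples, paired = FALSE, assumption_alpha = 0.05,
                           force = NULL) {
  if (!is.list(samples) || length(samples) < 2) {
    stop("`samples` must be a list of >= 2 groups", call. = FALSE)
  }
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  sizes <- lengths(samples)
  if (any(sizes < 3)) stop("each group needs n >= 3", call. = FALSE)
  if (paired && length(unique(sizes)) != 1) {
    stop("paired comparison requires equal group sizes", call. = FALSE)
  }
  k <- length(samples)

  shapiro_p <- vapply(samples, function(g) {
    if (sd(g) == 0) return(0)  # constant data: treat as non-normal
    shapiro.test(g)$p.value
  }, numeric(1))
  stacked <- data.frame(
    value = unlist(samples, use.names = FALSE),
    group = factor(rep(names(samples), sizes))
  )
  levene_p <- if (any(vapply(samples, sd, numeric(1)) == 0)) 1 else {
    car::leveneTest(value ~ group, data = stacked, center = median)[1, "Pr(>F)"]
  }
  normal_ok <- all(shapiro_p > assumption_alpha)
  var_ok <- levene_p > assumption_alpha
  parametric <- if (!is.null(force)) {
    match.arg(force, c("parametric", "nonparametric")) == "parametric"
  } else {
    normal_ok && (var_ok || (k == 2 && !paired))  # two-sample: Welch rescue
  }

  n_tot <- sum(sizes)
  if (parametric) {
    if (k == 2) {
      tt <- t.test(samples[[1]], samples[[2]], paired = paired,
                   var.equal = !paired && var_ok)
      sp <- sqrt(((sizes[1] - 1) * var(samples[[1]]) +
                  (sizes[2] - 1) * var(samples[[2]])) / (n_tot - 2))
      res <- list(
        test_name = if (paired) "paired t" else if (var_ok) "t" else "Welch t",
        statistic = unname(tt$statistic), p = tt$p.value,
        effect_size = (mean(samples[[1]]) - mean(samples[[2]])) / sp
      )
    } else if (!paired) {
      fit <- aov(value ~ group, data = stacked)
      s <- summary(fit)[[1]]
      res <- list(
        test_name = "one-way ANOVA",
        statistic = s[["F value"]][1], p = s[["Pr(>F)"]][1],
        effect_size = s[["Sum Sq"]][1] / sum(s[["Sum Sq"]])
      )
    } else {
      stacked$subject <- factor(rep(seq_len(sizes[1]), times = k))
      fit <- aov(value ~ group + Error(subject), data = stacked)
      s <- summary(fit)[["Error: Within"]][[1]]
      res <- list(
        test_name = "repeated-measures ANOVA",
        statistic = s[["F value"]][1], p = s[["Pr(>F)"]][1],
        effect_size = s[["Sum Sq"]][1] / sum(s[["Sum Sq"]])
      )
    }
  } else {
    if (k == 2 && !paired) {
      mw <- mann_whitney(samples[[1]], samples[[2]])
      res <- list(
        test_name = "Mann-Whitney U", statistic = mw$U, p = mw$p,
        effect_size = 1 - 2 * mw$U / prod(sizes)  # rank-biserial
      )
    } else if (k == 2) {
      ws <- wilcoxon_signed(samples[[1]], samples[[2]])
      res <- list(
        test_name = "Wilcoxon signed-rank", statistic = ws$W, p = ws$p,
        effect_size = 4 * abs(ws$W / (sizes[1] * (sizes[1] + 1) / 2) - 0.5) - 1
      )
    } else if (!paired) {
      kw <- kruskal.test(value ~ group, data = stacked)
      res <- list(
        test_name = "Kruskal-Wallis", statistic = unname(kw$statistic),
        p = kw$p.value,
        effect_size = (unname(kw$statistic) - k + 1) / (n_tot - k)  # epsilon^2
      )
    } else {
      mat <- do.call(cbind, samples)
      fr <- friedman.test(mat)
      res <- list(
        test_name = "Friedman", statistic = unname(fr$statistic),
        p = fr$p.value,
        effect_size = unname(fr$statistic) / (sizes[1] * (k - 1))  # Kendall W
      )
    }
  }

  posthoc <- NULL
  if (k >= 3) {
    pairs <- combn(names(samples), 2)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      a <- samples[[pairs[1, j]]]; b <- samples[[pairs[2, j]]]
      if (parametric) {
        tt <- t.test(a, b, paired = paired, var.equal = !paired && var_ok)
        data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                   test = if (paired) "paired t" else "t",
                   statistic = unname(tt$statistic), p = tt$p.value)
      } else if (paired) {
        ws <- wilcoxon_signed(a, b)
        data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                   test = "Wilcoxon signed-rank", statistic = ws$W, p = ws$p)
      } else {
        mw <- mann_whitney(a, b)
        data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                   test = "Mann-Whitney U", statistic = mw$U, p = mw$p)
      }
    })
    posthoc <- do.call(rbind, rows)
    posthoc$p_adj <- p.adjust(posthoc$p, method = "BH")
  }

  structure(
    c(res, list(
      assumptions = list(shapiro_p = shapiro_p, levene_p = levene_p),
      path = if (parametric) "parametric" else "nonparametric",
      paired = paired, posthoc = posthoc
    )),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s (%s path): statistic = %.4g, p = %.4g, effect size = %.3f\n",
    x$test_name, x$path, x$statistic, x$p, x$effect_size
  ))
  if (!is.null(x$posthoc)) {
    cat("  post hoc (BH-adjusted):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
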