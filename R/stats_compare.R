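# Treatment-comparison statistics: paired two-tailed t-test, one-way ANOVA
# with Tukey HSD post hoc, standard errors. Inference is delegated to base
# R (t.test, aov/TukeyHSD); this layer adds the degenerate-input policy
# small-n microcosm data make reachable, and applies Tukey only when the
# omnibus test is significant.

#' Standard error of the mean
#'
#' @param x Numeric sample with at least 2 observations.
#' @return `sd(x) / sqrt(n)`.
#' @examples
#' standard_error(c(1, 3))  # 1
#' @export
standard_error <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("standard error requires n >= 2")
  if (anyNA(x)) stop("missing values in sample")
  stats::sd(x) / sqrt(length(x))
}

.comparison_result <- function(groups, statistic, p_value, method,
                               degenerate = FALSE, pairwise = NULL,
                               df = NULL, alpha = 0.05) {
  structure(
    list(groups = groups, statistic = statistic, p_value = p_value,
         df = df, method = method, degenerate = degenerate,
         pairwise = pairwise, alpha = alpha),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %s, p = %s%s\n",
              x$method,
              format(x$statistic, digits = 4),
              format(x$p_value, digits = 4),
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  if (!is.null(x$pairwise) && nrow(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Two-tailed paired t-test
#'
#' Classical paired t-test on index-matched samples. Zero-variance
#' differences are flagged rather than propagating NaN: identical samples
#' return `t = 0, p = 1`; a constant non-zero shift returns an infinite
#' statistic with `p = NA` and `degenerate = TRUE`.
#'
#' @param a,b Numeric samples of equal length >= 2, paired by index.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05).
#' @return A `comparison_result` with `statistic` (t), `p_value`, `df`,
#'   `degenerate`, and `significant`.
#' @export
paired_t_test <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2L) stop("paired t-test requires n >= 2")
  if (anyNA(a) || anyNA(b)) stop("missing values in samples")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      res <- .comparison_result(c("a", "b"), statistic = 0, p_value = 1,
                                method = "paired t-test",
                                degenerate = TRUE, df = length(d) - 1L,
                                alpha = alpha)
    } else {
      res <- .comparison_result(c("a", "b"),
                                statistic = sign(mean(d)) * Inf,
                                p_value = NA_real_,
                                method = "paired t-test",
                                degenerate = TRUE, df = length(d) - 1L,
                                alpha = alpha)
    }
    res$significant <- FALSE
    return(res)
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  res <- .comparison_result(c("a", "b"), statistic = unname(tt$statistic),
                            p_value = tt$p.value, method = "paired t-test",
                            df = unname(tt$parameter), alpha = alpha)
  res$significant <- res$p_value < alpha
  res
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Single-factor ANOVA across treatment groups. When (and only when) the
#' omnibus F-test is significant at `alpha`, Tukey honestly-significant-
#' difference adjusted p-values are computed for every pair of groups.
#' All-identical data are flagged degenerate and returned as `F = 0,
#' p = 1`.
#'
#' @param groups Named list of numeric samples, each with n >= 2; at least
#'   2 groups.
#' @param alpha Significance level (default 0.05).
#' @return A `comparison_result` with `statistic` (F), `p_value`, `df`
#'   (numerator, denominator), and — when the omnibus test is significant —
#'   a `pairwise` data frame (`group_a`, `group_b`, `diff`, `adjusted_p`,
#'   `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs n >= 2 (offending: ",
         paste(names(groups)[sizes < 2L], collapse = ", "), ")")
  }
  y <- unlist(groups, use.names = FALSE)
  if (anyNA(y)) stop("missing values in groups")
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  if (stats::sd(y) == 0) {
    return(.comparison_result(names(groups), statistic = 0, p_value = 1,
                              method = "one-way ANOVA",
                              degenerate = TRUE, df = c(df1, df2),
                              alpha = alpha))
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  fstat <- tab[["F value"]][1]
  pval <- tab[["Pr(>F)"]][1]
  pairwise <- NULL
  if (isTRUE(pval < alpha)) {
    th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    pairs <- do.call(rbind, strsplit(rownames(th), "-", fixed = TRUE))
    pairwise <- data.frame(
      group_a = pairs[, 1], group_b = pairs[, 2],
      diff = unname(th[, "diff"]),
      adjusted_p = unname(th[, "p adj"]),
      significant = unname(th[, "p adj"]) < alpha,
      stringsAsFactors = FALSE
    )
  }
  .comparison_result(names(groups), statistic = fstat, p_value = pval,
                     method = "one-way ANOVA", pairwise = pairwise,
                     df = c(df1, df2), alpha = alpha)
}
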