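#' Kruskal-Wallis omnibus test with Dunn's pairwise post hoc
#'
#' Rank-based comparison of a value across groups (e.g. per-plaque transcript
#' densities across the three proximity zones). The omnibus H statistic uses
#' midranks with tie correction (via [stats::kruskal.test()]); pairwise
#' contrasts use Dunn's z on mean ranks with the same tie correction.
#' P-values over all pairs are adjusted with Holm's method by default
#' (Bonferroni available).
#'
#' @param data Data frame.
#' @param value,group Columns (tidy-eval) holding the observations and the
#'   grouping variable.
#' @param p_adjust `"holm"` (default) or `"bonferroni"`.
#' @return An object of class `kruskal_dunn`; see [tidy()]/[glance()]
#'   methods.
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                 g = rep(c("a", "b", "c"), each = 3))
#' glance(kruskal_dunn(d, v, g))   # H = 7.2
#' @export
kruskal_dunn <- function(data, value, group, p_adjust = c("holm", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- factor(g[keep])
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 groups.")
  if (any(sizes == 0)) {
    abort(sprintf("group(s) with no observations: %s",
                  paste(names(sizes)[sizes == 0], collapse = ", ")))
  }
  kw <- kruskal.test(v, g)
  # Dunn's z: mean midranks, pooled tie correction
  n <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    tibble(comparison = paste(a, b, sep = " - "), z = z,
           p_raw = 2 * pnorm(-abs(z)))
  })
  pw$p_adj <- p.adjust(pw$p_raw, method = p_adjust)
  structure(list(
    H = unname(kw$statistic), df = unname(kw$parameter),
    p_value = kw$p.value, pairwise = pw, n = n,
    group_sizes = sizes, p_adjust = p_adjust
  ), class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$H, x$df, x$p_value, x$n))
  cat(sprintf("Dunn pairwise (%s-adjusted):\n", x$p_adjust))
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' @rdname kruskal_dunn
#' @param x A `kruskal_dunn` object.
#' @param ... Unused.
#' @export
tidy.kruskal_dunn <- function(x, ...) {
  dplyr::mutate(x$pairwise, method = paste0("dunn-", x$p_adjust))
}

#' @rdname kruskal_dunn
#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble(statistic = x$H, df = x$df, p.value = x$p_value, n = x$n,
         method = "kruskal-wallis")
}

#' Spearman correlation with a linear-fit overlay
#'
#' Rank correlation between two paired measurements (e.g. per-section T-cell
#' frequency vs plaque burden), with an ordinary least-squares line and
#' confidence band for plotting. The p-value is exact for n <= 9 without
#' ties, otherwise the t approximation is used.
#'
#' @param data Data frame with at least 4 complete pairs.
#' @param x,y Columns (tidy-eval).
#' @return An object of class `spearman_fit`; see [tidy()]/[glance()].
#' @examples
#' d <- data.frame(a = 1:5, b = c(1, 3, 2, 5, 4))
#' glance(correlate(d, a, b))   # rho = 0.8
#' @export
correlate <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 4) abort("need at least 4 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("zero variance in one of the vectors: rho is undefined.")
  }
  has_ties <- anyDuplicated(xv) > 0 || anyDuplicated(yv) > 0
  ct <- suppressWarnings(
    cor.test(xv, yv, method = "spearman", exact = n <= 9 && !has_ties)
  )
  fit <- lm(yv ~ xv)
  ci <- stats::confint(fit)
  structure(list(
    rho = unname(ct$estimate), p_value = ct$p.value, n = n,
    exact = n <= 9 && !has_ties,
    fit = fit,
    intercept = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2]),
    conf_low = ci[2, 1], conf_high = ci[2, 2],
    data = tibble(x = xv, y = yv)
  ), class = "spearman_fit")
}

#' @export
print.spearman_fit <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4g, p = %.4g (n = %d, %s p)\n",
              x$rho, x$p_value, x$n, if (x$exact) "exact" else "approximate"))
  cat(sprintf("linear fit: y = %.4g + %.4g x (slope 95%% CI %.4g..%.4g)\n",
              x$intercept, x$slope, x$conf_low, x$conf_high))
  invisible(x)
}

#' @rdname correlate
#' @param x A `spearman_fit` object (for the methods).
#' @param ... Unused.
#' @export
tidy.spearman_fit <- function(x, ...) {
  ci <- stats::confint(x$fit)
  tibble(
    term = c("(Intercept)", "slope"),
    estimate = unname(stats::coef(x$fit)),
    conf.low = ci[, 1], conf.high = ci[, 2]
  )
}

#' @rdname correlate
#' @export
glance.spearman_fit <- function(x, ...) {
  tibble(rho = x$rho, p.value = x$p_value, n = x$n, exact = x$exact)
}
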