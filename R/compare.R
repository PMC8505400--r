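#' Per-phase descriptive statistics
#'
#' Arithmetic mean and sample (n-1) standard deviation of every parameter
#' column, by phase.
#'
#' @param samples Wide sample table (`site_id`, `phase`, parameter columns).
#' @return Tibble with columns `code`, `phase`, `n`, `mean`, `sd`.
#' @export
phase_describe <- function(samples) {
  param_cols <- setdiff(names(samples), c("site_id", "phase", "collected"))
  out <- list()
  for (ph in unique(samples$phase)) {
    sub <- samples[samples$phase == ph, param_cols, drop = FALSE]
    if (nrow(sub) < 2)
      stop("insufficient data: phase ", ph, " has fewer than 2 samples")
    out[[ph]] <- tibble::tibble(
      code = param_cols,
      phase = ph,
      n = unname(vapply(sub, function(x) sum(!is.na(x)), double(1))),
      mean = unname(vapply(sub, function(x) mean(x, na.rm = TRUE),
                           double(1))),
      sd = unname(vapply(sub, function(x) stats::sd(x, na.rm = TRUE),
                         double(1))))
  }
  do.call(rbind, out)
}

#' Percent change between two statistics
#'
#' `(b - a) / a * 100`, the change from a baseline phase A to phase B.
#'
#' @param a Baseline value(s); must be non-zero.
#' @param b Comparison value(s).
#' @return Percent change, vectorised.
#' @examples
#' percent_change(4.87, 7.29)   # +49.69% (dissolved oxygen, lockdown)
#' @export
percent_change <- function(a, b) {
  if (any(a == 0)) stop("undefined change: baseline statistic is zero")
  (b - a) / a * 100
}

#' Parameter-wise comparison of two phases
#'
#' Means and SDs of every parameter in each phase plus the percent change
#' of both statistics from phase A to phase B. Percent changes are computed
#' on unrounded statistics.
#'
#' @param samples Wide sample table covering both phases.
#' @param phase_a,phase_b Phase labels (A is the baseline).
#' @return Tibble with columns `code`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `mean_diff_pct`, `sd_diff_pct`.
#' @export
compare_phases <- function(samples, phase_a, phase_b) {
  d <- phase_describe(samples[samples$phase %in% c(phase_a, phase_b), ])
  a <- d[d$phase == phase_a, ]
  b <- d[d$phase == phase_b, ]
  b <- b[match(a$code, b$code), ]
  tibble::tibble(
    code = a$code,
    mean_a = a$mean, sd_a = a$sd,
    mean_b = b$mean, sd_b = b$sd,
    mean_diff_pct = ifelse(a$mean != 0, (b$mean - a$mean) / a$mean * 100, NA),
    sd_diff_pct = ifelse(a$sd != 0, (b$sd - a$sd) / a$sd * 100, NA))
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pearson correlation matrix with significance stars
#'
#' All pairwise Pearson correlations among parameter columns, with
#' two-sided p-values from the t-distribution on n-2 degrees of freedom
#' and stars at p < 0.05 (*), < 0.01 (**), < 0.001 (***). Pairs involving
#' a zero-variance parameter are reported with `NA` correlation.
#'
#' @param samples Wide sample table (optionally pre-filtered to one phase).
#' @param phase Optional phase label to filter on.
#' @return Tibble with columns `code_x`, `code_y`, `n`, `r`, `p`, `stars`,
#'   covering all ordered pairs (the matrix is symmetric; the diagonal has
#'   r = 1).
#' @export
correlation_matrix <- function(samples, phase = NULL) {
  if (!is.null(phase)) samples <- samples[samples$phase == phase, ]
  param_cols <- setdiff(names(samples), c("site_id", "phase", "collected"))
  m <- as.matrix(samples[, param_cols, drop = FALSE])
  if (nrow(m) < 3) stop("insufficient data: need >= 3 samples for correlation")
  out <- list(); k <- 0L
  for (x in param_cols) for (y in param_cols) {
    k <- k + 1L
    ok <- stats::complete.cases(m[, c(x, y)])
    n <- sum(ok)
    if (stats::sd(m[ok, x]) == 0 || stats::sd(m[ok, y]) == 0) {
      r <- NA_real_; p <- NA_real_
    } else if (x == y) {
      r <- 1; p <- 0
    } else {
      ct <- stats::cor.test(m[ok, x], m[ok, y], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    out[[k]] <- tibble::tibble(code_x = x, code_y = y, n = n, r = r, p = p,
                               stars = ifelse(is.na(p), "",
                                              significance_stars(p)))
  }
  do.call(rbind, out)
}

#' One-way ANOVA across phases with Fisher's LSD post-hoc
#'
#' Fixed-effects one-way analysis of variance of one parameter across the
#' sampling phases, followed by unadjusted pairwise least-significant-
#' difference t-tests using the pooled within-group mean square
#' (classic Fisher procedure; decisions at `alpha`).
#'
#' @param samples Wide sample table covering the phases to compare.
#' @param code Parameter column to analyse.
#' @param alpha Significance level for the LSD decisions (default 0.05).
#' @return A list of class `wq_anova`: `code`, `F`, `p`, `df` (between,
#'   within), and `lsd_pairs`, a tibble with one row per phase pair
#'   (`phase_a`, `phase_b`, `diff`, `se`, `t`, `p`, `significant`).
#' @export
anova_lsd <- function(samples, code, alpha = 0.05) {
  stopifnot(code %in% names(samples))
  d <- data.frame(y = samples[[code]], g = factor(samples$phase))
  d <- d[!is.na(d$y), ]
  n_per <- table(d$g)
  if (any(n_per < 2))
    stop("insufficient data: every phase needs >= 2 samples for ANOVA")
  fit <- stats::lm(y ~ g, data = d)
  an <- stats::anova(fit)
  fval <- an$`F value`[1]
  pval <- an$`Pr(>F)`[1]
  mse <- an$`Mean Sq`[2]
  df_w <- an$Df[2]
  lev <- levels(d$g)
  means <- tapply(d$y, d$g, mean)
  pairs <- utils::combn(lev, 2)
  lsd <- tibble::tibble(
    phase_a = pairs[1, ], phase_b = pairs[2, ],
    diff = as.numeric(means[pairs[2, ]] - means[pairs[1, ]]),
    se = as.numeric(sqrt(mse * (1 / n_per[pairs[1, ]] +
                                  1 / n_per[pairs[2, ]]))))
  lsd$t <- lsd$diff / lsd$se
  lsd$p <- 2 * stats::pt(-abs(lsd$t), df_w)
  lsd$significant <- lsd$p < alpha
  structure(list(code = code, F = fval, p = pval,
                 df = c(between = an$Df[1], within = df_w),
                 lsd_pairs = lsd),
            class = "wq_anova")
}

#' @export
print.wq_anova <- function(x, ...) {
  cat("One-way ANOVA for", x$code, ": F(", x$df[1], ",", x$df[2], ") =",
      round(x$F, 3), ", p =", signif(x$p, 3), "\n")
  print(x$lsd_pairs)
  invisible(x)
}

#' ANOVA table for every parameter
#'
#' Runs [anova_lsd()] on each parameter column and collects the omnibus
#' results into one tibble.
#'
#' @inheritParams anova_lsd
#' @return Tibble with columns `code`, `F`, `p`, `n_significant_pairs`.
#' @export
anova_table <- function(samples, alpha = 0.05) {
  param_cols <- setdiff(names(samples), c("site_id", "phase", "collected"))
  rows <- lapply(param_cols, function(code) {
    a <- anova_lsd(samples, code, alpha)
    tibble::tibble(code = code, F = a$F, p = a$p,
                   n_significant_pairs = sum(a$lsd_pairs$significant))
  })
  do.call(rbind, rows)
}
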