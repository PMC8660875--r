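# Group-comparison statistics for demographic, fluency and creativity
# summaries, recomputable either from raw per-participant scores or from
# published group summaries (mean, SD, n).

#' A group summary (mean, SD, n)
#'
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param n participant count (>= 2).
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  x <- as.numeric(x)
  stopifnot(length(x) >= 2L)
  group_summary(mean(x), sd(x), length(x))
}

# Pooled-variance or Welch two-sample t from summaries.
t_from_summaries <- function(sa, sb, var_equal = TRUE) {
  diff <- sa$mean - sb$mean
  if (var_equal) {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
    if (sp2 <= 0) stop_stage("stats", "zero variance in both groups")
    t <- diff / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  } else {
    va <- sa$sd^2 / sa$n
    vb <- sb$sd^2 / sb$n
    if (va + vb <= 0) stop_stage("stats", "zero variance in both groups")
    t <- diff / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  sp <- sqrt(((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / (sa$n + sb$n - 2))
  d <- if (sp > 0) diff / sp else 0
  list(t = t, df = df, p = 2 * pt(-abs(t), df), d = d)
}

t_from_raw <- function(a, b, var_equal = TRUE) {
  t_from_summaries(as_group_summary(a), as_group_summary(b),
                   var_equal = var_equal)
}

#' Independent two-sample t test with Cohen's d
#'
#' Accepts raw numeric vectors or `group_summary` objects (published
#' tables often print only mean, SD and n). With raw vectors and
#' `variant = "auto"`, Brown-Forsythe/Levene's test (center = median) is
#' run first and the Welch t is selected when it rejects at
#' `levene_alpha`; otherwise the pooled-variance Student t (df =
#' n_a + n_b - 2) is used. Cohen's d always uses the pooled SD with
#' (n - 1) weights and carries the sign of t.
#'
#' @param a,b numeric vectors of raw scores, or `group_summary` objects.
#' @param variant `"student"`, `"welch"`, or `"auto"` (raw vectors only).
#' @param levene_alpha significance level for the variance-homogeneity
#'   pre-check under `variant = "auto"`.
#' @return list of class `flunet_ttest`: `t`, `df`, `p`, `d`, `effect`,
#'   `variant`, and `levene_p` when computed.
#' @export
independent_t <- function(a, b, variant = c("auto", "student", "welch"),
                          levene_alpha = 0.05) {
  variant <- match.arg(variant)
  raw <- !inherits(a, "group_summary") && !inherits(b, "group_summary")
  levene_p <- NA_real_
  if (variant == "auto") {
    if (raw) {
      levene_p <- levene_test(a, b)$p
      variant <- if (levene_p < levene_alpha) "welch" else "student"
    } else {
      variant <- "student"
    }
  }
  res <- t_from_summaries(as_group_summary(a), as_group_summary(b),
                          var_equal = variant == "student")
  structure(c(res, list(effect = effect_label(res$d), variant = variant,
                        levene_p = levene_p)),
            class = "flunet_ttest")
}

#' @export
print.flunet_ttest <- function(x, ...) {
  cat(sprintf("Independent t (%s): t(%.4g) = %.3f, p = %.4g, d = %.2f (%s)\n",
              x$variant, x$df, x$t, x$p, x$d, x$effect))
  if (!is.na(x$levene_p)) {
    cat(sprintf("  Levene (center = median): p = %.4g\n", x$levene_p))
  }
  invisible(x)
}

# Brown-Forsythe variant of Levene's test (deviations from group medians),
# via car when available, with an equivalent ANOVA fallback.
levene_test <- function(a, b) {
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (requireNamespace("car", quietly = TRUE)) {
    tab <- car::leveneTest(y, g, center = median)
    list(statistic = tab[1, "F value"], p = tab[1, "Pr(>F)"])
  } else {
    dev <- abs(y - ave(y, g, FUN = median))
    fit <- anova(aov(dev ~ g))
    list(statistic = fit["g", "F value"], p = fit["g", "Pr(>F)"])
  }
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction, with the phi effect
#' size sqrt(chi2 / N).
#'
#' @param tab 2x2 matrix of nonnegative integer counts with all row and
#'   column marginals positive.
#' @return list: `chi2`, `df` (= 1), `p`, `phi`, `n`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_stage("stats", "zero marginal in 2x2 table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, phi = sqrt(unname(ct$statistic) / n), n = n)
}

#' Pearson correlation with a two-sided t-based p value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list: `r`, `df`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    stop_stage("stats", "constant input; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value,
       n = length(x))
}
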