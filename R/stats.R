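# Statistical battery for the behavioral metrics: mixed-design (split-plot)
# repeated-measures ANOVA with one between-subjects factor (genotype) and
# one within-subjects factor (day), Mauchly's sphericity test on the
# within-subject contrast covariance, Bonferroni-gated per-day post hoc
# comparisons, and pooled-variance two-sample t tests from raw samples or
# from printed mean +/- SEM summaries.

#' Build a repeated-measures design
#'
#' @param y Numeric matrix, subjects x days (rownames are subject ids).
#' @param group Factor/character of length `nrow(y)` with two levels
#'   (between-subjects factor).
#' @param listwise Drop subjects with any missing day (default `TRUE`);
#'   classical RM-ANOVA requires complete cases.
#' @return `list(y, group)` of complete cases, class `rm_design`.
#' @export
rm_design <- function(y, group, listwise = TRUE) {
  y <- as.matrix(y)
  if (is.null(rownames(y))) rownames(y) <- sprintf("S%02d", seq_len(nrow(y)))
  group <- factor(group)
  stopifnot(length(group) == nrow(y))
  if (listwise) {
    keep <- stats::complete.cases(y)
    y <- y[keep, , drop = FALSE]
    group <- droplevels(group[keep])
  }
  if (ncol(y) < 2) stop("need at least 2 within-factor levels", call. = FALSE)
  if (nlevels(group) != 2)
    stop("between factor must have exactly 2 levels after deletion", call. = FALSE)
  if (any(table(group) < 2))
    stop("each group needs at least 2 complete subjects", call. = FALSE)
  structure(list(y = y, group = group), class = "rm_design")
}

stat_result <- function(term, statistic, df1, df2, p, adjusted_p = NA_real_) {
  list(term = term, statistic = statistic, df1 = df1, df2 = df2,
       p = p, adjusted_p = adjusted_p)
}

#' Mixed-design repeated-measures ANOVA
#'
#' Classical split-plot sums-of-squares decomposition: the between factor is
#' tested against subjects-within-groups (df `g-1`, `N-g`), the within
#' factor (day) and the group x day interaction against the
#' subject x day residual (df `d-1` and `(g-1)(d-1)` over `(N-g)(d-1)`).
#' Greenhouse-Geisser epsilon is computed and reported but, by default, no
#' sphericity correction is applied; set `gg_correct = TRUE` to adjust the
#' within and interaction tests.
#'
#' @param design An [rm_design()].
#' @param gg_correct Apply the Greenhouse-Geisser correction to the
#'   within-subject tests (default `FALSE`).
#' @return `list(between, within, interaction, epsilon)`; each term is a
#'   `list(term, statistic, df1, df2, p, adjusted_p)`.
#' @export
rm_anova <- function(design, gg_correct = FALSE) {
  stopifnot(inherits(design, "rm_design"))
  y <- design$y; group <- design$group
  n <- nrow(y); d <- ncol(y); g <- nlevels(group)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  grp_means <- tapply(subj_means, group, mean)
  n_g <- table(group)

  # between-subject stratum
  ss_group <- d * sum(n_g * (grp_means - grand)^2)
  ss_subj <- d * sum((subj_means - grp_means[group])^2)
  df_group <- g - 1; df_subj <- n - g

  # within-subject stratum, on subject-centered data
  cent <- y - subj_means
  day_means <- colMeans(cent)                       # weighted grand day means
  ss_day <- n * sum(day_means^2)
  cell <- rowsum(cent, group) / as.vector(n_g)      # group x day cell means
  ss_int <- sum(as.vector(n_g) *
                  (cell - matrix(day_means, g, d, byrow = TRUE))^2)
  ss_resid <- sum((cent - cell[group, , drop = FALSE])^2)
  df_day <- d - 1; df_int <- (g - 1) * (d - 1); df_resid <- (n - g) * (d - 1)

  f_group <- (ss_group / df_group) / (ss_subj / df_subj)
  f_day <- (ss_day / df_day) / (ss_resid / df_resid)
  f_int <- (ss_int / df_int) / (ss_resid / df_resid)

  eps <- gg_epsilon(y, group)
  adj <- function(f, df1, df2) {
    if (gg_correct) stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
    else stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(
    between = stat_result("between", f_group, df_group, df_subj,
                          stats::pf(f_group, df_group, df_subj, lower.tail = FALSE)),
    within = stat_result("within", f_day, df_day, df_resid,
                         adj(f_day, df_day, df_resid)),
    interaction = stat_result("interaction", f_int, df_int, df_resid,
                              adj(f_int, df_int, df_resid)),
    epsilon = eps)
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance.
gg_epsilon <- function(y, group) {
  d <- ncol(y)
  if (d < 2) return(1)
  S <- pooled_cov(y, group)
  # epsilon on the (d-1) orthonormal contrasts
  C <- orthonormal_contrasts(d)
  Sc <- t(C) %*% S %*% C
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  sum(lam)^2 / ((d - 1) * sum(lam^2))
}

pooled_cov <- function(y, group = NULL) {
  if (is.null(group)) return(stats::cov(y))
  group <- factor(group)
  n <- nrow(y); g <- nlevels(group)
  S <- matrix(0, ncol(y), ncol(y))
  for (lv in levels(group)) {
    yg <- y[group == lv, , drop = FALSE]
    S <- S + stats::cov(yg) * (nrow(yg) - 1)
  }
  S / (n - g)
}

orthonormal_contrasts <- function(d) {
  C <- stats::contr.helmert(d)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Mauchly's test of sphericity
#'
#' Tests sphericity of the within-subject covariance on its `d - 1`
#' orthonormal contrasts, using the pooled within-group covariance and the
#' standard chi-square approximation. With `d = 2` a single contrast is
#' always spherical (`W = 1`, `p = 1`).
#'
#' @param design An [rm_design()] (or a bare numeric matrix for a
#'   single-group test).
#' @return `list(W, chi2, df, p)`.
#' @export
mauchly_test <- function(design) {
  if (inherits(design, "rm_design")) {
    y <- design$y; group <- design$group
  } else {
    y <- as.matrix(design); group <- factor(rep("all", nrow(y)))
  }
  n <- nrow(y); d <- ncol(y); g <- nlevels(group)
  if (d < 2) stop("need at least 2 within-factor levels", call. = FALSE)
  if (d == 2) return(list(W = 1, chi2 = 0, df = 0L, p = 1))
  df_e <- n - g
  S <- pooled_cov(y, group) * df_e  # cross-product matrix of residuals
  C <- orthonormal_contrasts(d)
  Sc <- t(C) %*% (S / df_e) %*% C
  p_dim <- d - 1
  detSc <- det(Sc)
  if (!is.finite(detSc) || detSc <= 0)
    stop("singular contrast covariance; Mauchly's W undefined", call. = FALSE)
  W <- detSc / (sum(diag(Sc)) / p_dim)^p_dim
  mult <- df_e - (2 * p_dim^2 + p_dim + 2) / (6 * p_dim)
  chi2 <- -mult * log(W)
  df <- as.integer(p_dim * (p_dim + 1) / 2 - 1)
  list(W = W, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Bonferroni-corrected per-day post hoc comparisons
#'
#' Guarded by the gating rule used with the ANOVA battery: post hoc tests
#' run only after a significant group x day interaction. Each day's
#' between-group comparison is a pooled two-sample t test with
#' `adjusted_p = min(1, p * d)`.
#'
#' @param design An [rm_design()].
#' @param interaction_p The interaction p-value; computed from the design
#'   when omitted.
#' @param alpha Gating level (default 0.05).
#' @return List of per-day `stat_result`s with `adjusted_p` filled in.
#' @export
bonferroni_posthoc <- function(design, interaction_p = NULL, alpha = 0.05) {
  stopifnot(inherits(design, "rm_design"))
  if (is.null(interaction_p))
    interaction_p <- rm_anova(design)$interaction$p
  if (!(interaction_p < alpha))
    stop(sprintf(paste0("post hoc tests require a significant interaction ",
                        "(p = %.4g >= %.2g)"), interaction_p, alpha),
         call. = FALSE)
  d <- ncol(design$y)
  lv <- levels(design$group)
  lapply(seq_len(d), function(j) {
    r <- pooled_t_from_data(design$y[design$group == lv[1], j],
                            design$y[design$group == lv[2], j])
    r$term <- "pairwise"
    r$adjusted_p <- min(1, r$p * d)
    r
  })
}

#' Pooled two-sample t test from printed summaries
#'
#' Reconstructs Student's unpaired t test from group means, SEMs and sizes
#' as printed in a summary table: `sd_i = sem_i * sqrt(n_i)`, pooled
#' variance with `df = n1 + n2 - 2`, two-sided p.
#'
#' @param m1,sem1,n1 Mean, SEM and size of group 1.
#' @param m2,sem2,n2 Mean, SEM and size of group 2.
#' @return `stat_result` with `term = "pairwise"` (statistic is
#'   `m1 - m2` signed).
#' @export
pooled_t_from_summary <- function(m1, sem1, n1, m2, sem2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sem1 <= 0 || sem2 <= 0) stop("SEMs must be > 0", call. = FALSE)
  v1 <- (sem1 * sqrt(n1))^2
  v2 <- (sem2 * sqrt(n2))^2
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  stat_result("pairwise", t, df, NA_integer_,
              2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Pooled two-sample t test from raw samples
#'
#' Identical to [pooled_t_from_summary()] applied to the samples' own
#' summaries.
#'
#' @param x1,x2 Numeric vectors (each of length >= 2; NAs dropped).
#' @return `stat_result` with `term = "pairwise"`.
#' @export
pooled_t_from_data <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean(x1) - mean(x2)) / se
  stat_result("pairwise", t, df, NA_integer_,
              if (se == 0 && mean(x1) == mean(x2)) 1
              else 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector of length >= 2 (NAs dropped).
#' @return `c(mean =, sem =)` with `sem = sd / sqrt(n)` (sample sd).
#' @export
mean_sem <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  c(mean = mean(values), sem = stats::sd(values) / sqrt(length(values)))
}

#' Significance markers used in figure legends
#' @param p Numeric vector of p-values.
#' @return Character vector: `****`, `***`, `**`, `*` at
#'   0.0001/0.001/0.01/0.05, else `ns`.
#' @export
sig_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}
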