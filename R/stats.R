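# Normality-gated group comparison: Shapiro-Wilk gate, then one-way ANOVA
# with Tukey HSD (parametric branch) or Kruskal-Wallis with Dunn post-hoc
# under Holm correction (non-parametric branch).

#' Significance flag for a p-value
#'
#' The reporting convention: `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector over `{"ns", "*", "**"}`.
#' @export
significance_flag <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("significance_flag: p-values must lie in [0, 1]", call. = FALSE)
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}

#' Normality gate for a set of groups
#'
#' Routes a multi-group comparison to the parametric branch only when
#' every group passes the Shapiro-Wilk normality test at `alpha`; any
#' failing group routes the whole comparison non-parametric. A
#' zero-variance group is degenerate for Shapiro-Wilk and is routed
#' non-parametric with a warning.
#'
#' @param groups Named list of numeric vectors, one per group, each with
#'   at least 3 observations.
#' @param alpha Gate level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 1L)
    stop("normality_gate: 'groups' must be a list of numeric vectors",
         call. = FALSE)
  if (any(vapply(groups, length, 1L) < 3L))
    stop("normality_gate: every group needs at least 3 observations",
         call. = FALSE)
  for (g in groups) {
    if (stats::sd(g) == 0) {
      warning("normality_gate: zero-variance group; routing nonparametric",
              call. = FALSE)
      return("nonparametric")
    }
    if (stats::shapiro.test(g)$p.value <= alpha) return("nonparametric")
  }
  "parametric"
}

# Dunn's post-hoc z statistics on Kruskal-Wallis ranks, with mid-ranks and
# the standard tie correction; two-sided p-values, Holm-adjusted over the
# family of all pairwise comparisons.
.dunn_pairs <- function(values, labels) {
  N <- length(values)
  r <- rank(values)                        # mid-ranks
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  lev <- unique(labels)
  rb <- tapply(r, factor(labels, levels = lev), mean)
  ns <- tapply(r, factor(labels, levels = lev), length)
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[k] <- (rb[[a]] - rb[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
             statistic = z, p_raw = p,
             adjusted_p = stats::p.adjust(p, method = "holm"))
}

#' Gated multi-group comparison
#'
#' Applies the full comparison procedure to labelled samples: the
#' Shapiro-Wilk gate decides the branch; the parametric branch runs
#' one-way ANOVA with Tukey HSD post-hoc (familywise-adjusted p-values),
#' the non-parametric branch runs the Kruskal-Wallis rank-sum test with
#' Dunn's all-pairs post-hoc and Holm step-down correction. Each pairwise
#' comparison is flagged by [significance_flag()].
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 3
#'   observations), or a data frame with columns `group` and `value`.
#' @param control Optional control-group label; marks the
#'   `vs_control` rows of the pairwise table (all pairs are reported
#'   regardless).
#' @param alpha Gate level for the Shapiro-Wilk test.
#'
#' @return An object of class `comparison_report`: `branch`,
#'   `omnibus_statistic`, `omnibus_p`, `omnibus_flag` and a `pairwise`
#'   data frame (`group_a`, `group_b`, `statistic`, `p_raw`, `adjusted_p`,
#'   `flag`, `vs_control`).
#' @export
compare_groups <- function(groups, control = NULL, alpha = 0.05) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups)))
      stop("compare_groups: data frame input needs 'group' and 'value' ",
           "columns", call. = FALSE)
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2L)
    stop("compare_groups: at least 2 groups are required", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  if (!is.null(control) && !control %in% names(groups))
    stop("compare_groups: control label '", control, "' not among groups",
         call. = FALSE)
  branch <- suppressWarnings(normality_gate(groups, alpha = alpha))
  labels <- rep(names(groups), vapply(groups, length, 1L))
  values <- unlist(groups, use.names = FALSE)
  if (branch == "parametric") {
    fit <- stats::aov(values ~ factor(labels))
    an <- summary(fit)[[1L]]
    omnibus <- an[["F value"]][1L]
    omnibus_p <- an[["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)[[1L]]
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(group_a = vapply(nm, `[`, "", 1L),
                           group_b = vapply(nm, `[`, "", 2L),
                           statistic = tk[, "diff"],
                           p_raw = tk[, "p adj"],
                           adjusted_p = tk[, "p adj"],
                           row.names = NULL)
  } else {
    kw <- stats::kruskal.test(values, factor(labels))
    omnibus <- unname(kw$statistic)
    omnibus_p <- kw$p.value
    pairwise <- .dunn_pairs(values, labels)
  }
  pairwise$flag <- significance_flag(pairwise$adjusted_p)
  pairwise$vs_control <- if (is.null(control)) FALSE else
    pairwise$group_a == control | pairwise$group_b == control
  structure(list(branch = branch,
                 omnibus_statistic = omnibus,
                 omnibus_p = omnibus_p,
                 omnibus_flag = significance_flag(omnibus_p),
                 control = control,
                 pairwise = pairwise),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", x$branch, "branch\n")
  omni <- if (x$branch == "parametric") "one-way ANOVA F" else
    "Kruskal-Wallis chi-squared"
  cat("  omnibus:", omni, "=", signif(x$omnibus_statistic, 4),
      ", p =", format.pval(x$omnibus_p, digits = 3), x$omnibus_flag, "\n")
  post <- if (x$branch == "parametric") "Tukey HSD" else "Dunn + Holm"
  cat("  post-hoc (", post, "):\n", sep = "")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
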