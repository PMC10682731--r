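# Group-comparison procedure: Lilliefors normality gate, ANOVA or
# Kruskal-Wallis omnibus at alpha = 0.05, pairwise t / Wilcoxon rank-sum
# tests at the Bonferroni-adjusted threshold 0.05 / 3, printed as 0.017.

# Cache of Monte Carlo null distributions of the Lilliefors statistic,
# keyed by (n, n_sim, seed).  The null law depends on the sample size only,
# so repeated tests at the same n are cheap.
.lillie_cache <- new.env(parent = emptyenv())

.lillie_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - p), max(p - (i - 1) / n))
}

.lillie_null <- function(n, n_sim, seed) {
  key <- paste(n, n_sim, seed, sep = "_")
  got <- .lillie_cache[[key]]
  if (!is.null(got)) return(got)
  # isolate the RNG so cached-table generation never perturbs caller streams
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", globalenv())
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * n_sim), nrow = n)
  mns <- colMeans(Z)
  sds <- sqrt((colSums(Z^2) - n * mns^2) / (n - 1))
  Zs <- apply(Z, 2L, sort)
  P <- stats::pnorm(sweep(sweep(Zs, 2L, mns, "-"), 2L, sds, "/"))
  i_n <- seq_len(n) / n
  i1_n <- (seq_len(n) - 1) / n
  D <- pmax(apply(i_n - P, 2L, max), apply(P - i1_n, 2L, max))
  if (has_seed) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  .lillie_cache[[key]] <- D
  D
}

#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov-type test of composite normality: the statistic is the
#' supremum distance between the empirical CDF and the normal CDF with
#' estimated mean and SD.  The p-value is obtained by Monte Carlo simulation
#' of the null distribution (which depends on the sample size only and is
#' cached), using at least 10^4 replicates by default.
#'
#' Degenerate samples (SD = 0) are rejected with an error rather than
#' assigned a p-value: the normal model is meaningless for a constant
#' sample.
#'
#' @param x Numeric sample, `n >= 4`.
#' @param n_sim Monte Carlo replicates for the null distribution.
#' @param rng_seed Seed for the null-table simulation (isolated from the
#'   caller's RNG stream).
#' @return List with `statistic`, `p_value`, `n`, `n_sim`.
#' @export
lilliefors_test <- function(x, n_sim = 10000L, rng_seed = 207L) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("Lilliefors test requires n >= 4")
  if (anyNA(x)) stop("sample contains NA")
  if (stats::sd(x) == 0)
    stop("degenerate sample (SD = 0): normality is undefined for a constant sample")
  D <- .lillie_stat(x)
  Dnull <- .lillie_null(length(x), n_sim, rng_seed)
  list(statistic = D, p_value = mean(Dnull >= D), n = length(x), n_sim = n_sim)
}

#' Compare groups for one metric
#'
#' Implements the gated three-group comparison: each group is tested for
#' normality (Lilliefors, alpha = `alpha_normality`); if every group passes,
#' the omnibus test is one-way ANOVA, otherwise Kruskal-Wallis.  All group
#' pairs are then compared with a two-tailed unpaired t-test (pooled variance
#' by default; `welch = TRUE` switches to Welch) when both groups pass
#' normality, and the Wilcoxon rank-sum test otherwise.  Pairwise
#' significance is declared at the Bonferroni-adjusted threshold
#' `pairwise_alpha` (0.05 / 3, printed as 0.017, for three groups).
#'
#' Groups smaller than 4 cannot be normality-tested and are treated as
#' non-normal (conservative gate).
#'
#' @param table A `cohort_table` (long format: `subject_id`, `group`,
#'   `metric`, `value`).
#' @param metric Metric name to compare.
#' @param alpha_normality Gate level for the Lilliefors test.
#' @param omnibus_alpha Omnibus significance level.
#' @param pairwise_alpha Pairwise threshold; default `round(0.05 / 3, 3)`.
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @param lillie_n_sim,lillie_seed Monte Carlo control for the normality
#'   gate.
#' @return A list of class `comparison_result`: `metric`, `omnibus_test`
#'   (`"anova"` or `"kruskal"`), `omnibus_p`, `omnibus_significant`,
#'   `normality_p` (named per group), `all_normal`, `pairwise` (data.frame:
#'   `group1`, `group2`, `test`, `p`, `significant`), `group_summary`
#'   (data.frame: `group`, `n`, `mean`, `sd`, `median`, `q1`, `q3`),
#'   `summary_style` (`"mean_sd"` or `"median_iqr"`), `pairwise_alpha`,
#'   `omnibus_alpha`.
#' @export
compare_groups <- function(table, metric, alpha_normality = 0.05,
                           omnibus_alpha = 0.05,
                           pairwise_alpha = round(0.05 / 3, 3),
                           welch = FALSE, lillie_n_sim = 10000L,
                           lillie_seed = 207L) {
  stopifnot(is.data.frame(table))
  sub <- table[table$metric == metric, , drop = FALSE]
  if (!nrow(sub)) stop("metric not present in cohort table: ", metric)
  groups <- unique(sub$group)
  if (length(groups) < 2L) stop("need at least 2 groups")
  values <- split(sub$value, factor(sub$group, levels = groups))
  ns <- vapply(values, length, integer(1))
  if (any(ns < 2L)) stop("each group needs n >= 2")

  norm_p <- vapply(values, function(v) {
    if (length(v) < 4L) return(NA_real_)
    lilliefors_test(v, n_sim = lillie_n_sim, rng_seed = lillie_seed)$p_value
  }, numeric(1))
  group_normal <- !is.na(norm_p) & norm_p >= alpha_normality
  all_normal <- all(group_normal)

  g <- factor(rep(names(values), ns), levels = groups)
  y <- unlist(values, use.names = FALSE)
  if (all_normal) {
    omnibus_test <- "anova"
    omnibus_p <- stats::oneway.test(y ~ g, var.equal = TRUE)$p.value
  } else {
    omnibus_test <- "kruskal"
    omnibus_p <- stats::kruskal.test(y, g)$p.value
  }

  pairs <- utils::combn(seq_along(groups), 2L)
  pw <- data.frame(group1 = character(0), group2 = character(0),
                   test = character(0), p = numeric(0),
                   significant = logical(0))
  for (ci in seq_len(ncol(pairs))) {
    a <- pairs[1L, ci]; b <- pairs[2L, ci]
    va <- values[[a]]; vb <- values[[b]]
    if (group_normal[a] && group_normal[b]) {
      test <- if (welch) "welch_t" else "t"
      p <- stats::t.test(va, vb, var.equal = !welch)$p.value
    } else {
      test <- "wilcoxon"
      exact <- max(length(va), length(vb)) <= 20L &&
        !anyDuplicated(c(va, vb))
      p <- suppressWarnings(
        stats::wilcox.test(va, vb, exact = exact, correct = TRUE)$p.value)
    }
    pw <- rbind(pw, data.frame(group1 = groups[a], group2 = groups[b],
                               test = test, p = p,
                               significant = p < pairwise_alpha))
  }

  gs <- data.frame(group = groups, n = as.integer(ns),
                   mean = vapply(values, mean, numeric(1)),
                   sd = vapply(values, stats::sd, numeric(1)),
                   median = vapply(values, stats::median, numeric(1)),
                   q1 = vapply(values, function(v) unname(stats::quantile(v, 0.25)), numeric(1)),
                   q3 = vapply(values, function(v) unname(stats::quantile(v, 0.75)), numeric(1)),
                   row.names = NULL)

  structure(list(metric = metric, omnibus_test = omnibus_test,
                 omnibus_p = omnibus_p,
                 omnibus_significant = omnibus_p < omnibus_alpha,
                 normality_p = norm_p, all_normal = all_normal,
                 pairwise = pw, group_summary = gs,
                 summary_style = if (all_normal) "mean_sd" else "median_iqr",
                 pairwise_alpha = pairwise_alpha,
                 omnibus_alpha = omnibus_alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s p = %.4g%s\n", x$metric,
              x$omnibus_test, x$omnibus_p,
              if (x$omnibus_significant) " *" else ""))
  for (i in seq_len(nrow(x$pairwise))) {
    r <- x$pairwise[i, ]
    cat(sprintf("  %s vs %s: %s p = %.4g%s\n", r$group1, r$group2, r$test,
                r$p, if (r$significant) " *" else ""))
  }
  invisible(x)
}

.fmt_group <- function(gs_row, style, digits = 3) {
  if (style == "mean_sd") {
    sprintf("%s ± %s", signif(gs_row$mean, digits), signif(gs_row$sd, digits))
  } else {
    sprintf("%s (%s–%s)", signif(gs_row$median, digits),
            signif(gs_row$q1, digits), signif(gs_row$q3, digits))
  }
}

#' Build a publication-style summary table
#'
#' One row per metric: per-group summary (mean +/- SD when all groups pass
#' the normality gate, median (IQR) otherwise), the pairwise p-values, the
#' omnibus p-value, and footnote markers for significant pairs.  For three
#' groups the marker convention follows the usual legend: `*` group 1 vs
#' group 3, `**` group 2 vs group 3, `***` group 1 vs group 2.
#'
#' @param table A `cohort_table`.
#' @param metrics Metrics to include; defaults to all present, in order of
#'   first appearance.
#' @param ... Passed to [compare_groups()].
#' @return A data.frame with one row per metric and attribute
#'   `"comparisons"` (the list of `comparison_result`s).
#' @export
build_summary_table <- function(table, metrics = unique(table$metric), ...) {
  comps <- lapply(metrics, function(m) compare_groups(table, m, ...))
  groups <- comps[[1L]]$group_summary$group
  rows <- lapply(comps, function(cmp) {
    gcols <- vapply(seq_along(groups), function(i)
      .fmt_group(cmp$group_summary[i, ], cmp$summary_style), character(1))
    names(gcols) <- groups
    pw <- cmp$pairwise
    pcols <- stats::setNames(pw$p, paste0("p_", pw$group1, "_vs_", pw$group2))
    markers <- ""
    if (length(groups) == 3L) {
      sig_of <- function(a, b) {
        hit <- pw$significant[(pw$group1 == a & pw$group2 == b) |
                                (pw$group1 == b & pw$group2 == a)]
        length(hit) && any(hit)
      }
      stars <- c(if (sig_of(groups[1], groups[3])) "*",
                 if (sig_of(groups[2], groups[3])) "**",
                 if (sig_of(groups[1], groups[2])) "***")
      markers <- paste(stars, collapse = ",")
    }
    c(list(metric = cmp$metric), as.list(gcols), as.list(pcols),
      list(p_omnibus = cmp$omnibus_p, omnibus_test = cmp$omnibus_test,
           markers = markers))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  attr(out, "comparisons") <- comps
  out
}

#' Render a summary table as markdown
#'
#' @param summary_df Output of [build_summary_table()].
#' @return A character scalar of markdown.
#' @export
summary_table_markdown <- function(summary_df) {
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  df <- summary_df
  for (nm in grep("^p_", names(df), value = TRUE)) df[[nm]] <- fmt_p(df[[nm]])
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}
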