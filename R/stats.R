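#' Gated two-group comparison
#'
#' Implements the standard normality-gated dispatch: Shapiro-Wilk on each
#' group at `alpha`; if both pass, a t-test is used (pooled or Welch according
#' to an F-test of variance homogeneity at `alpha`), otherwise the
#' Mann-Whitney U test. Groups with fewer than 3 observations skip the
#' normality gate and fall back to the nonparametric path, flagged.
#'
#' @param a,b numeric observation vectors (finite).
#' @param alpha gate significance level (default 0.05; p <= alpha triggers).
#' @param labels length-2 character group labels.
#' @return a `test_report`: list with `test`, `statistic`, `p_value`,
#'   `gates` (normality and variance p-values), `flags`, `posthoc` (NULL for
#'   two groups), `pairwise` (NULL).
#' @export
dispatch_two_groups <- function(a, b, alpha = 0.05,
                                labels = c("a", "b")) {
  check_group(a); check_group(b)
  flags <- character(0)
  small <- length(a) < 3L || length(b) < 3L
  if (small) {
    flags <- c(flags, "group n < 3: normality gate skipped, nonparametric fallback")
    norm_p <- c(NA_real_, NA_real_)
    normal <- FALSE
  } else {
    norm_p <- c(shapiro_p(a), shapiro_p(b))
    normal <- all(norm_p > alpha)
  }
  names(norm_p) <- labels
  if (normal) {
    var_p <- stats::var.test(a, b)$p.value
    equal_var <- var_p > alpha
    ht <- stats::t.test(a, b, var.equal = equal_var)
    test <- if (equal_var) "t-test (pooled)" else "Welch t-test"
  } else {
    var_p <- NA_real_
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    test <- "Mann-Whitney U"
  }
  new_test_report(test = test, statistic = unname(ht$statistic),
                  p_value = ht$p.value,
                  gates = list(normality_p = norm_p, variance_p = var_p),
                  flags = flags, labels = labels,
                  n = c(length(a), length(b)))
}

#' Gated multi-group comparison with post hoc tests
#'
#' Dispatch for three or more groups: all groups normal (Shapiro-Wilk) and
#' homogeneous variances (median-centered Levene) -> one-way ANOVA with
#' Bonferroni-corrected pairwise t-tests; all normal with inhomogeneous
#' variances -> Welch's ANOVA with Tamhane T2 post hoc; any group non-normal
#' -> Kruskal-Wallis with Dunn's post hoc. Any group with n < 3 forces the
#' nonparametric path, flagged.
#'
#' @param groups named list of numeric vectors (>= 3 groups).
#' @param alpha gate significance level.
#' @return a `test_report` with `posthoc` naming the pairwise procedure and
#'   `pairwise` a data.frame (group1, group2, statistic, p, p_adj).
#' @export
dispatch_multi_groups <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L)
    stopf("dispatch_multi_groups needs >= 3 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, check_group)
  labels <- names(groups)
  flags <- character(0)
  small <- any(vapply(groups, length, 1L) < 3L)
  if (small) {
    flags <- c(flags, "group n < 3: normality gate skipped, nonparametric path")
    norm_p <- rep(NA_real_, length(groups))
    normal <- FALSE
  } else {
    norm_p <- vapply(groups, shapiro_p, numeric(1))
    normal <- all(norm_p > alpha)
  }
  names(norm_p) <- labels
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, 1L)), levels = labels)
  if (normal) {
    lev <- car::leveneTest(x, g, center = stats::median)
    var_p <- lev[["Pr(>F)"]][1]
    if (var_p > alpha) {
      fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
      pw <- pairwise_bonferroni(groups)
      rep_ <- new_test_report("ANOVA", unname(fit$statistic), fit$p.value,
                              gates = list(normality_p = norm_p, variance_p = var_p),
                              posthoc = "Bonferroni pairwise t",
                              pairwise = pw, flags = flags, labels = labels,
                              n = vapply(groups, length, 1L))
    } else {
      fit <- stats::oneway.test(x ~ g, var.equal = FALSE)
      pw <- tamhane_t2(groups)
      rep_ <- new_test_report("Welch ANOVA", unname(fit$statistic), fit$p.value,
                              gates = list(normality_p = norm_p, variance_p = var_p),
                              posthoc = "Tamhane T2", pairwise = pw,
                              flags = flags, labels = labels,
                              n = vapply(groups, length, 1L))
    }
  } else {
    fit <- stats::kruskal.test(x, g)
    pw <- dunn_posthoc(groups)
    rep_ <- new_test_report("Kruskal-Wallis", unname(fit$statistic), fit$p.value,
                            gates = list(normality_p = norm_p, variance_p = NA_real_),
                            posthoc = "Dunn", pairwise = pw, flags = flags,
                            labels = labels, n = vapply(groups, length, 1L))
  }
  rep_
}

check_group <- function(x) {
  if (!is.numeric(x) || !length(x) || any(!is.finite(x)))
    stopf("observations must be finite numeric vectors")
  invisible(x)
}

shapiro_p <- function(x) {
  if (stats::sd(x) == 0) return(0)  # degenerate: clearly non-normal sample
  stats::shapiro.test(x)$p.value
}

#' Bonferroni-corrected pooled pairwise t-tests
#' @param groups named list of numeric vectors.
#' @return data.frame (group1, group2, statistic, p, p_adj) with
#'   p_adj = min(1, p * n_pairs).
#' @export
pairwise_bonferroni <- function(groups) {
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  # pooled SD across all groups (classical post-ANOVA pairwise t)
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  s2 <- sum((n - 1) * vapply(groups, stats::var, 1)) / (sum(n) - k)
  df <- sum(n) - k
  do.call(rbind, lapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    se <- sqrt(s2 * (1 / length(a) + 1 / length(b)))
    tstat <- (mean(a) - mean(b)) / se
    p <- 2 * stats::pt(-abs(tstat), df)
    data.frame(group1 = pr[1], group2 = pr[2], statistic = tstat,
               p = p, p_adj = min(1, p * m), stringsAsFactors = FALSE)
  }))
}

#' Tamhane T2 post hoc test
#'
#' Pairwise Welch t-tests with Welch-Satterthwaite degrees of freedom and a
#' Sidak-style multiplicity correction `p_adj = 1 - (1 - p)^m` over the m
#' pairs; appropriate after Welch's ANOVA when variances are inhomogeneous.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame (group1, group2, statistic, df, p, p_adj).
#' @export
tamhane_t2 <- function(groups) {
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  do.call(rbind, lapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    data.frame(group1 = pr[1], group2 = pr[2], statistic = tstat, df = df,
               p = p, p_adj = min(1, 1 - (1 - p)^m), stringsAsFactors = FALSE)
  }))
}

#' Dunn's post hoc test
#'
#' Rank-based pairwise comparisons after Kruskal-Wallis: z statistics from
#' mean pooled ranks with the tie-corrected variance
#' `(N(N+1)/12 - T)(1/n_i + 1/n_j)`, `T = sum(t^3 - t) / (12 (N - 1))`,
#' two-sided normal p-values, Bonferroni-adjusted.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame (group1, group2, statistic, p, p_adj).
#' @export
dunn_posthoc <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  do.call(rbind, lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = pr[1], group2 = pr[2], statistic = z, p = p,
               p_adj = min(1, p * m), stringsAsFactors = FALSE)
  }))
}

new_test_report <- function(test, statistic, p_value, gates,
                            posthoc = NULL, pairwise = NULL,
                            flags = character(0), labels = NULL, n = NULL) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 gates = gates, posthoc = posthoc, pairwise = pairwise,
                 flags = flags, labels = labels, n = n),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat("Test report\n")
  cat(sprintf("  omnibus: %s  statistic = %.4g  p = %.4g\n",
              x$test, x$statistic, x$p_value))
  np <- x$gates$normality_p
  cat("  gates: normality p =", paste(sprintf("%.3g", np), collapse = ", "),
      " variance p =", sprintf("%.3g", x$gates$variance_p), "\n")
  if (!is.null(x$posthoc)) {
    cat("  posthoc:", x$posthoc, "\n")
    print(x$pairwise, row.names = FALSE)
  }
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' Serialize a test report to JSON
#' @param report a `test_report`.
#' @param path optional output path; when NULL the JSON string is returned.
#' @export
test_report_json <- function(report, path = NULL) {
  x <- unclass(report)
  x$gates$normality_p <- as.list(x$gates$normality_p)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Trapezoidal area under a glucose-time curve
#'
#' Composite trapezoid over the measured grid, as used to summarize
#' intraperitoneal glucose tolerance tests (IGTT). Supports any strictly
#' increasing grid starting at 0 min, including the common
#' {0, 15, 40, 60, 120} and {0, 15, 30, 60, 120} minute designs. The default
#' is total AUC; `type = "incremental"` integrates glucose above the 0-min
#' baseline instead.
#'
#' @param times minutes, strictly increasing, starting at 0.
#' @param glucose mg/dL, non-negative, same length as `times`.
#' @param type "total" or "incremental".
#' @return AUC in mg/dL * min.
#' @export
auc_trapezoid <- function(times, glucose, type = c("total", "incremental")) {
  type <- match.arg(type)
  if (length(times) < 2L) stopf("AUC needs at least 2 time points")
  if (length(times) != length(glucose)) stopf("times and glucose lengths differ")
  if (any(!is.finite(times)) || any(!is.finite(glucose)))
    stopf("times and glucose must be finite")
  if (times[1] != 0) stopf("time grid must start at 0 min")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (any(glucose < 0)) stopf("negative glucose concentration")
  y <- if (type == "incremental") glucose - glucose[1] else glucose
  pracma::trapz(times, y)
}
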