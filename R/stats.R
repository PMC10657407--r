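# Cohort-level statistics: normality-gated descriptives and two-sample
# tests, Bland-Altman limits of agreement, one-way random-effects ICC(1,1),
# and the coded cross-species similarity table.

#' Normality-gated descriptive summary
#'
#' Shapiro-Wilk gates the reporting convention: when normality is not
#' rejected (p >= 0.05) the summary is mean +/- SD, otherwise
#' median \[IQR\] with quartiles by the linear-interpolation rule
#' (`quantile(type = 7)`). Constant samples skip the W-test with a warning
#' and report mean with SD 0.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha normality test level.
#' @return A `pamorph_describe` list: `method` ("mean_sd" or "median_iqr"),
#'   the corresponding statistics, `normality_p` and a formatted `label`.
#' @export
describe <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 values to describe")
  if (stats::sd(values) < 1e-12) {
    warning("constant sample: skipping the normality test")
    out <- list(method = "mean_sd", mean = mean(values), sd = 0,
                normality_p = NA_real_, n = length(values),
                label = sprintf("%.3g \u00b1 0", mean(values)))
    class(out) <- "pamorph_describe"
    return(out)
  }
  W <- shapiro.test(values)
  if (W$p.value >= alpha) {
    out <- list(method = "mean_sd", mean = mean(values), sd = stats::sd(values),
                normality_p = W$p.value, n = length(values))
    out$label <- sprintf("%.3g \u00b1 %.3g", out$mean, out$sd)
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    out <- list(method = "median_iqr", median = q[2], q25 = q[1], q75 = q[3],
                normality_p = W$p.value, n = length(values))
    out$label <- sprintf("%.3g [%.3g-%.3g]", q[2], q[1], q[3])
  }
  class(out) <- "pamorph_describe"
  out
}

#' @export
print.pamorph_describe <- function(x, ...) {
  cat(sprintf("%s (n=%d, %s)\n", x$label, x$n, x$method))
  invisible(x)
}

shapiro_p <- function(x) {
  if (length(x) < 3 || stats::sd(x) < 1e-12) return(NA_real_)
  shapiro.test(x)$p.value
}

#' Normality-gated two-sample comparison
#'
#' Selects the test the way cohort comparisons are usually gated: both
#' samples normal by Shapiro-Wilk (or, for paired data, normal differences)
#' use the two-tailed Student's t-test (paired where applicable); otherwise
#' the Mann-Whitney U test (unpaired) or the Wilcoxon signed-rank test
#' (paired). Degenerate zero-variance comparisons return the null result.
#'
#' @param a,b numeric samples.
#' @param paired logical; paired samples must have equal length.
#' @param alpha significance level (default 0.05).
#' @param bonferroni apply a Bonferroni correction across `m` comparisons
#'   (off by default).
#' @param m number of comparisons for the correction.
#' @param parameter optional name carried into the result.
#' @return A `test_result`: `test_name` (one of `"t"`, `"paired-t"`,
#'   `"mann-whitney-u"`, `"wilcoxon"`), `statistic`, `p_value`,
#'   `normality_p`, `significant`, `alpha_effective`.
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha = 0.05,
                           bonferroni = FALSE, m = 1L,
                           parameter = NA_character_) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (paired && length(a) != length(b))
    stop("paired comparison needs equal-length samples")
  if (length(a) < 3 || length(b) < 3) stop("need at least 3 values per group")
  alpha_eff <- if (bonferroni) alpha / m else alpha
  if (paired) {
    d <- a - b
    if (stats::sd(d) < 1e-12) {
      # zero-variance differences: identical pairs are the exact null, a
      # constant nonzero offset is a certain difference
      res <- list(test_name = "paired-t",
                  statistic = if (abs(mean(d)) < 1e-9) 0 else sign(mean(d)) * Inf,
                  p_value = if (abs(mean(d)) < 1e-9) 1 else 0,
                  normality_p = c(differences = NA_real_))
    } else {
      pn <- shapiro_p(d)
      if (!is.na(pn) && pn >= 0.05) {
        tt <- t.test(a, b, paired = TRUE)
        res <- list(test_name = "paired-t", statistic = unname(tt$statistic),
                    p_value = tt$p.value, normality_p = c(differences = pn))
      } else {
        wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                           correct = TRUE))
        res <- list(test_name = "wilcoxon", statistic = unname(wt$statistic),
                    p_value = wt$p.value, normality_p = c(differences = pn))
      }
    }
  } else {
    pa <- shapiro_p(a); pb <- shapiro_p(b)
    normal <- !is.na(pa) && !is.na(pb) && pa >= 0.05 && pb >= 0.05
    if (stats::sd(c(a, b)) < 1e-12) {
      res <- list(test_name = "t", statistic = 0, p_value = 1,
                  normality_p = c(a = pa, b = pb))
    } else if (normal) {
      tt <- t.test(a, b, var.equal = TRUE)
      res <- list(test_name = "t", statistic = unname(tt$statistic),
                  p_value = tt$p.value, normality_p = c(a = pa, b = pb))
    } else {
      wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
      res <- list(test_name = "mann-whitney-u", statistic = unname(wt$statistic),
                  p_value = wt$p.value, normality_p = c(a = pa, b = pb))
    }
  }
  res$parameter <- parameter
  res$paired <- paired
  res$alpha_effective <- alpha_eff
  res$significant <- res$p_value < alpha_eff
  res$mean_diff <- mean(a) - mean(b)
  class(res) <- "test_result"
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s%s: statistic=%.4g p=%.4g (%s at alpha=%.3g)\n",
              if (is.na(x$parameter)) "" else paste0(x$parameter, ": "),
              x$test_name, x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha_effective))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = x - y`; returns the mean difference and
#' `mean(d) +/- 1.96 * SD(d)` (sample SD, n-1 denominator).
#'
#' @param x,y paired measurements (equal length, n >= 2).
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       sd_diff = s)
}

#' ICC(1,1): one-way random effects, single measurement
#'
#' McGraw & Wong convention: from the one-way ANOVA of subjects across the
#' two raters, `ICC = (MSB - MSW) / (MSB + (k - 1) * MSW)` with k = 2.
#'
#' @param x,y one measurement per subject from each of the two raters
#'   (equal length, n >= 3 subjects).
#' @return The ICC as a number; degenerate data (no between-subject
#'   variance) return `NA` with a warning.
#' @export
icc_1_1 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 subjects")
  k <- 2
  subj_mean <- (x + y) / 2
  grand <- mean(c(x, y))
  ssb <- k * sum((subj_mean - grand)^2)
  ssw <- sum((x - subj_mean)^2) + sum((y - subj_mean)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  denom <- msb + (k - 1) * msw
  if (denom < 1e-15) {
    warning("degenerate data: no variance at all; ICC undefined")
    return(NA_real_)
  }
  if (ssb < 1e-15) warning("no between-subject variance: ICC is degenerate")
  (msb - msw) / denom
}

# ---------------------------------------------------------------------------
# Cross-species similarity table

#' Assemble per-subject records into a cohort table
#'
#' @param records list of `morphometry_record`s, or a data.frame already in
#'   record-column format.
#' @return A data.frame with one row per subject.
#' @export
cohort_table <- function(records) {
  if (is.data.frame(records)) return(records)
  do.call(rbind, lapply(records, as.data.frame))
}

#' Table-2-style descriptive report for one or more cohorts
#'
#' @param cohorts named list of cohort data.frames (see [cohort_table()]).
#' @return A data.frame: one row per parameter, one formatted column per
#'   cohort (mean +/- SD or median \[IQR\] as gated by Shapiro-Wilk).
#' @export
describe_cohorts <- function(cohorts) {
  pars <- c("n_side", "L_MPA", "L_RPA", "L_LPA", "D_MPA", "D_RPA", "D_LPA",
            "alpha", "T_RPA", "T_LPA", "CI_RPA", "CI_LPA", "EnI")
  get_par <- function(df, p) {
    if (p == "n_side") c(df$n_side_lpa, df$n_side_rpa) else df[[p]]
  }
  out <- data.frame(parameter = pars, stringsAsFactors = FALSE)
  for (nm in names(cohorts)) {
    out[[nm]] <- vapply(pars, function(p) {
      v <- get_par(cohorts[[nm]], p)
      if (sum(!is.na(v)) < 3) return(NA_character_)
      suppressWarnings(describe(v)$label)
    }, character(1))
  }
  out
}

# the similarity-table row set: simple rows compare a parameter between the
# animal and the human cohort; relational rows compare a within-species
# ordering of two parameters against the human ordering
similarity_rows <- function() {
  list(
    list(row = "side_branches", kind = "simple", par = "n_side"),
    list(row = "L_MPA", kind = "simple", par = "L_MPA"),
    list(row = "L_RPA", kind = "simple", par = "L_RPA"),
    list(row = "L_LPA", kind = "simple", par = "L_LPA"),
    list(row = "D_MPA", kind = "simple", par = "D_MPA"),
    list(row = "D_RPA", kind = "simple", par = "D_RPA"),
    list(row = "D_LPA", kind = "simple", par = "D_LPA"),
    list(row = "D_LPA_lt_D_RPA", kind = "relational", a = "D_LPA", b = "D_RPA"),
    list(row = "angle", kind = "simple", par = "alpha"),
    list(row = "T_RPA", kind = "simple", par = "T_RPA"),
    list(row = "T_LPA", kind = "simple", par = "T_LPA"),
    list(row = "T_RPA_lt_T_LPA", kind = "relational", a = "T_RPA", b = "T_LPA"),
    list(row = "CI_RPA", kind = "simple", par = "CI_RPA"),
    list(row = "CI_LPA", kind = "simple", par = "CI_LPA"),
    list(row = "CI_LPA_lt_CI_RPA", kind = "relational", a = "CI_LPA", b = "CI_RPA"),
    list(row = "EnI", kind = "simple", par = "EnI")
  )
}

#' Coded similarity table between an animal cohort and a human cohort
#'
#' Simple rows are coded "+" when the animal-vs-human comparison is NOT
#' significant (morphometric agreement) and "-" otherwise. Relational rows
#' (e.g. "LPA diameter < RPA diameter") are coded "+" when the animal cohort
#' reproduces the human within-species ordering: if the ordering is
#' significant in humans, it must be significant in the animal with the same
#' direction; if it is not significant in humans, it must not be significant
#' in the animal either. The similarity score counts the "+" entries.
#'
#' @param animal,human cohort data.frames (see [cohort_table()]).
#' @param alpha significance level.
#' @param bonferroni,m optional Bonferroni correction across `m` comparisons.
#' @return A `similarity_table` data.frame (row, kind, test, statistic,
#'   p-value, code) with attribute `score`.
#' @export
similarity_table <- function(animal, human, alpha = 0.05,
                             bonferroni = FALSE, m = 1L) {
  get_par <- function(df, p) {
    if (p == "n_side") c(df$n_side_lpa, df$n_side_rpa) else df[[p]]
  }
  rows <- similarity_rows()
  needed <- unique(unlist(lapply(rows, function(r)
    if (r$kind == "simple") r$par else c(r$a, r$b))))
  needed <- setdiff(needed, "n_side")
  miss <- setdiff(needed, names(animal))
  if (length(miss) > 0)
    stop("missing parameter columns in the cohort table: ",
         paste(miss, collapse = ", "))
  out <- list()
  for (r in rows) {
    if (r$kind == "simple") {
      tr <- compare_groups(get_par(animal, r$par), get_par(human, r$par),
                           paired = FALSE, alpha = alpha,
                           bonferroni = bonferroni, m = m, parameter = r$row)
      code <- if (tr$significant) "-" else "+"
      out[[length(out) + 1]] <- data.frame(
        row = r$row, kind = "simple", test = tr$test_name,
        statistic = tr$statistic, p_value = tr$p_value, code = code,
        stringsAsFactors = FALSE)
    } else {
      ta <- compare_groups(animal[[r$a]], animal[[r$b]], paired = TRUE,
                           alpha = alpha, bonferroni = bonferroni, m = m,
                           parameter = paste0("animal:", r$row))
      th <- compare_groups(human[[r$a]], human[[r$b]], paired = TRUE,
                           alpha = alpha, bonferroni = bonferroni, m = m,
                           parameter = paste0("human:", r$row))
      agree <- if (th$significant) {
        ta$significant && sign(ta$mean_diff) == sign(th$mean_diff)
      } else {
        !ta$significant
      }
      out[[length(out) + 1]] <- data.frame(
        row = r$row, kind = "relational", test = ta$test_name,
        statistic = ta$statistic, p_value = ta$p_value,
        code = if (agree) "+" else "-", stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  attr(tab, "score") <- sum(tab$code == "+")
  class(tab) <- c("similarity_table", class(tab))
  tab
}

#' @export
print.similarity_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("similarity score: %d / %d\n", attr(x, "score"), nrow(x)))
  invisible(x)
}
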