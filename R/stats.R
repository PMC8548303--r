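#' Summary statistics with t-based confidence interval
#'
#' Mean, median, standard deviation (n-1 denominator), standard error of
#' the mean, and the 95 percent confidence interval of the mean using the
#' Student t quantile with n-1 degrees of freedom.  The `crosses_zero`
#' flag is the symmetry verdict for one deformity parameter: a CI that
#' contains zero is consistent with left/right symmetry.
#'
#' @param x numeric vector, length >= 2.
#' @param conf confidence level (default 0.95).
#' @return a `ctma_summary` list: `n`, `mean`, `median`, `sd`, `sem`,
#'   `ci_low`, `ci_high`, `crosses_zero`.
#' @export
summarize_values <- function(x, conf = 0.95) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values not allowed")
  n <- length(x)
  if (n < 2L) stop("need at least 2 values for a confidence interval")
  m <- mean(x)
  s <- sd(x)
  sem <- s / sqrt(n)
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  ci <- m + c(-1, 1) * tq * sem
  structure(list(n = n, mean = m, median = median(x), sd = s, sem = sem,
                 ci_low = ci[1], ci_high = ci[2],
                 crosses_zero = ci[1] <= 0 && 0 <= ci[2]),
            class = "ctma_summary")
}

#' @export
print.ctma_summary <- function(x, ...) {
  cat(sprintf(
    "n %d  mean %.3f  median %.3f  sd %.3f  sem %.3f  CI [%.3f, %.3f]%s\n",
    x$n, x$mean, x$median, x$sd, x$sem, x$ci_low, x$ci_high,
    if (x$crosses_zero) "  (crosses zero)" else "  (excludes zero)"))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Royston's formulation of the Shapiro-Wilk test (the same algorithm used
#' by mainstream statistical software), for 3 <= n <= 5000.
#'
#' @param x numeric vector.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x)) < 2L) stop("Shapiro-Wilk undefined for constant input")
  if (length(x) < 3L || length(x) > 5000L) stop("need 3 <= n <= 5000")
  r <- shapiro.test(x)
  list(W = unname(r$statistic), p = r$p.value)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' The one-sample KS statistic against a normal distribution whose mean
#' and standard deviation are estimated from the data, with the Lilliefors
#' p-value approximation.  In the reporting convention of mainstream
#' statistical software, p-values beyond the tabulated range are shown as
#' a lower bound of 0.2 (`p_display = ">=0.200"`).
#'
#' @param x numeric vector, n >= 4.
#' @return list with `D`, `p` (raw approximation; `NA` for n = 4, below
#'   the approximation's range), `p_bound` (capped at 0.2) and
#'   `p_display`.
#' @export
lilliefors_ks <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x)) < 2L) stop("Lilliefors test undefined for constant input")
  n <- length(x)
  if (n < 4L) stop("need n >= 4")
  z <- pnorm(sort(x), mean(x), sd(x))
  D <- max(z - (seq_len(n) - 1) / n, seq_len(n) / n - z)
  if (n >= 5L) {
    r <- nortest::lillie.test(x)
    stopifnot(abs(unname(r$statistic) - D) < 1e-12)
    p <- r$p.value
  } else p <- NA_real_
  list(D = D, p = p, p_bound = if (is.na(p)) NA_real_ else min(p, 0.2),
       p_display = if (is.na(p)) "n < 5: p unavailable"
                   else if (p > 0.2) ">=0.200" else sprintf("%.3f", p))
}

#' Root-mean-square of a parameter about zero
#'
#' Optional per-column RMS deviation from perfect symmetry (zero), an
#' overall magnitude of asymmetry.
#'
#' @param x numeric vector.
#' @export
rms_about_zero <- function(x) sqrt(mean(as.numeric(x)^2))

#' Cohort symmetry report
#'
#' Per-parameter summary statistics and normality tests for a cohort table
#' of the six deformity parameters, the analogue of the published
#' per-cohort summary and tests-of-normality tables.
#'
#' @param table data.frame whose numeric columns are the per-subject
#'   deformity parameters (a `subject` column is ignored); needs >= 3
#'   rows.
#' @param conf confidence level for the mean CIs.
#' @return a `ctma_cohort_report`: list with `summary` (data.frame: n,
#'   mean, median, sd, sem, ci_low, ci_high, crosses_zero, rms per
#'   column) and `normality` (data.frame: shapiro_W, shapiro_p, ks_D,
#'   ks_p, ks_p_display; NA with a note where a test is undefined).
#' @export
cohort_report <- function(table, conf = 0.95) {
  num <- table[vapply(table, is.numeric, logical(1))]
  num <- num[setdiff(names(num), "subject")]
  if (nrow(num) < 3L) stop("need at least 3 subjects")
  summ <- do.call(rbind, lapply(names(num), function(nm) {
    s <- summarize_values(num[[nm]], conf)
    data.frame(parameter = nm, n = s$n, mean = s$mean, median = s$median,
               sd = s$sd, sem = s$sem, ci_low = s$ci_low,
               ci_high = s$ci_high, crosses_zero = s$crosses_zero,
               rms = rms_about_zero(num[[nm]]))
  }))
  norm <- do.call(rbind, lapply(names(num), function(nm) {
    sw <- tryCatch(shapiro_wilk(num[[nm]]), error = function(e) e)
    ks <- tryCatch(lilliefors_ks(num[[nm]]), error = function(e) e)
    data.frame(
      parameter = nm,
      shapiro_W = if (inherits(sw, "error")) NA_real_ else sw$W,
      shapiro_p = if (inherits(sw, "error")) NA_real_ else sw$p,
      ks_D = if (inherits(ks, "error")) NA_real_ else ks$D,
      ks_p = if (inherits(ks, "error")) NA_real_ else ks$p_bound,
      ks_p_display = if (inherits(ks, "error"))
        paste("undefined:", conditionMessage(ks)) else ks$p_display)
  }))
  rownames(summ) <- rownames(norm) <- NULL
  structure(list(summary = summ, normality = norm), class = "ctma_cohort_report")
}

#' @export
print.ctma_cohort_report <- function(x, ...) {
  cat("Cohort symmetry summary:\n")
  s <- x$summary
  s[, sapply(s, is.numeric)] <- round(s[, sapply(s, is.numeric)], 3)
  print(s, row.names = FALSE)
  flag <- x$summary$parameter[!x$summary$crosses_zero]
  cat(if (length(flag)) paste0("CI excludes zero (asymmetry): ",
                               paste(flag, collapse = ", "), "\n")
      else "All CIs cross zero (no asymmetry detected)\n")
  cat("\nTests of normality:\n")
  n <- x$normality
  n[, sapply(n, is.numeric)] <- round(n[, sapply(n, is.numeric)], 3)
  print(n, row.names = FALSE)
  invisible(x)
}

#' Render a cohort report to markdown
#' @param report a `ctma_cohort_report`.
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  df_md <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.3f", v))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                            " |"))
    c(header, sep, rows)
  }
  c("## Cohort symmetry summary", "", df_md(report$summary), "",
    "## Tests of normality", "", df_md(report$normality))
}

#' Write cohort report tables to CSV
#' @param report a `ctma_cohort_report`.
#' @param dir output directory (created if needed).
#' @return paths, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "summary.csv")
  p2 <- file.path(dir, "normality.csv")
  write.csv(report$summary, p1, row.names = FALSE)
  write.csv(report$normality, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
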