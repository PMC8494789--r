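# Demographic/clinical group-comparison statistics, computable from summary
# statistics (mean, SD, n per group) or 2x2 counts.

#' Two-sample t test from group summaries
#'
#' Student's pooled-variance t, or Welch's t with Satterthwaite degrees of
#' freedom; `"auto"` applies an F-ratio variance-equality screen at the 0.05
#' level and switches to Welch when the variances differ.
#'
#' @param mean1,sd1,n1 first group summary (n >= 2).
#' @param mean2,sd2,n2 second group summary.
#' @param varianceRule `"auto"`, `"student"` or `"welch"`.
#' @return list with `t`, `df`, `p` (two-sided) and `method`.
#' @export
twoSampleT <- function(mean1, sd1, n1, mean2, sd2, n2,
                       varianceRule = c("auto", "student", "welch")) {
  varianceRule <- match.arg(varianceRule)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be nonnegative")
  if (varianceRule == "auto") {
    f <- (sd1^2) / (sd2^2)
    pVar <- 2 * min(stats::pf(f, n1 - 1, n2 - 1),
                    1 - stats::pf(f, n1 - 1, n2 - 1))
    varianceRule <- if (pVar < 0.05) "welch" else "student"
  }
  if (varianceRule == "student") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       method = ifelse(varianceRule == "student",
                       "Student pooled-variance t", "Welch t"))
}

#' Pearson chi-square test of a 2x2 table
#'
#' Uncorrected (no continuity correction), matching the usual reporting of
#' sex ratios and similar categorical comparisons.
#'
#' @param counts 2x2 matrix of counts with positive margins.
#' @return list with `chisq`, `df` (1) and `p`.
#' @export
chiSquare2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be 2x2")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all table margins must be positive")
  ht <- stats::chisq.test(counts, correct = FALSE)
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Fisher's exact test of a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities no larger than that
#' of the observed table.
#'
#' @param counts 2x2 matrix of counts with positive margins.
#' @return two-sided p-value.
#' @export
fisherExact2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be 2x2")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all table margins must be positive")
  stats::fisher.test(counts)$p.value
}

#' Demographics comparison report
#'
#' Reads a summary table and prints the group-comparison statistic for each
#' row. Continuous rows (`type = "continuous"`) need columns mean1, sd1,
#' n1, mean2, sd2, n2 and are compared with [twoSampleT()] (auto
#' Student/Welch switch); categorical rows (`type = "categorical"`) need
#' counts a, b, c, d ([a,b] group 1, [c,d] group 2) and are compared with
#' the chi-square test, or Fisher's exact test when any expected cell count
#' is 5 or smaller.
#'
#' @param path TSV with columns `variable`, `type` and the columns above.
#' @return invisibly, a data.frame (`variable`, `statistic`, `value`, `p`).
#' @export
tableStatsReport <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (row$type == "continuous") {
      r <- twoSampleT(row$mean1, row$sd1, row$n1, row$mean2, row$sd2, row$n2)
      data.frame(variable = row$variable, statistic = "t",
                 value = r$t, p = r$p)
    } else {
      m <- matrix(c(row$a, row$b, row$c, row$d), 2, 2, byrow = TRUE)
      expected <- outer(rowSums(m), colSums(m)) / sum(m)
      if (any(expected <= 5)) {
        data.frame(variable = row$variable, statistic = "fisher.p",
                   value = NA_real_, p = fisherExact2x2(m))
      } else {
        r <- chiSquare2x2(m)
        data.frame(variable = row$variable, statistic = "chisq",
                   value = r$chisq, p = r$p)
      }
    }
  })
  out <- do.call(rbind, out)
  for (i in seq_len(nrow(out)))
    cat(sprintf("%-20s %-8s %8s  p = %.3g\n", out$variable[i],
                out$statistic[i],
                ifelse(is.na(out$value[i]), "-",
                       sprintf("%.3f", out$value[i])), out$p[i]))
  invisible(out)
}
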