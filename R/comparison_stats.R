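# Across-subject statistical comparison of model fits: Fisher z transform of
# correlation values, paired t-tests, and one-way within-subject
# (repeated-measures) ANOVA with Bonferroni-corrected post-hoc tests.

#' Fisher z-transformation
#'
#' `z = atanh(r)`, mapping correlation coefficients to approximately normal
#' scores before parametric testing.
#'
#' @param r correlation value(s), strictly inside (-1, 1).
#' @return z-score(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    bfb_stop("domain_error", "fisher_z requires |r| < 1")
  atanh(r)
}

# R values for testing: r = +sqrt(R2) when R2 >= 0; negative uncentered R2
# has no correlation interpretation, so those subjects are dropped with a
# warning (documented design decision; see the methods vignette).
r_from_r2 <- function(r2) {
  neg <- r2 < 0
  if (any(neg))
    warning(sprintf("dropping %d value(s) with negative uncentered R2 %s",
                    sum(neg), "from the Fisher-z comparison"))
  r <- sqrt(pmax(r2, 0))
  r[neg] <- NA_real_
  r
}

paired_t_core <- function(d) {
  n <- length(d)
  if (all(d == 0)) return(list(t = 0, df = n - 1L, p = 1))
  sdd <- sd(d)
  if (sdd == 0)
    bfb_stop("degenerate_test_error",
             "differences have zero variance (constant non-zero offset)")
  tval <- mean(d) / (sdd / sqrt(n))
  list(t = tval, df = n - 1L, p = 2 * pt(-abs(tval), df = n - 1L))
}

#' Paired comparison of two models across subjects
#'
#' Two-sided paired t-test of per-subject fit values for two models. With
#' `on_r = TRUE` the inputs are treated as uncentered R-squared values and
#' Fisher-z-transformed (via `r = sqrt(R2)`) before testing, the transform
#' used for correlation-type quantities; RMSE-type values are compared
#' untransformed (`on_r = FALSE`). Identical vectors return `t = 0, p = 1`;
#' a constant non-zero difference is a degenerate design and errors.
#'
#' @param per_subject_a,per_subject_b equal-length paired value vectors
#'   (one entry per subject), length >= 3.
#' @param on_r apply the Fisher z transform first.
#' @param labels character(2) naming the compared models.
#' @return an object of class `comparison_result` with fields `test`,
#'   `transformed`, `statistic`, `df`, `p`, `correction`, `contrast`, `n`.
#' @export
paired_model_test <- function(per_subject_a, per_subject_b, on_r = TRUE,
                              labels = c("model_a", "model_b")) {
  if (length(per_subject_a) != length(per_subject_b))
    bfb_stop("argument_error", "paired vectors must have equal length")
  a <- per_subject_a; b <- per_subject_b
  if (on_r) {
    a <- fisher_z_safe(a); b <- fisher_z_safe(b)
  }
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 3L)
    bfb_stop("argument_error", "need >= 3 usable subject pairs, got %d",
             sum(keep))
  res <- paired_t_core(a[keep] - b[keep])
  structure(list(test = "paired_t", transformed = on_r,
                 statistic = res$t, df = res$df, p = res$p,
                 correction = "none", contrast = labels, n = sum(keep)),
            class = "comparison_result")
}

fisher_z_safe <- function(r2) {
  r <- r_from_r2(r2)
  out <- rep(NA_real_, length(r))
  ok <- is.finite(r) & abs(r) < 1
  out[ok] <- atanh(r[ok])
  out[is.finite(r) & r >= 1] <- atanh(1 - 1e-12)  # perfect fits: cap
  out
}

#' One-way repeated-measures ANOVA with Bonferroni post-hoc tests
#'
#' Within-subject ANOVA over gain-model conditions (e.g. constant vs
#' Fy-modulated vs COP-modulated) on a complete subject x condition matrix,
#' with F computed from the within-subject sums-of-squares decomposition (no
#' sphericity correction). Post-hoc pairwise paired t-tests carry
#' Bonferroni-multiplied p-values capped at 1.
#'
#' @param per_subject_by_condition numeric matrix, rows = subjects,
#'   columns = conditions (named), complete (no missing cells), >= 3 subjects
#'   and >= 2 conditions.
#' @param on_r Fisher-z-transform R-squared inputs first.
#' @return a `comparison_result` with `test = "rm_anova"`, the F statistic,
#'   its p-value, and a `posthoc` data.frame of pairwise corrected p-values.
#' @export
rm_anova_bonferroni <- function(per_subject_by_condition, on_r = TRUE) {
  m <- as.matrix(per_subject_by_condition)
  if (anyNA(m))
    bfb_stop("incomplete_design_error",
             "subject x condition matrix has missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L)
    bfb_stop("argument_error", "need >= 3 subjects and >= 2 conditions")
  if (is.null(colnames(m))) colnames(m) <- paste0("cond", seq_len(k))
  if (on_r) {
    m <- apply(m, 2L, fisher_z_safe)
    if (anyNA(m))
      bfb_stop("incomplete_design_error",
               "negative R2 left missing cells after the Fisher transform")
  }
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_cond <- k - 1L
  df_err <- (n - 1L) * (k - 1L)
  ms_err <- ss_err / df_err
  if (ms_err <= 1e-300) {
    fval <- 0; p <- 1
    if (ss_cond > 1e-12)
      bfb_stop("degenerate_test_error",
               "zero error variance with non-zero condition effect")
  } else {
    fval <- (ss_cond / df_cond) / ms_err
    p <- pf(fval, df_cond, df_err, lower.tail = FALSE)
  }
  pairs <- utils::combn(colnames(m), 2L)
  n_cmp <- ncol(pairs)
  posthoc <- data.frame(a = pairs[1, ], b = pairs[2, ], t = NA_real_,
                        p_uncorrected = NA_real_, p_bonferroni = NA_real_)
  for (j in seq_len(n_cmp)) {
    res <- paired_t_core(m[, pairs[1, j]] - m[, pairs[2, j]])
    posthoc$t[j] <- res$t
    posthoc$p_uncorrected[j] <- res$p
    posthoc$p_bonferroni[j] <- min(1, res$p * n_cmp)
  }
  structure(list(test = "rm_anova", transformed = on_r, statistic = fval,
                 df = c(df_cond, df_err), p = p, correction = "bonferroni",
                 contrast = colnames(m), n = n, posthoc = posthoc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (%s%s): statistic=%.4g, p=%.4g (n=%d)\n",
              x$test, paste(x$contrast, collapse = " vs "),
              if (x$transformed) ", Fisher z" else "", x$statistic, x$p, x$n))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc (Bonferroni):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize comparison results to CSV
#'
#' @param comparisons a `comparison_result` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(comparisons, path) {
  if (inherits(comparisons, "comparison_result"))
    comparisons <- list(comparisons)
  rows <- lapply(comparisons, function(cr)
    data.frame(test = cr$test,
               contrast = paste(cr$contrast, collapse = " vs "),
               transformed = cr$transformed, statistic = cr$statistic,
               p = cr$p, correction = cr$correction, n = cr$n))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
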