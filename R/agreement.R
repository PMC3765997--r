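#' Intraclass correlation from a two-way random-effects model
#'
#' Single-measures ICC for a complete subjects x raters matrix, computed
#' from the mean squares of the two-way ANOVA without replication
#' (`value ~ subject + rater`). Two forms are offered:
#' \describe{
#'   \item{consistency}{`(MS_rows - MS_err) / (MS_rows + (k - 1) MS_err)` —
#'     insensitive to a systematic offset between raters, appropriate when
#'     one method is expected to read systematically lower (e.g. incomplete
#'     fat retrieval at autopsy).}
#'   \item{absolute}{`(MS_rows - MS_err) / (MS_rows + (k - 1) MS_err +
#'     k (MS_cols - MS_err) / n)` — penalizes systematic rater differences.}
#' }
#' The p-value is from the F test on the subject effect,
#' `F = MS_rows / MS_err` on `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' @param table A numeric matrix or data frame, subjects in rows, raters
#'   (methods/observers) in columns; no missing cells.
#' @param form `"consistency"` or `"absolute"`.
#' @return A `pat_icc` object; see [tidy.pat_icc()].
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1.1, 2.2, 2.9, 4.3))
#' icc(m, "consistency")
#' @export
icc <- function(table, form = c("consistency", "absolute")) {
  form <- match.arg(form)
  m <- as.matrix(table)
  if (!is.numeric(m)) abort("ICC table must be numeric")
  if (anyNA(m)) abort("ICC table has missing cells; no imputation is done")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) abort("ICC needs >= 2 subjects and >= 2 raters")
  if (stats::var(as.vector(m)) == 0)
    abort("ICC undefined: no variance across subjects")
  long <- data.frame(value = as.vector(m),
                     subject = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(value ~ subject + rater, data = long)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  ms_rows <- ms[1]; ms_cols <- ms[2]; ms_err <- ms[3]
  denom <- if (form == "consistency") ms_rows + (k - 1) * ms_err
           else ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n
  if (!is.finite(denom) || denom <= 0)
    abort("ICC undefined: no variance across subjects")
  est <- (ms_rows - ms_err) / denom
  f <- ms_rows / ms_err
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = est, form = form,
                 model = "two-way random effects, single measures",
                 n_subjects = n, n_raters = k,
                 ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_err,
                 f_statistic = f, p_value = p),
            class = "pat_icc")
}

#' @export
print.pat_icc <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.4f  [%s; n = %d subjects, k = %d raters; F = %.3g, p = %.3g]\n",
              x$form, x$icc, x$model, x$n_subjects, x$n_raters,
              x$f_statistic, x$p_value))
  invisible(x)
}

#' Bland-Altman agreement between two measurement methods
#'
#' Differences are oriented second minus first (`b - a`), so with the
#' reference method first a positive bias means the second method
#' over-estimates. Limits of agreement are `bias +/- k * SD` of the
#' differences (sample SD, `n - 1` denominator).
#'
#' @param a,b Numeric vectors of paired measurements (same length, >= 2), or
#'   `a` may be a two-column matrix/data frame with `b` omitted.
#' @param k Limits-of-agreement multiplier; default 2, with 1.96 the common
#'   alternative.
#' @return A `pat_bland_altman` object; see [tidy.pat_bland_altman()].
#' @examples
#' ba <- bland_altman(c(10, 20, 30), c(11, 22, 33))
#' ba$bias
#' @export
bland_altman <- function(a, b = NULL, k = 2) {
  if (is.null(b)) {
    m <- as.matrix(a)
    if (ncol(m) != 2L) abort("need two methods")
    a <- m[, 1]; b <- m[, 2]
  }
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  if (length(a) < 2L) abort("Bland-Altman needs >= 2 pairs")
  if (anyNA(a) || anyNA(b)) abort("paired measurements must be complete")
  d <- b - a
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff, k = k,
                 loa_lower = bias - k * sd_diff,
                 loa_upper = bias + k * sd_diff,
                 half_width = k * sd_diff, n = length(d),
                 data = tibble::tibble(mean = (a + b) / 2, diff = d)),
            class = "pat_bland_altman")
}

#' @export
print.pat_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3g, limits of agreement [%.3g, %.3g] (k = %g, n = %d)\n",
              x$bias, x$loa_lower, x$loa_upper, x$k, x$n))
  invisible(x)
}

#' Full agreement report for a paired measurement table
#'
#' For every quantity in the table, computes per-method mean and SD, the
#' Bland-Altman bias and limits of agreement (second method minus first),
#' and the two-way random-effects single-measures ICC in both forms.
#'
#' @param paired_table A `pat_paired_table` from [read_paired_table()], or
#'   any data frame with `subject`, `quantity` and two numeric method
#'   columns.
#' @param k Limits-of-agreement multiplier (default 2).
#' @return A tibble of class `pat_agreement_report`, one row per quantity,
#'   with columns `quantity`, `n`, `mean_<method>`, `sd_<method>` for each
#'   method, `bias`, `sd_diff`, `loa_half_width`, `loa_lower`, `loa_upper`,
#'   `icc_consistency`, `icc_absolute`, `p_value` (F test on the subject
#'   effect).
#' @examples
#' tab <- read_paired_table(pat_example("sheep_pat_autopsy_cmr.csv"))
#' agreement_report(tab)
#' @export
agreement_report <- function(paired_table, k = 2) {
  methods <- attr(paired_table, "methods")
  if (is.null(methods))
    methods <- setdiff(names(paired_table), c("subject", "quantity"))
  if (length(methods) != 2L)
    abort("paired table must have exactly two method columns")
  if (!all(c("subject", "quantity") %in% names(paired_table)))
    abort("paired table must have `subject` and `quantity` columns")
  rows <- lapply(split(as.data.frame(paired_table),
                       paired_table$quantity), function(df) {
    if (nrow(df) < 2L)
      abort(sprintf("quantity `%s` has fewer than 2 subjects", df$quantity[1]))
    if (anyNA(df[methods]))
      abort(sprintf("quantity `%s` has missing values", df$quantity[1]))
    va <- df[[methods[1]]]; vb <- df[[methods[2]]]
    ba <- bland_altman(va, vb, k = k)
    ic <- icc(cbind(va, vb), "consistency")
    ia <- icc(cbind(va, vb), "absolute")
    out <- tibble::tibble(quantity = df$quantity[1], n = nrow(df))
    out[[paste0("mean_", methods[1])]] <- mean(va)
    out[[paste0("sd_", methods[1])]] <- stats::sd(va)
    out[[paste0("mean_", methods[2])]] <- mean(vb)
    out[[paste0("sd_", methods[2])]] <- stats::sd(vb)
    dplyr::bind_cols(out, tibble::tibble(
      bias = ba$bias, sd_diff = ba$sd_diff,
      loa_half_width = ba$half_width,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      icc_consistency = ic$icc, icc_absolute = ia$icc,
      p_value = ic$p_value))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "methods") <- methods
  attr(out, "k") <- k
  class(out) <- c("pat_agreement_report", class(out))
  out
}
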