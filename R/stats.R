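# Nonparametric cohort comparisons: Mann-Whitney U and Wilcoxon signed-rank
# with tie-corrected normal approximations (0.5 continuity correction),
# common language effect size by pair enumeration, Spearman correlation, and
# the bronchodilator responder rule. z statistics are computed explicitly so
# that published-style comparison tables (parameter, medians/IQRs, z, p,
# CLES) can be reproduced; p values are left unadjusted, with the
# Bonferroni-adjusted threshold reported as an annotation.

tie_sizes <- function(r) {
  t <- table(r)
  as.numeric(t[t > 1])
}

#' Mann-Whitney U test (normal approximation)
#'
#' U counts pairs in which the second sample exceeds the first (ties count
#' one half). z uses the tie-corrected normal approximation with a 0.5
#' continuity correction; p is two-sided.
#'
#' @param x,y numeric vectors (two independent groups), each of length >= 2.
#' @return list with `U` (for the "y greater" direction), `z`, `p_value`.
#' @export
mwu_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- tie_sizes(r)
  s2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (s2 <= 0) return(list(U = U, z = 0, p_value = 1))
  cc <- sign(U - mu) * 0.5
  z <- (U - mu - cc) / sqrt(s2)
  if (sign(z) != sign(U - mu) && U != mu) z <- 0  # continuity overshoot
  if (U == mu) z <- 0
  list(U = U, z = z, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Zero differences are dropped; W is the sum of ranks of positive
#' differences (`post - pre`); z uses the tie-corrected normal approximation
#' with continuity correction; p is two-sided.
#'
#' @param pre,post paired numeric vectors of equal length >= 2.
#' @return list with `W`, `z`, `p_value`, `n_nonzero`.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  if (length(pre) < 2) stop("need >= 2 pairs")
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, z = 0, p_value = 1, n_nonzero = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- tie_sizes(r)
  s2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (s2 <= 0) return(list(W = W, z = 0, p_value = 1, n_nonzero = n))
  cc <- sign(W - mu) * 0.5
  z <- (W - mu - cc) / sqrt(s2)
  if (W == mu) z <- 0
  list(W = W, z = z, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       n_nonzero = as.integer(n))
}

#' Common language effect size, unpaired
#'
#' Percentage of all cross-group pairs satisfying the hypothesized direction,
#' ties counting one half; equals `100 * U / (n1 * n2)` for the matching U.
#'
#' @param x,y the two groups.
#' @param direction `"y_greater"` (default) or `"x_greater"`.
#' @return percent in \[0, 100\].
#' @export
cles_unpaired <- function(x, y, direction = c("y_greater", "x_greater")) {
  direction <- match.arg(direction)
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  U_y <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  U <- if (direction == "y_greater") U_y else n1 * n2 - U_y
  100 * U / (n1 * n2)
}

#' Common language effect size, paired
#'
#' Percentage of pairs changing in the hypothesized direction; pairs with no
#' change count one half.
#'
#' @param pre,post paired vectors of equal length >= 1.
#' @param direction `"decrease"` (post < pre) or `"increase"`.
#' @return percent in \[0, 100\].
#' @export
cles_paired <- function(pre, post, direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (length(pre) != length(post) || !length(pre))
    stop("pre and post must be nonempty and paired")
  d <- post - pre
  hit <- if (direction == "decrease") d < 0 else d > 0
  100 * (sum(hit) + 0.5 * sum(d == 0)) / length(d)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Average ranks for ties; two-sided p from the t approximation with n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need >= 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Classify bronchodilator responders
#'
#' A subject responds when FEV1 increases by at least 12% of the
#' pre-bronchodilator value (`(post - pre)/pre >= 0.12`).
#'
#' @param fev1_pre,fev1_post paired FEV1 values (any consistent unit),
#'   `fev1_pre` strictly positive.
#' @param subject_ids optional ids.
#' @return data frame with `subject_id`, `change_pct`, `responder`.
#' @export
classify_responders <- function(fev1_pre, fev1_post, subject_ids = NULL) {
  if (length(fev1_pre) != length(fev1_post)) stop("inputs must be paired")
  if (any(fev1_pre <= 0)) stop("nonpositive pre-bronchodilator FEV1")
  if (is.null(subject_ids)) subject_ids <- seq_along(fev1_pre)
  change <- (fev1_post - fev1_pre) / fev1_pre
  data.frame(subject_id = subject_ids, change_pct = 100 * change,
             responder = change >= 0.12)
}

#' Compare two cohorts of subject summaries parameter by parameter
#'
#' One row per `m_`/`v_` parameter column shared by the two summary tables:
#' group medians and IQRs, the test statistic (Mann-Whitney U for independent
#' groups, Wilcoxon signed-rank for paired pre/post contrasts), the
#' unadjusted two-sided p value, and the common language effect size in the
#' hypothesized direction. The Bonferroni-adjusted significance threshold
#' `0.05 / n_comparisons` is attached as an annotation, mirroring the
#' practice of reporting unadjusted p values alongside it.
#'
#' @param summaries_a,summaries_b data frames from [summarize_subject()] /
#'   [summarize_cohort()]. For `paired = TRUE`, rows are matched by
#'   `subject_id` suffix-insensitively: ids must correspond one-to-one after
#'   stripping the group prefix, or be identical.
#' @param paired use the signed-rank test on subject-matched rows.
#' @param directions optional named character vector: for each parameter,
#'   `"b_greater"`/`"a_greater"` (unpaired) or `"decrease"`/`"increase"`
#'   (paired). Defaults to `"b_greater"` / `"decrease"`.
#' @return data frame of class `slp_comparison` with columns `parameter`,
#'   `median_a`, `iqr_a`, `median_b`, `iqr_b`, `z`, `p_value`,
#'   `cles_percent`, `test`; attributes `n_comparisons` and
#'   `bonferroni_threshold`.
#' @export
compare_groups <- function(summaries_a, summaries_b, paired = FALSE,
                           directions = NULL) {
  if (nrow(summaries_a) < 2 || nrow(summaries_b) < 2)
    stop("each group needs >= 2 subjects")
  pcols <- intersect(grep("^(m|v)_", names(summaries_a), value = TRUE),
                     grep("^(m|v)_", names(summaries_b), value = TRUE))
  if (paired) {
    strip <- function(id) sub("^[A-Za-z_]*_", "", id)
    ka <- strip(summaries_a$subject_id); kb <- strip(summaries_b$subject_id)
    if (nrow(summaries_a) != nrow(summaries_b) ||
        !setequal(ka, kb) || anyDuplicated(ka) || anyDuplicated(kb))
      stop("paired comparison requires matched subject ids")
    summaries_b <- summaries_b[match(ka, kb), , drop = FALSE]
  }
  rows <- lapply(pcols, function(p) {
    a <- summaries_a[[p]]; b <- summaries_b[[p]]
    ok <- !is.na(a) & !is.na(b)
    if (paired) { a <- a[ok]; b <- b[ok] }
    else { a <- a[!is.na(a)]; b <- b[!is.na(b)] }
    dir <- if (!is.null(directions) && p %in% names(directions))
      directions[[p]] else if (paired) "decrease" else "b_greater"
    if (paired) {
      tst <- wilcoxon_signed_rank(a, b)
      cles <- cles_paired(a, b, dir)
      test <- "wilcoxon"
    } else {
      tst <- mwu_test(a, b)
      cles <- cles_unpaired(a, b,
                            if (dir == "b_greater") "y_greater" else "x_greater")
      test <- "mwu"
    }
    data.frame(parameter = p,
               median_a = stats::median(a), iqr_a = stats::IQR(a, type = 7),
               median_b = stats::median(b), iqr_b = stats::IQR(b, type = 7),
               z = tst$z, p_value = tst$p_value, cles_percent = cles,
               test = test)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_comparisons") <- nrow(out)
  attr(out, "bonferroni_threshold") <- 0.05 / nrow(out)
  class(out) <- c("slp_comparison", class(out))
  out
}

#' @export
print.slp_comparison <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, 2)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, digits))
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("\n%d comparisons; Bonferroni-adjusted threshold 0.05/%d = %.4g (p values unadjusted)\n",
              attr(x, "n_comparisons"), attr(x, "n_comparisons"),
              attr(x, "bonferroni_threshold")))
  invisible(x)
}
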