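#' One-way fixed-effects ANOVA across groups
#'
#' The classical between/within decomposition for independent samples, fitted
#' with \code{stats::lm}/\code{stats::anova}. Group order is the order of the
#' input list (declared factor order), never lexical.
#'
#' @param groups named list of numeric vectors, one per group (>= 2 groups).
#' @param pairwise if TRUE, append a Bonferroni-corrected pairwise table
#'   (see [bonferroni_pairwise()]).
#' @return An object of class \code{comparison_result}: list with
#'   \code{levels}, \code{f}, \code{df} (length-2), \code{p}, \code{means},
#'   \code{n}, and optionally \code{pairwise}. With zero residual variance
#'   the F statistic is undefined and reported as NA.
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6)))$f   # 13.5
#' @export
anova_oneway <- function(groups, pairwise = FALSE) {
  groups <- validate_groups(groups)
  lv <- names(groups)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(lv, lengths(groups)), levels = lv))
  if (nrow(df) <= length(lv))
    stop("total observations must exceed the number of groups")
  fit <- stats::lm(value ~ group, data = df)
  # zero-residual fits are handled explicitly below; silence lm's complaint
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ms_within <- an["Residuals", "Mean Sq"]
  f <- an["group", "F value"]
  p <- an["group", "Pr(>F)"]
  scale <- mean((df$value - mean(df$value))^2)
  if (!is.finite(ms_within) || ms_within <= 1e-12 * max(scale, 1e-300)) {
    if (an["group", "Mean Sq"] == 0) {        # identical groups: no effect
      f <- 0; p <- 1
    } else {                                  # zero within-group variance
      f <- NA_real_; p <- NA_real_
    }
  }
  res <- structure(
    list(levels = lv, f = f, df = c(an["group", "Df"], an["Residuals", "Df"]),
         p = p,
         means = vapply(groups, mean, numeric(1)),
         n = lengths(groups),
         ms_within = ms_within, df_within = an["Residuals", "Df"]),
    class = "comparison_result")
  if (pairwise) res$pairwise <- bonferroni_pairwise(groups)
  res
}

validate_groups <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 1L)) stop("every group needs at least 1 value")
  groups
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> F(%d, %d) = %s, p = %s\n",
              x$df[1], x$df[2],
              if (is.na(x$f)) "undefined" else sprintf("%.4g", x$f),
              if (is.na(x$p)) "undefined" else sprintf("%.4g", x$p)))
  if (!is.null(x$subjects_per_group)) {
    cat("subjects per group:",
        paste(sprintf("%s=%d", names(x$subjects_per_group),
                      x$subjects_per_group), collapse = ", "), "\n")
    if (length(x$flagged_groups))
      cat("flagged (single subject):", paste(x$flagged_groups, collapse = ", "),
          "\n")
  }
  if (!is.null(x$pairwise)) print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Subject-aware ANOVA for repeated measurements
#'
#' When several measurements come from the same individual (e.g. many hair
#' cells per animal), the individual is the inferential unit. Measurements
#' are aggregated to per-subject means within each group and a one-way
#' fixed-effects ANOVA is run on the subject means, which keeps the type-I
#' error at its nominal level where naive pooling inflates it.
#'
#' @param values numeric vector of measurements.
#' @param group group label per measurement.
#' @param subject subject identifier per measurement (unique across groups,
#'   or nested labels per group).
#' @param pairwise if TRUE, append a Bonferroni-corrected pairwise table on
#'   the subject means.
#' @return a \code{comparison_result} as in [anova_oneway()], with
#'   \code{subjects_per_group} and \code{flagged_groups} (groups retained
#'   with a single subject) added.
#' @export
anova_subject_aware <- function(values, group, subject, pairwise = FALSE) {
  stopifnot(length(values) == length(group), length(values) == length(subject))
  group <- as.character(group)
  lv <- unique(group)
  agg <- tapply(values, list(paste(group, subject, sep = "\r")), mean)
  keys <- strsplit(names(agg), "\r", fixed = TRUE)
  agg_group <- vapply(keys, `[`, character(1), 1)
  groups <- split(unname(agg), factor(agg_group, levels = lv))
  n_subj <- lengths(groups)
  res <- anova_oneway(groups, pairwise = pairwise)
  res$subjects_per_group <- n_subj
  res$flagged_groups <- names(n_subj)[n_subj < 2L]
  if (length(res$flagged_groups))
    warning("group(s) with a single subject retained: ",
            paste(res$flagged_groups, collapse = ", "),
            "; degrees of freedom reduced accordingly")
  res
}

#' Bonferroni-corrected pairwise post hoc tests
#'
#' All pairwise comparisons between groups using t statistics built on the
#' pooled within-group mean square of the one-way ANOVA, with the raw p
#' multiplied by the number of pairs and capped at 1. Planned comparisons
#' skip the correction.
#'
#' @param groups named list of numeric vectors.
#' @param planned if TRUE, no multiplicity correction is applied.
#' @return data.frame with one row per pair: \code{level1}, \code{level2},
#'   \code{mean_difference}, \code{p_raw}, \code{p_corrected},
#'   \code{significance} ("*" for p < 0.05, "**" for p < 0.01 on the
#'   corrected p).
#' @export
bonferroni_pairwise <- function(groups, planned = FALSE) {
  groups <- validate_groups(groups)
  lv <- names(groups)
  k <- length(lv)
  npairs <- k * (k - 1) / 2
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_within <- sum(n) - k
  if (df_within < 1L) stop("no residual degrees of freedom for pairwise tests")
  mse <- ss_within / df_within
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    diff <- means[i] - means[j]
    se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
    p_raw <- if (se == 0) as.numeric(diff != 0) * 0 + (diff == 0) else
      2 * stats::pt(-abs(diff / se), df_within)
    p_corr <- if (planned) p_raw else min(1, p_raw * npairs)
    data.frame(level1 = lv[i], level2 = lv[j], mean_difference = unname(diff),
               p_raw = unname(p_raw), p_corrected = unname(p_corr),
               significance = sig_stars(p_corr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
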