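#' Two-sided Wilcoxon rank-sum test
#'
#' Thin surface over the rank-sum (Mann-Whitney) test with the exactness
#' rule fixed: the exact permutation distribution is used whenever the
#' combined sample size is at most 25 and there are no ties, and the
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param alternative passed through (default two-sided).
#' @return the p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two observations")
  no_ties <- !anyDuplicated(c(a, b))
  use_exact <- (length(a) + length(b) <= 25L) && no_ties
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative,
                       exact = use_exact, correct = TRUE)$p.value)
}

#' Group comparison of RGF features and fibroglandular composition
#'
#' For every (region, feature) cell of a cohort table, and once for the
#' per-subject fibroglandular composition (FC), computes the two group
#' means and the two-sided Wilcoxon rank-sum p-value between the
#' non-sparse and sparse groups. Significance is flagged at alpha = 0.05
#' per test, matching per-feature reporting without multiple-testing
#' correction; note that each region contributes a family of 13 tests.
#'
#' @param table a cohort feature table from [cohort_features()] (columns
#'   `subject`, `region`, `f1`..`f13`, `fc`, `label`).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `region`, `feature` (1..13 or "FC"),
#'   `mean_nonsparse`, `mean_sparse`, `p_value`, `significant`.
#' @export
compare_groups <- function(table, alpha = 0.05) {
  check_cohort_table(table)
  labs <- unique(table$label)
  if (!all(c("nonsparse", "sparse") %in% labs))
    stop("both group labels (nonsparse, sparse) must be present")
  rows <- list()
  for (reg in unique(table$region)) {
    sub <- table[table$region == reg, ]
    for (k in 1:13) {
      v <- sub[[paste0("f", k)]]
      a <- v[sub$label == "nonsparse"]; b <- v[sub$label == "sparse"]
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, feature = as.character(k),
        mean_nonsparse = mean(a), mean_sparse = mean(b),
        p_value = wilcoxon_rank_sum(a, b))
    }
  }
  subj <- table[!duplicated(table$subject), ]
  rows[[length(rows) + 1L]] <- data.frame(
    region = "breast", feature = "FC",
    mean_nonsparse = mean(subj$fc[subj$label == "nonsparse"]),
    mean_sparse = mean(subj$fc[subj$label == "sparse"]),
    p_value = wilcoxon_rank_sum(subj$fc[subj$label == "nonsparse"],
                                subj$fc[subj$label == "sparse"]))
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out
}

check_cohort_table <- function(table) {
  need <- c("subject", "region", paste0("f", 1:13), "fc", "label")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(table) == 0) stop("cohort table is empty")
  if (anyDuplicated(table[, c("subject", "region")]))
    stop("cohort table has duplicate (subject, region) rows")
  invisible(table)
}
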