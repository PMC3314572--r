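#' Per-gene two-sample t statistics
#'
#' Computes, for every gene, the pooled-variance two-sample t statistic
#' contrasting group A against group B:
#' \deqn{T_i = \frac{\bar x_{Ai} - \bar x_{Bi}}
#'   {s_{pool,i}\sqrt{1/n_A + 1/n_B}}}
#' with \eqn{s^2_{pool,i} = ((n_A-1)s^2_{Ai} + (n_B-1)s^2_{Bi})/(n_A+n_B-2)}.
#' Genes whose pooled variance is zero get a non-finite statistic, are
#' excluded from the ranking, and trigger a warning: they carry no usable
#' scale for the plain t statistic (use [sam_statistic()] to stabilise them).
#'
#' @param data An [expression_dataset()]; each class must have at least two
#'   samples.
#' @return A `gene_score_table`: a tibble with columns `gene_id`, `statistic`
#'   and `rank` (1 = largest absolute statistic; ties broken by gene order;
#'   `NA` for excluded genes), plus a `method` attribute.
#' @seealso [sam_statistic()], [select_seeds()]
#' @export
t_statistic <- function(data) {
  stats <- group_stats(data)
  se <- stats$s_pool * stats$se_factor
  t_i <- ifelse(se > 0, (stats$mean_a - stats$mean_b) / se, NaN)
  new_score_table(rownames(data$values), t_i, method = "t")
}

#' Per-gene SAM-style moderated t statistics
#'
#' A two-sample t statistic with a small positive constant `s0` (the "fudge
#' factor") added to the per-gene standard error, so that genes with tiny
#' variance do not dominate the ranking:
#' \deqn{T_i = \frac{\bar x_{Ai} - \bar x_{Bi}}{se_i + s_0},\qquad
#'   se_i = s_{pool,i}\sqrt{1/n_A + 1/n_B}.}
#'
#' By default `s0` is the median of the gene-wise standard errors `se_i`; a
#' fixed value or a percentile of the `se_i` distribution can be requested
#' instead. With `s0 = 0` the result equals [t_statistic()] exactly.
#'
#' @inheritParams t_statistic
#' @param s0 Fixed non-negative fudge constant, or `NULL` (default) to use
#'   the `s0_quantile` rule.
#' @param s0_quantile Percentile (0-100) of the gene-wise standard errors
#'   used when `s0` is `NULL`; default 50 (the median).
#' @return A `gene_score_table` (see [t_statistic()]) with
#'   `method = "sam"` and an `s0` attribute recording the constant used.
#' @export
sam_statistic <- function(data, s0 = NULL, s0_quantile = 50) {
  stats <- group_stats(data)
  se <- stats$s_pool * stats$se_factor
  if (is.null(s0)) {
    if (!is.numeric(s0_quantile) || length(s0_quantile) != 1L ||
        s0_quantile < 0 || s0_quantile > 100) {
      stopf("`s0_quantile` must be a single value in [0, 100].")
    }
    s0 <- unname(stats::quantile(se, s0_quantile / 100, type = 7))
  } else if (!is_scalar_number(s0) || s0 < 0) {
    stopf("`s0` must be a single non-negative number.")
  }
  if (all(se == 0) && s0 == 0) {
    stopf("Degenerate dataset: every gene has zero pooled standard error.")
  }
  denom <- se + s0
  t_i <- ifelse(denom > 0, (stats$mean_a - stats$mean_b) / denom, NaN)
  out <- new_score_table(rownames(data$values), t_i, method = "sam")
  attr(out, "s0") <- s0
  out
}

#' Select the top-ranked seed genes
#'
#' Returns the `m` genes with the largest absolute statistic, in rank order.
#' Ties are broken by ascending position in the score table, so the selection
#' is deterministic. Genes with a non-finite statistic are never selected.
#'
#' @param scores A `gene_score_table` from [t_statistic()] or
#'   [sam_statistic()].
#' @param m Number of seed genes, between 1 and the number of ranked genes.
#' @return Character vector of `m` gene IDs, strongest first.
#' @export
select_seeds <- function(scores, m) {
  check_score_table(scores)
  if (!is_count(m)) stopf("`m` must be a positive integer.")
  ranked <- scores$gene_id[order(scores$rank, na.last = NA)]
  if (m > length(ranked)) {
    stopf("m = %d exceeds the %d genes with a finite statistic.",
          m, length(ranked))
  }
  ranked[seq_len(m)]
}

# internal ------------------------------------------------------------------

# per-gene class means and pooled sd; shared by t and SAM statistics
group_stats <- function(data) {
  check_fittable(data, min_per_class = 2L)
  nk <- class_counts(data)
  a <- is_group_a(data)
  xa <- data$values[, a, drop = FALSE]
  xb <- data$values[, !a, drop = FALSE]
  mean_a <- rowMeans(xa)
  mean_b <- rowMeans(xb)
  ss_a <- rowSums((xa - mean_a)^2)
  ss_b <- rowSums((xb - mean_b)^2)
  s_pool <- sqrt((ss_a + ss_b) / (nk[["n_a"]] + nk[["n_b"]] - 2))
  list(
    mean_a = mean_a, mean_b = mean_b, s_pool = s_pool,
    se_factor = sqrt(1 / nk[["n_a"]] + 1 / nk[["n_b"]])
  )
}

new_score_table <- function(gene_ids, statistic, method) {
  finite <- is.finite(statistic)
  if (!all(finite)) {
    warnf("%d gene(s) with zero pooled variance excluded from ranking: %s.",
          sum(!finite),
          paste(head(gene_ids[!finite], 5L), collapse = ", "))
  }
  rank <- rep(NA_integer_, length(statistic))
  idx <- which(finite)
  # stable order: decreasing |T|, ties by ascending gene position
  ord <- idx[order(-abs(statistic[idx]), idx)]
  rank[ord] <- seq_along(ord)
  out <- tibble::tibble(
    gene_id = gene_ids,
    statistic = as.numeric(statistic),
    rank = rank
  )
  class(out) <- c("gene_score_table", class(out))
  attr(out, "method") <- method
  out
}

check_score_table <- function(scores) {
  if (!inherits(scores, "gene_score_table")) {
    stopf("Expected a `gene_score_table` (from t_statistic()/sam_statistic()).")
  }
  invisible(scores)
}
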