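#' Stratified fold assignment
#'
#' Partitions samples into `k` folds of approximately equal size. By default
#' the split is stratified by class, so each class's samples are spread over
#' the folds with sizes differing by at most one within each class —
#' preventing training folds that lose a whole class at small n. The
#' assignment is deterministic given `seed`.
#'
#' @param labels Factor or character vector of class labels (length n).
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param stratified Stratify by class (default `TRUE`).
#' @return Integer vector of fold numbers in `1:k`, one per sample.
#' @export
make_folds <- function(labels, k = 10L, seed = NULL, stratified = TRUE) {
  n <- length(labels)
  if (!is_count(k, min = 2L) || k > n) stopf("`k` must be in 2..n (n = %d).", n)
  labels <- as.factor(labels)
  if (stratified && any(table(labels) < k)) {
    warnf("A class has fewer than k = %d samples; some folds will miss it.", k)
  }
  with_seed(seed, {
    folds <- integer(n)
    if (stratified) {
      # within each class: whole cycles over all folds, then the remainder
      # goes to the currently least-filled folds, so global fold sizes also
      # stay within one of each other (k = n gives leave-one-out)
      load <- integer(k)
      for (cls in levels(labels)) {
        idx <- which(labels == cls)
        n_c <- length(idx)
        assign_f <- rep(seq_len(k), n_c %/% k)
        rem <- n_c %% k
        if (rem > 0L) {
          order_f <- order(load, sample(k))  # least-filled first, random ties
          assign_f <- c(assign_f, order_f[seq_len(rem)])
        }
        folds[idx] <- sample(assign_f)
        load <- load + tabulate(assign_f, nbins = k)
      }
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
    folds
  })
}

#' Repeated k-fold cross-validation of a classification pipeline
#'
#' The evaluation protocol: samples are split into `k` stratified folds;
#' for each fold, gene statistics, seed selection, module discovery and
#' classifier fitting are all recomputed on the remaining k-1 folds only
#' ([fit_pipeline()]), and the held-out fold is predicted — so each sample
#' is predicted exactly once per repeat and no information leaks from test
#' to training. The per-repeat error rate is the fraction of misclassified
#' samples; the whole procedure is repeated `repeats` times with fresh
#' splits and the mean of the per-repeat errors is reported.
#'
#' A classifier failure inside any fold aborts the run with a diagnostic
#' naming the repeat and fold; failed folds are never silently skipped or
#' averaged over.
#'
#' @param data An [expression_dataset()].
#' @param method,m,statistic,grid,corr_mode,shrink,s0 Passed to
#'   [fit_pipeline()].
#' @param k Folds per repeat (default 10).
#' @param repeats Number of repeats (default 10).
#' @param seed RNG seed making the whole result reproducible; `NULL` uses
#'   the current RNG state.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @return A `cv_result`: list with `mean_error`, `errors` (tibble of
#'   per-repeat error rates), `predictions` (tibble: `rep`, `fold`,
#'   `sample_id`, `truth`, `predicted`), `folds` (n x repeats integer
#'   matrix), and `config`.
#' @export
run_cv <- function(data, method = "mlda", m = 10L, statistic = "t",
                   k = 10L, repeats = 10L, seed = NULL,
                   grid = default_r_grid(),
                   corr_mode = "pooled_centered", shrink = TRUE, s0 = NULL,
                   stratified = TRUE) {
  if (!inherits(data, "expression_dataset")) stopf("`data` must be an expression_dataset.")
  if (!is_count(repeats)) stopf("`repeats` must be a positive integer.")
  n <- ncol(data$values)
  if (nlevels(droplevels(data$labels)) < 2L) {
    stopf("Cross-validation needs both classes present.")
  }
  sample_ids <- colnames(data$values)
  truth <- as.character(data$labels)

  with_seed(seed, {
    fold_mat <- matrix(NA_integer_, n, repeats,
                       dimnames = list(sample_ids, NULL))
    preds <- vector("list", repeats)
    errors <- numeric(repeats)
    for (r in seq_len(repeats)) {
      folds <- make_folds(data$labels, k = k, stratified = stratified)
      fold_mat[, r] <- folds
      rows <- vector("list", k)
      for (f in seq_len(k)) {
        test_idx <- which(folds == f)
        if (length(test_idx) == 0L) next
        fit <- tryCatch(
          fit_pipeline(subset_samples(data, -test_idx),
                       method = method, m = m, statistic = statistic,
                       grid = grid, corr_mode = corr_mode, shrink = shrink,
                       s0 = s0),
          error = function(e) {
            stopf("Classifier failed in repeat %d, fold %d: %s", r, f,
                  conditionMessage(e))
          }
        )
        pr <- predict_pipeline(fit, data$values[, test_idx, drop = FALSE])
        rows[[f]] <- tibble::tibble(
          rep = r, fold = f,
          sample_id = sample_ids[test_idx],
          truth = truth[test_idx],
          predicted = pr$label
        )
      }
      preds[[r]] <- dplyr::bind_rows(rows)
      errors[r] <- mean(preds[[r]]$predicted != preds[[r]]$truth)
    }
    structure(
      list(
        mean_error = mean(errors),
        errors = tibble::tibble(rep = seq_len(repeats), error = errors),
        predictions = dplyr::bind_rows(preds),
        folds = fold_mat,
        config = list(method = method, m = m, statistic = statistic, k = k,
                      repeats = repeats, seed = seed, shrink = shrink,
                      corr_mode = corr_mode, stratified = stratified,
                      grid = grid)
      ),
      class = "cv_result"
    )
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<cv_result> %s, m = %d (%s statistic): %d x %d-fold CV, mean error = %.4f\n",
    cfg$method, cfg$m, cfg$statistic, cfg$repeats, cfg$k, x$mean_error
  ))
  invisible(x)
}

#' Per-repeat error rates of a cross-validation run
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with columns `rep` and `error`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$errors

#' One-row summary of a cross-validation run
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with the configuration and the mean/sd of per-repeat
#'   errors.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    method = x$config$method,
    m = x$config$m,
    statistic = x$config$statistic,
    k = x$config$k,
    repeats = x$config$repeats,
    mean_error = x$mean_error,
    sd_error = sd(x$errors$error)
  )
}

#' Plot per-repeat cross-validation error rates
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot: per-repeat error rates with the mean drawn as a line.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$errors, ggplot2::aes(x = .data$rep, y = .data$error)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_error, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$errors$rep) +
    ggplot2::labs(
      x = "repeat", y = "error rate",
      title = sprintf("%s: mean CV error %.3f",
                      object$config$method, object$mean_error)
    )
}
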