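#' Fit a full classification pipeline on one training set
#'
#' Runs every stage on the supplied data: per-gene statistics, seed
#' selection, co-expression network, correlation-sharing module discovery,
#' and classifier fitting. For the module-based methods (`"mlda"`,
#' `"mpclr"`) the modules become covariance blocks / super-genes; the
#' baseline methods (`"dlda"`, `"dqda"`, `"1nn"`) use the `m` selected seed
#' genes directly as their feature set.
#'
#' This is the unit of work refit inside every cross-validation training
#' fold, so nothing here may look at held-out samples.
#'
#' @param data Training [expression_dataset()].
#' @param method One of `"mlda"`, `"mpclr"`, `"dlda"`, `"dqda"`, `"1nn"`.
#' @param m Number of seed genes.
#' @param statistic `"t"` or `"sam"`.
#' @param grid Correlation cutoffs for module discovery.
#' @param corr_mode Correlation mode (see [correlation_matrix()]).
#' @param shrink Covariance shrinkage for MLDA.
#' @param s0 SAM fudge constant (see [sam_statistic()]); `NULL` = median
#'   rule.
#' @return A `pipeline_fit`: list with `method`, `scores`, `seeds`,
#'   `modules` (`NULL` for baselines), and `model` (the fitted classifier;
#'   for `"1nn"` the retained training data).
#' @export
fit_pipeline <- function(data, method = c("mlda", "mpclr", "dlda", "dqda", "1nn"),
                         m = 10L, statistic = c("t", "sam"),
                         grid = default_r_grid(),
                         corr_mode = c("pooled_centered", "overall"),
                         shrink = TRUE, s0 = NULL) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  corr_mode <- match.arg(corr_mode)
  scores <- if (statistic == "t") t_statistic(data) else sam_statistic(data, s0 = s0)
  seeds <- select_seeds(scores, m)
  modules <- NULL
  if (method %in% c("mlda", "mpclr")) {
    corr <- correlation_matrix(data, mode = corr_mode)
    modules <- build_module_set(seeds, corr, scores, grid = grid)
  }
  model <- switch(
    method,
    mlda = mlda_fit(data, modules, shrink = shrink),
    mpclr = mpclr_fit(data, modules),
    dlda = dlda_fit(data, genes = seeds),
    dqda = dqda_fit(data, genes = seeds),
    `1nn` = list(train = data, genes = seeds)
  )
  structure(
    list(method = method, scores = scores, seeds = seeds,
         modules = modules, model = model),
    class = "pipeline_fit"
  )
}

#' Predict with a fitted pipeline
#'
#' @param fit A `pipeline_fit` from [fit_pipeline()].
#' @param newdata As in [mlda_predict()].
#' @return Tibble with `sample_id` and `label`, plus the method's score
#'   columns (`lp`, `probability`, ...).
#' @export
predict_pipeline <- function(fit, newdata) {
  if (!inherits(fit, "pipeline_fit")) stopf("`fit` must come from fit_pipeline().")
  switch(
    fit$method,
    mlda = mlda_predict(fit$model, newdata),
    mpclr = mpclr_predict(fit$model, newdata),
    dlda = dlda_predict(fit$model, newdata),
    dqda = dqda_predict(fit$model, newdata),
    `1nn` = one_nn_predict(fit$model$train, newdata, genes = fit$model$genes)
  )
}

#' @export
print.pipeline_fit <- function(x, ...) {
  cat(sprintf("<pipeline_fit> method = %s, %d seed gene(s)%s\n",
              x$method, length(x$seeds),
              if (!is.null(x$modules)) sprintf(", %d module(s)", length(x$modules$modules)) else ""))
  invisible(x)
}
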