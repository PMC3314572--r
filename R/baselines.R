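#' Diagonal linear discriminant analysis (DLDA)
#'
#' The diagonal-covariance special case of MLDA: every gene is its own
#' block, so the linear predictor reduces to
#' \deqn{LP = \sum_i \left(x_i - \tfrac12(\hat\mu_{Ai}+\hat\mu_{Bi})\right)
#'   (\hat\mu_{Ai}-\hat\mu_{Bi})/\hat\sigma_i^2,}
#' with the pooled per-gene variances \eqn{\hat\sigma_i^2}, and the same
#' decision rule `LP >= log(n_B/n_A)` => group A. Genes with zero pooled
#' variance are excluded with a warning.
#'
#' @param data An [expression_dataset()]; at least two samples per class.
#' @param genes Optional character vector restricting the gene set (e.g.
#'   the selected seed genes); default: all genes.
#' @return A `dlda_model`.
#' @export
dlda_fit <- function(data, genes = NULL) {
  check_fittable(data)
  stats <- group_stats(data)
  keep <- if (is.null(genes)) rownames(data$values) else {
    missing <- setdiff(genes, rownames(data$values))
    if (length(missing) > 0L) stopf("Unknown gene(s): %s.", paste(missing, collapse = ", "))
    genes
  }
  v <- stats$s_pool[keep]^2
  if (any(v == 0)) {
    warnf("Excluding zero-variance gene(s) from DLDA: %s.",
          paste(head(keep[v == 0], 5L), collapse = ", "))
    keep <- keep[v > 0]
    if (length(keep) == 0L) stopf("No gene with positive pooled variance left.")
  }
  nk <- class_counts(data)
  structure(
    list(genes = keep,
         mu_a = stats$mean_a[keep], mu_b = stats$mean_b[keep],
         var_pool = stats$s_pool[keep]^2,
         n_a = nk[["n_a"]], n_b = nk[["n_b"]],
         class_a = data$class_a, class_b = data$class_b,
         threshold = log(nk[["n_b"]] / nk[["n_a"]])),
    class = "dlda_model"
  )
}

#' @rdname dlda_fit
#' @param model A `dlda_model`.
#' @param newdata As in [mlda_predict()].
#' @return For `dlda_predict`: tibble with `sample_id`, `lp`, `label`.
#' @export
dlda_predict <- function(model, newdata) {
  x <- as_prediction_matrix(newdata, model$genes)[model$genes, , drop = FALSE]
  w <- (model$mu_a - model$mu_b) / model$var_pool
  lp <- drop(crossprod(x - (model$mu_a + model$mu_b) / 2, w))
  tibble::tibble(
    sample_id = colnames(x),
    lp = unname(lp),
    label = ifelse(lp >= model$threshold, model$class_a, model$class_b)
  )
}

#' @export
predict.dlda_model <- function(object, newdata, ...) dlda_predict(object, newdata)

#' Diagonal quadratic discriminant analysis (DQDA)
#'
#' Like DLDA but with class-specific per-gene variances. The class score is
#' \deqn{d_k(x) = -\sum_i \frac{(x_i-\hat\mu_{ki})^2}{2\hat\sigma_{ki}^2}
#'   - \tfrac12\sum_i \log \hat\sigma_{ki}^2 + \log(n_k/n)}
#' and a sample is assigned to the class with the larger score (ties to
#' group A). The `log(n_k/n)` prior term mirrors MLDA's handling of unequal
#' class sizes; with equal class variances DQDA reduces to DLDA.
#'
#' @inheritParams dlda_fit
#' @return A `dqda_model`.
#' @export
dqda_fit <- function(data, genes = NULL) {
  check_fittable(data)
  keep <- if (is.null(genes)) rownames(data$values) else {
    missing <- setdiff(genes, rownames(data$values))
    if (length(missing) > 0L) stopf("Unknown gene(s): %s.", paste(missing, collapse = ", "))
    genes
  }
  a <- is_group_a(data)
  xa <- data$values[keep, a, drop = FALSE]
  xb <- data$values[keep, !a, drop = FALSE]
  var_a <- apply(xa, 1L, var)
  var_b <- apply(xb, 1L, var)
  bad <- var_a == 0 | var_b == 0
  if (any(bad)) {
    warnf("Excluding gene(s) with zero per-class variance from DQDA: %s.",
          paste(head(keep[bad], 5L), collapse = ", "))
    keep <- keep[!bad]
    if (length(keep) == 0L) stopf("No gene with positive per-class variances left.")
    xa <- xa[keep, , drop = FALSE]; xb <- xb[keep, , drop = FALSE]
    var_a <- var_a[keep]; var_b <- var_b[keep]
  }
  nk <- class_counts(data)
  structure(
    list(genes = keep,
         mu_a = rowMeans(xa), mu_b = rowMeans(xb),
         var_a = var_a, var_b = var_b,
         n_a = nk[["n_a"]], n_b = nk[["n_b"]],
         class_a = data$class_a, class_b = data$class_b),
    class = "dqda_model"
  )
}

#' @rdname dqda_fit
#' @param model A `dqda_model`.
#' @param newdata As in [mlda_predict()].
#' @return For `dqda_predict`: tibble with `sample_id`, `score_a`,
#'   `score_b`, `label`.
#' @export
dqda_predict <- function(model, newdata) {
  x <- as_prediction_matrix(newdata, model$genes)[model$genes, , drop = FALSE]
  n <- model$n_a + model$n_b
  score_k <- function(mu, v, nk) {
    -colSums((x - mu)^2 / (2 * v)) - sum(log(v)) / 2 + log(nk / n)
  }
  d_a <- score_k(model$mu_a, model$var_a, model$n_a)
  d_b <- score_k(model$mu_b, model$var_b, model$n_b)
  tibble::tibble(
    sample_id = colnames(x),
    score_a = unname(d_a),
    score_b = unname(d_b),
    label = unname(ifelse(d_a >= d_b, model$class_a, model$class_b))
  )
}

#' @export
predict.dqda_model <- function(object, newdata, ...) dqda_predict(object, newdata)

#' One-nearest-neighbour classification
#'
#' Assigns each new sample the class of its Euclidean-nearest training
#' sample over the given gene set. Distance ties go to the training sample
#' with the smallest column index, making the rule deterministic.
#'
#' @param train An [expression_dataset()] (the training samples).
#' @param newdata As in [mlda_predict()].
#' @param genes Optional gene subset; default: all genes of `train`.
#' @return Tibble: `sample_id`, `neighbor` (training sample ID), `label`.
#' @export
one_nn_predict <- function(train, newdata, genes = NULL) {
  if (!inherits(train, "expression_dataset")) stopf("`train` must be an expression_dataset.")
  keep <- if (is.null(genes)) rownames(train$values) else {
    missing <- setdiff(genes, rownames(train$values))
    if (length(missing) > 0L) stopf("Unknown gene(s): %s.", paste(missing, collapse = ", "))
    genes
  }
  x <- as_prediction_matrix(newdata, keep)[keep, , drop = FALSE]
  tr <- train$values[keep, , drop = FALSE]
  nn <- vapply(seq_len(ncol(x)), function(j) {
    d2 <- colSums((tr - x[, j])^2)
    which.min(d2)  # first minimum -> smallest index on ties
  }, 0L)
  tibble::tibble(
    sample_id = colnames(x),
    neighbor = colnames(tr)[nn],
    label = as.character(train$labels[nn])
  )
}
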