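#' Pooled, shrunken covariance estimate for one module
#'
#' Estimates the covariance block for a module from the pooled within-class
#' scatter
#' \deqn{\hat\Sigma_c = \frac{(n_A-1)S_{Ac} + (n_B-1)S_{Bc}}{n_A+n_B-2}}
#' and, when `shrink = TRUE` (default), replaces every off-diagonal entry by
#' \eqn{\hat\sigma_i \hat\sigma_{i'} \hat r_c}, where \eqn{\hat\sigma_i^2}
#' are the pooled per-gene variances (the diagonal of \eqn{\hat\Sigma_c})
#' and \eqn{\hat r_c} is the median of the module's pairwise pooled
#' correlations. This compound-symmetry-style shrinkage stabilises the block
#' when samples are few. With an even number of gene pairs the median is the
#' mean of the two central values (the R default).
#'
#' @param data An [expression_dataset()] with `n >= 3` and both classes
#'   present.
#' @param module A `gene_module`, or a character vector of member gene IDs.
#' @param shrink Apply the median-correlation shrinkage? Default `TRUE`.
#'   With `FALSE` the plain pooled covariance is returned.
#' @return A `module_block`: list with `members`, `mu_a`, `mu_b` (class mean
#'   vectors), `sigma` (the p_c x p_c estimate), `sd` (pooled per-gene
#'   standard deviations), `r_med` (the median correlation; `NA` for
#'   singleton modules or `shrink = FALSE`), and `shrink`.
#' @export
estimate_block_covariance <- function(data, module, shrink = TRUE) {
  members <- if (inherits(module, "gene_module")) module$members else as.character(module)
  if (length(members) < 1L) stopf("Module has no members.")
  missing <- setdiff(members, rownames(data$values))
  if (length(missing) > 0L) {
    stopf("Module gene(s) not in dataset: %s.", paste(missing, collapse = ", "))
  }
  nk <- class_counts(data)
  if (nk[["n_a"]] + nk[["n_b"]] < 3L) {
    stopf("Pooled covariance needs n_A + n_B >= 3.")
  }
  a <- is_group_a(data)
  xa <- t(data$values[members, a, drop = FALSE])
  xb <- t(data$values[members, !a, drop = FALSE])
  mu_a <- colMeans(xa)
  mu_b <- colMeans(xb)
  # (n_k - 1) S_k = centered cross-product of class k
  scatter <- crossprod(sweep(xa, 2L, mu_a)) + crossprod(sweep(xb, 2L, mu_b))
  sigma <- scatter / (nk[["n_a"]] + nk[["n_b"]] - 2L)
  sds <- sqrt(diag(sigma))
  if (any(sds == 0)) {
    stopf("Zero pooled variance for module gene(s): %s.",
          paste(members[sds == 0], collapse = ", "))
  }
  r_med <- NA_real_
  if (shrink && length(members) > 1L) {
    r_pair <- sigma / tcrossprod(sds)
    r_med <- median(r_pair[upper.tri(r_pair)])
    sigma <- tcrossprod(sds) * r_med
    diag(sigma) <- sds^2
  }
  structure(
    list(members = members, mu_a = mu_a, mu_b = mu_b, sigma = sigma,
         sd = sds, r_med = r_med, shrink = shrink),
    class = "module_block"
  )
}

#' SVD-based inverse or Moore-Penrose pseudo-inverse
#'
#' Inverts a symmetric covariance block through its singular value
#' decomposition \eqn{\Sigma = U D V^T}, \eqn{\Sigma^{-1} = V D^{-1} U^T}.
#' Singular values below `rel_tol` times the largest are treated as zero and
#' their reciprocals set to zero, yielding the Moore-Penrose pseudo-inverse;
#' this handles blocks with more genes than samples, where the pooled
#' estimate is singular. On full-rank blocks the result equals the exact
#' inverse to numerical precision.
#'
#' @param sigma Symmetric numeric matrix.
#' @param rel_tol Relative singular-value threshold; default `1e-8`.
#' @return The (pseudo-)inverse matrix.
#' @export
invert_block <- function(sigma, rel_tol = 1e-8) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma) ||
      max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stopf("`sigma` must be a symmetric square matrix.")
  }
  dec <- svd(sigma)
  keep <- dec$d > rel_tol * dec$d[1L]
  if (!any(keep)) stopf("Block is numerically rank zero; cannot invert.")
  d_inv <- ifelse(keep, 1 / dec$d, 0)
  inv <- dec$v %*% (d_inv * t(dec$u))
  (inv + t(inv)) / 2  # symmetrise against round-off
}

#' Fit the modular linear discriminant (MLDA) classifier
#'
#' Fits per-module class means and shrunken pooled covariance blocks
#' ([estimate_block_covariance()]), inverts each block by SVD
#' ([invert_block()]), and stores the decision threshold
#' \eqn{\log(n_B/n_A)}. Prediction sums the per-module linear predictors
#' \deqn{LP = \sum_c \left(x_c - \tfrac12(\hat\mu_{Ac}+\hat\mu_{Bc})\right)^T
#'   \hat\Sigma_c^{-1} (\hat\mu_{Ac}-\hat\mu_{Bc})}
#' and assigns group A when \eqn{LP \ge \log(n_B/n_A)}, else group B.
#'
#' Limiting cases: a single module containing every gene with
#' `shrink = FALSE` (and `n > p`) is classical full LDA; one singleton
#' module per gene is DLDA.
#'
#' @param data An [expression_dataset()]; each class needs at least two
#'   samples.
#' @param modules A `module_set` (from [build_module_set()] or
#'   [module_set_from_list()]).
#' @param shrink Apply median-correlation shrinkage in each block
#'   (default `TRUE`).
#' @param rel_tol Singular-value tolerance for [invert_block()].
#' @return An `mlda_model`: blocks (each with means, covariance and its
#'   inverse), class counts and names, and the decision threshold.
#' @export
mlda_fit <- function(data, modules, shrink = TRUE, rel_tol = 1e-8) {
  if (!inherits(modules, "module_set")) stopf("`modules` must be a `module_set`.")
  check_fittable(data)
  nk <- class_counts(data)
  blocks <- lapply(modules$modules, function(mod) {
    blk <- estimate_block_covariance(data, mod, shrink = shrink)
    blk$sigma_inv <- invert_block(blk$sigma, rel_tol = rel_tol)
    blk
  })
  structure(
    list(
      blocks = blocks,
      n_a = nk[["n_a"]], n_b = nk[["n_b"]],
      class_a = data$class_a, class_b = data$class_b,
      threshold = log(nk[["n_b"]] / nk[["n_a"]]),
      shrink = shrink, rel_tol = rel_tol
    ),
    class = "mlda_model"
  )
}

#' Predict classes with a fitted MLDA model
#'
#' @param model An `mlda_model` from [mlda_fit()].
#' @param newdata An [expression_dataset()], or a numeric matrix with gene
#'   IDs as row names and sample IDs as column names, covering every gene
#'   used by the model.
#' @return Tibble with one row per sample: `sample_id`, `lp` (the summed
#'   linear predictor), and `label` (predicted class name; the boundary
#'   `lp == log(n_B/n_A)` goes to group A).
#' @export
mlda_predict <- function(model, newdata) {
  x <- as_prediction_matrix(newdata, model_genes(model))
  lp <- rep(0, ncol(x))
  for (blk in model$blocks) {
    xc <- x[blk$members, , drop = FALSE]
    d <- blk$sigma_inv %*% (blk$mu_a - blk$mu_b)
    lp <- lp + drop(crossprod(xc - (blk$mu_a + blk$mu_b) / 2, d))
  }
  tibble::tibble(
    sample_id = colnames(x),
    lp = unname(lp),
    label = ifelse(lp >= model$threshold, model$class_a, model$class_b)
  )
}

#' @export
predict.mlda_model <- function(object, newdata, ...) mlda_predict(object, newdata)

#' @export
print.mlda_model <- function(x, ...) {
  cat(sprintf(
    "<mlda_model> %d block(s), %d gene(s); n_A = %d (%s), n_B = %d (%s); threshold = %.4g\n",
    length(x$blocks), length(model_genes(x)),
    x$n_a, x$class_a, x$n_b, x$class_b, x$threshold
  ))
  invisible(x)
}

#' Tabulate the blocks of an MLDA model
#'
#' @param x An `mlda_model`.
#' @param ... Unused.
#' @return Tibble with one row per block: size, median correlation used for
#'   shrinkage, and the block's contribution scale
#'   `d_mahalanobis = d' Sigma^-1 d` (the squared Mahalanobis distance
#'   between class means within the block).
#' @method tidy mlda_model
#' @export
tidy.mlda_model <- function(x, ...) {
  tibble::tibble(
    module = seq_along(x$blocks),
    seed = vapply(x$blocks, function(b) b$members[[1L]], ""),
    size = vapply(x$blocks, function(b) length(b$members), 0L),
    r_med = vapply(x$blocks, function(b) b$r_med, 0),
    d_mahalanobis = vapply(x$blocks, function(b) {
      d <- b$mu_a - b$mu_b
      drop(crossprod(d, b$sigma_inv %*% d))
    }, 0)
  )
}

#' @method glance mlda_model
#' @export
glance.mlda_model <- function(x, ...) {
  tibble::tibble(
    n_blocks = length(x$blocks),
    p = length(model_genes(x)),
    n_a = x$n_a, n_b = x$n_b,
    threshold = x$threshold,
    shrink = x$shrink
  )
}

# internal ------------------------------------------------------------------

model_genes <- function(model) {
  unlist(lapply(model$blocks, `[[`, "members"), use.names = FALSE)
}

# coerce prediction input to a genes x samples matrix covering `genes`
as_prediction_matrix <- function(newdata, genes) {
  x <- if (inherits(newdata, "expression_dataset")) {
    newdata$values
  } else if (is.numeric(newdata) && is.matrix(newdata)) {
    newdata
  } else if (is.numeric(newdata) && !is.null(names(newdata))) {
    matrix(newdata, ncol = 1L, dimnames = list(names(newdata), "sample_1"))
  } else {
    stopf("`newdata` must be an expression_dataset, a named numeric vector, or a genes x samples matrix.")
  }
  if (is.null(rownames(x))) stopf("`newdata` must carry gene IDs as row names.")
  missing <- setdiff(genes, rownames(x))
  if (length(missing) > 0L) {
    stopf("Gene(s) required by the model are missing from `newdata`: %s.",
          paste(head(missing, 5L), collapse = ", "))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("sample_", seq_len(ncol(x)))
  x
}
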