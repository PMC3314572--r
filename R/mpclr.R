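#' First principal component of a module ("super-gene")
#'
#' Standardises each member gene to zero mean and unit variance on the
#' training samples, takes the SVD of the resulting n x p_c matrix, and
#' returns the first right singular vector as the loading vector
#' \eqn{e_1}. The module score of a sample is \eqn{e_1^T x} on the
#' standardised scale. Because an SVD determines singular vectors only up to
#' sign, the sign is fixed so that the largest-magnitude loading is
#' positive, making repeated fits deterministic. The training centering and
#' scaling constants are stored and reused verbatim at prediction time.
#'
#' @param data An [expression_dataset()] with at least 2 samples.
#' @param module A `gene_module` or character vector of member gene IDs.
#' @return A `module_pc`: list with `members`, `center`, `scale` (training
#'   per-gene constants), `loadings` (unit vector), and `scores` (training
#'   sample scores, named by sample ID).
#' @export
first_pc <- function(data, module) {
  members <- if (inherits(module, "gene_module")) module$members else as.character(module)
  if (length(members) < 1L) stopf("Module has no members.")
  missing <- setdiff(members, rownames(data$values))
  if (length(missing) > 0L) {
    stopf("Module gene(s) not in dataset: %s.", paste(missing, collapse = ", "))
  }
  if (ncol(data$values) < 2L) stopf("Need at least 2 samples.")
  e <- t(data$values[members, , drop = FALSE])  # n x p_c
  center <- colMeans(e)
  scale_ <- apply(e, 2L, sd)
  if (any(scale_ == 0)) {
    stopf("Zero-variance gene(s) in module: %s.",
          paste(members[scale_ == 0], collapse = ", "))
  }
  z <- sweep(sweep(e, 2L, center), 2L, scale_, "/")
  dec <- svd(z, nu = 0L, nv = 1L)
  e1 <- drop(dec$v)
  if (e1[which.max(abs(e1))] < 0) e1 <- -e1
  structure(
    list(members = members, center = center, scale = scale_,
         loadings = setNames(e1, members),
         scores = setNames(drop(z %*% e1), rownames(e))),
    class = "module_pc"
  )
}

#' Fit the modular PC logistic-regression (MPCLR) classifier
#'
#' Stage 1 of the pipeline (module discovery) is supplied as `modules`;
#' this function performs stages 2 and 3: it extracts each module's first
#' principal component score ([first_pc()]) as a one-dimensional
#' "super-gene", then fits a logistic regression of class membership
#' (Y = 1 for group A) on the C module scores by maximum likelihood (IRLS,
#' via [stats::glm.fit()]):
#' \deqn{\log\frac{p_j}{1-p_j} = \beta_0 + \sum_{c=1}^C \beta_c\,
#'   PC1_{cj}.}
#'
#' With well-separating modules the likelihood has no finite maximiser
#' (complete separation); iterations are capped and the coefficients at the
#' stopping point are returned with `separation = TRUE` — predicted labels
#' remain well defined even though coefficient magnitudes are not.
#'
#' @param data An [expression_dataset()]; both classes present.
#' @param modules A `module_set` with C >= 1 modules. A warning is issued
#'   when C is not smaller than the sample count (the fit is then saturated
#'   or overparameterised).
#' @param maxit IRLS iteration cap (default 100).
#' @return An `mpclr_model`: `module_pcs` (list of `module_pc`),
#'   `coefficients` (length C + 1: intercept then one slope per module),
#'   `converged`, `separation`, `fitted` (training probabilities), and class
#'   names/counts.
#' @export
mpclr_fit <- function(data, modules, maxit = 100L) {
  if (!inherits(modules, "module_set")) stopf("`modules` must be a `module_set`.")
  if (length(modules$modules) < 1L) stopf("Need at least one module.")
  check_fittable(data, min_per_class = 1L)
  n <- ncol(data$values)
  c_mod <- length(modules$modules)
  if (c_mod >= n) {
    warnf("C = %d modules with only n = %d samples; logistic fit is overparameterised.",
          c_mod, n)
  }
  module_pcs <- lapply(modules$modules, function(mod) first_pc(data, mod))
  scores <- vapply(module_pcs, `[[`, numeric(n), "scores")
  scores <- matrix(scores, nrow = n)
  y <- as.integer(is_group_a(data))
  xmat <- cbind(`(Intercept)` = 1, scores)
  colnames(xmat) <- c("(Intercept)", paste0("module_", seq_len(c_mod)))
  fit <- suppressWarnings(
    glm.fit(xmat, y, family = binomial(), control = list(maxit = maxit))
  )
  fitted <- fit$fitted.values
  separation <- any(fitted > 1 - 1e-8 | fitted < 1e-8) &&
    all((fitted >= 0.5) == (y == 1L))
  nk <- class_counts(data)
  structure(
    list(
      module_pcs = module_pcs,
      coefficients = setNames(fit$coefficients, colnames(xmat)),
      converged = isTRUE(fit$converged),
      separation = separation,
      fitted = setNames(fitted, colnames(data$values)),
      y = y,
      n_a = nk[["n_a"]], n_b = nk[["n_b"]],
      class_a = data$class_a, class_b = data$class_b
    ),
    class = "mpclr_model"
  )
}

#' Predict classes and probabilities with a fitted MPCLR model
#'
#' Module scores for new samples are computed with the training
#' normalisation and loadings; the class-A probability is the logistic of
#' the linear predictor, and a sample is assigned to group A when
#' `probability >= 0.5` (the boundary goes to A).
#'
#' @param model An `mpclr_model` from [mpclr_fit()].
#' @param newdata As in [mlda_predict()].
#' @return Tibble: `sample_id`, `probability` (of group A), `label`.
#' @export
mpclr_predict <- function(model, newdata) {
  genes <- unique(unlist(lapply(model$module_pcs, `[[`, "members")))
  x <- as_prediction_matrix(newdata, genes)
  n_new <- ncol(x)
  scores <- vapply(model$module_pcs, function(pc) {
    z <- (t(x[pc$members, , drop = FALSE]) -
            matrix(pc$center, n_new, length(pc$members), byrow = TRUE)) /
      matrix(pc$scale, n_new, length(pc$members), byrow = TRUE)
    drop(z %*% pc$loadings)
  }, numeric(n_new))
  scores <- matrix(scores, nrow = n_new)
  eta <- drop(cbind(1, scores) %*% model$coefficients)
  p <- plogis(eta)
  tibble::tibble(
    sample_id = colnames(x),
    probability = unname(p),
    label = ifelse(p >= 0.5, model$class_a, model$class_b)
  )
}

#' @export
predict.mpclr_model <- function(object, newdata, ...) mpclr_predict(object, newdata)

#' @export
print.mpclr_model <- function(x, ...) {
  cat(sprintf(
    "<mpclr_model> %d module(s); n_A = %d (%s), n_B = %d (%s)%s%s\n",
    length(x$module_pcs), x$n_a, x$class_a, x$n_b, x$class_b,
    if (!x$converged) "; IRLS not converged" else "",
    if (x$separation) "; complete separation" else ""
  ))
  invisible(x)
}

#' Tabulate MPCLR coefficients and module sizes
#'
#' @param x An `mpclr_model`.
#' @param ... Unused.
#' @return Tibble with one row per model term (intercept first).
#' @method tidy mpclr_model
#' @export
tidy.mpclr_model <- function(x, ...) {
  sizes <- c(NA_integer_,
             vapply(x$module_pcs, function(pc) length(pc$members), 0L))
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    module_size = sizes
  )
}

#' @method glance mpclr_model
#' @export
glance.mpclr_model <- function(x, ...) {
  tibble::tibble(
    n_modules = length(x$module_pcs),
    n_a = x$n_a, n_b = x$n_b,
    converged = x$converged,
    separation = x$separation,
    training_error = mean((x$fitted >= 0.5) != (x$y == 1L))
  )
}
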