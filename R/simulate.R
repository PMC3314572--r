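#' Describe a two-class synthetic expression study
#'
#' Specifies a genes x samples simulation with planted correlated gene
#' blocks: within each block, genes follow a compound-symmetry correlation
#' (pairwise correlation `rho`), blocks are mutually independent, and the
#' remaining "background" genes are independent noise. Class separation is a
#' mean shift of `delta` gene-level standard deviations applied, in group A,
#' to each block's designated seed gene (or to every block gene with
#' `shift = "all"`). Shifting only the seed means that correlation sharing —
#' not the shift itself — has to recover the rest of the block.
#'
#' @param n_a,n_b Samples per class (group A is named `"case"`, group B
#'   `"control"`; `"case"` maps to A lexicographically).
#' @param p Total genes (at least the sum of block sizes).
#' @param blocks Data frame with one row per planted block and columns
#'   `size` (genes in the block, >= 1), `rho` (within-block correlation in
#'   \[0, 1)), and `delta` (seed mean shift in units of the gene standard
#'   deviation, >= 0).
#' @param noise_sd Gene-level standard deviation (default 1).
#' @param shift `"seed"` (default) or `"all"`: which block genes receive the
#'   mean shift.
#' @param seed RNG seed for [simulate_expression()]; `NULL` uses the current
#'   RNG state.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_a, n_b, p, blocks, noise_sd = 1,
                              shift = c("seed", "all"), seed = NULL) {
  shift <- match.arg(shift)
  if (!is_count(n_a) || !is_count(n_b)) stopf("`n_a` and `n_b` must be positive integers.")
  if (!is_count(p)) stopf("`p` must be a positive integer.")
  blocks <- as.data.frame(blocks)
  req <- c("size", "rho", "delta")
  if (!all(req %in% names(blocks))) {
    stopf("`blocks` needs columns: %s.", paste(req, collapse = ", "))
  }
  if (nrow(blocks) > 0) {
    if (any(blocks$size < 1 | blocks$size != round(blocks$size))) {
      stopf("Block sizes must be positive integers.")
    }
    if (any(blocks$rho < 0 | blocks$rho >= 1)) {
      stopf("Within-block correlation `rho` must lie in [0, 1) for a positive-definite covariance.")
    }
    if (any(blocks$delta < 0)) stopf("`delta` must be non-negative.")
  }
  if (sum(blocks$size) > p) {
    stopf("Block sizes sum to %d but p = %d.", sum(blocks$size), p)
  }
  if (!is_scalar_number(noise_sd) || noise_sd <= 0) stopf("`noise_sd` must be positive.")
  structure(
    list(n_a = as.integer(n_a), n_b = as.integer(n_b), p = as.integer(p),
         blocks = blocks, noise_sd = noise_sd, shift = shift, seed = seed),
    class = "simulation_design"
  )
}

#' Simulate a two-class expression dataset with planted modules
#'
#' Draws each sample from a multivariate normal whose covariance is
#' block-diagonal with compound-symmetry blocks (generated as
#' \eqn{x = \sqrt\rho\, f + \sqrt{1-\rho}\, e} with a shared block factor
#' `f`, scaled by `noise_sd`). Group-A samples additionally receive the
#' designed mean shifts. The first gene of each block is its seed gene,
#' named `bK_seed`; other block genes `bK_gJ`; background genes `bgJ`.
#'
#' @param design A [simulation_design()].
#' @return List with `data` (an [expression_dataset()], classes `"case"` =
#'   group A and `"control"`) and `truth`, a list with `blocks` (list of
#'   gene-ID vectors), `seed_genes`, and `shifted_genes`.
#' @export
simulate_expression <- function(design) {
  if (!inherits(design, "simulation_design")) {
    stopf("`design` must come from simulation_design().")
  }
  with_seed(design$seed, {
    n <- design$n_a + design$n_b
    p <- design$p
    blocks <- design$blocks
    gene_ids <- character(0)
    x <- matrix(NA_real_, nrow = 0L, ncol = n)
    truth_blocks <- list()
    for (k in seq_len(nrow(blocks))) {
      sz <- blocks$size[k]
      rho <- blocks$rho[k]
      f <- rnorm(n)
      e <- matrix(rnorm(sz * n), sz, n)
      xb <- sqrt(rho) * matrix(f, sz, n, byrow = TRUE) + sqrt(1 - rho) * e
      ids <- if (sz == 1L) sprintf("b%d_seed", k) else {
        c(sprintf("b%d_seed", k), sprintf("b%d_g%d", k, seq_len(sz - 1L)))
      }
      gene_ids <- c(gene_ids, ids)
      x <- rbind(x, xb)
      truth_blocks[[k]] <- ids
    }
    n_bg <- p - sum(blocks$size)
    if (n_bg > 0L) {
      gene_ids <- c(gene_ids, sprintf("bg%d", seq_len(n_bg)))
      x <- rbind(x, matrix(rnorm(n_bg * n), n_bg, n))
    }
    x <- x * design$noise_sd
    rownames(x) <- gene_ids
    colnames(x) <- sprintf("s%d", seq_len(n))

    is_a <- seq_len(n) <= design$n_a
    shifted <- character(0)
    for (k in seq_len(nrow(blocks))) {
      if (blocks$delta[k] <= 0) next
      tgt <- if (design$shift == "seed") truth_blocks[[k]][1L] else truth_blocks[[k]]
      x[tgt, is_a] <- x[tgt, is_a] + blocks$delta[k] * design$noise_sd
      shifted <- c(shifted, tgt)
    }
    labels <- ifelse(is_a, "case", "control")
    data <- expression_dataset(x, labels, class_a = "case")
    list(
      data = data,
      truth = list(
        blocks = truth_blocks,
        seed_genes = vapply(truth_blocks, `[[`, "", 1L),
        shifted_genes = shifted
      )
    )
  })
}
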