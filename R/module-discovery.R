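#' Default grid of correlation cutoffs
#'
#' The ten cutoffs 0.50, 0.55, ..., 0.95 used by the correlation-sharing
#' module search. Scanning a coarse grid rather than all of \[0, 1\] keeps
#' the search fast; the grid is configurable in [find_module()].
#'
#' @return Numeric vector of strictly increasing cutoffs in \[0, 1\].
#' @export
default_r_grid <- function() seq(0.50, 0.95, by = 0.05)

#' Gene-gene Pearson correlation matrix
#'
#' Builds the co-expression network underlying module discovery. In the
#' default `"pooled_centered"` mode each gene is centered within its class
#' before correlating across all samples, so that a class-mean shift does not
#' masquerade as co-expression; `"overall"` is the plain Pearson correlation
#' over all samples.
#'
#' Genes whose (centered) values have zero variance have no defined
#' correlation; their rows and columns are set to `NA` (diagonal included)
#' with a warning, and they are never picked up as module members.
#'
#' @param data An [expression_dataset()] with at least 3 samples.
#' @param mode `"pooled_centered"` (default) or `"overall"`.
#' @return A symmetric p x p matrix with unit diagonal (for well-defined
#'   genes), dimnames = gene IDs, and attribute `mode`.
#' @export
correlation_matrix <- function(data, mode = c("pooled_centered", "overall")) {
  mode <- match.arg(mode)
  if (ncol(data$values) < 3L) stopf("Need at least 3 samples for correlations.")
  x <- data$values
  if (mode == "pooled_centered") {
    a <- is_group_a(data)
    x[, a] <- x[, a] - rowMeans(x[, a, drop = FALSE])
    x[, !a] <- x[, !a] - rowMeans(x[, !a, drop = FALSE])
  }
  sds <- apply(x, 1L, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    warnf("%d zero-variance gene(s) excluded from the co-expression network: %s.",
          sum(zero), paste(head(rownames(x)[zero], 5L), collapse = ", "))
  }
  r <- suppressWarnings(cor(t(x)))
  r[zero, ] <- NA_real_
  r[, zero] <- NA_real_
  diag(r)[!zero] <- 1
  attr(r, "mode") <- mode
  r
}

#' Correlation-sharing module search for one seed gene
#'
#' For each cutoff `r` in the grid, the candidate module is the seed's
#' correlation neighbourhood
#' \eqn{C_r(i^*) = \{s : |corr(x_{i^*}, x_s)| \ge r\}} (which always contains
#' the seed itself). The chosen module is the neighbourhood whose average
#' absolute differential-expression statistic over its members is maximal;
#' ties are broken toward the largest cutoff, i.e. the smallest module.
#'
#' Because the seed belongs to every candidate set, a seed that is itself the
#' highest-|T| gene among its candidates always yields the singleton module
#' \{seed\}: adding only weaker genes can never raise the average. Modules
#' grow only by pulling in neighbours whose statistic exceeds the running
#' average.
#'
#' @param seed Gene ID of the seed; must have a finite statistic.
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param scores A `gene_score_table` over the same genes.
#' @param grid Strictly increasing correlation cutoffs in \[0, 1\];
#'   default [default_r_grid()].
#' @param candidates Optional character vector restricting which genes may be
#'   members (the seed is always eligible); used by [build_module_set()] to
#'   keep modules disjoint.
#' @return A `gene_module`: list with `seed`, `members` (gene IDs, seed
#'   included), `chosen_r`, and `score` (mean |statistic| over members).
#' @export
find_module <- function(seed, corr, scores, grid = default_r_grid(),
                        candidates = NULL) {
  check_score_table(scores)
  check_grid(grid)
  if (!seed %in% rownames(corr)) stopf("Seed gene '%s' not in correlation matrix.", seed)
  stat <- setNames(scores$statistic, scores$gene_id)
  if (!is.finite(stat[[seed]])) stopf("Seed gene '%s' has a non-finite statistic.", seed)

  pool <- rownames(corr)
  if (!is.null(candidates)) pool <- intersect(pool, union(candidates, seed))
  r_seed <- abs(corr[seed, pool])
  # eligible members need a defined correlation and a finite statistic
  ok <- is.finite(r_seed) & is.finite(stat[pool])
  ok[pool == seed] <- TRUE
  pool <- pool[ok]
  r_seed <- r_seed[pool]
  r_seed[pool == seed] <- 1

  best <- NULL
  for (r in grid) {
    members <- pool[r_seed >= r]
    score <- mean(abs(stat[members]))
    # >= replaces on equal scores while scanning r upward, so ties resolve
    # toward the largest cutoff (smallest module)
    if (is.null(best) || score >= best$score) {
      best <- list(members = members, score = score, chosen_r = r)
    }
  }
  structure(
    list(seed = seed, members = unname(best$members),
         chosen_r = best$chosen_r, score = unname(best$score)),
    class = "gene_module"
  )
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("<gene_module> seed %s, %d gene(s), r = %.2f, score = %.4g\n",
              x$seed, length(x$members), x$chosen_r, x$score))
  invisible(x)
}

#' Build a disjoint set of modules from ranked seeds
#'
#' Processes seeds in rank order (strongest first). Each seed's module is
#' searched over the genes not yet claimed by an earlier module, so the
#' resulting modules are pairwise disjoint — a requirement for using them as
#' blocks of a block-diagonal covariance. A seed that was absorbed into an
#' earlier module produces no module of its own.
#'
#' @param seeds Character vector of seed gene IDs in rank order, e.g. from
#'   [select_seeds()].
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param scores A `gene_score_table`.
#' @param grid Correlation cutoffs; default [default_r_grid()].
#' @return A `module_set`: list with `modules` (list of `gene_module`, in
#'   seed-rank order) and `assignment` (named character vector mapping each
#'   claimed gene to its module's seed).
#' @export
build_module_set <- function(seeds, corr, scores, grid = default_r_grid()) {
  if (length(seeds) == 0L) stopf("`seeds` must contain at least one gene.")
  if (anyDuplicated(seeds)) stopf("`seeds` contains duplicates.")
  claimed <- character(0)
  modules <- list()
  free <- rownames(corr)
  for (seed in seeds) {
    if (seed %in% claimed) next
    mod <- find_module(seed, corr, scores, grid, candidates = setdiff(free, claimed))
    modules[[length(modules) + 1L]] <- mod
    claimed <- c(claimed, mod$members)
  }
  assignment <- setNames(
    rep(vapply(modules, `[[`, "", "seed"),
        vapply(modules, function(m) length(m$members), 0L)),
    unlist(lapply(modules, `[[`, "members"))
  )
  stopifnot(!anyDuplicated(names(assignment)))  # disjointness, by construction
  structure(list(modules = modules, assignment = assignment),
            class = "module_set")
}

#' Wrap explicit gene groupings as a module set
#'
#' Builds a `module_set` directly from a list of gene-ID vectors, bypassing
#' the correlation-sharing search. Useful for fitting [mlda_fit()] or
#' [mpclr_fit()] on externally defined blocks (e.g. known pathways, or the
#' limiting cases: one module with every gene, or one module per gene).
#'
#' @param members_list List of character vectors of gene IDs; must be
#'   pairwise disjoint and non-empty. Each group's first gene is recorded as
#'   its seed.
#' @return A `module_set`.
#' @export
module_set_from_list <- function(members_list) {
  if (length(members_list) == 0L) stopf("Need at least one module.")
  all_genes <- unlist(members_list)
  if (anyDuplicated(all_genes)) {
    stopf("Modules must be disjoint; duplicated gene(s): %s.",
          paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  }
  modules <- lapply(members_list, function(g) {
    if (length(g) == 0L) stopf("Empty module in `members_list`.")
    structure(list(seed = g[[1L]], members = g, chosen_r = NA_real_,
                   score = NA_real_),
              class = "gene_module")
  })
  assignment <- setNames(
    rep(vapply(modules, `[[`, "", "seed"), lengths(members_list)),
    all_genes
  )
  structure(list(modules = modules, assignment = assignment),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$members), 0L)
  cat(sprintf("<module_set> %d module(s), %d gene(s); sizes: %s\n",
              length(x$modules), length(x$assignment),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Tabulate a module set
#'
#' @param x A `module_set`.
#' @param ... Unused.
#' @return Tibble with one row per module: `module`, `seed`, `size`,
#'   `chosen_r`, `score`, and `members` (comma-joined gene IDs).
#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  tibble::tibble(
    module = seq_along(x$modules),
    seed = vapply(x$modules, `[[`, "", "seed"),
    size = vapply(x$modules, function(m) length(m$members), 0L),
    chosen_r = vapply(x$modules, `[[`, 0, "chosen_r"),
    score = vapply(x$modules, `[[`, 0, "score"),
    members = vapply(x$modules, function(m) paste(m$members, collapse = ","), "")
  )
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1L || anyNA(grid) ||
      any(grid < 0) || any(grid > 1) || is.unsorted(grid, strictly = TRUE)) {
    stopf("`grid` must be strictly increasing cutoffs in [0, 1].")
  }
  invisible(grid)
}
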