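# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# genes x samples dataset from a plain matrix (dimnames added if missing)
toy_dataset <- function(values, labels, class_a = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  expression_dataset(values, labels, class_a = class_a)
}

# iid-normal dataset with balanced-ish classes
random_dataset <- function(p, n_a, n_b, seed = 1, delta = 0, shifted = integer(0)) {
  set.seed(seed)
  x <- matrix(rnorm(p * (n_a + n_b)), p, n_a + n_b)
  if (length(shifted) > 0) x[shifted, seq_len(n_a)] <- x[shifted, seq_len(n_a)] + delta
  toy_dataset(x, rep(c("case", "control"), c(n_a, n_b)), class_a = "case")
}

# hand-built score table (for module-search toys with prescribed statistics)
fake_scores <- function(statistics, gene_ids = paste0("g", seq_along(statistics))) {
  modlda:::new_score_table(gene_ids, statistics, method = "t")
}

# hand-built symmetric correlation matrix from the upper triangle
fake_corr <- function(p, pairs, gene_ids = paste0("g", seq_len(p))) {
  r <- diag(1, p)
  dimnames(r) <- list(gene_ids, gene_ids)
  for (pr in pairs) r[pr[[1]], pr[[2]]] <- r[pr[[2]], pr[[1]]] <- pr[[3]]
  r
}

# standard planted-block design used by several tests
block_design <- function(n_a = 50, n_b = 50, sizes = c(10, 8, 6, 5, 12),
                         rho = 0.8, delta = 3, p = 80, seed = 42,
                         shift = "seed") {
  simulation_design(n_a, n_b, p,
                    blocks = data.frame(size = sizes, rho = rho, delta = delta),
                    shift = shift, seed = seed)
}

# exhaustive re-implementation of the correlation-sharing search, used as the
# independent oracle for find_module(): evaluate every cutoff, keep the best
# average |T|, ties toward the largest cutoff
brute_force_module <- function(seed_gene, corr, stats, grid) {
  best <- NULL
  for (r in grid) {
    nb <- abs(corr[seed_gene, ])
    nb[seed_gene] <- 1
    members <- names(nb)[!is.na(nb) & nb >= r & is.finite(stats[names(nb)])]
    score <- mean(abs(stats[members]))
    if (is.null(best) || score > best$score ||
        (score == best$score && r > best$chosen_r)) {
      best <- list(members = sort(members), score = score, chosen_r = r)
    }
  }
  best
}

# Jaccard similarity of two gene sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

`%||%` <- function(a, b) if (is.null(a)) b else a
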