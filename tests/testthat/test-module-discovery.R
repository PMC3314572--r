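# Co-expression network and correlation-sharing module search.

test_that("correlation matrix has unit diagonal and detects affine relations", {
  set.seed(5)
  x <- matrix(rnorm(40), 4, 10)
  x[2, ] <- 2 * x[1, ] + 3
  d <- toy_dataset(x, rep(c("A", "B"), each = 5))
  r <- correlation_matrix(d, mode = "overall")
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r["g1", "g2"], 1)
  expect_equal(r, t(r))
  expect_true(all(abs(r) <= 1 + 1e-12))
})

test_that("correlation entries match a brute-force Pearson computation", {
  set.seed(7)
  d <- random_dataset(p = 4, n_a = 6, n_b = 6, seed = 7)
  for (mode in c("overall", "pooled_centered")) {
    r <- correlation_matrix(d, mode = mode)
    x <- d$values
    if (mode == "pooled_centered") {
      x[, 1:6] <- x[, 1:6] - rowMeans(x[, 1:6])
      x[, 7:12] <- x[, 7:12] - rowMeans(x[, 7:12])
    }
    for (i in 1:4) {
      for (j in 1:4) {
        num <- sum((x[i, ] - mean(x[i, ])) * (x[j, ] - mean(x[j, ])))
        den <- sqrt(sum((x[i, ] - mean(x[i, ]))^2) * sum((x[j, ] - mean(x[j, ]))^2))
        expect_equal(r[i, j], num / den, tolerance = 1e-12)
      }
    }
  }
})

test_that("pooled centering removes class-mean signal from co-expression", {
  set.seed(13)
  n <- 60
  shift <- rep(c(0, 6), each = n / 2)
  x <- rbind(shift + rnorm(n, sd = 0.5), shift + rnorm(n, sd = 0.5))
  d <- toy_dataset(x, rep(c("A", "B"), each = n / 2))
  r_overall <- correlation_matrix(d, mode = "overall")
  r_pooled <- correlation_matrix(d, mode = "pooled_centered")
  expect_gt(r_overall["g1", "g2"], 0.9)   # driven purely by the class shift
  expect_lt(abs(r_pooled["g1", "g2"]), 0.3)
})

test_that("zero-variance genes are dropped from the network with a warning", {
  x <- rbind(matrix(rnorm(20), 2, 10), rep(1, 10))
  d <- toy_dataset(x, rep(c("A", "B"), each = 5))
  expect_warning(r <- correlation_matrix(d), "g3")
  expect_true(all(is.na(r["g3", ])))
  expect_true(all(is.na(r[, "g3"])))
  # and they cannot become module members
  sc <- suppressWarnings(t_statistic(d))
  mod <- find_module("g1", r, sc, grid = c(0.0001, 0.5))
  expect_false("g3" %in% mod$members)
})

test_that("find_module reproduces the exhaustive cutoff scan on toy instances", {
  # 3-gene toys with prescribed statistics and correlations
  corr <- fake_corr(3, list(list("g1", "g2", 0.9), list("g1", "g3", 0.6),
                            list("g2", "g3", 0.5)))

  # weaker neighbours never raise the average: singleton at the top cutoff
  m1 <- find_module("g1", corr, fake_scores(c(5, 4, 1)))
  expect_identical(m1$members, "g1")
  expect_equal(m1$chosen_r, 0.95)
  expect_equal(m1$score, 5)

  # a stronger neighbour is pulled in; tie rule keeps the largest cutoff
  m2 <- find_module("g1", corr, fake_scores(c(5, 6, 1)))
  expect_setequal(m2$members, c("g1", "g2"))
  expect_equal(m2$chosen_r, 0.9)
  expect_equal(m2$score, 5.5)

  # seed with no neighbour above the lowest cutoff
  corr_iso <- fake_corr(3, list(list("g1", "g2", 0.2), list("g1", "g3", 0.1),
                                list("g2", "g3", 0.9)))
  m3 <- find_module("g1", corr_iso, fake_scores(c(2, 9, 9)))
  expect_identical(m3$members, "g1")
  expect_equal(m3$chosen_r, 0.95)
})

test_that("find_module agrees with the brute-force oracle on random instances", {
  grid <- default_r_grid()
  for (s in 1:20) {
    set.seed(s)
    p <- sample(3:10, 1)
    d <- random_dataset(p = p, n_a = 6, n_b = 6, seed = 100 + s)
    sc <- t_statistic(d)
    corr <- correlation_matrix(d)
    stats <- setNames(sc$statistic, sc$gene_id)
    for (seed_gene in sc$gene_id) {
      got <- find_module(seed_gene, corr, sc, grid = grid)
      want <- brute_force_module(seed_gene, corr, stats, grid)
      expect_setequal(got$members, want$members)
      expect_equal(got$score, want$score, tolerance = 1e-12)
      expect_equal(got$chosen_r, want$chosen_r)
    }
  }
})

test_that("module score and correlation floor are recomputable from members", {
  sim <- simulate_expression(block_design(seed = 21, delta = 2))
  d <- sim$data
  sc <- t_statistic(d)
  corr <- correlation_matrix(d)
  ms <- build_module_set(select_seeds(sc, 5), corr, sc)
  stats <- setNames(sc$statistic, sc$gene_id)
  for (mod in ms$modules) {
    expect_equal(mod$score, mean(abs(stats[mod$members])), tolerance = 1e-12)
    others <- setdiff(mod$members, mod$seed)
    if (length(others) > 0) {
      expect_true(all(abs(corr[mod$seed, others]) >= mod$chosen_r))
    }
  }
})

test_that("module sets are pairwise disjoint and ordered by seed rank", {
  sim <- simulate_expression(block_design(seed = 31, delta = 2))
  d <- sim$data
  sc <- t_statistic(d)
  corr <- correlation_matrix(d)
  seeds <- select_seeds(sc, 8)
  ms <- build_module_set(seeds, corr, sc)
  members <- unlist(lapply(ms$modules, `[[`, "members"))
  expect_identical(anyDuplicated(members), 0L)
  expect_identical(vapply(ms$modules, `[[`, "", "seed"),
                   seeds[seeds %in% vapply(ms$modules, `[[`, "", "seed")])
  expect_error(build_module_set(character(0), corr, sc), "at least one")
})

test_that("rank-ordered seeds make every discovered module a singleton", {
  # The search average always includes the seed, so a seed that is the
  # strongest remaining gene can never gain from weaker members: with seeds
  # taken from the top of the ranking, the disjoint module set degenerates
  # to singletons. This pins the behaviour the decision rule implies.
  sim <- simulate_expression(block_design(seed = 41, delta = 2, shift = "all"))
  d <- sim$data
  sc <- t_statistic(d)
  ms <- build_module_set(select_seeds(sc, 5), correlation_matrix(d), sc)
  expect_true(all(vapply(ms$modules, function(m) length(m$members), 0L) == 1L))
})

test_that("modules anchored at planted seeds stay within their own block", {
  # between-block correlation is ~0, so no module should mix planted blocks
  # or absorb background genes
  for (s in 1:5) {
    sim <- simulate_expression(block_design(seed = 50 + s, delta = 2))
    d <- sim$data
    sc <- t_statistic(d)
    corr <- correlation_matrix(d)
    truth <- sim$truth
    for (k in seq_along(truth$blocks)) {
      mod <- find_module(truth$seed_genes[k], corr, sc)
      expect_true(all(mod$members %in% truth$blocks[[k]]))
    }
  }
})
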