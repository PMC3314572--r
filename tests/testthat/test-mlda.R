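# Block covariance estimation, SVD inversion, and the MLDA classifier.

# independent direct implementation of the pooled + median-correlation
# covariance, written against stats::cov rather than the package's internals
direct_block_cov <- function(d, members, shrink = TRUE) {
  a <- d$labels == levels(d$labels)[1]
  xa <- t(d$values[members, a, drop = FALSE])
  xb <- t(d$values[members, !a, drop = FALSE])
  na <- nrow(xa); nb <- nrow(xb)
  sig <- ((na - 1) * cov(xa) + (nb - 1) * cov(xb)) / (na + nb - 2)
  if (shrink && length(members) > 1) {
    sds <- sqrt(diag(sig))
    rr <- cov2cor(sig)
    r_med <- median(rr[upper.tri(rr)])
    out <- outer(sds, sds) * r_med
    diag(out) <- sds^2
    return(out)
  }
  sig
}

test_that("block covariance matches a direct evaluation of the pooled/shrunken formulas", {
  d <- random_dataset(p = 12, n_a = 9, n_b = 7, seed = 17)
  genes <- rownames(d$values)

  # singleton: the DLDA variance for that gene
  blk1 <- estimate_block_covariance(d, genes[1])
  pooled_var <- ((8) * var(d$values[1, 1:9]) + (6) * var(d$values[1, 10:16])) / 14
  expect_equal(unname(blk1$sigma[1, 1]), pooled_var, tolerance = 1e-12)
  expect_true(is.na(blk1$r_med))

  # two genes: the median of one pairwise correlation is that correlation
  blk2 <- estimate_block_covariance(d, genes[1:2])
  plain <- direct_block_cov(d, genes[1:2], shrink = FALSE)
  r12 <- plain[1, 2] / sqrt(plain[1, 1] * plain[2, 2])
  expect_equal(blk2$r_med, r12, tolerance = 1e-12)
  expect_equal(unname(blk2$sigma[1, 2]),
               sqrt(plain[1, 1] * plain[2, 2]) * r12, tolerance = 1e-12)

  # larger modules, shrunken and plain, entrywise against the oracle
  for (sz in c(4, 7)) {
    mem <- genes[seq_len(sz)]
    expect_equal(unname(estimate_block_covariance(d, mem)$sigma),
                 unname(direct_block_cov(d, mem)), tolerance = 1e-12)
    expect_equal(unname(estimate_block_covariance(d, mem, shrink = FALSE)$sigma),
                 unname(direct_block_cov(d, mem, shrink = FALSE)),
                 tolerance = 1e-12)
  }

  expect_error(estimate_block_covariance(d, c(genes[1], "nope")), "nope")
})

test_that("invert_block inverts full-rank matrices and pseudo-inverts singular ones", {
  expect_equal(invert_block(diag(3)), diag(3))
  expect_equal(invert_block(matrix(c(2, 1, 1, 2), 2)),
               matrix(c(2, -1, -1, 2) / 3, 2), tolerance = 1e-12)

  # rank-1 block: Moore-Penrose pseudo-inverse
  a <- matrix(1, 2, 2)
  a_plus <- invert_block(a)
  expect_equal(a_plus, matrix(0.25, 2, 2), tolerance = 1e-12)
  expect_equal(a %*% a_plus %*% a, a, tolerance = 1e-10)
  expect_equal(a_plus %*% a %*% a_plus, a_plus, tolerance = 1e-10)
  expect_equal(a %*% a_plus, t(a %*% a_plus), tolerance = 1e-10)

  # well-conditioned random SPD blocks agree with solve()
  for (s in 1:5) {
    set.seed(s)
    m <- crossprod(matrix(rnorm(36), 6)) + diag(6)
    expect_lt(max(abs(invert_block(m) - solve(m))) / max(abs(solve(m))), 1e-10)
  }

  expect_error(invert_block(matrix(c(1, 2, 3, 4), 2)), "symmetric")
  expect_error(invert_block(matrix(0, 2, 2)), "rank zero")
})

test_that("linear predictor sums per-block terms: whole-matrix oracle", {
  d <- random_dataset(p = 10, n_a = 12, n_b = 10, seed = 23,
                      delta = 1, shifted = 1:3)
  genes <- rownames(d$values)
  ms <- module_set_from_list(list(genes[1:4], genes[5:6], genes[7:10]))
  fit <- mlda_fit(d, ms)

  # assemble the full block-diagonal covariance explicitly, invert it whole
  p <- length(genes)
  sigma_full <- matrix(0, p, p, dimnames = list(genes, genes))
  for (blk in fit$blocks) sigma_full[blk$members, blk$members] <- blk$sigma
  mu_a <- unlist(lapply(fit$blocks, `[[`, "mu_a"))[genes]
  mu_b <- unlist(lapply(fit$blocks, `[[`, "mu_b"))[genes]
  set.seed(99)
  x_new <- matrix(rnorm(p * 25), p, 25, dimnames = list(genes, paste0("t", 1:25)))
  lp_oracle <- drop(crossprod(x_new - (mu_a + mu_b) / 2,
                              solve(sigma_full, mu_a - mu_b)))
  got <- mlda_predict(fit, x_new)
  expect_lt(max(abs(got$lp - lp_oracle)) / max(abs(lp_oracle)), 1e-10)
})

test_that("decision rule uses the log(n_B/n_A) threshold with boundary to A", {
  d <- random_dataset(p = 5, n_a = 8, n_b = 8, seed = 29)
  genes <- rownames(d$values)
  fit <- mlda_fit(d, module_set_from_list(list(genes[1:3], genes[4:5])))
  expect_equal(fit$threshold, 0)

  mu_a <- unlist(lapply(fit$blocks, `[[`, "mu_a"))[genes]
  mu_b <- unlist(lapply(fit$blocks, `[[`, "mu_b"))[genes]
  at_mean <- mlda_predict(fit, matrix(mu_a, ncol = 1,
                                      dimnames = list(genes, "m")))
  expect_gte(at_mean$lp, 0)            # half the squared Mahalanobis distance
  expect_identical(at_mean$label, "case")
  at_mid <- mlda_predict(fit, matrix((mu_a + mu_b) / 2, ncol = 1,
                                     dimnames = list(genes, "m")))
  expect_equal(at_mid$lp, 0, tolerance = 1e-10)
  expect_identical(at_mid$label, "case")  # boundary assigned to A

  # unequal class sizes shift the threshold
  d2 <- random_dataset(p = 5, n_a = 12, n_b = 6, seed = 31)
  fit2 <- mlda_fit(d2, module_set_from_list(list(rownames(d2$values))))
  expect_equal(fit2$threshold, log(6 / 12))

  expect_error(mlda_predict(fit, matrix(0, 2, 1, dimnames = list(genes[1:2], "z"))),
               "missing")
})

test_that("C = 1 without shrinkage reproduces classical full LDA", {
  skip_if_not_installed("MASS")
  for (s in 1:3) {
    d <- random_dataset(p = 8, n_a = 30, n_b = 24, seed = 60 + s,
                        delta = 1.5, shifted = 1:2)
    genes <- rownames(d$values)
    fit <- mlda_fit(d, module_set_from_list(list(genes)), shrink = FALSE)
    set.seed(s)
    x_new <- matrix(rnorm(8 * 40), 8, 40, dimnames = list(genes, paste0("t", 1:40)))
    got <- mlda_predict(fit, x_new)$label
    ref <- MASS::lda(t(d$values), grouping = d$labels)
    want <- as.character(predict(ref, t(x_new))$class)
    expect_identical(got, want)
  }
})

test_that("C = p singleton modules reproduce DLDA exactly", {
  d <- random_dataset(p = 15, n_a = 10, n_b = 14, seed = 71,
                      delta = 1, shifted = 1:4)
  genes <- rownames(d$values)
  fit_m <- mlda_fit(d, module_set_from_list(as.list(genes)))
  fit_d <- dlda_fit(d)
  set.seed(72)
  x_new <- matrix(rnorm(15 * 200), 15, 200,
                  dimnames = list(genes, paste0("t", 1:200)))
  pm <- mlda_predict(fit_m, x_new)
  pd <- dlda_predict(fit_d, x_new)
  expect_identical(pm$label, pd$label)
  expect_equal(pm$lp, pd$lp, tolerance = 1e-10)
})

test_that("swapping the A/B mapping negates the linear predictor coherently", {
  d <- random_dataset(p = 6, n_a = 9, n_b = 12, seed = 81)
  genes <- rownames(d$values)
  ms <- module_set_from_list(list(genes[1:3], genes[4:6]))
  fit_ab <- mlda_fit(d, ms)
  d_swap <- toy_dataset(d$values, as.character(d$labels), class_a = "control")
  fit_ba <- mlda_fit(d_swap, ms)
  set.seed(82)
  x_new <- matrix(rnorm(6 * 50), 6, 50, dimnames = list(genes, paste0("t", 1:50)))
  p_ab <- mlda_predict(fit_ab, x_new)
  p_ba <- mlda_predict(fit_ba, x_new)
  expect_equal(p_ba$lp, -p_ab$lp, tolerance = 1e-10)
  expect_equal(fit_ba$threshold, log(fit_ab$n_a / fit_ab$n_b))
  off_boundary <- abs(p_ab$lp - fit_ab$threshold) > 1e-8
  expect_identical(p_ab$label[off_boundary], p_ba$label[off_boundary])
})

test_that("test error falls as the planted mean shift grows", {
  errs <- vapply(c(0.5, 1.5, 3), function(delta) {
    train <- simulate_expression(block_design(n_a = 50, n_b = 50, delta = delta,
                                              seed = 90))
    test <- simulate_expression(block_design(n_a = 100, n_b = 100, delta = delta,
                                             seed = 91))
    fit <- fit_pipeline(train$data, method = "mlda", m = 5)
    pred <- predict_pipeline(fit, test$data)
    mean(pred$label != as.character(test$data$labels))
  }, 0)
  expect_true(errs[2] <= errs[1] + 0.05)   # monotone within Monte-Carlo error
  expect_true(errs[3] <= errs[2] + 0.05)
  expect_lt(errs[3], 0.05)                 # delta = 3 sd: near-perfect
})
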