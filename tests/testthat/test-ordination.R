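make_toy <- function(n = 6, m = 4, p = 2, seed = 91) {
  set.seed(seed)
  list(Y = matrix(runif(n * m), n, m,
                  dimnames = list(paste0("s", 1:n), paste0("t", 1:m))),
       X = as.data.frame(matrix(rnorm(n * p), n, p,
                                dimnames = list(NULL, paste0("e", 1:p)))))
}

test_that("RDA matches the regression-then-eigendecomposition oracle", {
  toy <- make_toy()
  fit <- rda_fit(toy$Y, toy$X)
  o <- oracle_rda(toy$Y, toy$X)
  k <- length(fit$constrained_fractions)
  expect_equal(fit$constrained_fractions, o$constrained[seq_len(k)],
               tolerance = 1e-10)
  ku <- length(fit$unconstrained_fractions)
  expect_equal(fit$unconstrained_fractions, o$unconstrained[seq_len(ku)],
               tolerance = 1e-10)
  # axis scores agree up to sign with the oracle's eigenvectors
  sv <- eigen(crossprod(o$fitted) / (nrow(toy$Y) - 1), symmetric = TRUE)
  for (a in 1:2)
    expect_equal(abs(unname(fit$species_scores[, a])), abs(sv$vectors[, a]),
                 tolerance = 1e-8)
})

test_that("variance is conserved and fractions agree with vegan", {
  toy <- make_toy(n = 12, m = 6, p = 3, seed = 92)
  fit <- rda_fit(toy$Y, toy$X, n_axes = 12)
  expect_equal(sum(fit$constrained_fractions) +
                 sum(fit$unconstrained_fractions), 1, tolerance = 1e-9)
  vg <- vegan::rda(toy$Y ~ ., data = toy$X)
  expect_equal(sum(fit$constrained_fractions),
               unname(vg$CCA$tot.chi / vg$tot.chi), tolerance = 1e-8)
  expect_equal(fit$constrained_fractions[1],
               unname(vg$CCA$eig[1] / vg$tot.chi), tolerance = 1e-8)
})

test_that("species driven by one predictor give constrained fraction 1", {
  set.seed(93)
  x <- rnorm(10)
  Y <- outer(x, c(1, -2, 0.5))   # exactly linear in x
  colnames(Y) <- paste0("t", 1:3)
  Y <- Y - min(Y)                # keep abundances nonnegative
  fit <- rda_fit(Y, data.frame(x = x))
  expect_equal(sum(fit$constrained_fractions), 1, tolerance = 1e-9)
  expect_equal(length(fit$constrained_fractions), 1L)  # one nonzero axis
})

test_that("RDA on a spanning predictor set reduces to PCA", {
  toy <- make_toy(n = 8, m = 5, seed = 94)
  dummies <- as.data.frame(diag(8)[, 1:7])
  fit <- rda_fit(toy$Y, dummies, n_axes = 8)
  pca <- rda_fit(toy$Y, n_axes = 8)
  k <- length(pca$unconstrained_fractions)
  expect_equal(fit$constrained_fractions[seq_len(k)],
               pca$unconstrained_fractions, tolerance = 1e-9)
})

test_that("collinear predictors are dropped deterministically", {
  toy <- make_toy(n = 10, m = 4, seed = 95)
  X <- toy$X
  X$dup <- 2 * X$e1
  expect_warning(fit <- rda_fit(toy$Y, X), "collinear.*dup")
  expect_identical(fit$predictors, c("e1", "e2"))
})

test_that("permutation tests flag generating variables and are seeded", {
  set.seed(96)
  x <- rnorm(30)
  Y <- outer(x, c(1, 2, -1)) + matrix(rnorm(90, 0, 0.05), 30, 3)
  colnames(Y) <- paste0("t", 1:3)
  Y <- Y - min(Y)
  env <- data.frame(x = x, noise = rnorm(30))
  p <- permutation_significance(Y, env, n_perm = 199, seed = 5)
  expect_equal(p$p[p$variable == "x"], 1 / 200)
  expect_gt(p$p[p$variable == "noise"], 0.05)
  p2 <- permutation_significance(Y, env, n_perm = 199, seed = 5)
  expect_identical(p, p2)
})

test_that("variance partitioning: oracle match and analytic limits", {
  set.seed(97)
  n <- 8
  Y <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("t", 1:5)))
  env <- data.frame(f = rnorm(n), c1 = rnorm(n), c2 = rnorm(n))
  vp <- variance_partition(Y, env, "f", c("c1", "c2"))
  o <- oracle_partition(Y, env, "f", c("c1", "c2"))
  expect_equal(vp$total_fraction, o$total, tolerance = 1e-10)
  expect_equal(vp$unique_fraction, o$unique, tolerance = 1e-10)
  # focal exactly orthogonal to the conditioners: unique = total
  Z <- cbind(1, env$c1, env$c2)
  f_orth <- as.numeric(residuals(lm(env$f ~ env$c1 + env$c2)))
  env2 <- data.frame(f = f_orth, c1 = env$c1, c2 = env$c2)
  vp2 <- variance_partition(Y, env2, "f", c("c1", "c2"))
  expect_equal(vp2$unique_fraction, vp2$total_fraction, tolerance = 1e-10)
  # focal inside the conditioners' span: unique = 0 with a note
  env3 <- data.frame(f = env$c1 + 2 * env$c2, c1 = env$c1, c2 = env$c2)
  vp3 <- variance_partition(Y, env3, "f", c("c1", "c2"))
  expect_equal(vp3$unique_fraction, 0)
  expect_match(vp3$note, "span")
  expect_error(variance_partition(Y, env, "f", c("f", "c1")), "conditioner")
})

test_that("passive projection: identity, centroid, hand multiplication", {
  b <- simulate_benchmark(n_sites = 30, n_taxa = 8, seed = 98)
  Y <- b$abundance / rowSums(b$abundance)
  set.seed(99)
  fit <- rda_fit(Y, data.frame(tp = b$x, other = rnorm(30)))
  # a fossil sample identical to a training sample gets its training scores
  sc <- passive_project(fit, Y[3, , drop = FALSE], axes = 1)
  expect_equal(unname(sc[1, 1]), unname(fit$site_scores[3, 1]),
               tolerance = 1e-10)
  # the mean assemblage projects to the origin
  ctr <- matrix(fit$centers, 1, dimnames = list("c", names(fit$centers)))
  expect_lt(abs(passive_project(fit, ctr, axes = 1)[1, 1]), 1e-10)
  # hand multiplication on a 2-interval fossil matrix
  fossil <- Y[c(5, 7), ]
  sc2 <- passive_project(fit, fossil, axes = 1:2)
  hand <- sweep(fossil, 2, fit$centers) %*% fit$species_scores[, 1:2]
  expect_equal(unname(sc2), unname(hand), tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- matrix(1, 1, 1, dimnames = list("z", "nope"))
  expect_error(passive_project(fit, bad), "no taxa shared")
})
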