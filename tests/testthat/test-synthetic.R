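test_that("degenerate field (sill = nugget = 0) equals the mean exactly", {
  xy <- data.frame(x = 1:10, y = rep(0, 10))
  env <- simulate_environment(
    xy, list(TP = field_spec(mean = 1.3, nugget = 0, sill = 0)), seed = 4)
  expect_identical(unname(env_values(env)[, "TP"]), rep(1.3, 10))
})

test_that("independent variables stay uncorrelated, requested correlation is induced", {
  set.seed(10)
  xy <- data.frame(x = runif(500, 0, 500), y = runif(500, 0, 500))
  specs <- list(a = field_spec(sill = 1, range = 30),
                b = field_spec(sill = 2, range = 60))
  env0 <- simulate_environment(xy, specs, correlation = diag(2), seed = 5)
  v0 <- env_values(env0)
  expect_lt(abs(cor(v0[, 1], v0[, 2])), 0.1)

  rho <- matrix(c(1, 0.7, 0.7, 1), 2)
  env1 <- simulate_environment(xy, specs, correlation = rho, seed = 5)
  v1 <- env_values(env1)
  expect_lt(abs(cor(v1[, 1], v1[, 2]) - 0.7), 0.15)
  # marginal variances preserved exactly by the mixing construction
  expect_lt(abs(sd(v1[, 1]) - 1), 0.2)
})

test_that("non-PSD correlation matrices are rejected with an explanation", {
  xy <- data.frame(x = 1:5, y = rep(0, 5))
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  specs <- list(a = field_spec(), b = field_spec(), c = field_spec())
  expect_error(simulate_environment(xy, specs, correlation = bad),
               "positive semi-definite")
  expect_error(simulate_environment(xy[c(1, 1, 3:5), ], list(a = field_spec())),
               "distinct")
})

test_that("simulated fields reproduce the requested variogram", {
  set.seed(2)
  xy <- data.frame(x = runif(600, 0, 400), y = runif(600, 0, 400))
  env <- simulate_environment(
    xy, list(z = field_spec(mean = 0, nugget = 0.1, sill = 1, range = 50)),
    seed = 9)
  emp <- empirical_variogram(xy, env_values(env)[, "z"], n_bins = 10)
  expected <- 0.1 + 1 * (1 - exp(-emp$lag / 50))
  expect_lt(mean(abs(emp$gamma - expected) / expected), 0.3)
})

test_that("multinomial counts sum exactly to the count total", {
  pool <- random_species_pool(20, seed = 3)
  xy <- data.frame(x = runif(50, 0, 100), y = runif(50, 0, 100))
  env <- simulate_environment(xy, list(TP = field_spec(mean = 1, sill = 0.3)),
                              seed = 6)
  ab <- suppressWarnings(
    simulate_assemblages(pool, env, "TP", count_total = 400, seed = 7))
  expect_true(all(rowSums(ab) == 400))
  expect_error(simulate_assemblages(pool, env, "TP", count_total = 0),
               "count_total")
})

test_that("a taxon's expected share peaks at the site nearest its optimum", {
  pool <- species_pool(true_optimum = c(0.5, 1.5), true_tolerance = 0.3)
  env <- env_table(data.frame(TP = seq(0, 2, length.out = 21)),
                   coords = data.frame(x = 1:21, y = rep(0, 21)))
  ab <- simulate_assemblages(pool, env, "TP", count_total = 1e6, seed = 8)
  shares <- ab / rowSums(ab)
  expect_equal(which.max(shares[, "taxon01"]), 6, tolerance = 1)  # TP = 0.5
  expect_equal(which.max(shares[, "taxon02"]), 16, tolerance = 1) # TP = 1.5
})

test_that("WA optima recomputed from a simulation recover the truth", {
  b <- simulate_benchmark(n_sites = 300, n_taxa = 50, seed = 21)
  m <- wa_fit(b$abundance, b$x, tolerance_dw = FALSE)
  u_true <- b$pool$true_optimum[match(names(m$optima), b$pool$taxon_id)]
  expect_gt(cor(m$optima, u_true), 0.95)
})

test_that("fixed seeds give bit-identical simulations, and RNG state is restored", {
  xy <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100))
  specs <- list(TP = field_spec(mean = 1, sill = 0.2))
  e1 <- simulate_environment(xy, specs, seed = 11)
  set.seed(99); junk <- rnorm(5)  # perturb global RNG
  e2 <- simulate_environment(xy, specs, seed = 11)
  expect_identical(e1$values, e2$values)

  pool <- random_species_pool(10, seed = 12)
  a1 <- simulate_assemblages(pool, e1, "TP", seed = 13)
  a2 <- simulate_assemblages(pool, e2, "TP", seed = 13)
  expect_identical(a1, a2)

  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simulate_environment(xy, specs, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("core scenarios validate their chronology and trajectory", {
  expect_error(core_scenario(c(1900, 1950, 1925), c(1, 1, 1)), "monotone")
  expect_error(core_scenario(numeric(0), numeric(0)), "at least one")
  expect_error(core_scenario(1900, NaN), "finite")
  sc <- core_scenario(2000, 0.8)  # single interval is valid
  pool <- random_species_pool(10, seed = 1)
  core <- simulate_core(pool, sc, seed = 2)
  expect_equal(nrow(core$assemblage), 1L)
  expect_equal(sum(core$assemblage), 1, tolerance = 1e-12)
})

test_that("core relative abundances sum to one per interval", {
  pool <- random_species_pool(15, seed = 5)
  sc <- enrichment_scenario()
  core <- simulate_core(pool, sc, seed = 6)
  expect_equal(unname(rowSums(core$assemblage)), rep(1, 26),
               tolerance = 1e-12)
  core2 <- simulate_core(pool, sc, seed = 6)
  expect_identical(core$assemblage, core2$assemblage)
})
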