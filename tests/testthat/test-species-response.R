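test_that("occurrence screen is a strict threshold", {
  m <- cbind(five = c(rep(1, 5), rep(0, 5)),
             six = c(rep(1, 6), rep(0, 4)),
             all = rep(2, 10))
  expect_identical(eligible_taxa(m, 5), c("six", "all"))
  expect_identical(eligible_taxa(m[, 0, drop = FALSE], 5), character(0))
})

test_that("linear response: exact signs, antisymmetry, degenerate input", {
  x <- seq(0, 1, length.out = 20)
  fl <- fit_linear(2 * x, x)
  expect_identical(fl$sign, 1L)
  expect_equal(fl$r, 1)
  expect_identical(fit_linear(2 * x, -x)$sign, -1L)
  flat <- fit_linear(rep(3, 20), x)
  expect_identical(flat$sign, 0L)
  expect_equal(flat$p, 1)
})

test_that("linear test attains nominal size on null data", {
  set.seed(51)
  hits <- replicate(400, fit_linear(rnorm(50), rnorm(50))$sign != 0L)
  rate <- mean(hits)
  bounds <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])
})

test_that("Gaussian fit finds symmetric peaks, boundaries, and recovers truth", {
  x <- seq(0, 10, length.out = 41)
  tri <- pmax(0, 5 - abs(x - 5))       # symmetric triangular peak at 5
  g <- fit_gaussian(tri, x)
  expect_lt(abs(g$optimum - 5), 0.1)
  mono <- fit_gaussian(exp(x / 4), x)  # strictly increasing
  expect_equal(mono$optimum, 10)
  set.seed(52)
  xg <- runif(200, -3, 3)
  yg <- rpois(200, 20 * exp(-(xg - 0.7)^2 / 2))
  gr <- fit_gaussian(yg, xg)
  expect_lt(abs(gr$optimum - 0.7), 0.2)
  expect_true(gr$better_than_linear)
  # genuinely linear data must not flag the Gaussian fit as better
  set.seed(53)
  ylin <- 2 + 3 * xg + rnorm(200, 0, 0.2)
  expect_false(fit_gaussian(ylin, xg)$better_than_linear)
})

test_that("WA optimum is the abundance-weighted mean, scale invariant", {
  expect_equal(wa_optimum(c(2, 1), c(1, 4)), 2)
  expect_equal(wa_optimum(c(0, 0, 5), c(1, 3, 7)), 7)
  expect_true(is.na(wa_optimum(c(0, 0), c(1, 2))))
  set.seed(54)
  y <- runif(30); x <- rnorm(30)
  expect_equal(wa_optimum(10 * y, x), wa_optimum(y, x), tolerance = 1e-12)
  # matching tolerance definition
  u <- wa_optimum(y, x)
  expect_equal(wa_tolerance(y, x), sqrt(sum(y * (x - u)^2) / sum(y)),
               tolerance = 1e-12)
})

test_that("indicator rescaling maps the gradient to integers 0-10", {
  expect_identical(rescale_indicator(c(0, 10, 5), 0, 10), c(0L, 10L, 5L))
  expect_identical(rescale_indicator(0.55, 0, 1), 6L)  # half rounds up
  expect_warning(out <- rescale_indicator(12, 0, 10), "clipped")
  expect_identical(out, 10L)
  expect_error(rescale_indicator(1, 5, 5), "gradient_min")
})

test_that("categorical specificity matches brute-force shares", {
  y <- c(0, 0, 1, 2, 3, 4)
  season <- c("spring", "spring", "summer", "summer", "summer", "summer")
  expect_identical(categorical_specificity(y, season),
                   c(spring = 0L, summer = 10L))
  expect_identical(categorical_specificity(c(1, 1, 1, 1), rep(c("a", "b"), 2)),
                   c(a = 5L, b = 5L))
  lakes <- c("erie", "erie", "huron", "huron", "superior", "superior")
  y2 <- c(3, 1, 0, 4, 2, 0)
  shares <- c(erie = 4, huron = 4, superior = 2) / 10
  expect_identical(categorical_specificity(y2, lakes),
                   setNames(as.integer(round(shares * 10)), names(shares)))
  expect_error(categorical_specificity(y2, lakes[-1]), "length")
})

test_that("GAM permutation test: deterministic signal, seeding, confounding", {
  set.seed(55)
  tp <- runif(60, 0, 2)
  y <- exp(-(tp - 1)^2 / 0.1)          # noise-free unimodal response
  g <- gam_tp_significance(y, tp, n_perm = 99, seed = 7)
  expect_equal(g$p, 1 / 100)
  g2 <- gam_tp_significance(y, tp, n_perm = 99, seed = 7)
  expect_identical(g, g2)
  # TP identical to the covariate: no added deviance
  gc <- gam_tp_given_cov(y, tp, tp, n_perm = 49, seed = 8)
  expect_gt(gc$p, 0.3)
  # TP effect orthogonal to the covariate survives conditioning
  z <- runif(60, 0, 2)
  go <- gam_tp_given_cov(y, tp, z, n_perm = 49, seed = 9)
  expect_lt(go$p, 0.05)
})

test_that("coefficient tables assemble, recover optima, and rerun identically", {
  b <- simulate_benchmark(n_sites = 120, n_taxa = 20, seed = 61)
  env <- b$env
  env$season <- rep(c("spring", "summer"), length.out = 120)
  env$lake <- rep(paste0("lake", 1:5), length.out = 120)
  tab <- build_coefficient_table(b$abundance, env, basis = "rel_density")
  expect_s3_class(tab, "coefficient_table")
  expect_true(all(tab$coefficients$indicator_wa %in% 0:10))
  expect_true(all(tab$coefficients$indicator_gau %in% 0:10))
  expect_identical(sort(unique(tab$coefficients$variable)), "TP")
  u_true <- b$pool$true_optimum[match(tab$coefficients$taxon,
                                      b$pool$taxon_id)]
  expect_gt(cor(tab$coefficients$wa_optimum, u_true), 0.9)
  expect_equal(unname(rowSums(tab$season_specificity)), rep(10, length(tab$taxa)),
               tolerance = 1)  # shares sum to ~1 before rounding
  tab2 <- build_coefficient_table(b$abundance, env, basis = "rel_density")
  expect_identical(tab, tab2)
  # empty eligible list still yields a well-formed empty table
  empty <- build_coefficient_table(matrix(0, 3, 2,
                                          dimnames = list(NULL, c("a", "b"))),
                                   env_table(data.frame(TP = c(1, 2, 3))),
                                   basis = "rel_density")
  expect_identical(nrow(empty$coefficients), 0L)
  expect_true(all(c("taxon", "wa_optimum") %in% names(empty$coefficients)))
})
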