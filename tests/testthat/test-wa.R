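toy_y <- matrix(c(10, 0, 2,
                  4, 4, 0,
                  0, 6, 1,
                  1, 2, 7,
                  3, 0, 5), 5, 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:5), c("ta", "tb", "tc")))
toy_x <- c(1.0, 1.5, 2.0, 2.5, 3.0)

test_that("WA coefficients match the hand-sum oracle exactly", {
  for (tw in c(TRUE, FALSE)) {
    m <- wa_fit(toy_y, toy_x, tolerance_dw = tw)
    o <- oracle_wa_fit(toy_y, toy_x, tolerance_dw = tw)
    expect_equal(unname(m$optima), o$u, tolerance = 1e-12)
    expect_equal(unname(m$tolerances), o$tol, tolerance = 1e-12)
    expect_equal(c(m$b0, m$b1), c(o$b0, o$b1), tolerance = 1e-12)
    expect_equal(unname(m$fitted), o$fitted, tolerance = 1e-12)
  }
})

test_that("perfectly separated samples give exact optima and apparent r2 = 1", {
  y <- diag(3) * c(5, 7, 2)
  colnames(y) <- c("a", "b", "c"); rownames(y) <- paste0("s", 1:3)
  x <- c(2, 4, 6)
  m <- wa_fit(y, x, tolerance_dw = FALSE)
  expect_equal(unname(m$optima), x)
  expect_equal(r_squared_for_test(x, predict(m, y)$fit), 1, tolerance = 1e-9)
})

test_that("inverse deshrinking preserves the observed mean", {
  set.seed(71)
  b <- simulate_benchmark(n_sites = 60, n_taxa = 15, seed = 72)
  m <- wa_fit(b$abundance, b$x)
  expect_equal(mean(predict(m, b$abundance)$fit), mean(b$x),
               tolerance = 1e-10)
})

test_that("predictions: monospecific, mixtures, batching, bounds, scaling", {
  m <- wa_fit(toy_y, toy_x, tolerance_dw = FALSE)
  mono <- matrix(c(8, 0, 0), 1, dimnames = list("m", colnames(toy_y)))
  expect_equal(predict(m, mono)$fit, m$b0 + m$b1 * m$optima[["ta"]],
               tolerance = 1e-12, ignore_attr = TRUE)
  # 50/50 mixture of two taxa averages their optima before deshrinking
  y2 <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 3, 2, byrow = TRUE,
               dimnames = list(NULL, c("p", "q")))
  m2 <- wa_fit(y2, c(2, 4, 3), tolerance_dw = FALSE)
  mix <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("p", "q")))
  expect_equal(predict(m2, mix)$raw,
               mean(m2$optima), tolerance = 1e-12, ignore_attr = TRUE)
  # batch equals looped single-sample prediction
  batch <- predict(m, toy_y)$fit
  looped <- vapply(1:5, function(i)
    predict(m, toy_y[i, , drop = FALSE])$fit, numeric(1))
  expect_equal(batch, looped, tolerance = 1e-12, ignore_attr = TRUE)
  # raw estimates stay inside the span of optima of taxa present
  set.seed(73)
  yr <- matrix(runif(40), 8, 5, dimnames = list(NULL, letters[1:5]))
  mr <- wa_fit(yr, rnorm(8))
  raw <- predict(mr, yr)$raw
  expect_true(all(raw >= min(mr$optima) - 1e-12 &
                    raw <= max(mr$optima) + 1e-12))
  # abundance-scale invariance for relative bases
  expect_equal(predict(mr, 10 * yr)$fit, predict(mr, yr)$fit,
               tolerance = 1e-12)
})

test_that("zero-abundance taxa are dropped, unknown samples flagged", {
  y <- cbind(toy_y, dead = 0)
  expect_warning(m <- wa_fit(y, toy_x), "zero total abundance")
  expect_false("dead" %in% names(m$optima))
  stranger <- matrix(1, 1, 1, dimnames = list("z", "unknown_taxon"))
  pr <- predict(m, stranger)
  expect_true(pr$no_analog)
  expect_true(is.na(pr$fit))
  expect_equal(pr$coverage, 0)
})

test_that("jackknife equals a naive refit-in-a-loop oracle", {
  set.seed(74)
  y <- matrix(rpois(15 * 8, 3) + matrix(rpois(15 * 8, 1), 15, 8), 15, 8,
              dimnames = list(paste0("s", 1:15), paste0("t", 1:8)))
  y[y < 2] <- 0
  y <- y[rowSums(y) > 0, colSums(y) > 0]
  x <- seq_len(nrow(y)) / 4
  for (tw in c(TRUE, FALSE)) {
    cv <- wa_jackknife(y, x, tolerance_dw = tw)
    expect_equal(cv$predictions$jackknife, oracle_jackknife(y, x, tw),
                 tolerance = 1e-10)
  }
})

test_that("duplicated samples make jackknife match apparent performance", {
  b <- simulate_benchmark(n_sites = 40, n_taxa = 15, seed = 75)
  y <- rbind(b$abundance, b$abundance)
  x <- c(b$x, b$x)
  cv <- wa_jackknife(y, x)
  expect_lt(abs(cv$r2_jack - cv$r2_apparent), 0.02)
  expect_lt(abs(cv$rmsep_jack - cv$rmse_apparent), 0.02)
})

test_that("MAT: identity analog, k = n mean, hand-computed chord distances", {
  ytr <- matrix(c(0.5, 0.5, 0.0,
                  0.2, 0.3, 0.5,
                  1.0, 0.0, 0.0), 3, 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), c("a", "b", "c")))
  xtr <- c(1, 2, 3)
  self <- mat_predict(ytr, xtr, ytr[2, , drop = FALSE], k = 1)
  expect_equal(self$min_distance, 0, tolerance = 1e-12)
  expect_equal(self$fit, 2)
  all_mean <- mat_predict(ytr, xtr, ytr[1, , drop = FALSE], k = 3)
  expect_equal(all_mean$fit, 2)
  D <- attr(mat_predict(ytr, xtr, ytr, k = 1), "distances")
  expect_equal(D[1, 2], oracle_sq_chord(ytr[1, ], ytr[2, ]),
               tolerance = 1e-12)
  expect_equal(D[1, 3], oracle_sq_chord(ytr[1, ], ytr[3, ]),
               tolerance = 1e-12)
  expect_error(mat_predict(ytr, xtr, ytr, k = 9), "exceeds")
})

test_that("MAT includes all analogs tied at the k-th distance", {
  ytr <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  colnames(ytr) <- c("p", "q")
  out <- mat_predict(ytr, c(1, 5, 9), ytr[1, , drop = FALSE], k = 1)
  expect_equal(out$k_used, 2)  # both zero-distance analogs included
  expect_equal(out$fit, 3)
})

test_that("model serialization round-trips predictions", {
  m <- wa_fit(toy_y, toy_x)
  path <- tempfile(fileext = ".txt")
  write_wa_model(m, path)
  m2 <- read_wa_model(path)
  expect_equal(m2$optima, m$optima, tolerance = 1e-15)
  expect_equal(predict(m2, toy_y)$fit, predict(m, toy_y)$fit,
               tolerance = 1e-12)
  expect_identical(m2$options$tolerance_dw, m$options$tolerance_dw)
})
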