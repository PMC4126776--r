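# Independent brute-force oracles, written as explicit scalar loops /
# projection matrices so they share no code path with the package.

oracle_wa_fit <- function(y, x, tolerance_dw = TRUE, deshrink = TRUE) {
  y <- y / rowSums(y)
  n <- nrow(y); m <- ncol(y)
  u <- tol <- numeric(m)
  for (k in seq_len(m)) {
    u[k] <- sum(y[, k] * x) / sum(y[, k])
    tol[k] <- sqrt(sum(y[, k] * (x - u[k])^2) / sum(y[, k]))
  }
  floor_k <- sd(x) / 10
  tol <- pmax(tol, floor_k)
  x0 <- numeric(n)
  for (i in seq_len(n)) {
    w <- if (tolerance_dw) y[i, ] / tol^2 else y[i, ]
    x0[i] <- sum(w * u) / sum(w)
  }
  if (deshrink) {
    b <- coef(lm(x ~ x0))
  } else b <- c(0, 1)
  list(u = u, tol = tol, x0 = x0, b0 = unname(b[1]), b1 = unname(b[2]),
       fitted = unname(b[1] + b[2] * x0))
}

oracle_jackknife <- function(y, x, tolerance_dw = TRUE) {
  n <- nrow(y)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- y[-i, , drop = FALSE]
    keep <- colSums(ytr / rowSums(ytr)) > 0
    fit <- oracle_wa_fit(ytr[, keep, drop = FALSE], x[-i], tolerance_dw)
    yi <- y[i, keep]
    yi <- yi / sum(y[i, ])            # relative over all taxa
    yi <- yi / sum(yi)                # renormalized over modeled taxa
    w <- if (tolerance_dw) yi / fit$tol^2 else yi
    pred[i] <- fit$b0 + fit$b1 * sum(w * fit$u) / sum(w)
  }
  pred
}

oracle_sq_chord <- function(p, q) {
  s <- 0
  for (j in seq_along(p)) s <- s + (sqrt(p[j]) - sqrt(q[j]))^2
  unname(s)
}

oracle_variogram_bins <- function(coords, values, breaks) {
  n <- nrow(coords)
  lag <- g <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    h <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    lag[[length(lag) + 1]] <- h
    g[[length(g) + 1]] <- (values[i] - values[j])^2 / 2
  }
  lag <- unlist(lag); g <- unlist(g)
  out <- NULL
  for (b in seq_len(length(breaks) - 1)) {
    sel <- lag > breaks[b] & lag <= breaks[b + 1]
    if (b == 1) sel <- sel | (lag > 0 & lag <= breaks[2])
    sel <- sel & lag > 0
    if (any(sel))
      out <- rbind(out, data.frame(lag = (breaks[b] + breaks[b + 1]) / 2,
                                   gamma = mean(g[sel]), n_pairs = sum(sel)))
  }
  out
}

# Two-step RDA oracle: per-species OLS on standardized predictors, then
# eigendecomposition of the fitted-value covariance.
oracle_rda <- function(Y, X) {
  n <- nrow(Y)
  Yc <- scale(Y, scale = FALSE)
  Xs <- scale(as.matrix(X))
  fitted <- matrix(0, n, ncol(Yc))
  for (j in seq_len(ncol(Yc))) {
    fitted[, j] <- fitted(lm(Yc[, j] ~ Xs))
  }
  eig_c <- eigen(crossprod(fitted) / (n - 1), symmetric = TRUE)$values
  eig_u <- eigen(crossprod(Yc - fitted) / (n - 1), symmetric = TRUE)$values
  total <- sum(diag(crossprod(Yc))) / (n - 1)
  list(constrained = eig_c / total, unconstrained = eig_u / total,
       fitted = fitted)
}

# Variance-partition oracle via explicit projection matrices.
oracle_partition <- function(Y, env, focal, conditioners) {
  n <- nrow(Y)
  Yc <- scale(Y, scale = FALSE)
  total <- sum(Yc^2) / (n - 1)
  xf <- env[[focal]] - mean(env[[focal]])
  proj <- function(M) M %*% solve(crossprod(M)) %*% t(M)
  Hf <- proj(cbind(xf))
  total_frac <- sum((Hf %*% Yc)^2) / (n - 1) / total
  Z <- cbind(1, scale(as.matrix(env[, conditioners, drop = FALSE])))
  Rz <- diag(n) - proj(Z)
  xr <- Rz %*% xf
  Yr <- Rz %*% Yc
  Hu <- proj(cbind(xr))
  unique_frac <- sum((Hu %*% Yr)^2) / (n - 1) / total
  list(total = total_frac, unique = unique_frac)
}

r_squared_for_test <- function(obs, pred) cor(obs, pred)^2
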