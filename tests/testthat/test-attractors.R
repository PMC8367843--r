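# 1-unit network dynamics: tau xdot = -x + w f(x) + b + win u. With large
# self-excitation w the system is bistable; with w = 0 it contracts.
unit_params <- function(w, b = 0, win = rep(0, 6)) {
  rnn_params(W_in = matrix(win, 1, 6), W_rec = matrix(w, 1, 1),
             W_out = matrix(0, 4, 1), b = b, b_out = rep(0, 4),
             sigma_rec = 0, sigma_in = 0)
}

test_that("q is zero at an exact fixed point and non-negative everywhere", {
  # 1 unit, w = 0, b = 0, u = 0: xdot = -x / tau, so x = 0 is the fixed
  # point and q(0) = 0 exactly
  p <- unit_params(0, b = 0)
  expect_equal(state_speed(0, rep(0, 6), p), 0)
  for (x in seq(-3, 3, 0.5)) {
    expect_gte(state_speed(x, rep(0, 6), p), 0)
  }
})

test_that("q matches a symbolic evaluation on a 2-unit toy", {
  p <- rnn_params(W_in = matrix(0.1, 2, 6),
                  W_rec = rbind(c(0.5, -0.2), c(0.3, 0.1)),
                  W_out = matrix(0, 4, 2), b = c(0.1, -0.1),
                  b_out = rep(0, 4), sigma_rec = 0, sigma_in = 0)
  x <- c(0.7, -0.4)
  u <- c(1, 0, 0.5, 0.5, 1, 1)
  f <- log(1 + exp(x))
  xdot <- (-x + p$W_rec %*% f + p$W_in %*% u + p$b) / p$tau
  expect_equal(state_speed(x, u, p), 0.5 * sum(xdot^2))
})

test_that("the search recovers the closed-form point of a linear regime", {
  # small-signal 2-unit system: around strongly negative currents the
  # softplus is ~ exp(x), so choose currents near 0 where f is smooth and
  # solve by an independent generic root-finder on the 2-D system
  set.seed(131)
  p <- rnn_params(W_in = matrix(runif(12, -0.2, 0.2), 2, 6),
                  W_rec = rbind(c(0.3, 0.1), c(-0.2, 0.4)),
                  W_out = matrix(0, 4, 2), b = c(0.2, -0.3),
                  b_out = rep(0, 4), sigma_rec = 0, sigma_in = 0)
  u <- c(0, 0, 1.04, 0.96, 1, 1)
  # oracle: dense grid + Nelder-Mead refinement, no gradients shared with
  # the implementation under test
  obj <- function(x) {
    f <- log(1 + exp(x))
    sum((-x + p$W_rec %*% f + p$W_in %*% u + p$b)^2)
  }
  grid <- expand.grid(x1 = seq(-2, 3, 0.25), x2 = seq(-2, 3, 0.25))
  vals <- apply(grid, 1, obj)
  x0 <- as.numeric(grid[which.min(vals), ])
  oracle <- optim(x0, obj, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-16))
  oracle <- optim(oracle$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-16))
  set.seed(2)
  fps <- find_fixed_points(p, u, x_ref = c(0, 0), n_restarts = 20,
                           init_sd = 1)
  fixed <- fps[fps$class == "fixed", ]
  expect_equal(nrow(fixed), 1)   # unique fixed point after dedup
  expect_lt(sqrt(sum((fixed$x[[1]] - oracle$par)^2)), 1e-6)
  expect_lt(fixed$q[1], 1e-4)
})

test_that("a two-fixed-point 1-unit network yields both points", {
  # tau xdot = -x + w f(x) + b with convex softplus f: w f(x) + b - x is
  # convex, so there are at most two crossings. With w = 3, b = -2 there
  # are exactly two: a stable one (flow converges from both sides) and an
  # unstable one beyond which self-excitation runs away.
  p <- unit_params(3, b = -2)
  u <- rep(0, 6)
  g <- function(x) -x + 3 * log(1 + exp(x)) - 2
  # independent root-finding oracle on sign changes of g
  xs <- seq(-6, 12, 0.01)
  sg <- sign(g(xs))
  roots <- sort(vapply(which(diff(sg) != 0), function(i) {
    uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-12)$root
  }, numeric(1)))
  expect_length(roots, 2)
  set.seed(3)
  fps <- find_fixed_points(p, u, n_restarts = 60, init = "gaussian",
                           init_sd = 2)
  fixed <- fps[fps$class == "fixed", ]
  found <- sort(unlist(fixed$x))
  expect_true(any(abs(found - roots[1]) < 1e-6))
  expect_true(any(abs(found - roots[2]) < 1e-6))
  expect_true(all(fixed$q < 1e-4))
  # stability agrees with the flow direction around each root
  expect_true(classify_stability(roots[1], p, u)$stable)
  expect_false(classify_stability(roots[2], p, u)$stable)
})

test_that("stability probes match the Jacobian oracle on toy systems", {
  u <- rep(0, 6)
  # contracting: w = 0, the map x -> 0 pulls every probe home
  p_c <- unit_params(0)
  st <- classify_stability(0, p_c, u)
  expect_true(st$stable)
  expect_lt(st$jac_abscissa, 0)
  # expanding: the upper crossing of a self-exciting unit
  p_e <- unit_params(3, b = -2)
  g <- function(x) -x + 3 * log(1 + exp(x)) - 2
  mid <- uniroot(g, c(-1, 0), tol = 1e-13)$root
  st_e <- classify_stability(mid, p_e, u)
  expect_false(st_e$stable)
  expect_gt(st_e$jac_abscissa, 0)
  # 2-unit saddle: one stable, one unstable eigendirection
  p_s <- rnn_params(W_in = matrix(0, 2, 6),
                    W_rec = diag(c(3, 0)), W_out = matrix(0, 4, 2),
                    b = c(-2, 0), b_out = rep(0, 4),
                    sigma_rec = 0, sigma_in = 0)
  xsad <- c(mid, 0)
  expect_lt(state_speed(xsad, u, p_s), 1e-10)
  st_s <- classify_stability(xsad, p_s, u)
  expect_false(st_s$stable)
  eg <- eigen(rnn_jacobian(xsad, p_s), only.values = TRUE)$values
  expect_gt(max(Re(eg)), 0)
  expect_lt(min(Re(eg)), 0)
})

test_that("deduplication is idempotent and keeps the lowest-q member", {
  set.seed(137)
  centers <- rbind(c(0, 0), c(5, 5), c(-3, 2))
  xs <- centers[rep(1:3, each = 10), ] + matrix(rnorm(60, 0, 0.01), 30, 2)
  qs <- runif(30)
  d1 <- rnngeom:::dedup_points(xs, qs, dedup_dist = 0.5)
  expect_length(d1$keep, 3)
  expect_equal(sort(d1$n_hits), c(10, 10, 10))
  for (k in d1$keep) {
    grp <- which(sqrt(rowSums((xs - rep(xs[k, ], each = 30))^2)) < 0.5)
    expect_equal(qs[k], min(qs[grp]))
  }
  xs2 <- xs[d1$keep, ]
  qs2 <- qs[d1$keep]
  d2 <- rnngeom:::dedup_points(xs2, qs2, dedup_dist = 0.5)
  expect_equal(length(d2$keep), length(d1$keep))
  expect_equal(d2$n_hits, rep(1L, 3))
})

test_that("line summaries report exact collinearity and planted residuals", {
  set.seed(139)
  N <- 8
  B <- qr.Q(qr(matrix(rnorm(N * 3), N, 3)))
  sub <- structure(list(basis = B, center = rep(0, N)), class = "subspace")
  # points on an exact line in the projected space
  dir <- c(1, 2, -1) / sqrt(6)
  tline <- seq(-2, 2, length.out = 8)
  P3 <- outer(tline, dir)
  pts <- P3 %*% t(B)
  res <- line_attractor_summary(pts, rep("color", 8), sub,
                                endpoints = pts,
                                endpoint_contexts = rep("color", 8))
  expect_equal(res$collinearity, 1, tolerance = 1e-12)
  expect_equal(res$mean_endpoint_residual, 0, tolerance = 1e-10)
  expect_equal(res$frac_nearest_own, 1)
  # planted line + isotropic 2-D jitter of the endpoints: mean distance to
  # the line approaches sigma * sqrt(pi / 2) (2-D residual, half-normal
  # radius) -- checked against a Monte Carlo oracle band
  sigma <- 0.2
  n_end <- 4000
  te <- runif(n_end, -2, 2)
  E3 <- outer(te, dir)
  # jitter orthogonal to the line within the 3-D projection
  ortho <- qr.Q(qr(cbind(dir, diag(3)[, 1:2])))[, 2:3]
  E3 <- E3 + (matrix(rnorm(2 * n_end, 0, sigma), n_end, 2) %*% t(ortho))
  ends <- E3 %*% t(B)
  res2 <- line_attractor_summary(pts, rep("color", 8), sub,
                                 endpoints = ends,
                                 endpoint_contexts = rep("color", n_end))
  expect_equal(res2$mean_endpoint_residual, sigma * sqrt(pi / 2),
               tolerance = 0.05)
  # degenerate: fewer than two points
  res3 <- line_attractor_summary(pts[1, , drop = FALSE], "color", sub,
                                 endpoints = ends[1:2, ],
                                 endpoint_contexts = c("color", "color"))
  expect_true(is.na(res3$collinearity))
})

test_that("returned fixed points hold their class threshold after probes", {
  # contract: every fixed-class member of a search satisfies q < 1e-4 and
  # re-simulating from a stable fixed point stays put
  p <- unit_params(3, b = -2)
  u <- rep(0, 6)
  set.seed(5)
  fps <- find_fixed_points(p, u, n_restarts = 30, init = "gaussian",
                           init_sd = 4)
  fixed <- fps[fps$class == "fixed", ]
  expect_true(all(fixed$q < 1e-4))
  for (i in seq_len(nrow(fixed))) {
    st <- classify_stability(fixed$x[[i]], p, u)
    if (st$stable) {
      x <- fixed$x[[i]]
      r <- softplus(x)
      for (s in 1:100) {
        step <- rnn_step(x, r, u, p, noise = FALSE)
        x <- as.numeric(step$x)
        r <- step$r
      }
      expect_lt(abs(x - fixed$x[[i]]), 0.05)
    }
  }
})
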