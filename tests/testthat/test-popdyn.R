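test_that("peak sorting recovers a planted order and normalizes rows", {
  set.seed(73)
  nt <- 40
  peaks <- c(35, 5, 20, 10, 28)
  R <- sequence_rates(5, nt, peaks)
  ps <- peak_sort(R)
  expect_equal(ps$order, order(peaks))
  expect_equal(unname(apply(ps$heatmap, 1, max)), rep(1, 5))
  expect_true(all(diff(ps$peak_time) >= 0))
  # an all-zero unit is excluded with a warning
  R0 <- rbind(R, 0)
  expect_warning(ps0 <- peak_sort(R0), "excluded")
  expect_equal(ps0$excluded, 6L)
  expect_equal(ps0$order, order(peaks))
})

test_that("random activity shows no ridge beyond its shuffle null", {
  set.seed(79)
  nt <- 40
  n <- 60
  R <- matrix(abs(rnorm(n * nt)) + 0.5, n, nt)
  si_obs <- sequentiality_index(R)$si
  # shuffle oracle: permuting each row's time bins must give a similar SI
  si_null <- replicate(20, {
    Rs <- t(apply(R, 1, sample))
    sequentiality_index(Rs)$si
  })
  expect_lt(abs(si_obs - mean(si_null)), 4 * sd(si_null) + 0.05)
  # and a genuinely sequential pattern clears the same null decisively
  seqR <- sequence_rates(n, nt, round(seq(2, nt - 1, length.out = n))) + 0.1
  expect_gt(sequentiality_index(seqR)$si, max(si_null))
})

test_that("SI terms take their closed-form values in designed cases", {
  nt <- 32
  n <- 32
  # uniform peak times, sharp ridges: entropy = log(number of bins)
  R <- sequence_rates(n, nt, seq_len(nt), width = 0.8) + 1e-6
  st <- sequentiality_index(R, ridge_window = 4, n_entropy_bins = nt)
  expect_equal(st$entropy, log(nt), tolerance = 1e-10)
  # all units peaking in one bin: entropy 0
  R1 <- sequence_rates(n, nt, rep(10, n)) + 1e-6
  st1 <- sequentiality_index(R1, ridge_window = 4)
  expect_equal(st1$entropy, 0)
  # SI = entropy + mean log ridge term, by definition
  expect_equal(st$si, st$entropy + st$mean_log_ridge)
})

test_that("SI matches a hand computation on a 3-unit toy", {
  R <- rbind(c(1, 8, 1, 1),
             c(1, 1, 8, 1),
             c(2, 2, 2, 8))
  # ridge window 1 bin: ridge = peak value, background = mean of the rest
  st <- sequentiality_index(R, ridge_window = 1, n_entropy_bins = 4)
  p <- c(1, 1, 1) / 3
  H <- -sum(p * log(p))            # peaks in bins 2, 3, 4
  ridge <- c(log(8 / 1), log(8 / 1), log(8 / 2))
  expect_equal(st$entropy, H)
  expect_equal(st$mean_log_ridge, mean(ridge))
  expect_equal(st$si, H + mean(ridge))
})

test_that("SI is unit-relabeling invariant and rises with ridge sharpness", {
  set.seed(83)
  nt <- 40
  n <- 30
  peaks <- round(seq(2, nt - 1, length.out = n))
  R <- sequence_rates(n, nt, peaks, width = 3) + 0.05
  perm <- sample(n)
  expect_equal(sequentiality_index(R)$si,
               sequentiality_index(R[perm, ])$si)
  widths <- c(6, 4, 2.5, 1.5)   # sharper ridges, ascending SI
  sis <- vapply(widths, function(w) {
    sequentiality_index(sequence_rates(n, nt, peaks, width = w) + 0.05)$si
  }, numeric(1))
  expect_true(all(diff(sis) > 0))
})

test_that("Monte Carlo SI distribution is reproducible and sized", {
  set.seed(89)
  R <- sequence_rates(20, 30, round(seq(2, 29, length.out = 20))) + 0.1
  set.seed(1)
  d1 <- si_monte_carlo(R, n_samples = 200, subsample = 16)
  set.seed(1)
  d2 <- si_monte_carlo(R, n_samples = 200, subsample = 16)
  expect_identical(d1, d2)
  expect_length(d1, 200)
  expect_warning(si_monte_carlo(R, n_samples = 50, subsample = 8),
                 "coarse")
})

test_that("KS comparison separates distinct SI distributions, not identical ones", {
  fx <- fixture_net()
  set.seed(97)
  untrained <- init_params(fx$params$N)
  act_u <- condition_activity(untrained, noise = FALSE)
  set.seed(7)
  si_t <- si_monte_carlo(fx$activity, n_samples = 300,
                         subsample = fx$params$N)
  si_u <- si_monte_carlo(act_u, n_samples = 300,
                         subsample = fx$params$N)
  ks <- suppressWarnings(ks.test(si_t, si_u))
  expect_lt(ks$p.value, 0.05)
  # calibration: two draws from the same network are not separable more
  # often than chance (p roughly uniform; a single draw suffices as a
  # smoke check that the test does not always reject)
  set.seed(8)
  si_t2 <- si_monte_carlo(fx$activity, n_samples = 300,
                          subsample = fx$params$N)
  ks_same <- suppressWarnings(ks.test(si_t, si_t2))
  expect_gt(ks_same$p.value, 1e-4)
})

test_that("weight-order profiles expose planted asymmetry", {
  set.seed(101)
  n <- 30
  # symmetric matrix: asymmetry statistic sits inside its permutation null
  S <- matrix(rnorm(n * n), n)
  S <- (S + t(S)) / 2
  ord <- sample(n)
  wp <- weight_order_profile(S, ord)
  expect_equal(wp$asymmetry, 0, tolerance = 1e-12)
  null_asym <- replicate(50, weight_order_profile(S, sample(n))$asymmetry)
  expect_equal(mean(null_asym), 0, tolerance = 1e-10)
  # planted forward bias: W[post, pre] larger when pre peaks earlier
  W <- matrix(0, n, n)
  ordf <- seq_len(n)
  pos <- order(ordf)
  for (i in 1:n) for (j in 1:n) {
    d <- pos[i] - pos[j]
    if (d > 0 && d <= 5) W[i, j] <- 1   # forward, short range
    if (d < 0 && d >= -5) W[i, j] <- -0.5
  }
  wpf <- weight_order_profile(W, ordf)
  expect_gt(wpf$asymmetry, 0)
  expect_setequal(wpf$profile$offset, setdiff(-(n - 1):(n - 1), 0))
})

test_that("the skew-symmetric fit matches brute-force optimization", {
  set.seed(103)
  for (k in c(3, 4)) {
    X <- matrix(rnorm(k * 80), k, 80)
    Y <- matrix(rnorm(k * 80), k, 80)
    M <- rnngeom:::skew_lsq(X, Y)
    expect_equal(M, -t(M), tolerance = 1e-12)
    # brute force over the k(k-1)/2 free entries
    np <- k * (k - 1) / 2
    obj <- function(theta) {
      Mb <- matrix(0, k, k)
      Mb[upper.tri(Mb)] <- theta
      Mb <- Mb - t(Mb)
      sum((Y - Mb %*% X)^2)
    }
    o <- optim(rep(0, np), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
    Mb <- matrix(0, k, k)
    Mb[upper.tri(Mb)] <- o$par
    Mb <- Mb - t(Mb)
    expect_lt(max(abs(M - Mb)), 1e-6)
  }
})

test_that("rotation fits recover a planted 2-D rotation", {
  set.seed(107)
  omega <- 0.21          # rad per step
  nt <- 60
  th <- omega * (0:(nt - 1))
  N <- 10
  B <- qr.Q(qr(matrix(rnorm(N * 2), N, 2)))
  # several conditions: same rotation, different phases and radii
  trajs <- lapply(1:4, function(ci) {
    r0 <- 1 + 0.3 * ci
    ph <- ci
    circ <- cbind(r0 * cos(th + ph), r0 * sin(th + ph))
    circ %*% t(B)
  })
  fit <- fit_rotation(trajs, k = 2)
  # invariants
  expect_equal(fit$M, -t(fit$M), tolerance = 1e-10)
  expect_equal(fit$Q %*% t(fit$Q), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(abs(Re(eigen(fit$M)$values)) < 1e-8))
  expect_equal(fit$P, t(fit$P), tolerance = 1e-10)
  expect_true(all(eigen(fit$P, only.values = TRUE)$values > -1e-10))
  expect_equal(fit$Q %*% fit$P, fit$A, tolerance = 1e-10,
               ignore_attr = TRUE)
  # frequency recovery: for isotropic circle data the least-squares skew
  # fit of the first-difference map R - I is its skew part (R - R') / 2,
  # whose eigenvalue magnitude is sin(omega)
  expect_equal(fit$frequencies[1], sin(omega), tolerance = 0.01)
  # Q is the exact one-step rotation
  expect_equal(sort(Arg(eigen(fit$Q)$values)), sort(c(-omega, omega)),
               tolerance = 1e-6)
  expect_gt(fit$r2_M, 0.98)
  # projections are circles of constant radius per condition
  pr <- project_rotations(fit, 1)
  for (ci in 1:4) {
    rad <- sqrt(rowSums(pr[[ci]]^2))
    expect_lt(diff(range(rad)) / mean(rad), 0.01)
  }
  expect_error(project_rotations(fit, 5), "out of range")
})

test_that("an already-orthogonal least-squares map passes through polar", {
  set.seed(109)
  th <- 0.4
  R2 <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  # exact VAR data: x_{t+1} = R2 x_t, two conditions
  trajs <- lapply(1:2, function(ci) {
    X <- matrix(0, 2, 50)
    X[, 1] <- rnorm(2)
    for (t in 2:50) X[, t] <- R2 %*% X[, t - 1]
    t(X)
  })
  fit <- fit_rotation(trajs, k = 2)
  expect_equal(fit$Q, fit$A, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("zero dynamics yield a null generator and no rotation planes", {
  N <- 6
  set.seed(113)
  tr <- matrix(rep(rnorm(N), each = 20), 20, N)
  trajs <- list(tr + 0, tr + 0.5)   # two constant trajectories
  expect_warning(fit <- fit_rotation(trajs, k = 2), "singular")
  expect_equal(fit$M, matrix(0, 2, 2), tolerance = 1e-10)
  expect_length(fit$planes, 0)
  # reduced trajectories themselves are motionless
  for (p in fit$proj) expect_lt(max(abs(diff(p))), 1e-10)
})
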