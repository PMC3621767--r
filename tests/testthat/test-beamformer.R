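test_that("window covariance matches hand computation and basic limits", {
  # one trial, two channels, window values ch1 = ch2 = (1, -1):
  # mean-removed outer products / (n - 1) -> [[1, 1], [1, 1]]
  data <- array(0, c(1, 2, 2))
  data[1, 1, ] <- c(1, -1); data[1, 2, ] <- c(1, -1)
  ep <- make_epochs(data, fs = 1, condition = "deviant")
  C <- compute_covariance(ep, c(0, 2), trials = 1)
  # zero-mean samples (1,-1): sum of outer products / (n - 1) = 2/(2-1)
  expect_equal(C$matrix, matrix(2, 2, 2))

  # constant epochs carry no variance
  const <- make_epochs(array(7, c(3, 2, 10)), fs = 10)
  expect_equal(compute_covariance(const, c(0, 1))$matrix, matrix(0, 2, 2))

  # a 1-sample window cannot define a covariance
  expect_error(compute_covariance(const, c(0, 0.05)), "fewer than 2")
})

test_that("white-noise covariance converges to sigma^2 I (law of large numbers)", {
  set.seed(101)
  sigma <- 2.5
  data <- array(rnorm(500 * 2 * 40, sd = sigma), c(500, 2, 40))
  ep <- make_epochs(data, fs = 40)
  C <- compute_covariance(ep, c(0, 1))$matrix
  expect_lt(max(abs(C - sigma^2 * diag(2))) / sigma^2, 0.1)
})

test_that("optimal orientation solves the pseudo-Z criterion", {
  set.seed(7)
  # single nonzero gain column -> that axis
  G1 <- cbind(rnorm(6), 0, 0)
  expect_equal(abs(sum(optimal_orientation(G1, diag(6)) * c(1, 0, 0))), 1)

  # identity covariance -> dominant right-singular direction of the gain
  G <- matrix(rnorm(18), 6, 3)
  o <- optimal_orientation(G, diag(6), regularization = 0)
  v1 <- svd(G)$v[, 1]
  expect_equal(abs(sum(o * v1)), 1, tolerance = 1e-8)

  # random tangential (rank-2) case against a 3600-angle grid search
  G2 <- matrix(rnorm(12), 6, 2) %*% diag(c(2, 1))
  gain <- G2 %*% t(matrix(rnorm(6), 3, 2))          # channels x 3, rank 2
  A <- crossprod(matrix(rnorm(120), 20, 6)) / 20 + diag(6)  # SPD covariance
  crit <- function(u3) {
    h <- gain %*% u3 / sqrt(sum(u3^2))
    Ci <- solve(A)
    as.numeric((t(h) %*% Ci %*% h) / (t(h) %*% Ci %*% Ci %*% h))
  }
  o2 <- optimal_orientation(gain, A, regularization = 0)
  # grid-search oracle over the gain's 2-D right-singular plane
  V <- svd(gain)$v[, 1:2]
  angs <- seq(0, pi, length.out = 3600)
  vals <- vapply(angs, function(a)
    crit(V %*% c(cos(a), sin(a))), numeric(1))
  expect_equal(crit(o2), max(vals), tolerance = 1e-6)

  expect_error(optimal_orientation(matrix(0, 6, 3), diag(6)), "zero gain")
})

test_that("SAM weights have unit gain and solve the constrained problem", {
  set.seed(8)
  G <- matrix(rnorm(12), 4, 3)
  ori <- c(0, 1, 0)
  h <- as.numeric(G %*% ori)

  # identity covariance -> closed form h / (h'h)
  flt <- sam_weights(G, ori, diag(4), regularization = 0)
  expect_equal(flt$weights, h / sum(h^2), tolerance = 1e-12)

  # unit gain holds for a general covariance
  C <- crossprod(matrix(rnorm(40), 10, 4)) / 10 + 0.5 * diag(4)
  flt2 <- sam_weights(G, ori, C, regularization = 0)
  expect_equal(sum(flt2$weights * h), 1, tolerance = 1e-10)

  # generic-optimizer oracle: minimize w'Cw on the affine constraint set,
  # parameterized on the null space of h'
  N <- qr.Q(qr(cbind(h)), complete = TRUE)[, 2:4]
  w0 <- h / sum(h^2)
  obj <- function(al) { w <- w0 + N %*% al; sum(w * (C %*% w)) }
  opt <- optim(c(0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  w_opt <- w0 + N %*% opt$par
  expect_equal(flt2$weights, as.numeric(w_opt), tolerance = 1e-5)

  expect_error(sam_weights(matrix(0, 4, 3), ori, C), "zero")
})

test_that("projected noise power follows the SVD noise estimate", {
  w <- c(0.3, -0.2, 0.5)
  expect_equal(noise_power(4 * diag(3), w), 4 * sum(w^2))
  expect_equal(noise_power(diag(c(4, 1)), c(0, 1)), 1)
  C <- crossprod(matrix(rnorm(30), 10, 3)) / 10
  expect_equal(noise_power(7 * C, w), 7 * noise_power(C, w),
               tolerance = 1e-12)
})

test_that("pseudo-T equals a fully hand-computed chain on a two-channel toy", {
  # two channels, two grid points, rank-1 gains; every quantity recomputed
  # by hand from the definitions with plain matrix algebra
  set.seed(9)
  ntr <- 6; nsamp <- 20
  data <- array(rnorm(2 * ntr * 2 * nsamp, sd = 1), c(2 * ntr, 2, nsamp))
  sig <- sin(2 * pi * (1:nsamp) / 10)
  h1 <- c(1, 0.5); h2 <- c(-0.3, 1)
  for (tr in seq_len(ntr) * 2) {                  # even trials: deviants
    data[tr, , ] <- data[tr, , ] + 3 * h1 %*% t(sig)
  }
  ep <- make_epochs(data, fs = 10,
                    condition = rep(c("standard", "deviant"), ntr))
  pairs <- data.frame(run_id = 1L,
                      standard_trial = seq_len(ntr) * 2 - 2,
                      deviant_trial = seq_len(ntr) * 2 - 1)
  grid <- list(points = matrix(0, 2, 3), spacing_mm = 10, dim = c(1, 1, 2),
               origin_mm = c(0, 0, 0), index = 1:2,
               head = head_model())
  class(grid) <- "source_grid"
  lf <- structure(list(gain = cbind(h1, 0, 0, h2, 0, 0),
                       grid = grid), class = "leadfield")
  win <- window_pair(c(0.2, 1.8))
  m <- pseudo_t_map(pairs, ep, lf, win, regularization = 0)

  # ---- independent chain ----
  idx <- which((0:(nsamp - 1)) / 10 >= 0.2 & (0:(nsamp - 1)) / 10 < 1.8)
  cov_of <- function(rows) {
    acc <- matrix(0, 2, 2)
    for (r in rows) {
      X <- data[r, , idx]
      X <- X - rowMeans(X)
      acc <- acc + X %*% t(X) / (length(idx) - 1)
    }
    acc / length(rows)
  }
  Ca <- cov_of(pairs$deviant_trial + 1)
  Cc <- cov_of(pairs$standard_trial + 1)
  Cp <- (Ca + Cc) / 2
  smin <- min(svd(Cp)$d)
  hand <- vapply(list(h1, h2), function(h) {
    w <- solve(Cp, h) / as.numeric(t(h) %*% solve(Cp, h))
    (as.numeric(t(w) %*% Ca %*% w) - as.numeric(t(w) %*% Cc %*% w)) /
      (smin * sum(w^2))
  }, numeric(1))
  expect_equal(m$values, hand, tolerance = 1e-10)
  expect_gt(m$values[1], m$values[2])             # source lives on point 1
})

test_that("identical active and control data give an exactly zero map", {
  data <- array(rnorm(8 * 2 * 30), c(8, 2, 30))
  for (tr in seq_len(4)) data[2 * tr, , ] <- data[2 * tr - 1, , ]
  ep <- make_epochs(data, fs = 10,
                    condition = rep(c("standard", "deviant"), 4))
  pairs <- data.frame(run_id = 1L, standard_trial = (1:4) * 2 - 2,
                      deviant_trial = (1:4) * 2 - 1)
  grid <- list(points = matrix(c(0, 0, 0.05), 1, 3), spacing_mm = 10,
               dim = c(1, 1, 1), origin_mm = c(0, 0, 0), index = 1,
               head = head_model())
  class(grid) <- "source_grid"
  lf <- structure(list(gain = cbind(c(1, 2), c(0.5, -1), 0),
                       grid = grid), class = "leadfield")
  m <- pseudo_t_map(pairs, ep, lf, window_pair(c(0.5, 2.5)))
  expect_equal(m$values, 0)
})

test_that("pseudo-T is invariant under a global gain rescaling of the data", {
  set.seed(10)
  data <- array(rnorm(8 * 3 * 40), c(8, 3, 40))
  ep <- make_epochs(data, fs = 20,
                    condition = rep(c("standard", "deviant"), 4))
  pairs <- data.frame(run_id = 1L, standard_trial = (1:4) * 2 - 2,
                      deviant_trial = (1:4) * 2 - 1)
  grid <- list(points = matrix(c(0, 0, 0.05), 1, 3), spacing_mm = 10,
               dim = c(1, 1, 1), origin_mm = c(0, 0, 0), index = 1,
               head = head_model())
  class(grid) <- "source_grid"
  lf <- structure(list(gain = cbind(rnorm(3), rnorm(3), rnorm(3)),
                       grid = grid), class = "leadfield")
  m1 <- pseudo_t_map(pairs, ep, lf, window_pair(c(0.2, 1.8)))
  ep2 <- ep; ep2$epochs <- 1e6 * ep2$epochs
  m2 <- pseudo_t_map(pairs, ep2, lf, window_pair(c(0.2, 1.8)))
  expect_equal(m1$values, m2$values, tolerance = 1e-8)
})

test_that("source-free contrasts are symmetric about zero across seeds", {
  head <- small_head(); arr <- small_array(32)
  grid <- make_source_grid(head, 25)
  lf <- build_leadfield(grid, arr, head)
  spec <- short_spec(9, 4)
  pos <- 0; tot <- 0
  for (seed in 1:4) {
    s <- sim_subject(list(), spec, head, arr, seed = 300 + seed,
                     background_dipoles = 40, background_amplitude = 10e-9)
    m <- pseudo_t_map(s$pairs, s$epochs, lf, window_pair(c(0.1, 0.2)))
    pos <- pos + sum(m$values > 0); tot <- tot + length(m$values)
  }
  expect_gt(binom.test(pos, tot)$p.value, 0.01)
})
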