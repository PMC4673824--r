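test_that("community initialisation seeds one carrier clone among uniques", {
  set.seed(1)
  p <- ibm_params(N = 1e4, n = 3, z = 0.5, s = 0.05, r = 0, m = 0, C0 = 0.1,
                  t_end = 10)
  st <- init_community(p)
  expect_equal(sum(st$count), 1e4)
  expect_equal(sum(st$count[st$focal == 1]), 1000)
  expect_true(all(st$background[st$focal == 1] == 1))
  d <- community_diversity(st)
  expect_equal(d$C, 0.1)

  # C0 = 1: a single clone
  st1 <- init_community(ibm_params(N = 500, n = 2, z = 0.6, s = 0, r = 0,
                                   m = 0, C0 = 1, t_end = 1))
  d1 <- community_diversity(st1)
  expect_equal(c(d1$D_f, d1$D_bg, d1$DR), c(1, 1, 1))

  # C0 = 0: everyone unique, Hill number equals N
  st0 <- init_community(ibm_params(N = 2000, s = 0, r = 0, m = 0, C0 = 0,
                                   t_end = 1))
  d0 <- community_diversity(st0)
  expect_equal(c(d0$D_f, d0$D_bg), c(2000, 2000))

  expect_warning(init_community(ibm_params(N = 100, s = 0.1, r = 0, m = 0,
                                           C0 = 1e-4, t_end = 1)),
                 "cannot start")
  expect_warning(ibm_params(N = 100, n = 10, z = 0.01, s = 0, r = 0, m = 0,
                            C0 = 0, t_end = 1), "foreign niches")
})

test_that("niche association weights cover the stated regimes", {
  expect_equal(niche_weights(ibm_params(N = 10, n = 1, z = 0.3, s = 0, r = 0,
                                        m = 0, C0 = 0, t_end = 1)),
               matrix(1, 1, 1))
  sig <- niche_weights(ibm_params(N = 10, n = 5, z = 1, s = 0, r = 0, m = 0,
                                  C0 = 0, t_end = 1))
  expect_equal(sig, diag(5))
  sig <- niche_weights(ibm_params(N = 10, n = 5, z = 1 / 5, s = 0, r = 0,
                                  m = 0, C0 = 0, t_end = 1))
  expect_true(all(abs(sig - 0.2) < 1e-15))
  sig <- niche_weights(ibm_params(N = 10, n = 4, z = 0.4, s = 0, r = 0, m = 0,
                                  C0 = 0, t_end = 1))
  expect_equal(rowSums(sig), rep(1, 4))
})

test_that("resource allocation shares each niche by competitive weight", {
  # a sole competitor takes the whole community's resources
  p <- ibm_params(N = 50, n = 1, z = 1, s = 0.1, r = 0, m = 0, C0 = 0,
                  t_end = 1)
  st <- hgtsweep:::.new_community(2, 2, 1, 1, N = 50, n = 1, next_id = 3)
  expect_equal(allocate_resources(st, p)$R, 50)

  # carriers vs non-carriers in one niche: per-capita ratio (1 + s) : 1
  st <- hgtsweep:::.new_community(c(1, 2), c(1, 2), c(1, 1), c(30, 70),
                                  N = 100, n = 1, next_id = 3)
  res <- allocate_resources(st, p)
  expect_equal(res$R[1] / res$R[2], 1.1)
  expect_equal(sum(st$count * res$R), 100) # resource conservation

  # symmetric classes get equal shares
  p2 <- ibm_params(N = 100, n = 2, z = 0.7, s = 0, r = 0, m = 0, C0 = 0,
                   t_end = 1)
  st <- hgtsweep:::.new_community(c(2, 3), c(2, 3), c(1, 2), c(50, 50),
                                  N = 100, n = 2, next_id = 4)
  res <- allocate_resources(st, p2)
  expect_equal(res$R[1], res$R[2])
  expect_equal(sum(st$count * res$R), 100)

  # an empty niche forfeits its share
  p3 <- ibm_params(N = 100, n = 2, z = 1, s = 0, r = 0, m = 0, C0 = 0,
                   t_end = 1)
  st <- hgtsweep:::.new_community(2, 2, 1, 100, N = 100, n = 2, next_id = 3)
  expect_equal(sum(st$count * allocate_resources(st, p3)$R), 50)
})

test_that("reproduction is a conditioned-Poisson Wright-Fisher update", {
  p <- ibm_params(N = 1e4, n = 1, z = 1, s = 0.1, r = 0, m = 0, C0 = 0.3,
                  t_end = 1)
  C <- 0.3; N <- 1e4
  st <- hgtsweep:::.new_community(c(1, 2), c(1, 2), c(1, 1),
                                  c(C * N, (1 - C) * N), N = N, n = 1,
                                  next_id = 3)
  res <- allocate_resources(st, p)
  set.seed(7)
  reps <- 1e4
  inc <- replicate(reps, {
    nxt <- reproduce(st, res, p)
    sum(nxt$count[nxt$focal == 1]) - C * N
  })
  expect_equal(sapply(replicate(3, reproduce(st, res, p), simplify = FALSE),
                      function(x) sum(x$count)), rep(N, 3))
  # expected carrier gain s C (1-C) N / (1 + s C), the ODE selection term
  expected <- p$s * C * (1 - C) * N / (1 + p$s * C)
  expect_lt(abs(mean(inc) - expected), 3 * sd(inc) / sqrt(reps))
  expect_error(reproduce(st, list(R = c(0, 0)), p), "zero resources")
})

test_that("transfer converts non-carriers at per-capita rate C r", {
  N <- 1e4; C <- 0.4
  p <- ibm_params(N = N, n = 1, z = 1, s = 0, r = 0.01, m = 0, C0 = C,
                  t_end = 1)
  st <- hgtsweep:::.new_community(c(1, 2), c(1, 2), c(1, 1),
                                  c(C * N, (1 - C) * N), N = N, n = 1,
                                  next_id = 3)
  set.seed(11)
  reps <- 1e4
  conv <- replicate(reps, transfer_step(st, p)$conversions)
  expected <- p$r * C * (1 - C) * N
  expect_lt(abs(mean(conv) - expected), 3 * sd(conv) / sqrt(reps))
  # no donors or no transfer: nothing happens
  p0 <- ibm_params(N = N, n = 1, z = 1, s = 0, r = 0, m = 0, C0 = C, t_end = 1)
  expect_equal(transfer_step(st, p0)$conversions, 0)
  st0 <- hgtsweep:::.new_community(2, 2, 1, N, N = N, n = 1, next_id = 3)
  expect_equal(transfer_step(st0, p)$conversions, 0)
  # converts keep background and niche
  out <- transfer_step(st, p)$state
  gained <- out[out$focal == 1 & out$background == 2, ]
  expect_true(nrow(gained) == 1 && gained$niche == 1)
})

test_that("migration replaces a uniform Binomial(N, m) slice with uniques", {
  N <- 5e3; C <- 0.5
  st <- hgtsweep:::.new_community(c(1, 2), c(1, 2), c(1, 1),
                                  c(C * N, (1 - C) * N), N = N, n = 1,
                                  next_id = 3)
  p0 <- ibm_params(N = N, n = 1, z = 1, s = 0, r = 0, m = 0, C0 = C, t_end = 1)
  expect_identical(migrate_step(st, p0), st)
  p1 <- ibm_params(N = N, n = 1, z = 1, s = 0, r = 0, m = 1, C0 = C, t_end = 1)
  wiped <- migrate_step(st, p1)
  expect_equal(sum(wiped$count[wiped$focal == 1]), 0)
  expect_equal(sum(wiped$count), N)
  expect_equal(nrow(wiped), N) # every immigrant unique
  pm <- ibm_params(N = N, n = 1, z = 1, s = 0, r = 0, m = 0.05, C0 = C,
                   t_end = 1)
  set.seed(13)
  reps <- 2000
  lost <- replicate(reps, {
    out <- migrate_step(st, pm)
    C * N - sum(out$count[out$focal == 1])
  })
  expect_lt(abs(mean(lost) - pm$m * C * N), 3 * sd(lost) / sqrt(reps))
})

test_that("runs are reproducible and conserve the community size", {
  p <- ibm_params(N = 5000, n = 5, z = 0.5, s = 0.05, r = 1e-3, m = 0.02,
                  C0 = 0.1, t_end = 300, seed = 9)
  a <- ibm_run(p)
  b <- ibm_run(p)
  expect_identical(a, b)
  expect_equal(nrow(a), 301)
  expect_true(all(a$C >= 0 & a$C <= 1))
  expect_true(all(diff(a$cumulative_flux) >= 0))
  c2 <- ibm_run(ibm_params(N = 5000, n = 5, z = 0.5, s = 0.05, r = 1e-3,
                           m = 0.02, C0 = 0.1, t_end = 300, seed = 10))
  expect_false(identical(a$C, c2$C))
})

test_that("beneficial alleles fix without migration in nearly every run", {
  fixed <- vapply(1:20, function(k) {
    p <- ibm_params(N = 1e5, n = 1, z = 1, s = 0.05, r = 0, m = 0, C0 = 0.01,
                    t_end = 1500, seed = 400 + k)
    res <- ibm_run(p, record_every = 1500)
    res$C[nrow(res)] == 1
  }, logical(1))
  expect_gte(sum(fixed), 19)
})

test_that("neutral heterozygosity decays by 1 - 1/N per generation", {
  N <- 100; t <- 30; reps <- 400
  H <- vapply(1:reps, function(k) {
    p <- ibm_params(N = N, n = 1, z = 1, s = 0, r = 0, m = 0, C0 = 0,
                    t_end = t, seed = 8000 + k)
    res <- ibm_run(p, record_every = t)
    1 - 1 / res$D_bg[nrow(res)]
  }, numeric(1))
  expected <- (1 - 1 / N)^(t + 1) # founding uniques give H_0 = 1 - 1/N
  expect_lt(abs(mean(H) - expected), 3 * sd(H) / sqrt(reps))
})

test_that("the single-niche IBM tracks the compartment-model dynamics", {
  p <- sweep_params(N = 1e5, s = 0.05, r = 1e-4, m = 0.02, C0 = 0.01)
  ode <- sweep_integrate(p, 500)
  Cs <- vapply(1:10, function(k) {
    res <- ibm_run(ibm_params(N = 1e5, n = 1, z = 1, s = 0.05, r = 1e-4,
                              m = 0.02, C0 = 0.01, t_end = 500,
                              seed = 600 + k), record_every = 500)
    res$C[nrow(res)]
  }, numeric(1))
  # the ODE tracks the pre-migration fraction; the IBM records after the
  # migration step, so allow the O(m) ordering offset plus sampling noise
  expect_lt(abs(mean(Cs) - ode$C[nrow(ode)]), 0.02)
})
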