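test_that("weighted histogram normalises, ignores weight scale, errors off-range", {
  s <- sample_set(c(-0.5, -0.2, 0.2, 0.5))
  edges <- c(-1, 0, 1)
  expect_equal(weighted_histogram(s, edges), c(0.5, 0.5))
  s2 <- sample_set(c(-0.5, -0.2, 0.2, 0.5), weights = rep(2, 4))
  expect_equal(weighted_histogram(s2, edges), c(0.5, 0.5))
  expect_error(weighted_histogram(sample_set(c(5, 6)), edges), "outside")
  expect_error(sample_set(1:3, weights = c(1, -1, 1)), "finite and > 0")
})

test_that("flat probabilities give a flat zero profile; empty bins are masked", {
  s <- sample_set(c(0.25, 0.75))
  p <- profile_from_samples(s, c(0, 0.5, 1))
  expect_equal(p$dG, c(0, 0))
  p2 <- profile_from_samples(s, c(0, 0.5, 1, 1.5))
  expect_true(p2$mask[3])
  expect_true(is.na(p2$dG[3]))
  expect_equal(min(p2$dG, na.rm = TRUE), 0)
})

test_that("a 51:1 population ratio maps to ~10 kJ/mol at 310 K", {
  kT <- kT_at(310)
  expect_equal(kT, 2.577, tolerance = 2e-4)
  s <- sample_set(rep(c(0.25, 0.75), times = c(51, 1)), kT = kT)
  p <- profile_from_samples(s, c(0, 0.5, 1))
  ddG <- p$dG[2] - p$dG[1]
  expect_equal(ddG, kT * log(51), tolerance = 1e-12)
  expect_equal(ddG, 10.1, tolerance = 0.05)
})

test_that("importance reweighting recovers unbiased bin masses", {
  # draw from exp(-(U+V)/kT) by direct inversion on a discrete grid, then
  # reweight by exp(+V/kT); oracle = numerical integration of exp(-U/kT)
  set.seed(41)
  kT <- kT_at(310)
  grid <- seq(-pi, pi, length.out = 4001)
  U <- 3 * cos(grid); V <- 2 * sin(grid)
  pb <- exp(-(U + V) / kT); pb <- pb / sum(pb)
  draws <- sample(grid, 4e4, replace = TRUE, prob = pb)
  Vd <- 2 * sin(draws)
  rw <- reweight_metadynamics(draws, Vd, kT)
  edges <- seq(-pi, pi, length.out = 9)
  got <- weighted_histogram(rw, edges)
  pu <- exp(-U / kT) / sum(exp(-U / kT))
  want <- vapply(seq_len(8), function(b)
    sum(pu[grid >= edges[b] & grid < edges[b + 1]]), numeric(1))
  want <- want / sum(want)
  se <- sqrt(want * (1 - want) / 4e4) * 3  # crude multinomial bound, inflated
  expect_true(all(abs(got - want) < pmax(3 * se, 0.01)))
})

test_that("zero or constant bias reduces bit-for-bit to the plain pipeline", {
  set.seed(42)
  vals <- runif(500, -1, 1)
  edges <- seq(-1, 1, length.out = 11)
  plain <- profile_from_samples(sample_set(vals), edges)
  rw0 <- profile_from_samples(reweight_metadynamics(vals, rep(0, 500),
                                                    kT_at(310)), edges)
  rwc <- profile_from_samples(reweight_metadynamics(vals, rep(7.3, 500),
                                                    kT_at(310)), edges)
  expect_identical(plain$dG, rw0$dG)
  expect_identical(plain$dG, rwc$dG)
  expect_error(reweight_metadynamics(vals, c(NA, rep(0, 499))), "finite")
})

test_that("adding a constant to the bias leaves profiles unchanged", {
  set.seed(43)
  vals <- rnorm(300)
  bias <- runif(300, 0, 5)
  edges <- seq(-4, 4, length.out = 17)
  p1 <- profile_from_samples(reweight_metadynamics(vals, bias), edges)
  p2 <- profile_from_samples(reweight_metadynamics(vals, bias + 11), edges)
  expect_equal(p1$dG, p2$dG)
})

test_that("replica combination averages, propagates SE and unions masks", {
  mk <- function(dg) structure(list(edges = c(0, 1, 2), centers = c(0.5, 1.5),
                                    dG = dg, se = c(0, 0),
                                    mask = is.na(dg), kT = kT_at(310)),
                               class = "qw_fes")
  comb <- combine_replicas(list(mk(c(0, 2)), mk(c(0, 4))))
  expect_equal(comb$dG, c(0, 3))
  expect_equal(comb$se, c(0, 1))
  same <- combine_replicas(list(mk(c(0, 2)), mk(c(0, 2))))
  expect_equal(same$se, c(0, 0))
  masked <- combine_replicas(list(mk(c(0, NA)), mk(c(0, 4))))
  expect_true(masked$mask[2])
  expect_error(combine_replicas(list(mk(c(0, 2)),
                                     structure(list(edges = c(0, 1, 3)),
                                               class = "qw_fes"))),
               "identical bin edges")
})

test_that("replica SE shrinks like 1/sqrt(n) on repeated synthetic runs", {
  spec <- double_well_potential()
  edges <- seq(-pi, pi, length.out = 37)
  profs <- lapply(1:8, function(r)
    profile_from_samples(sample_set(sample_potential(spec, 8000,
                                                     seed = 50 + r)$values,
                                    kT = spec$kT), edges))
  se2 <- mean(combine_replicas(profs[1:2])$se, na.rm = TRUE)
  se8 <- mean(combine_replicas(profs)$se, na.rm = TRUE)
  expect_lt(se8, se2)  # noisy, but the 2x shrink should dominate
})

test_that("harmonic-well samples recover the quadratic profile", {
  kT <- kT_at(310)
  kappa <- 10
  spec <- potential_spec(function(s) 0.5 * kappa * s^2, domain = c(-4, 4),
                         periodic = FALSE, kT = kT)
  s <- sample_potential(spec, 5e4, seed = 44)
  expect_equal(var(s$values), kT / kappa, tolerance = 0.1)
  edges <- seq(-1.6, 1.6, length.out = 17)
  prof <- profile_from_samples(sample_set(s$values, kT = kT), edges)
  ref <- analytic_profile(spec, edges)
  # compare over well-sampled bins; the extreme tails are shot-noise bound
  sel <- ref$dG < 6
  expect_lt(max(abs(prof$dG - ref$dG)[sel], na.rm = TRUE), 0.45)
})

test_that("2D profiles marginalise to the 1D profile of the same samples", {
  set.seed(45)
  kT <- kT_at(310)
  v <- cbind(rnorm(2e4), rnorm(2e4))
  e1 <- seq(-3, 3, length.out = 13)
  s2 <- sample_set(v, kT = kT)
  p2 <- weighted_histogram(s2, list(e1, e1))
  in_range <- v[, 1] >= -3 & v[, 1] <= 3 & v[, 2] >= -3 & v[, 2] <= 3
  p1 <- weighted_histogram(sample_set(v[in_range, 1], kT = kT), e1)
  expect_equal(rowSums(p2), p1, tolerance = 1e-10)
})

test_that("the accumulated bias evaluator honours periodic images", {
  v <- eval_bias(c(-pi + 0.05), centers = pi - 0.05, heights = 1, sigma = 0.4,
                 period = 2 * pi)
  expect_equal(v, exp(-0.1^2 / (2 * 0.16)), tolerance = 1e-10)
  far <- eval_bias(0, centers = pi - 0.05, heights = 1, sigma = 0.4)
  expect_lt(far, v)
})
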