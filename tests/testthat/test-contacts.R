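make_pair_traj <- function(distances, dt = 0.002) {
  # two atoms separated by the given distance in each frame
  n <- length(distances)
  atoms <- data.frame(chain = "A", resid = 1:2, resname = c("GLU", "TYR"),
                      atom = c("OE1", "OH"), stringsAsFactors = FALSE)
  coords <- array(0, c(n, 2, 3))
  coords[, 2, 1] <- distances
  trajectory(coords, atoms, dt = dt)
}

test_that("direct H-bond uses a strict heavy-atom distance cutoff", {
  tr <- make_pair_traj(c(0.30, 0.35, 1.2))
  sp <- contact_spec(1L, 2L, bridge_order = 0L, cutoff = 0.35)
  expect_true(detect_direct(tr, 1, sp))
  expect_false(detect_direct(tr, 2, sp))  # boundary: not formed at 0.35
  expect_false(detect_direct(tr, 3, sp))
})

test_that("one-water bridge needs both legs under the cutoff", {
  mk <- function(w_acc) toy_bridge_traj(c(0, 0, 0), c(0.6, 0, 0),
                                        matrix(c(0.6 - w_acc, 0, 0), 1))
  sp <- contact_spec(1L, 2L, bridge_order = 1L)
  r <- detect_bridge(mk(0.33), 1, sp)   # donor-w 0.27, w-acc 0.33
  expect_true(r$formed)
  expect_length(r$waters, 1L)
  expect_false(detect_bridge(mk(0.36), 1, sp)$formed)  # one leg fails
})

test_that("bridge detection is symmetric and matches the exhaustive oracle", {
  set.seed(31)
  for (rep in 1:40) {
    nw <- sample(4:12, 1)
    waters <- matrix(runif(nw * 3, 0, 1.2), ncol = 3)
    donor <- matrix(runif(3, 0, 0.3), 1)
    acceptor <- matrix(runif(3, 0.5, 1.2), 1)
    tr <- toy_bridge_traj(donor, acceptor, waters)
    for (k in 1:3) {
      sp <- contact_spec(1L, 2L, bridge_order = k)
      sp_rev <- contact_spec(2L, 1L, bridge_order = k)
      got <- detect_bridge(tr, 1, sp)$formed
      expect_identical(got, brute_bridge(donor, acceptor, waters, k, 0.35))
      expect_identical(got, detect_bridge(tr, 1, sp_rev)$formed)
    }
  }
})

test_that("contact series summarises occupancy and respects strictness", {
  tr <- make_pair_traj(c(0.3, 0.3, 0.3, 0.3))
  cs <- contact_series(tr, contact_spec(1L, 2L))
  expect_equal(cs$occupancy, 1)
  expect_error(contact_series(make_pair_traj(0.3), contact_spec(1L, 2L)),
               "2 frames")
})

test_that("square-wave pulses give exact lifetimes at zero tolerance", {
  formed <- rep(rep(c(TRUE, FALSE), each = 10), 5)
  cs <- contact_series_from_logical(formed, dt = 0.002, gap_tolerance = 0)
  expect_equal(cs$lifetimes, rep(0.02, 5))
  expect_equal(hbond_lifetime(cs), 0.02)
})

test_that("gap tolerance merges short interruptions and is monotone", {
  formed <- c(rep(TRUE, 10), FALSE, rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 4))
  dt <- 0.002
  lt0 <- hbond_lifetime(formed, gap_tolerance = 0, dt = dt)
  lt1 <- hbond_lifetime(formed, gap_tolerance = dt, dt = dt)
  expect_equal(lt0, mean(c(10, 10, 4)) * dt)
  expect_equal(lt1, mean(c(21, 4)) * dt)  # one-frame gap absorbed
  tols <- seq(0, 0.02, by = dt)
  lts <- vapply(tols, function(tl) hbond_lifetime(formed, tl, dt = dt),
                numeric(1))
  expect_true(all(diff(lts) >= -1e-12))
})

test_that("random formation records keep lifetimes monotone in tolerance", {
  set.seed(32)
  for (rep in 1:25) {
    formed <- runif(400) < 0.4
    if (!any(formed)) next
    dt <- 0.002
    lts <- vapply(dt * (0:6), function(tl)
      hbond_lifetime(formed, tl, dt = dt), numeric(1))
    expect_true(all(diff(lts) >= -1e-12))
  }
})

test_that("no formed frames yields zero lifetime with a warning", {
  expect_warning(lt <- hbond_lifetime(rep(FALSE, 10), dt = 0.1), "no formed")
  expect_equal(lt, 0)
})

test_that("the moving average preserves the series mean up to edge effects", {
  set.seed(33)
  x <- as.numeric(runif(5000) < 0.3)
  for (w in c(5, 50, 501)) {
    ma <- moving_average(x, w)
    expect_length(ma, length(x))
    expect_equal(mean(ma), mean(x), tolerance = w / length(x))
  }
  expect_equal(moving_average(x, 1), x)
})

test_that("telegraph occupancy and lifetime match the analytic laws", {
  k_on <- 2; k_off <- 4; dt <- 0.01; n <- 1e5
  x <- telegraph_series(k_on, k_off, dt, n, seed = 34)
  theta <- k_on / (k_on + k_off)
  se <- telegraph_theta_se(k_on, k_off, dt, n)
  expect_lt(abs(mean(x) - theta), 3 * se)
  lt <- hbond_lifetime(x, gap_tolerance = 0, dt = dt)
  n_events <- length(qowire:::contact_events(x, dt, 0)$durations)
  expect_lt(abs(lt - 1 / k_off), 3 * (1 / k_off) / sqrt(n_events))
})

test_that("hydration counts are exact on planted frames and label-invariant", {
  set.seed(35)
  nw <- 6
  waters <- rbind(matrix(runif(9, 0, 0.2), 3),    # 3 within 0.35 of origin-ish
                  matrix(runif(9, 2, 3), 3))      # 3 far away
  tr <- toy_bridge_traj(c(0, 0, 0), c(5, 0, 0), waters)
  hy <- hydration_counts(tr, center = 1L, cutoff = 0.35)
  expect_equal(hy$counts, rep(3L, 2))
  expect_equal(unname(hy$summary), c(3, 3, 3))
  # permuting water order changes nothing
  tr2 <- toy_bridge_traj(c(0, 0, 0), c(5, 0, 0), waters[sample(nw), ])
  expect_equal(hydration_counts(tr2, center = 1L, cutoff = 0.35)$counts,
               hy$counts)
  expect_true(all(hy$summary[1] <= hy$summary[2],
                  hy$summary[2] <= hy$summary[3]))
})

test_that("trajectories round-trip through multi-model PDB files", {
  set.seed(36)
  waters <- matrix(runif(12, 0, 1), 4)
  tr <- toy_bridge_traj(c(0, 0, 0), c(0.6, 0, 0), waters)
  f <- withr::local_tempfile(fileext = ".pdb")
  # write each frame as a MODEL using the model writer
  at <- tr$atoms; at$occ <- 1
  m1 <- structure_model("frame", cbind(at,
        data.frame(x = tr$coords[1, , 1], y = tr$coords[1, , 2],
                   z = tr$coords[1, , 3])))
  write_model_pdb(m1, f)
  rt <- read_trajectory(f, dt = 0.1)
  expect_equal(dim(rt$coords), c(1, 6, 3))
  expect_equal(rt$coords[1, , ], tr$coords[1, , ], tolerance = 1e-4)
})
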