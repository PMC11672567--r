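test_that("analytic sphere formula and guards", {
  expect_equal(analytic_sphere_sasa(1.9, 1.4), 4 * pi * 3.3^2)
  expect_equal(analytic_sphere_sasa(1.0, 0.0), 4 * pi)
  expect_error(analytic_sphere_sasa(0, 1.4), "r_vdw")
  expect_error(analytic_sphere_sasa(1.9, -0.1), "probe")
  expect_equal(analytic_two_sphere_sasa(3.3, 1.9, 1.4),
               4 * pi * 3.3^2 - 2 * pi * 3.3 * 1.65)
  expect_error(analytic_two_sphere_sasa(7, 1.9, 1.4), "overlap")
})

test_that("isolated sphere is within 1% of closed form and converges", {
  fx <- make_toy_structure("single_atom", dir = tempfile())
  st <- read_structure(fx$files[["pdb"]], radius_table = fx$radius_table)
  truth <- fx$truth$sasa_per_atom
  errs <- vapply(c(60, 240, 960), function(np) {
    s <- compute_sasa(st, sasa_params(n_sphere_points = np))
    abs(s$per_atom - truth) / truth
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_true(errs[3] <= errs[1])  # error decreases with point count
})

test_that("two-sphere case matches the spherical-cap closed form", {
  fx <- make_toy_structure("two_sphere", dir = tempfile(), d = 3.3, r = 1.9)
  st <- read_structure(fx$files[["pdb"]], radius_table = fx$radius_table)
  s <- compute_sasa(st)
  expect_equal(s$per_atom, fx$truth$sasa_per_atom, tolerance = 0.01)
  expect_equal(fx$truth$sasa_per_atom[1], 102.6358, tolerance = 1e-4)
})

test_that("Monte Carlo oracle agrees on the analytic cases", {
  fx <- make_toy_structure("single_atom", dir = tempfile())
  st <- read_structure(fx$files[["pdb"]], radius_table = fx$radius_table)
  mc <- monte_carlo_sasa(st, n_samples_per_atom = 1e5, seed = 7)
  expect_equal(mc$per_atom, fx$truth$sasa_per_atom, tolerance = 1e-6)
  fx2 <- make_toy_structure("two_sphere", dir = tempfile())
  st2 <- read_structure(fx2$files[["pdb"]], radius_table = fx2$radius_table)
  mc2 <- monte_carlo_sasa(st2, n_samples_per_atom = 1e5, seed = 7)
  expect_true(all(abs(mc2$per_atom - fx2$truth$sasa_per_atom) <=
                    3 * mc2$se_per_atom))
  # reproducible under a fixed seed
  mc2b <- monte_carlo_sasa(st2, n_samples_per_atom = 1e5, seed = 7)
  expect_identical(mc2$per_atom, mc2b$per_atom)
})

test_that("Shrake-Rupley agrees with the Monte Carlo oracle on random packings", {
  # ~170 atoms are compared simultaneously, so the per-atom standard-error
  # band carries a Sidak family-wise correction (nominal error rate 1%);
  # the uncorrected per-atom 3 SE check would falsely fail ~1 run in 3
  zs <- numeric(0)
  for (seed in 1:20) {
    n <- 3 + (seed %% 13)
    st <- random_cluster_structure(n, seed)
    # dense quadrature so that the Monte Carlo standard error dominates
    sr <- compute_sasa(st, sasa_params(n_sphere_points = 20000))
    mc <- monte_carlo_sasa(st, n_samples_per_atom = 2000, seed = seed + 100)
    zs <- c(zs, abs(sr$per_atom - mc$per_atom) / pmax(mc$se_per_atom, 1e-9))
  }
  z_crit <- qnorm(1 - 0.005 / length(zs))
  expect_true(all(zs <= z_crit),
              label = sprintf("max |z| %.2f vs critical %.2f over %d atoms",
                              max(zs), z_crit, length(zs)))
  # and the bulk of atoms sit comfortably inside the plain 3 SE band
  expect_gte(mean(zs <= 3), 0.98)
})

test_that("grid neighbor search equals all-pairs (dense and sparse packings)", {
  # brute-force reference: per-atom burial with every other atom checked
  brute_sasa <- function(st, params = sasa_params()) {
    a <- st$atoms
    xyz <- as.matrix(a[, c("x", "y", "z")])
    rexp <- a$radius + params$probe_radius
    pts <- golden_spiral_points(params$n_sphere_points)
    vapply(seq_len(nrow(a)), function(i) {
      p <- sweep(pts * rexp[i], 2, xyz[i, ], "+")
      exposed <- rep(TRUE, nrow(p))
      for (j in seq_len(nrow(a))[-i]) {
        d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        exposed <- exposed & d2 >= rexp[j]^2
      }
      sum(exposed) / nrow(p) * 4 * pi * rexp[i]^2
    }, numeric(1))
  }
  for (seed in c(3, 11)) {
    st <- random_cluster_structure(12, seed, box = 6)
    expect_equal(compute_sasa(st)$per_atom, brute_sasa(st),
                 tolerance = 1e-12)
  }
  st_far <- random_cluster_structure(8, 5, box = 60)  # mostly isolated
  expect_equal(compute_sasa(st_far)$per_atom, brute_sasa(st_far),
               tolerance = 1e-12)
})

test_that("per-residue areas are exact sums of per-atom areas", {
  st <- random_cluster_structure(10, 2)
  s <- compute_sasa(st)
  a <- st$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  manual <- vapply(split(s$per_atom, key), sum, numeric(1))
  expect_equal(sum(s$per_residue), sum(s$per_atom))
  expect_equal(s$per_residue[names(manual)], manual)
})

test_that("rigid transformation leaves per-atom areas unchanged within jitter", {
  st <- random_cluster_structure(9, 4)
  params <- sasa_params(n_sphere_points = 20000)
  s0 <- compute_sasa(st, params)$per_atom
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
  st2 <- st
  st2$atoms$x <- xyz[, 1] + 5
  st2$atoms$y <- xyz[, 2] - 3
  st2$atoms$z <- xyz[, 3] + 1
  s1 <- compute_sasa(st2, params)$per_atom
  expect_true(all(abs(s1 - s0) <= 0.1))
})

test_that("adding an atom never increases any existing atom's area", {
  st <- random_cluster_structure(8, 6, box = 6)
  s0 <- compute_sasa(st)$per_atom
  st2 <- st
  new <- st$atoms[1, ]
  new$serial <- max(st$atoms$serial) + 1L
  new$resno <- max(st$atoms$resno) + 1L
  new$x <- mean(st$atoms$x); new$y <- mean(st$atoms$y)
  new$z <- mean(st$atoms$z) + 1
  st2$atoms <- rbind(st$atoms, new)
  s1 <- compute_sasa(st2)$per_atom[seq_along(s0)]
  expect_true(all(s1 <= s0 + 1e-9))
})

test_that("a caged atom has zero area and the cage truly encloses it", {
  fx <- make_toy_structure("cage", dir = tempfile())
  st <- read_structure(fx$files[["pdb"]], radius_table = fx$radius_table)
  # numeric coverage check, independent of the engine: every direction on
  # the central expanded sphere lies inside some cage expanded sphere
  pts <- golden_spiral_points(2000) * (1.5 + 1.4)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  covered <- rep(FALSE, nrow(pts))
  for (j in 2:nrow(xyz)) {
    d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
      (pts[, 3] - xyz[j, 3])^2
    covered <- covered | d2 < (3.0 + 1.4)^2
  }
  expect_true(all(covered))
  expect_equal(compute_sasa(st)$per_atom[1], 0)
  mc <- monte_carlo_sasa(st, n_samples_per_atom = 5000, seed = 1)
  expect_lt(mc$per_atom[1], 3 * max(mc$se_per_atom[1], 1e-9) + 1e-9)
})

test_that("degenerate inputs are rejected", {
  fx <- make_toy_structure("single_atom", dir = tempfile())
  st <- read_structure(fx$files[["pdb"]], radius_table = fx$radius_table)
  st$atoms <- st$atoms[0, ]
  expect_error(compute_sasa(st), "empty")
  expect_error(sasa_params(probe_radius = -1), "probe")
  expect_error(sasa_params(n_sphere_points = 4), "sphere_points")
  expect_error(monte_carlo_sasa(read_structure(fx$files[["pdb"]]),
                                n_samples_per_atom = 10), ">= 100")
})
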