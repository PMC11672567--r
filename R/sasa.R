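# Shrake-Rupley solvent-accessible surface area.
#
# Each atom is expanded by the probe radius; a deterministic golden-spiral
# point set is placed on the expanded sphere and points falling inside any
# neighboring expanded sphere are buried. The accessible area is the exposed
# point fraction times the expanded sphere area.

#' Golden-spiral unit sphere points
#'
#' Deterministic quasi-uniform point set on the unit sphere (Fibonacci
#' lattice). Used as the Shrake-Rupley quadrature.
#'
#' @param n Number of points (>= 12).
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  if (n < 12) stop("n_sphere_points must be >= 12")
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' SASA parameters
#'
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points Quadrature points per atom (default 960).
#' @param point_set `"golden-spiral"` (deterministic, default) or
#'   `"fixed-seed-random"`.
#' @param seed Seed for the random point set.
#' @return List of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        point_set = c("golden-spiral", "fixed-seed-random"),
                        seed = 1L) {
  point_set <- match.arg(point_set)
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_sphere_points < 12) stop("n_sphere_points must be >= 12")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 point_set = point_set, seed = as.integer(seed)),
            class = "sasa_params")
}

# grid-based neighbor candidate lists; cell size 2*(r_max + probe) so that
# any two atoms with intersecting expanded spheres sit in adjacent cells
.neighbor_lists <- function(xyz, rexp) {
  n <- nrow(xyz)
  cell <- 2 * max(rexp)
  ix <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  cid <- paste(ix[, 1], ix[, 2], ix[, 3])
  cells <- split(seq_len(n), cid)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(n), function(i) {
    nb_ids <- paste(ix[i, 1] + offs[, 1], ix[i, 2] + offs[, 2],
                    ix[i, 3] + offs[, 3])
    cand <- unlist(cells[nb_ids], use.names = FALSE)
    cand[cand != i]
  })
}

#' Compute solvent-accessible surface area (Shrake-Rupley)
#'
#' @param structure An `ab_structure` with radii assigned.
#' @param params A [sasa_params()] object.
#' @return Object of class `sasa_result`: list with `per_atom` (numeric,
#'   one value per atom row, Angstrom squared), `per_residue` (named by
#'   residue key), `residues` (residue table with an `sasa` column) and
#'   `params`.
#' @export
compute_sasa <- function(structure, params = sasa_params()) {
  a <- structure$atoms
  if (is.null(a) || nrow(a) == 0L) stop("empty structure")
  if (any(!is.finite(a$radius)) || any(a$radius <= 0))
    stop("all atoms need positive radii before SASA")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rexp <- a$radius + params$probe_radius
  n <- nrow(xyz)
  np <- params$n_sphere_points
  pts <- if (params$point_set == "golden-spiral") {
    golden_spiral_points(np)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(params$seed)
    .runif_sphere(np)
  }
  nb <- .neighbor_lists(xyz, rexp)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    cand <- nb[[i]]
    if (length(cand)) {
      d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
      cand <- cand[d < rexp[i] + rexp[cand]]
    }
    if (!length(cand)) {
      per_atom[i] <- 4 * pi * rexp[i]^2
      next
    }
    p <- pts * rexp[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, np)
    for (j in cand) {
      if (!any(exposed)) break
      dj <- (p[exposed, 1] - xyz[j, 1])^2 + (p[exposed, 2] - xyz[j, 2])^2 +
        (p[exposed, 3] - xyz[j, 3])^2
      exposed[exposed] <- dj >= rexp[j]^2
    }
    per_atom[i] <- sum(exposed) / np * 4 * pi * rexp[i]^2
  }
  key <- res_key(a$chain, a$resno, a$icode)
  per_residue <- vapply(split(per_atom, key), sum, numeric(1))
  rt <- residue_table(structure)
  rt$sasa <- unname(per_residue[rt$key])
  per_residue <- per_residue[rt$key]   # file order
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 residues = rt, params = params),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, %d residues, total %.1f A^2 (probe %.2f, %d pts)\n",
              length(x$per_atom), length(x$per_residue), sum(x$per_atom),
              x$params$probe_radius, x$params$n_sphere_points))
  invisible(x)
}

#' Closed-form SASA of an isolated sphere
#'
#' @param r_vdw Van der Waals radius (Angstrom), > 0.
#' @param probe Probe radius (Angstrom), >= 0.
#' @return `4 * pi * (r_vdw + probe)^2` in Angstrom squared.
#' @export
analytic_sphere_sasa <- function(r_vdw, probe = 1.4) {
  if (any(r_vdw <= 0)) stop("r_vdw must be > 0")
  if (any(probe < 0)) stop("probe must be >= 0")
  4 * pi * (r_vdw + probe)^2
}

#' Closed-form per-atom SASA of two equal intersecting spheres
#'
#' Two atoms of radius `r_vdw` with centers `d` apart; each expanded sphere
#' loses a spherical cap of height `h = R - d/2` to the other
#' (`R = r_vdw + probe`).
#'
#' @inheritParams analytic_sphere_sasa
#' @param d Center distance, Angstrom; must satisfy `0 < d < 2R` for
#'   partial overlap.
#' @return Accessible area of each atom: `4*pi*R^2 - 2*pi*R*h`.
#' @export
analytic_two_sphere_sasa <- function(d, r_vdw, probe = 1.4) {
  R <- r_vdw + probe
  if (d <= 0 || d >= 2 * R) stop("need 0 < d < 2*(r_vdw+probe) for overlap")
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

# uniform points on the unit sphere
.runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Monte Carlo SASA oracle
#'
#' Brute-force unbiased estimator: uniform random points on each expanded
#' sphere, counting points outside every other expanded sphere. Independent
#' of the Shrake-Rupley code path; used to validate it.
#'
#' @param structure An `ab_structure`.
#' @param probe Probe radius (Angstrom).
#' @param n_samples_per_atom Samples per atom (>= 100).
#' @param seed RNG seed.
#' @return List with `per_atom` (estimate, Angstrom squared), `se_per_atom`
#'   (binomial standard errors), `per_residue`.
#' @export
monte_carlo_sasa <- function(structure, probe = 1.4,
                             n_samples_per_atom = 1000L, seed = 1L) {
  if (n_samples_per_atom < 100) stop("n_samples_per_atom must be >= 100")
  a <- structure$atoms
  if (is.null(a) || nrow(a) == 0L) stop("empty structure")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rexp <- a$radius + probe
  n <- nrow(xyz)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  per_atom <- se <- numeric(n)
  for (i in seq_len(n)) {
    p <- .runif_sphere(n_samples_per_atom) * rexp[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    outside <- rep(TRUE, n_samples_per_atom)
    for (j in seq_len(n)[-i]) {
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      outside <- outside & dj >= rexp[j]^2
    }
    phat <- mean(outside)
    area <- 4 * pi * rexp[i]^2
    per_atom[i] <- phat * area
    se[i] <- sqrt(phat * (1 - phat) / n_samples_per_atom) * area
  }
  key <- res_key(a$chain, a$resno, a$icode)
  list(per_atom = per_atom, se_per_atom = se,
       per_residue = vapply(split(per_atom, key), sum, numeric(1)))
}
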