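# Synthetic fixtures with analytic ground truth: toy structures for the
# SASA engine, liability-planted sequences, and assay data (AC-SINS
# spectra, 4PL binding curves, SEC standards, B-factor sets). Every
# generator is seed-deterministic and emits a truth list describing
# exactly what was written.

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

# fixed-width PDB ATOM record with the element column populated, so the
# reader never has to fall back to name inference for fixtures
.pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                           occ = 1, b = 0, element = "C") {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resid, chain, resno, x, y, z, occ, b, element)
}

.write_toy_pdb <- function(path, xyz, elements, chain = "A",
                           resid = "UNK", b = NULL) {
  n <- nrow(xyz)
  if (is.null(b)) b <- rep(0, n)
  chain <- rep_len(chain, n)
  lines <- vapply(seq_len(n), function(i) {
    .pdb_atom_line(i, elements[i], resid, chain[i], i,
                   xyz[i, 1], xyz[i, 2], xyz[i, 3], b = b[i],
                   element = elements[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a toy structure with known SASA
#'
#' Geometries:
#' * `single_atom`: one atom; truth SASA is the closed-form sphere area.
#' * `two_sphere`: two equal atoms `d` apart; truth per-atom SASA from the
#'   spherical-cap formula.
#' * `cage`: one small central atom enclosed by 12 large atoms on
#'   icosahedron vertices whose expanded spheres cover it completely;
#'   truth SASA of the central atom is 0.
#' * `random_cluster`: `n` atoms uniform in a box (no analytic truth).
#'
#' All toy atoms are written as carbon; pass the returned `radius_table`
#' to [read_structure()] so the intended radii are used.
#'
#' @param kind One of `"single_atom"`, `"two_sphere"`, `"cage"`,
#'   `"random_cluster"`.
#' @param dir Output directory (created if needed).
#' @param r Van der Waals radius of the (non-cage) atoms, Angstrom.
#' @param d Center distance for `two_sphere`; needs
#'   `0 < d < 2*(r + probe)`.
#' @param n Atom count for `random_cluster`.
#' @param box Edge of the sampling box for `random_cluster`, Angstrom.
#' @param probe Probe radius the truth values assume.
#' @param seed RNG seed (used by `random_cluster`).
#' @return List of class `fixture_bundle`: `files` (named paths), `truth`
#'   (list, also written as JSON next to the PDB), `radius_table`.
#' @export
make_toy_structure <- function(kind = c("single_atom", "two_sphere",
                                        "cage", "random_cluster"),
                               dir = tempfile("fixture"),
                               r = 1.9, d = 3.3, n = 10, box = 8,
                               probe = 1.4, seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(kind, ".pdb"))
  truth <- list(kind = kind, probe = probe, seed = seed)
  if (kind == "single_atom") {
    xyz <- matrix(0, 1, 3)
    radius_table <- c(C = r)
    truth$radii <- r
    truth$sasa_per_atom <- analytic_sphere_sasa(r, probe)
  } else if (kind == "two_sphere") {
    if (!(d > 0 && d < 2 * (r + probe)))
      stop("two_sphere needs 0 < d < 2*(r+probe)")
    xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
    radius_table <- c(C = r)
    truth$radii <- c(r, r); truth$d <- d
    truth$sasa_per_atom <- rep(analytic_two_sphere_sasa(d, r, probe), 2)
    truth$cap_area <- analytic_sphere_sasa(r, probe) -
      analytic_two_sphere_sasa(d, r, probe)
  } else if (kind == "cage") {
    # central C atom r_c = 1.5 at origin; 12 S cage atoms r_big = 3.0 at
    # distance 2.0 on icosahedron vertices; expanded cage spheres cover
    # the central expanded sphere completely (verified numerically in the
    # test suite), so truth SASA of atom 1 is 0
    phi <- (1 + sqrt(5)) / 2
    v <- rbind(
      c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
      c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
      c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
    v <- v / sqrt(rowSums(v^2)) * 2.0
    xyz <- rbind(c(0, 0, 0), v)
    radius_table <- c(C = 1.5, S = 3.0)
    truth$radii <- c(1.5, rep(3.0, 12))
    truth$sasa_central_atom <- 0
  } else {
    xyz <- .with_seed(seed, matrix(runif(3 * n, 0, box), ncol = 3))
    radius_table <- c(C = r)
    truth$radii <- rep(r, n)
    truth$box <- box
  }
  elements <- if (kind == "cage") c("C", rep("S", 12)) else
    rep("C", nrow(xyz))
  chains <- if (kind == "two_sphere") c("A", "B") else "A"
  .write_toy_pdb(pdb, xyz, elements, chain = chains)
  truth$xyz <- xyz
  truth_path <- file.path(dir, paste0(kind, "_truth.json"))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  structure(list(files = c(pdb = pdb, truth = truth_path), truth = truth,
                 radius_table = radius_table),
            class = "fixture_bundle")
}

# background alphabet that cannot form any default motif (no N, D, S, T,
# E or L, so neither the deamidation/isomerization/proteolysis literals
# nor the glycosylation sequon can arise outside planted sites)
.liability_background <- c("A", "G", "V", "F", "H", "R", "K", "P")

.planted_motif_text <- function(kind) {
  switch(kind,
         deamidation = "SNG", glycosylation = "NAT", proteolysis = "DP",
         isomerization = "DS",
         stop("unknown liability kind: ", kind))
}

#' Generate a sequence with planted liability motifs
#'
#' Background residues are drawn from a motif-avoiding alphabet
#' (A/G/V/F/H/R/K/P) so that the only motif hits are the planted ones
#' (plus any overlap the caller plants deliberately).
#'
#' @param length Sequence length.
#' @param planted Data frame with columns `kind` (deamidation,
#'   glycosylation, proteolysis, isomerization) and `position` (1-based
#'   start), or NULL for background only.
#' @param dir Output directory.
#' @param seed RNG seed.
#' @return `fixture_bundle` with a FASTA file and truth listing the
#'   planted hits (kind, position, matched_text).
#' @export
make_liability_sequence <- function(length = 60, planted = NULL,
                                    dir = tempfile("fixture"), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chars <- .with_seed(seed,
                      sample(.liability_background, length, replace = TRUE))
  truth_hits <- data.frame(kind = character(), position = integer(),
                           matched_text = character(),
                           stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted)) {
    occupied <- rep(FALSE, length)
    for (i in seq_len(nrow(planted))) {
      txt <- .planted_motif_text(planted$kind[i])
      pos <- planted$position[i]
      span <- pos:(pos + nchar(txt) - 1L)
      if (pos < 1 || max(span) > length)
        stop("planted motif out of bounds at position ", pos)
      if (any(occupied[span]))
        stop("conflicting planted motifs at position ", pos)
      occupied[span] <- TRUE
      chars[span] <- strsplit(txt, "")[[1]]
      truth_hits <- rbind(truth_hits, data.frame(
        kind = planted$kind[i], position = pos, matched_text = txt,
        stringsAsFactors = FALSE))
    }
  }
  seqstr <- paste(chars, collapse = "")
  fa <- file.path(dir, "sequence.fasta")
  writeLines(c(">synthetic_liability_sequence", seqstr), fa)
  truth <- list(kind = "liability_sequence", seed = seed,
                sequence = seqstr,
                planted = truth_hits[order(truth_hits$position), ,
                                     drop = FALSE])
  truth_path <- file.path(dir, "sequence_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  structure(list(files = c(fasta = fa, truth = truth_path), truth = truth),
            class = "fixture_bundle")
}

#' Generate synthetic assay data with known parameters
#'
#' * `acsins`: absorbance spectrum on the 480-580 nm grid (2 nm step) from
#'   a concave quadratic with vertex `lambda_max`, plus additive Gaussian
#'   noise.
#' * `binding`: 4PL curve at log-spaced concentrations with multiplicative
#'   log-normal noise of coefficient of variation `noise`.
#' * `sec`: calibration standards on a known log-linear MW/retention line.
#' * `bfactor`: `n` Gaussian B-factors with mean `mu` and SD `sigma`.
#'
#' @param kind One of `"acsins"`, `"binding"`, `"sec"`, `"bfactor"`.
#' @param dir Output directory.
#' @param lambda_max,a,peak AC-SINS truth: vertex (nm), curvature (< 0),
#'   peak absorbance (AU).
#' @param noise Noise level: additive SD in AU (`acsins`), relative CV
#'   (`binding`).
#' @param bottom,top,ec50,hill,n_conc,conc_range 4PL truth and design.
#' @param mw_kda,slope,intercept SEC truth: standard MWs and the
#'   log10(MW)-vs-retention line generating their retention volumes.
#' @param n,mu,sigma B-factor set design.
#' @param seed RNG seed.
#' @return `fixture_bundle` with a CSV file and a truth list.
#' @export
make_assay_fixtures <- function(kind = c("acsins", "binding", "sec",
                                         "bfactor"),
                                dir = tempfile("fixture"),
                                lambda_max = 530, a = -0.001, peak = 0.5,
                                noise = 0,
                                bottom = 0.05, top = 2.0, ec50 = 200,
                                hill = 1.0, n_conc = 12,
                                conc_range = c(1, 1e5),
                                mw_kda = c(670, 158, 44, 17, 1.35),
                                slope = -0.29565, intercept = 5.19,
                                n = 50, mu = 30, sigma = 10,
                                seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(kind, ".csv"))
  truth <- list(kind = kind, seed = seed)
  if (kind == "acsins") {
    if (a >= 0) stop("spectrum curvature a must be < 0")
    wl <- seq(480, 580, by = 2)
    y0 <- a * (wl - lambda_max)^2 + peak
    y <- .with_seed(seed, y0 + rnorm(length(wl), 0, noise))
    write.csv(data.frame(wavelength_nm = wl, absorbance = y), csv,
              row.names = FALSE)
    truth <- c(truth, list(lambda_max = lambda_max, a = a, peak = peak,
                           noise_sd = noise))
  } else if (kind == "binding") {
    if (ec50 <= 0) stop("ec50 must be > 0")
    conc <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
                   length.out = n_conc)
    y0 <- bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
    y <- .with_seed(seed, y0 * exp(rnorm(n_conc, 0, log(1 + noise))))
    write.csv(data.frame(concentration_pM = conc, response = y), csv,
              row.names = FALSE)
    truth <- c(truth, list(bottom = bottom, top = top, ec50 = ec50,
                           hill = hill, noise_cv = noise))
  } else if (kind == "sec") {
    retention <- (log10(mw_kda) - intercept) / slope
    write.csv(data.frame(mw_kda = mw_kda, retention_ml = retention), csv,
              row.names = FALSE)
    truth <- c(truth, list(mw_kda = mw_kda, retention_ml = retention,
                           slope = slope, intercept = intercept))
  } else {
    b <- .with_seed(seed, rnorm(n, mu, sigma))
    write.csv(data.frame(b_factor = b), csv, row.names = FALSE)
    truth <- c(truth, list(n = n, mu = mu, sigma = sigma))
  }
  truth_path <- file.path(dir, paste0(kind, "_truth.json"))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  structure(list(files = c(csv = csv, truth = truth_path), truth = truth),
            class = "fixture_bundle")
}
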