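# Rigid-body superposition (Kabsch) and normalized B-factors.

#' Optimal rigid superposition of paired coordinates (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `coords_b`
#' onto `coords_a`, with the resulting RMSD. Reflections are prevented by
#' the determinant correction of the SVD solution.
#'
#' @param coords_a,coords_b N x 3 matrices (Angstrom) of paired atoms,
#'   N >= 3, not all collinear.
#' @return List of class `superposition`: `rmsd` (Angstrom), `rotation`
#'   (3 x 3, det +1), `translation` (length-3), `n_atoms_paired`.
#'   `rotation %*% t(coords_b) + translation` approximates `t(coords_a)`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b))
    stop("coordinate sets must pair atom-for-atom")
  n <- nrow(coords_a)
  if (n < 3) stop("need at least 3 paired atoms")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  structure(list(rmsd = rmsd, rotation = R,
                 translation = as.numeric(ca - R %*% cb),
                 n_atoms_paired = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms paired, RMSD %.4f A\n",
              x$n_atoms_paired, x$rmsd))
  invisible(x)
}

#' Pair atoms of two structures for superposition
#'
#' Pairs residues by shared scheme label (both structures must be
#' numbered), or by residue key when `by = "key"`, then selects atoms
#' according to the pairing policy. Residues with insertion codes pair only
#' through their labels/keys, which carry the insertion code.
#'
#' @param structure_a,structure_b `ab_structure` objects.
#' @param policy `"CA-only"` (default), `"backbone"` (N, CA, C, O) or
#'   `"all-atom"` (atoms matched by name within paired residues).
#' @param by `"scheme_label"` (default) or `"key"`.
#' @return List with `coords_a`, `coords_b` (N x 3), `labels` (per pair)
#'   and `unpaired_a`, `unpaired_b`.
#' @export
pair_atoms <- function(structure_a, structure_b,
                       policy = c("CA-only", "backbone", "all-atom"),
                       by = c("scheme_label", "key")) {
  policy <- match.arg(policy); by <- match.arg(by)
  sel <- switch(policy, "CA-only" = "CA",
                backbone = c("N", "CA", "C", "O"), "all-atom" = NULL)
  tag <- function(s) {
    a <- s$atoms
    lab <- if (by == "scheme_label") a$scheme_label
           else res_key(a$chain, a$resno, a$icode)
    if (by == "scheme_label" && (is.null(lab) || all(is.na(lab))))
      stop("structures must be numbered to pair by scheme label")
    keep <- !is.na(lab)
    if (!is.null(sel)) keep <- keep & a$name %in% sel
    data.frame(lab = lab[keep], name = a$name[keep], x = a$x[keep],
               y = a$y[keep], z = a$z[keep], stringsAsFactors = FALSE)
  }
  ta <- tag(structure_a); tb <- tag(structure_b)
  ta$id <- paste(ta$lab, ta$name); tb$id <- paste(tb$lab, tb$name)
  ta <- ta[!duplicated(ta$id), , drop = FALSE]
  tb <- tb[!duplicated(tb$id), , drop = FALSE]
  shared <- intersect(ta$id, tb$id)
  if (!length(shared)) stop("no atoms could be paired")
  ia <- match(shared, ta$id); ib <- match(shared, tb$id)
  list(coords_a = as.matrix(ta[ia, c("x", "y", "z")]),
       coords_b = as.matrix(tb[ib, c("x", "y", "z")]),
       labels = ta$lab[ia],
       unpaired_a = setdiff(unique(ta$lab), ta$lab[ia]),
       unpaired_b = setdiff(unique(tb$lab), tb$lab[ib]))
}

#' Superpose two structures
#'
#' Convenience wrapper: [pair_atoms()] then [kabsch_superpose()].
#'
#' @inheritParams pair_atoms
#' @return A `superposition` (see [kabsch_superpose()]) with an extra
#'   `pairing` element.
#' @export
superpose_structures <- function(structure_a, structure_b,
                                 policy = "CA-only", by = "scheme_label") {
  pr <- pair_atoms(structure_a, structure_b, policy = policy, by = by)
  out <- kabsch_superpose(pr$coords_a, pr$coords_b)
  out$pairing <- pr
  out
}

#' Normalize B-factors to z-scores
#'
#' `z_i = (b_i - mu) / sigma` with, by default, the population convention
#' for sigma (divide by n), so the output has exactly zero mean and unit
#' variance.
#'
#' @param values Numeric vector of B-factors (Angstrom squared), length
#'   >= 2, non-constant.
#' @param convention `"population"` (default) or `"sample"` (n - 1).
#' @return List of class `normalized_bfactors`: `z`, `mu`, `sigma`.
#' @export
normalize_bfactors <- function(values,
                               convention = c("population", "sample")) {
  convention <- match.arg(convention)
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 B-factors")
  mu <- mean(values)
  sigma <- if (convention == "population") {
    sqrt(mean((values - mu)^2))
  } else {
    sd(values)
  }
  if (sigma == 0) stop("constant B-factors: sigma = 0")
  structure(list(z = (values - mu) / sigma, mu = mu, sigma = sigma,
                 convention = convention),
            class = "normalized_bfactors")
}
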