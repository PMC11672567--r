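# Inter-group (e.g. Fab-Fab) contact detection and interface burial.

.subset_chains <- function(structure, chains) {
  a <- structure$atoms[structure$atoms$chain %in% chains, , drop = FALSE]
  .new_structure(paste0(structure$id, ":", paste(chains, collapse = "")),
                 a, structure$source_format)
}

#' Find inter-group residue contacts
#'
#' Exhaustive heavy-atom contact search between two disjoint chain groups.
#' A residue pair is a contact when any atom pair lies within `cutoff`.
#'
#' @param structure An `ab_structure`.
#' @param group_a,group_b Disjoint, nonempty character vectors of chain ids.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return Data frame ordered by (chain, resno): `key_a`, `key_b`,
#'   `min_atom_distance`, `n_atom_pairs_within_cutoff`.
#' @export
find_intergroup_contacts <- function(structure, group_a, group_b,
                                     cutoff = 4.5) {
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  a <- structure$atoms
  ia <- which(a$chain %in% group_a)
  ib <- which(a$chain %in% group_b)
  if (!length(ia) || !length(ib)) stop("both groups must be nonempty")
  xa <- as.matrix(a[ia, c("x", "y", "z")])
  xb <- as.matrix(a[ib, c("x", "y", "z")])
  ka <- res_key(a$chain[ia], a$resno[ia], a$icode[ia])
  kb <- res_key(a$chain[ib], a$resno[ib], a$icode[ib])
  # all-pairs distances, blocked over group A atoms to bound memory
  recs <- list()
  block <- 2000L
  for (s in seq(1L, length(ia), by = block)) {
    e <- min(s + block - 1L, length(ia))
    d2 <- outer(rowSums(xa[s:e, , drop = FALSE]^2), rowSums(xb^2), "+") -
      2 * (xa[s:e, , drop = FALSE] %*% t(xb))
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      recs[[length(recs) + 1L]] <- data.frame(
        key_a = ka[s:e][hit[, 1]], key_b = kb[hit[, 2]],
        d = sqrt(pmax(0, d2[hit])), stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    return(data.frame(key_a = character(), key_b = character(),
                      min_atom_distance = numeric(),
                      n_atom_pairs_within_cutoff = integer(),
                      stringsAsFactors = FALSE))
  }
  pairs <- do.call(rbind, recs)
  grp <- paste(pairs$key_a, pairs$key_b, sep = " & ")
  out <- do.call(rbind, lapply(split(pairs, grp), function(p) {
    data.frame(key_a = p$key_a[1], key_b = p$key_b[1],
               min_atom_distance = min(p$d),
               n_atom_pairs_within_cutoff = nrow(p),
               stringsAsFactors = FALSE)
  }))
  kp <- function(k, i) vapply(strsplit(k, "|", fixed = TRUE), `[`,
                              character(1), i)
  ord <- order(kp(out$key_a, 1), as.integer(kp(out$key_a, 2)),
               kp(out$key_b, 1), as.integer(kp(out$key_b, 2)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue buried SASA across an interface
#'
#' For each residue, buried area = SASA computed on its own group alone
#' minus SASA in the full complex. Small negative values (quadrature
#' jitter) are clamped to zero.
#'
#' @param structure An `ab_structure`.
#' @param group_a,group_b Disjoint chain groups.
#' @param params [sasa_params()].
#' @return Data frame: `key`, `chain`, `resno`, `aa`, `group` ("A"/"B"),
#'   `sasa_isolated`, `sasa_complex`, `buried`.
#' @export
buried_sasa <- function(structure, group_a, group_b,
                        params = sasa_params()) {
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  sub <- .subset_chains(structure,  c(group_a, group_b))
  full <- compute_sasa(sub, params)
  iso_a <- compute_sasa(.subset_chains(structure, group_a), params)
  iso_b <- compute_sasa(.subset_chains(structure, group_b), params)
  iso <- rbind(cbind(iso_a$residues, group = "A"),
               cbind(iso_b$residues, group = "B"))
  m <- match(iso$key, full$residues$key)
  out <- data.frame(key = iso$key, chain = iso$chain, resno = iso$resno,
                    aa = iso$aa, group = iso$group,
                    sasa_isolated = iso$sasa,
                    sasa_complex = full$residues$sasa[m],
                    stringsAsFactors = FALSE)
  out$buried <- pmax(0, out$sasa_isolated - out$sasa_complex)
  out
}

#' Summarize the hydrophobic character of an interface
#'
#' @param contacts Output of [find_intergroup_contacts()].
#' @param profile A `hydro_profile` covering the contact residues.
#' @param h_cutoff Hydrophobicity-index cutoff above which a residue counts
#'   as hydrophobic. The default 0.7 admits F, W, Y, L, I, V and M under
#'   the Black-Mould scale.
#' @param burial Optional [buried_sasa()] table; adds a `rank_score`
#'   (buried area times h) ranking of interface residues.
#' @return List of class `interface_summary`: `contact_residues` (data
#'   frame: key, aa, h, hydrophobic), `hydrophobic_fraction` (NULL when no
#'   contacts), and `top_residues` when `burial` is given.
#' @export
summarize_interface <- function(contacts, profile, h_cutoff = 0.7,
                                burial = NULL) {
  keys <- unique(c(contacts$key_a, contacts$key_b))
  if (!length(keys)) {
    return(structure(list(contact_residues = data.frame(),
                          hydrophobic_fraction = NULL,
                          h_cutoff = h_cutoff),
                     class = "interface_summary"))
  }
  rt <- profile$residues
  m <- match(keys, rt$key)
  if (any(is.na(m))) stop("profile does not cover contact residues: ",
                          paste(keys[is.na(m)], collapse = ", "))
  cr <- data.frame(key = keys, aa = rt$aa[m], h = rt$h[m],
                   score = rt$score[m],
                   hydrophobic = rt$h[m] >= h_cutoff,
                   stringsAsFactors = FALSE)
  top <- NULL
  if (!is.null(burial)) {
    bm <- match(cr$key, burial$key)
    cr$buried <- burial$buried[bm]
    cr$rank_score <- cr$buried * cr$h
    top <- cr[order(-cr$rank_score), , drop = FALSE]
  }
  structure(list(contact_residues = cr,
                 hydrophobic_fraction = mean(cr$hydrophobic),
                 h_cutoff = h_cutoff, top_residues = top),
            class = "interface_summary")
}

#' @export
print.interface_summary <- function(x, ...) {
  if (is.null(x$hydrophobic_fraction)) {
    cat("<interface_summary> no contacts\n")
  } else {
    cat(sprintf("<interface_summary> %d contact residues, hydrophobic fraction %.2f (h >= %.2f)\n",
                nrow(x$contact_residues), x$hydrophobic_fraction, x$h_cutoff))
  }
  invisible(x)
}
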