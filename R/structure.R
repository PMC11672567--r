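#' @importFrom stats coef lm median sd optim runif rnorm residuals approx aggregate
#' @importFrom utils read.csv write.csv head modifyList packageVersion
NULL

# ---- internal representation ---------------------------------------------
# An `ab_structure` is a list:
#   id            character
#   atoms         data.frame: chain, resno (int), icode (chr, "" if none),
#                 resid (3-letter), aa (1-letter or "X"), serial, name,
#                 element, x, y, z, occupancy, altloc, b, radius
#   source_format "PDB" or "mmCIF"
# Residues are identified by the key "chain|resno|icode".

res_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste(chain, resno, icode, sep = "|")
}

.new_structure <- function(id, atoms, source_format) {
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source_format = source_format),
            class = "ab_structure")
}

#' @export
print.ab_structure <- function(x, ...) {
  rk <- res_key(x$atoms$chain, x$atoms$resno, x$atoms$icode)
  cat(sprintf("<ab_structure> %s [%s]: %d chains, %d residues, %d atoms\n",
              x$id, x$source_format, length(unique(x$atoms$chain)),
              length(unique(rk)), nrow(x$atoms)))
  invisible(x)
}

#' @export
as.data.frame.ab_structure <- function(x, ...) x$atoms

.water_names <- c("HOH", "WAT")

.assign_radii <- function(atoms, radius_table, default_radius) {
  el <- toupper(trimws(atoms$element))
  # name-based inference when element column is blank: first letter of the
  # atom name that is not a digit (PDB v2 style names)
  blank <- is.na(el) | el == ""
  if (any(blank)) {
    nm <- gsub("[0-9']", "", toupper(atoms$name[blank]))
    el[blank] <- substr(nm, 1, 1)
  }
  r <- unname(radius_table[el])
  r[is.na(r)] <- default_radius
  atoms$element <- el
  atoms$radius <- r
  atoms
}

.apply_altloc <- function(atoms, policy = c("highest_occupancy", "first", "all")) {
  policy <- match.arg(policy)
  if (policy == "all") return(atoms)
  alt <- ifelse(is.na(atoms$altloc), "", atoms$altloc)
  if (all(alt == "")) return(atoms)
  key <- paste(res_key(atoms$chain, atoms$resno, atoms$icode), atoms$name)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ix) {
    if (length(ix) == 1L) return(ix)
    if (policy == "first") return(ix[1L])
    occ <- atoms$occupancy[ix]
    best <- ix[occ == max(occ)]
    if (length(best) > 1L) {   # tie -> lowest altloc letter ('A' first)
      best <- best[order(alt[best])][1L]
    }
    best[1L]
  }))
  atoms[sort(keep), , drop = FALSE]
}

#' Read an antibody structure from PDB or mmCIF
#'
#' Parses atomic coordinates, applies the standard filters and assigns van
#' der Waals radii. PDB files are read with bio3d; mmCIF files with a
#' minimal `atom_site` loop reader.
#'
#' @param path Path to the structure file.
#' @param format `"PDB"` or `"mmCIF"`; default guessed from the extension.
#' @param drop_waters Drop residues named HOH/WAT (default TRUE).
#' @param drop_hetero Drop HETATM records other than waters (default TRUE).
#'   Waters are controlled by `drop_waters` alone.
#' @param drop_hydrogens Drop H/D atoms (default TRUE).
#' @param altloc_policy One of `"highest_occupancy"` (default; ties keep the
#'   alphabetically first altloc), `"first"`, `"all"`.
#' @param radius_table Named element-to-radius vector, default [vdw_radii()].
#' @param default_radius Radius for unresolvable elements (Angstrom).
#' @return An `ab_structure` object.
#' @export
read_structure <- function(path,
                           format = c("auto", "PDB", "mmCIF"),
                           drop_waters = TRUE,
                           drop_hetero = TRUE,
                           drop_hydrogens = TRUE,
                           altloc_policy = "highest_occupancy",
                           radius_table = vdw_radii(),
                           default_radius = .default_vdw_radius) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmCIF" else "PDB"
  }
  atoms <- if (format == "PDB") .read_pdb_atoms(path) else .read_cif_atoms(path)
  if (nrow(atoms) == 0L) stop("no atoms parsed from ", path)

  is_water <- atoms$resid %in% .water_names
  if (drop_waters) atoms <- atoms[!is_water, , drop = FALSE]
  if (drop_hetero) {
    atoms <- atoms[atoms$record != "HETATM" |
                     atoms$resid %in% names(modified_residue_aliases()), ,
                   drop = FALSE]
  }
  atoms <- .apply_altloc(atoms, altloc_policy)
  if (drop_hydrogens) {
    el <- toupper(trimws(atoms$element))
    guess <- ifelse(is.na(el) | el == "",
                    substr(gsub("[0-9']", "", toupper(atoms$name)), 1, 1), el)
    atoms <- atoms[!(guess %in% c("H", "D")), , drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("structure is empty after filtering: ", path)

  atoms <- .assign_radii(atoms, radius_table, default_radius)
  atoms$aa <- unname(.aa3to1[atoms$resid])
  atoms$aa[is.na(atoms$aa)] <- "X"
  atoms$record <- NULL
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in ", path)
  }
  .new_structure(tools::file_path_sans_ext(basename(path)), atoms, format)
}

.read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) {
                    stop("PDB parse error in ", path, ": ", conditionMessage(e))
                  })
  a <- pdb$atom
  data.frame(
    record = a$type, serial = a$eleno, name = a$elety,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resid = a$resid, chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    element = ifelse(is.na(a$elesy), "", a$elesy),
    stringsAsFactors = FALSE
  )
}

# minimal mmCIF atom_site reader: handles one loop_ with _atom_site.* tags
.read_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_ix <- grep("^_atom_site\\.", lines)
  if (length(tag_ix) == 0L) stop("no _atom_site loop in ", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_ix]))
  body_start <- max(tag_ix) + 1L
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(#|loop_|_)", ln)) break
    body <- c(body, ln)
  }
  fields <- strsplit(body, "[[:space:]]+")
  bad <- which(lengths(fields) != length(tags))
  if (length(bad)) stop("mmCIF parse error in ", path, ": atom_site row ",
                        bad[1], " has ", lengths(fields)[bad[1]],
                        " fields, expected ", length(tags))
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  g <- function(tag, alt = NULL, default = NA_character_) {
    if (tag %in% tags) return(m[, tag])
    if (!is.null(alt) && alt %in% tags) return(m[, alt])
    rep(default, nrow(m))
  }
  dot <- function(v) ifelse(v %in% c(".", "?"), "", v)
  num <- function(v, default = NA_real_) {
    out <- suppressWarnings(as.numeric(v)); out[is.na(out)] <- default; out
  }
  data.frame(
    record = g("group_PDB", "ATOM"),
    serial = as.integer(num(g("id"))),
    name = dot(g("auth_atom_id", "label_atom_id")),
    altloc = dot(g("label_alt_id")),
    resid = dot(g("auth_comp_id", "label_comp_id")),
    chain = dot(g("auth_asym_id", "label_asym_id")),
    resno = as.integer(num(g("auth_seq_id", "label_seq_id"))),
    icode = dot(g("pdbx_PDB_ins_code")),
    x = num(g("Cartn_x")), y = num(g("Cartn_y")), z = num(g("Cartn_z")),
    occupancy = num(g("occupancy"), 1), b = num(g("B_iso_or_equiv"), 0),
    element = dot(g("type_symbol")),
    stringsAsFactors = FALSE
  )
}

#' Write a structure to a PDB file
#'
#' @param structure An `ab_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    eleno = a$serial, elety = a$name, resid = a$resid,
    chain = a$chain, resno = a$resno,
    insert = ifelse(a$icode == "", NA, a$icode),
    alt = ifelse(a$altloc == "", NA, a$altloc),
    o = a$occupancy, b = a$b, elesy = a$element
  )
  invisible(path)
}

#' Residue table of a structure
#'
#' One row per residue in file order, with the residue key, chain, number,
#' insertion code, one-letter code and atom count.
#'
#' @param structure An `ab_structure`.
#' @return Data frame with columns `key`, `chain`, `resno`, `icode`, `aa`,
#'   `n_atoms` (plus `scheme_label` and `region` after [apply_numbering()]).
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- res_key(a$chain, a$resno, a$icode)
  first <- !duplicated(key)
  out <- data.frame(
    key = key[first], chain = a$chain[first], resno = a$resno[first],
    icode = a$icode[first], aa = a$aa[first],
    n_atoms = as.integer(table(key)[key[first]]),
    stringsAsFactors = FALSE
  )
  if (!is.null(a$scheme_label)) {
    out$scheme_label <- a$scheme_label[first]
    out$region <- a$region[first]
  }
  rownames(out) <- NULL
  out
}

#' Extract a chain's amino-acid sequence
#'
#' @param structure An `ab_structure`.
#' @param chain_id Chain identifier.
#' @param strict If TRUE (default) non-standard residues become `"X"`;
#'   if FALSE, `aliases` is consulted first.
#' @param aliases Modified-residue alias table,
#'   default [modified_residue_aliases()].
#' @return One-letter amino-acid string in chain order.
#' @export
extract_chain_sequence <- function(structure, chain_id, strict = TRUE,
                                   aliases = modified_residue_aliases()) {
  rt <- residue_table(structure)
  rt <- rt[rt$chain == chain_id, , drop = FALSE]
  if (nrow(rt) == 0L) stop("chain not found (or empty): ", chain_id)
  aa <- rt$aa
  if (!strict) {
    a <- structure$atoms
    key <- res_key(a$chain, a$resno, a$icode)
    resid3 <- a$resid[!duplicated(key)]
    names(resid3) <- key[!duplicated(key)]
    unknown <- aa == "X"
    ali <- aliases[resid3[rt$key[unknown]]]
    aa[unknown][!is.na(ali)] <- ali[!is.na(ali)]
  }
  paste(aa, collapse = "")
}

# ---- numbering -----------------------------------------------------------

#' Read a residue numbering map from CSV
#'
#' Expected columns: `chain`, `resnum`, `icode`, `aa`, `scheme_label`,
#' `region`. An empty/missing `region` is filled from the scheme label via
#' [kabat_region()].
#'
#' @param path CSV path.
#' @return Data frame of class `numbering_map`.
#' @export
read_numbering_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(icode = "character"))
  need <- c("chain", "resnum", "icode", "aa", "scheme_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("numbering map missing columns: ",
                         paste(miss, collapse = ", "))
  df$icode[is.na(df$icode)] <- ""
  if (is.null(df$region)) df$region <- NA_character_
  fill <- is.na(df$region) | df$region == ""
  df$region[fill] <- kabat_region(df$scheme_label[fill])
  class(df) <- c("numbering_map", "data.frame")
  df
}

.region_vocab <- c(paste0("FR", 1:4), paste0("CDR", 1:3), "constant", "other")

#' Attach scheme labels and regions to a structure
#'
#' Each mapped residue gains a `scheme_label` (e.g. `"H97"`) and a `region`
#' (FR1-FR4, CDR1-CDR3, constant). Unmapped residues get region `"other"`.
#' Coordinates and atom counts are never modified.
#'
#' @param structure An `ab_structure`.
#' @param numbering A `numbering_map` data frame (see [read_numbering_map()]),
#'   or NULL for an empty map.
#' @param strict If TRUE, a map key absent from the structure is an error;
#'   if FALSE it is skipped with a warning.
#' @return The annotated `ab_structure`.
#' @export
apply_numbering <- function(structure, numbering = NULL, strict = TRUE) {
  a <- structure$atoms
  a$scheme_label <- NA_character_
  a$region <- "other"
  if (!is.null(numbering) && nrow(numbering) > 0L) {
    bad <- !(numbering$region %in% .region_vocab)
    if (any(bad)) stop("region labels outside vocabulary: ",
                       paste(unique(numbering$region[bad]), collapse = ", "))
    mkey <- res_key(numbering$chain, numbering$resnum, numbering$icode)
    if (anyDuplicated(mkey)) stop("duplicate keys in numbering map")
    if (anyDuplicated(numbering$scheme_label))
      stop("duplicate scheme labels in numbering map")
    akey <- res_key(a$chain, a$resno, a$icode)
    absent <- !(mkey %in% akey)
    if (any(absent)) {
      msg <- paste("numbering keys absent from structure:",
                   paste(head(mkey[absent], 5), collapse = ", "))
      if (strict) stop(msg) else warning(msg)
      numbering <- numbering[!absent, , drop = FALSE]
      mkey <- mkey[!absent]
    }
    ix <- match(akey, mkey)
    hit <- !is.na(ix)
    a$scheme_label[hit] <- numbering$scheme_label[ix[hit]]
    a$region[hit] <- numbering$region[ix[hit]]
  }
  structure$atoms <- a
  structure
}
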