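# In-code fixtures: tiny PDB writers for structures with real residue
# names, plus small CSV helpers. All fixtures are built at test time.

pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, b = 0, element = substr(name, 1, 1),
                     record = "ATOM", altloc = " ", icode = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resid, chain, resno, ifelse(icode == "", " ", icode),
          x, y, z, occ, b, element)
}

# one dummy atom per residue; spec: list of lists with chain, resno, resid,
# xyz (length 3), and optional name/element/b/icode/record
write_residue_pdb <- function(residues, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    pdb_line(i, r$name %||% "CA", r$resid, r$chain, r$resno,
             r$xyz[1], r$xyz[2], r$xyz[3],
             b = r$b %||% 0, element = r$element %||% "C",
             record = r$record %||% "ATOM", icode = r$icode %||% "")
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small two-chain "mini-Fv": isolated single-atom residues far apart so
# every residue has full-sphere SASA (136.85 A^2 for a carbon at the
# default probe). Composition chosen to exercise hotspots (W), oxidation
# flags (M, W), and non-hydrophobic residues (S, G).
mini_fv_residues <- function() {
  list(
    list(chain = "H", resno = 97, resid = "TRP", xyz = c(0, 0, 0)),
    list(chain = "H", resno = 31, resid = "ILE", xyz = c(20, 0, 0)),
    list(chain = "H", resno = 40, resid = "SER", xyz = c(40, 0, 0)),
    list(chain = "L", resno = 93, resid = "TRP", xyz = c(0, 20, 0)),
    list(chain = "L", resno = 30, resid = "MET", xyz = c(20, 20, 0)),
    list(chain = "L", resno = 50, resid = "GLY", xyz = c(40, 20, 0))
  )
}

write_mini_fv <- function(path = tempfile(fileext = ".pdb")) {
  write_residue_pdb(mini_fv_residues(), path)
}

mini_fv_numbering_csv <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    chain = c("H", "H", "H", "L", "L", "L"),
    resnum = c(97, 31, 40, 93, 30, 50),
    icode = "",
    aa = c("W", "I", "S", "W", "M", "G"),
    scheme_label = c("H97", "H31", "H40", "L93", "L30", "L50"),
    region = ""
  )
  write.csv(df, path, row.names = FALSE)
  path
}

# independent brute-force motif scanner used as oracle for scan_motifs
brute_force_scan <- function(sequence, rules = motif_rules()) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  hits <- data.frame(kind = character(), position = integer(),
                     matched_text = character(), stringsAsFactors = FALSE)
  lits <- list(deamidation = rules$deamidation,
               proteolysis = rules$proteolysis,
               isomerization = rules$isomerization)
  for (kind in names(lits)) {
    for (m in lits[[kind]]) {
      w <- nchar(m)
      if (n < w) next
      for (i in 1:(n - w + 1)) {
        if (paste(chars[i:(i + w - 1)], collapse = "") == m) {
          hits <- rbind(hits, data.frame(kind = kind, position = i,
                                         matched_text = m))
        }
      }
    }
  }
  if (rules$glycosylation && n >= 3) {
    for (i in 1:(n - 2)) {
      if (chars[i] == "N" && chars[i + 1] != "P" &&
          chars[i + 2] %in% c("S", "T")) {
        hits <- rbind(hits, data.frame(
          kind = "glycosylation", position = i,
          matched_text = paste(chars[i:(i + 2)], collapse = "")))
      }
    }
  }
  hits <- hits[order(hits$position, hits$kind), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# locations where the deposited crystal structures would be found if a
# user has fetched them with scripts/fetch_structures.R
deposited_structure_path <- function(id) {
  cands <- c(
    system.file("extdata", "structures", paste0(tolower(id), ".pdb"),
                package = "abdev"),
    file.path("..", "..", "inst", "extdata", "structures",
              paste0(tolower(id), ".pdb"))
  )
  cands <- cands[cands != "" & file.exists(cands)]
  if (length(cands)) normalizePath(cands[1]) else NA_character_
}

random_cluster_structure <- function(n, seed, r = 1.9, box = 8) {
  fx <- make_toy_structure("random_cluster", dir = tempfile(), n = n,
                           box = box, r = r, seed = seed)
  read_structure(fx$files[["pdb"]], radius_table = fx$radius_table)
}
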