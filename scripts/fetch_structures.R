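#!/usr/bin/env Rscript
# Convenience download of the deposited crystal structures analyzed by the
# developability screen: the parent Fab (PDB 6FOE) and the engineered
# variant Fab (PDB 9FQO). Requires network access; the test suite and
# acceptance script never depend on it, but the structure-integration
# tests only run their computations once these files exist.
#
# Usage: Rscript scripts/fetch_structures.R [dest_dir]

dest <- commandArgs(trailingOnly = TRUE)
dest <- if (length(dest)) dest[1] else "inst/extdata/structures"
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

for (id in c("6FOE", "9FQO")) {
  out <- file.path(dest, paste0(tolower(id), ".pdb"))
  if (file.exists(out)) {
    message(out, " already present, skipping")
    next
  }
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", id)
  message("downloading ", url)
  utils::download.file(url, out, mode = "wb", quiet = TRUE)
}
message("done; structures in ", dest)
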