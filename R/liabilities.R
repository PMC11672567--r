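# Sequence liability scanning: PTM motifs, exposed oxidation-prone
# residues, rare framework residues.

#' Default liability motif rule set
#'
#' Asn deamidation trimers SNG/ENN/LNG/LNN, the N-linked glycosylation
#' sequon N-X-(S/T) with X != P, the DP proteolysis dipeptide, and Asp
#' isomerization dipeptides DS/DN/DQ/DK/DL.
#'
#' @param deamidation,proteolysis,isomerization Character vectors of literal
#'   motifs (can be extended).
#' @param glycosylation If TRUE (default) include the sequon rule.
#' @return List of class `motif_rules`.
#' @export
motif_rules <- function(deamidation = c("SNG", "ENN", "LNG", "LNN"),
                        proteolysis = "DP",
                        isomerization = c("DS", "DN", "DQ", "DK", "DL"),
                        glycosylation = TRUE) {
  structure(list(deamidation = toupper(deamidation),
                 proteolysis = toupper(proteolysis),
                 isomerization = toupper(isomerization),
                 glycosylation = isTRUE(glycosylation)),
            class = "motif_rules")
}

#' Scan a sequence for liability motifs
#'
#' Reports all (including overlapping) occurrences, ordered by position then
#' kind. The glycosylation sequon is a positional rule, not a literal
#' string: N at i, anything but P at i+1, S or T at i+2.
#'
#' @param sequence Uppercase one-letter amino-acid string (20 codes + X).
#' @param rules A [motif_rules()] object.
#' @return Data frame of hits: `kind`, `position` (1-based start),
#'   `matched_text`, `context` (+/- 3 residues).
#' @export
scan_motifs <- function(sequence, rules = motif_rules()) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!(chars %in% c(unname(.aa3to1), "X")))
  if (length(bad)) stop("illegal character '", chars[bad[1]],
                        "' at position ", bad[1])
  n <- length(chars)
  hits <- list()
  add <- function(kind, pos, text) {
    hits[[length(hits) + 1L]] <<- data.frame(
      kind = kind, position = pos, matched_text = text,
      context = substr(sequence, max(1, pos - 3),
                       min(n, pos + nchar(text) - 1 + 3)),
      stringsAsFactors = FALSE)
  }
  scan_literal <- function(kind, motifs) {
    for (m in motifs) {
      w <- nchar(m)
      if (n < w) next
      for (i in seq_len(n - w + 1L)) {
        if (substr(sequence, i, i + w - 1L) == m) add(kind, i, m)
      }
    }
  }
  scan_literal("deamidation", rules$deamidation)
  scan_literal("proteolysis", rules$proteolysis)
  scan_literal("isomerization", rules$isomerization)
  if (isTRUE(rules$glycosylation) && n >= 3) {
    for (i in seq_len(n - 2L)) {
      if (chars[i] == "N" && chars[i + 1] != "P" &&
          chars[i + 2] %in% c("S", "T")) {
        add("glycosylation", i, substr(sequence, i, i + 2))
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(kind = character(), position = integer(),
                      matched_text = character(), context = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$position, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag solvent-exposed oxidation-prone residues
#'
#' Flags Met and Trp residues whose relative exposure (residue SASA divided
#' by the reference maximum for that amino acid) meets the threshold.
#' Oxidation risk is assessed from exposure alone, with no sequence-context
#' requirement.
#'
#' @param structure An (optionally numbered) `ab_structure`.
#' @param sasa A `sasa_result` computed on the same structure.
#' @param rel_exposure_threshold Relative SASA threshold in (0, 1),
#'   default 0.2.
#' @param reference_max Named per-aa maximal SASA table,
#'   default [max_sasa_gxg()].
#' @return Data frame of hits: `kind` ("oxidation_exposed"), `key`, `chain`,
#'   `resno`, `aa`, `scheme_label` (NA when unnumbered), `sasa`,
#'   `rel_exposure`.
#' @export
flag_exposed_oxidation_sites <- function(structure, sasa,
                                         rel_exposure_threshold = 0.2,
                                         reference_max = max_sasa_gxg()) {
  if (!(rel_exposure_threshold > 0 && rel_exposure_threshold < 1))
    stop("rel_exposure_threshold must be in (0,1)")
  rt <- sasa$residues
  rt <- rt[rt$aa %in% c("M", "W"), , drop = FALSE]
  if (nrow(rt) && any(!(rt$aa %in% names(reference_max))))
    stop("reference max SASA missing for: ",
         paste(setdiff(rt$aa, names(reference_max)), collapse = ", "))
  rel <- rt$sasa / unname(reference_max[rt$aa])
  keep <- rel >= rel_exposure_threshold
  data.frame(
    kind = rep("oxidation_exposed", sum(keep)),
    key = rt$key[keep], chain = rt$chain[keep], resno = rt$resno[keep],
    aa = rt$aa[keep],
    scheme_label = if (is.null(rt$scheme_label)) NA_character_
                   else rt$scheme_label[keep],
    sasa = rt$sasa[keep], rel_exposure = rel[keep],
    stringsAsFactors = FALSE
  )
}

#' Read a germline position-frequency table
#'
#' CSV with columns `scheme_label`, `aa`, `frequency` (0-1 within each
#' position).
#'
#' @param path CSV path.
#' @return Data frame of class `germline_freq`.
#' @export
read_germline_frequencies <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("scheme_label", "aa", "frequency")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("germline table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$frequency < 0 | df$frequency > 1))
    stop("frequencies must be in [0,1]")
  s <- vapply(split(df$frequency, df$scheme_label), sum, numeric(1))
  if (any(s > 1 + 1e-6))
    stop("frequencies sum to > 1 at: ",
         paste(names(s)[s > 1 + 1e-6], collapse = ", "))
  class(df) <- c("germline_freq", "data.frame")
  df
}

#' Flag rare framework residues
#'
#' Flags framework positions where the observed amino acid's germline
#' repertoire frequency is below the threshold. CDR positions are never
#' flagged; positions missing from the table produce a warning, not an
#' error.
#'
#' @param labelled_sequence Data frame with columns `scheme_label`, `aa`,
#'   `region` (e.g. the residue table of a numbered structure, or built
#'   from a numbering map).
#' @param table A `germline_freq` table.
#' @param freq_threshold Frequency cutoff, default 0.02.
#' @return Data frame of hits: `kind` ("rare_framework"), `scheme_label`,
#'   `aa`, `region`, `frequency`.
#' @export
flag_rare_framework_residues <- function(labelled_sequence, table,
                                         freq_threshold = 0.02) {
  ls <- labelled_sequence
  fr <- ls[grepl("^FR", ls$region), , drop = FALSE]
  if (nrow(fr) == 0L) return(data.frame(
    kind = character(), scheme_label = character(), aa = character(),
    region = character(), frequency = numeric(), stringsAsFactors = FALSE))
  f <- table$frequency[match(paste(fr$scheme_label, fr$aa),
                             paste(table$scheme_label, table$aa))]
  known_pos <- fr$scheme_label %in% table$scheme_label
  if (any(!known_pos)) {
    warning("positions missing from germline table: ",
            paste(unique(fr$scheme_label[!known_pos]), collapse = ", "))
  }
  # a position present in the table but with the observed aa unlisted has
  # observed frequency 0
  f[known_pos & is.na(f)] <- 0
  keep <- known_pos & f < freq_threshold
  data.frame(kind = rep("rare_framework", sum(keep)),
             scheme_label = fr$scheme_label[keep], aa = fr$aa[keep],
             region = fr$region[keep], frequency = f[keep],
             stringsAsFactors = FALSE)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}
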