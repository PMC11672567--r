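# SASA-weighted hydrophobicity: score_r = SASA_r * h_aa with the
# Black-Mould index; region aggregates, hotspot classes, profile diffs.

#' Per-residue hydrophobicity profile
#'
#' Multiplies each residue's solvent-accessible surface area by its
#' Black-Mould hydrophobicity index. Residues with unknown identity
#' (`aa == "X"`) are skipped and reported.
#'
#' @param sasa A `sasa_result` from [compute_sasa()].
#' @param scale A `hydrophobicity_scale`, default [black_mould_scale()].
#' @param strict If TRUE, a standard residue missing from the scale is an
#'   error (cannot happen with the shipped scale).
#' @return Object of class `hydro_profile`: data frame `residues` with
#'   columns of the residue table plus `sasa`, `h`, `score`, and attributes
#'   `scale`, `skipped` (keys of skipped residues).
#' @export
score_profile <- function(sasa, scale = black_mould_scale(), strict = TRUE) {
  rt <- sasa$residues
  h <- unname(scale$index[rt$aa])
  known <- rt$aa != "X"
  if (strict && any(known & is.na(h))) {
    stop("amino acids missing from scale: ",
         paste(unique(rt$aa[known & is.na(h)]), collapse = ", "))
  }
  skipped <- rt$key[!known | is.na(h)]
  rt$h <- h
  rt$score <- rt$sasa * h
  out <- rt[!is.na(rt$score), , drop = FALSE]
  structure(list(residues = out, scale = scale$name, skipped = skipped),
            class = "hydro_profile")
}

#' @export
print.hydro_profile <- function(x, ...) {
  cat(sprintf("<hydro_profile> %d residues scored (%s scale), total %.1f\n",
              nrow(x$residues), x$scale, sum(x$residues$score)))
  if (length(x$skipped))
    cat("  skipped (unknown aa):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate hydrophobicity scores by annotated region
#'
#' Sums per-residue scores within each (chain, region); residues without a
#' region annotation are counted in a `remainder` bucket per chain, so that
#' region sums plus remainder equal the chain total exactly.
#'
#' @param profile A `hydro_profile` whose residue table carries a `region`
#'   column (from [apply_numbering()]), or an explicit `annotation` data
#'   frame with columns `key`, `region`.
#' @param annotation Optional key-to-region table overriding the profile's
#'   own annotation.
#' @return Data frame with columns `chain`, `region`, `score`, `n_residues`;
#'   unannotated residues appear as region `"remainder"`.
#' @export
aggregate_regions <- function(profile, annotation = NULL) {
  rt <- profile$residues
  if (!is.null(annotation)) {
    rt$region <- annotation$region[match(rt$key, annotation$key)]
  }
  if (is.null(rt$region)) rt$region <- NA_character_
  rt$region[is.na(rt$region) | rt$region %in% c("", "other")] <- "remainder"
  agg <- aggregate(score ~ chain + region, data = rt, FUN = sum)
  cnt <- aggregate(score ~ chain + region, data = rt, FUN = length)
  agg$n_residues <- cnt$score
  agg[order(agg$chain, agg$region), , drop = FALSE]
}

#' Chain totals of a profile
#'
#' @param profile A `hydro_profile`.
#' @return Named numeric vector, total score per chain.
#' @export
chain_totals <- function(profile) {
  vapply(split(profile$residues$score, profile$residues$chain), sum,
         numeric(1))
}

#' Classify hydrophobic hotspots
#'
#' Residues with score at or above `t_elevated` are "elevated"; scores in
#' `[t_moderate, t_elevated)` are "moderate".
#'
#' @param profile A `hydro_profile`.
#' @param t_elevated Elevated threshold (score units), default 100.
#' @param t_moderate Moderate threshold, default 50; must satisfy
#'   `t_elevated > t_moderate > 0`.
#' @return List of class `hotspot_report` with data frames `elevated`,
#'   `moderate` (residue rows) and `thresholds`.
#' @export
classify_hotspots <- function(profile, t_elevated = 100, t_moderate = 50) {
  if (!(t_elevated > t_moderate && t_moderate > 0))
    stop("need t_elevated > t_moderate > 0")
  rt <- profile$residues
  structure(list(
    elevated = rt[rt$score >= t_elevated, , drop = FALSE],
    moderate = rt[rt$score >= t_moderate & rt$score < t_elevated, ,
                  drop = FALSE],
    thresholds = c(t_elevated = t_elevated, t_moderate = t_moderate)
  ), class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  lab <- function(df) if (nrow(df) == 0) "none" else
    paste(ifelse(is.na(df$scheme_label), df$key, df$scheme_label),
          collapse = ", ")
  cat(sprintf("<hotspot_report> elevated (>= %g): %s\n", x$thresholds[1],
              lab(x$elevated)))
  cat(sprintf("                 moderate (>= %g): %s\n", x$thresholds[2],
              lab(x$moderate)))
  invisible(x)
}

#' Difference two hydrophobicity profiles
#'
#' Pairs residues of two profiles by scheme label (or an explicit pairing)
#' and reports per-position deltas of SASA and score as `b - a`.
#'
#' @param profile_a,profile_b `hydro_profile` objects whose residue tables
#'   carry `scheme_label` columns, or plain data frames with columns
#'   `scheme_label`, `sasa`, `score`.
#' @param pairing Optional data frame with columns `label_a`, `label_b`;
#'   default pairs identical scheme labels.
#' @return List with `deltas` (data frame: `label_a`, `label_b`, `sasa_a`,
#'   `sasa_b`, `delta_sasa`, `score_a`, `score_b`, `delta_score`) and
#'   `unpaired_a`, `unpaired_b` (labels present on one side only).
#' @export
diff_profiles <- function(profile_a, profile_b, pairing = NULL) {
  tab <- function(p) {
    rt <- if (inherits(p, "hydro_profile")) p$residues else p
    if (is.null(rt$scheme_label)) stop("profiles need scheme labels to pair")
    rt <- rt[!is.na(rt$scheme_label), , drop = FALSE]
    if (anyDuplicated(rt$scheme_label))
      stop("duplicate scheme labels; pair one copy at a time")
    rt
  }
  a <- tab(profile_a); b <- tab(profile_b)
  if (is.null(pairing)) {
    shared <- intersect(a$scheme_label, b$scheme_label)
    pairing <- data.frame(label_a = shared, label_b = shared,
                          stringsAsFactors = FALSE)
  }
  if (anyDuplicated(pairing$label_a) || anyDuplicated(pairing$label_b))
    stop("duplicate pairing target")
  ia <- match(pairing$label_a, a$scheme_label)
  ib <- match(pairing$label_b, b$scheme_label)
  if (any(is.na(ia)) || any(is.na(ib)))
    stop("pairing refers to labels absent from a profile")
  deltas <- data.frame(
    label_a = pairing$label_a, label_b = pairing$label_b,
    sasa_a = a$sasa[ia], sasa_b = b$sasa[ib],
    delta_sasa = b$sasa[ib] - a$sasa[ia],
    score_a = a$score[ia], score_b = b$score[ib],
    delta_score = b$score[ib] - a$score[ia],
    stringsAsFactors = FALSE
  )
  list(deltas = deltas,
       unpaired_a = setdiff(a$scheme_label, pairing$label_a),
       unpaired_b = setdiff(b$scheme_label, pairing$label_b))
}
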