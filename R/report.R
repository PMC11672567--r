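# Orchestration of the full developability screen: parse -> SASA ->
# profile -> hotspots -> liabilities -> interface -> compare -> assays,
# with graceful degradation when optional inputs are absent.

#' Default screen parameters
#'
#' All tunable thresholds of the screen in one place: SASA quadrature,
#' hotspot score cutoffs, relative-exposure threshold for oxidation flags,
#' germline rarity cutoff, contact cutoff and hydrophobic-residue cutoff.
#'
#' @return Named list of defaults.
#' @export
screen_defaults <- function() {
  list(probe_radius = 1.4, n_sphere_points = 960,
       t_elevated = 100, t_moderate = 50,
       rel_exposure_threshold = 0.2, freq_threshold = 0.02,
       contact_cutoff = 4.5, h_cutoff = 0.7)
}

.check_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package needed to read YAML configs")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a config file path")
  if (is.null(config$candidates) || !length(config$candidates))
    stop("config error: 'candidates' must list at least one candidate")
  for (cand in config$candidates) {
    if (is.null(cand$id)) stop("config error: every candidate needs an 'id'")
    for (f in c("structure", "numbering", "sequences")) {
      if (!is.null(cand[[f]]) && !file.exists(cand[[f]]))
        stop("config error: ", f, " file not found for candidate ",
             cand$id, ": ", cand[[f]])
    }
  }
  config$params <- utils::modifyList(screen_defaults(),
                                     config$params %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.screen_candidate <- function(cand, params, germline, log) {
  res <- list(id = cand$id)
  seqs <- character()
  if (!is.null(cand$structure)) {
    log("parse", cand$id)
    st <- read_structure(cand$structure, format = cand$format %||% "auto")
    if (!is.null(cand$chains))
      st <- .subset_chains(st, cand$chains)
    if (!is.null(cand$numbering))
      st <- apply_numbering(st, read_numbering_map(cand$numbering),
                            strict = FALSE)
    log("sasa", cand$id)
    sasa <- compute_sasa(st, sasa_params(params$probe_radius,
                                         params$n_sphere_points))
    log("profile", cand$id)
    prof <- score_profile(sasa)
    hs <- classify_hotspots(prof, params$t_elevated, params$t_moderate)
    res$profile <- prof$residues
    res$chain_totals <- as.list(chain_totals(prof))
    res$region_scores <- aggregate_regions(prof)
    res$hotspots <- list(
      elevated = hs$elevated[, c("key", "aa", "score"), drop = FALSE],
      moderate = hs$moderate[, c("key", "aa", "score"), drop = FALSE],
      thresholds = as.list(hs$thresholds))
    res$oxidation_exposed <-
      flag_exposed_oxidation_sites(st, sasa, params$rel_exposure_threshold)
    for (ch in unique(st$atoms$chain))
      seqs[ch] <- extract_chain_sequence(st, ch)
    rt <- residue_table(st)
    if (!is.null(rt$scheme_label) && !is.null(germline)) {
      res$rare_framework <- flag_rare_framework_residues(
        rt[!is.na(rt$scheme_label), c("scheme_label", "aa", "region")],
        germline, params$freq_threshold)
    }
    res$.structure <- st
    res$.profile_obj <- prof
  } else {
    res$structure <- "absent"
  }
  if (!is.null(cand$sequences)) {
    fa <- read_fasta(cand$sequences)
    seqs[names(fa)] <- fa
  }
  if (length(seqs)) {
    log("liabilities", cand$id)
    res$motif_hits <- lapply(seqs, function(s)
      scan_motifs(gsub("X", "A", s)))  # unknown residues cannot match
  }
  # slot reserved for externally computed MHC-II epitope lists
  res$immunogenicity <- cand$immunogenicity %||% NULL
  res
}

#' Run the full developability screen
#'
#' Stages run in a fixed order (parse, SASA, hydrophobicity profile,
#' hotspots, liabilities, interface, structure comparison, assays); any
#' stage whose inputs are absent from the config is skipped and recorded.
#' See the vignette for the config schema; minimally
#' `list(candidates = list(list(id = "x", structure = "x.pdb")))`.
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @param out Optional path for the JSON report.
#' @param quiet Suppress per-stage log messages.
#' @return List of class `developability_report`.
#' @export
run_screen <- function(config, out = NULL, quiet = TRUE) {
  config <- .check_config(config)
  log <- if (quiet) function(...) invisible() else
    function(stage, id) message(sprintf("[%s] %s", stage, id))
  params <- config$params
  germline <- if (!is.null(config$germline))
    read_germline_frequencies(config$germline) else NULL

  cands <- lapply(config$candidates, .screen_candidate,
                  params = params, germline = germline, log = log)
  names(cands) <- vapply(config$candidates, `[[`, character(1), "id")

  # interface analysis on the first candidate with the configured groups
  interface <- NULL
  if (!is.null(config$interface)) {
    ic <- config$interface
    st <- cands[[ic$candidate %||% 1L]]$.structure
    if (!is.null(st)) {
      log("interface", st$id)
      contacts <- find_intergroup_contacts(
        st, ic$group_a, ic$group_b,
        cutoff = ic$cutoff %||% params$contact_cutoff)
      burial <- buried_sasa(st, ic$group_a, ic$group_b,
                            sasa_params(params$probe_radius,
                                        params$n_sphere_points))
      prof_full <- cands[[ic$candidate %||% 1L]]$.profile_obj
      interface <- list(
        contacts = contacts,
        buried = burial[burial$buried > 0, , drop = FALSE],
        summary = summarize_interface(contacts, prof_full,
                                      params$h_cutoff, burial))
    }
  }

  # pairwise deltas vs the reference candidate, by scheme label
  deltas <- NULL
  if (!is.null(config$reference) && length(cands) > 1L) {
    ref <- cands[[config$reference]]
    if (!is.null(ref$.profile_obj)) {
      deltas <- lapply(cands[names(cands) != config$reference],
                       function(cd) {
        if (is.null(cd$.profile_obj)) return(NULL)
        tryCatch(diff_profiles(ref$.profile_obj, cd$.profile_obj)$deltas,
                 error = function(e) paste("not comparable:",
                                           conditionMessage(e)))
      })
    }
  }

  assays <- NULL
  if (!is.null(config$assays)) {
    log("assays", "-")
    assays <- list()
    ac <- config$assays$acsins
    if (!is.null(ac)) {
      rd <- function(p) read.csv(p)
      sfit <- with(rd(ac$sample), acsins_lambda_max(wavelength_nm,
                                                    absorbance))
      cfit <- with(rd(ac$control), acsins_lambda_max(wavelength_nm,
                                                     absorbance))
      assays$acsins <- list(lambda_max_sample = sfit$lambda_max,
                            lambda_max_control = cfit$lambda_max,
                            delta_lambda_max = acsins_shift(sfit, cfit))
    }
    bd <- config$assays$binding
    if (!is.null(bd)) {
      fit_one <- function(p) {
        d <- read.csv(p)
        fit_4pl(d$concentration_pM, d$response)
      }
      sf <- fit_one(bd$sample)
      assays$binding <- list(ec50_sample = sf$ec50, hill = sf$hill,
                             converged = sf$converged)
      if (!is.null(bd$reference)) {
        rf <- fit_one(bd$reference)
        assays$binding$ec50_reference <- rf$ec50
        assays$binding$potency_pct <- relative_potency(rf$ec50, sf$ec50)
      }
    }
    sc <- config$assays$sec
    if (!is.null(sc)) {
      std <- read.csv(sc$standards)
      cal <- sec_calibration(std$mw_kda, std$retention_ml)
      assays$sec <- list(slope = cal$slope, intercept = cal$intercept)
      if (!is.null(sc$retention))
        assays$sec$mw_kda <- sec_mw_estimate(sc$retention, cal)
    }
  }

  input_files <- unlist(lapply(config$candidates, function(cd)
    unlist(cd[c("structure", "numbering", "sequences")])))
  report <- list(
    candidates = lapply(cands, function(cd)
      cd[!startsWith(names(cd), ".")]),
    interface = interface,
    deltas = deltas,
    assays = assays,
    provenance = list(
      package = "abdev",
      version = as.character(utils::packageVersion("abdev")),
      parameters = params,
      input_hashes = as.list(tools::md5sum(input_files)),
      timestamp = format(Sys.time(), tz = "UTC"))
  )
  class(report) <- "developability_report"
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.developability_report <- function(x, ...) {
  cat("<developability_report>\n")
  for (id in names(x$candidates)) {
    cd <- x$candidates[[id]]
    cat(" candidate", id, "\n")
    if (!is.null(cd$hotspots)) {
      cat("   elevated hotspots:",
          paste(cd$hotspots$elevated$key, collapse = ", "), "\n")
      cat("   oxidation-exposed:",
          paste(cd$oxidation_exposed$key, collapse = ", "), "\n")
    }
    if (!is.null(cd$motif_hits)) {
      nh <- sum(vapply(cd$motif_hits, nrow, integer(1)))
      cat("   sequence motif hits:", nh, "\n")
    }
  }
  if (!is.null(x$assays)) cat(" assays:",
                              paste(names(x$assays), collapse = ", "), "\n")
  invisible(x)
}
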