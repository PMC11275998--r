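stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[stage %s] %s", name, conditionMessage(e)),
                        class = c("prm_stage_error", class(e))))
  })
}

pkg_version <- function() {
  as.character(utils::packageVersion("prmassay"))
}

#' Run the full scheduling pipeline
#'
#' Library in, validated assay out: reads the library, FASTA and target
#' lists, ranks candidates and selects transitions, aligns retention
#' times against an observed-RT table (identity map if none is given),
#' builds one greedy schedule per requested density, optionally runs the
#' dimethyl background-exclusion validator, and writes the inclusion
#' list CSV, the scheduling report TSV and a JSON run manifest.
#'
#' @param library_path library TSV path.
#' @param dialect `"DIA"` or `"DDA"`.
#' @param fasta_path protein FASTA path.
#' @param targets_path target accession/keyword list.
#' @param include_path,exclude_path optional peptide lists.
#' @param observed_rt_path optional observed-RT TSV from a recent DIA
#'   run.
#' @param config a [schedule_config()].
#' @param policy a [transition_policy()].
#' @param densities optional integer vector of tier densities
#'   (descending); default is the single density in `config`.
#' @param out_csv inclusion-list CSV path (tier densities are suffixed
#'   when more than one tier is requested).
#' @param report_path scheduling-report TSV path.
#' @param manifest_path JSON manifest path (default: `out_csv` +
#'   `".manifest.json"`).
#' @param validate_dimethyl run the background-exclusion validator.
#' @param max_charge highest charge for the dimethyl check.
#' @param quiet suppress stderr progress messages.
#' @return the run manifest (list), invisibly.
#' @export
run_schedule_pipeline <- function(library_path, dialect, fasta_path, targets_path,
                                  include_path = NULL, exclude_path = NULL,
                                  observed_rt_path = NULL,
                                  config = schedule_config(),
                                  policy = transition_policy(),
                                  densities = NULL,
                                  out_csv, report_path = NULL,
                                  manifest_path = NULL,
                                  validate_dimethyl = FALSE, max_charge = 3L,
                                  quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  lib <- stage("library_io", read_library(library_path, dialect))
  say("read %d library entries from %s", nrow(lib), library_path)
  fasta <- stage("library_io", read_fasta(fasta_path))
  targets <- stage("library_io", read_target_list(targets_path, include_path, exclude_path))
  resolved <- stage("library_io", resolve_targets(fasta, targets))
  say("resolved %d target accessions", length(resolved))

  cand <- stage("ranking", build_candidates(lib, resolved, policy,
                                            forced = targets$forced,
                                            excluded = targets$excluded))
  say("built %d candidates (%d excluded)", nrow(cand), attr(cand, "n_excluded"))

  rt_map <- rt_identity_map()
  if (!is.null(observed_rt_path)) {
    observed <- stage("rt_alignment", read_observed_rt(observed_rt_path))
    anchors <- stage("rt_alignment", make_rt_anchors(cand, observed))
    rt_map <- stage("rt_alignment", fit_rt_map(anchors))
    say("rt map: %s slope=%.4f intercept=%.3f (%d anchors)",
        rt_map$kind, rt_map$slope, rt_map$intercept, rt_map$n_anchors)
  }

  dens <- densities %||% config$max_density
  tiers <- lapply(dens, function(d) { cf <- config; cf$max_density <- as.integer(d); cf })
  schedules <- stage("scheduler", tier_assay(cand, rt_map, tiers))

  suffix <- function(path, d) {
    if (length(dens) == 1L) return(path)
    sub("(\\.[A-Za-z0-9]+)$", sprintf("_density%d\\1", d), path)
  }
  outputs <- list()
  dimethyl_reports <- list()
  for (k in seq_along(schedules)) {
    sch <- schedules[[k]]
    csv <- suffix(out_csv, dens[k])
    stage("library_io", write_inclusion_list(sch, csv))
    outputs[[length(outputs) + 1L]] <- csv
    if (!is.null(report_path)) {
      rp <- suffix(report_path, dens[k])
      stage("library_io", write_schedule_report(sch, rp))
      outputs[[length(outputs) + 1L]] <- rp
    }
    if (validate_dimethyl) {
      rep <- stage("dimethyl", validate_background_exclusion(sch, max_charge))
      dimethyl_reports[[names(schedules)[k]]] <- rep
      dp <- sub("\\.[A-Za-z0-9]+$", ".dimethyl.tsv", csv)
      utils::write.table(rep, dp, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs[[length(outputs) + 1L]] <- dp
      say("dimethyl exclusion (%s): %d/%d targets pass", names(schedules)[k],
          sum(rep$pass), nrow(rep))
    }
    say("density %d: scheduled %d of %d candidates", dens[k],
        nrow(sch$targets), sch$n_candidates)
  }

  counts <- lapply(schedules, function(sch) {
    rej <- table(factor(sch$rejections$reason,
                        levels = c("density", "protein_cap", "ineligible")))
    list(candidates = sch$n_candidates, excluded = sch$n_excluded,
         scheduled = nrow(sch$targets),
         rejected_density = as.integer(rej[["density"]]),
         rejected_protein_cap = as.integer(rej[["protein_cap"]]),
         rejected_ineligible = as.integer(rej[["ineligible"]]))
  })
  manifest <- list(
    tool = "prmassay", version = pkg_version(),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(library = library_path, dialect = dialect, fasta = fasta_path,
                  targets = targets_path, include = include_path,
                  exclude = exclude_path, observed_rt = observed_rt_path),
    config = unclass(config),
    rt_map = unclass(rt_map),
    densities = dens,
    entries_read = nrow(lib),
    stage_counts = counts,
    dimethyl_pass = if (validate_dimethyl)
      lapply(dimethyl_reports, function(r) sum(r$pass)) else NULL,
    outputs = unlist(outputs)
  )
  manifest_path <- manifest_path %||% paste0(out_csv, ".manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  manifest$schedules <- schedules
  invisible(manifest)
}

#' Run the calibration figures-of-merit pipeline
#'
#' Reads a per-peptide quantification table, fits each (peptide, charge)
#' calibration curve, estimates LoD and LoQ, writes the per-peptide
#' figures-of-merit CSV and a JSON manifest with the assay summary
#' (median LoD/LoQ, fraction of peptides without a LoQ).
#'
#' @param quant_path quant CSV (see [read_quant_table()]).
#' @param out_csv output figures-of-merit CSV.
#' @param cv_threshold LoQ bootstrap-CV threshold (default 0.20).
#' @param n_boot bootstrap resamples (default 100).
#' @param seed RNG seed for the bootstrap.
#' @param manifest_path JSON manifest path (default `out_csv` +
#'   `".manifest.json"`).
#' @param quiet suppress progress messages.
#' @return list with `fom` (data frame) and `summary`, invisibly.
#' @export
run_calibration_pipeline <- function(quant_path, out_csv, cv_threshold = 0.20,
                                     n_boot = 100L, seed = 17L,
                                     manifest_path = NULL, quiet = FALSE) {
  quant <- stage("calibration", read_quant_table(quant_path))
  if (nrow(quant) == 0L)
    prm_stop("[stage calibration] quant table is empty", "prm_insufficient_data")
  keys <- unique(quant[, c("peptide", "charge")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- quant[quant$peptide == keys$peptide[i] & quant$charge == keys$charge[i], ]
    fom <- stage("calibration",
                 figures_of_merit(sub, cv_threshold, n_boot, seed = seed + i))
    rows[[i]] <- data.frame(Peptide = keys$peptide[i], Charge = keys$charge[i],
                            LoD = fom$lod, LoQ = fom$loq, Slope = fom$slope,
                            NoiseFloor = fom$noise_floor,
                            CVatLoQ = fom$cv_at_loq, Status = fom$status,
                            stringsAsFactors = FALSE)
  }
  fom_tab <- do.call(rbind, rows)
  utils::write.table(fom_tab, out_csv, sep = ",", quote = FALSE, row.names = FALSE)
  summary <- summarize_assay(data.frame(lod = fom_tab$LoD, loq = fom_tab$LoQ))
  if (!quiet)
    message(sprintf("calibrated %d peptides: median LoD %.4g, median LoQ %.4g, %.1f%% no LoQ",
                    summary$n, summary$median_lod, summary$median_loq,
                    100 * summary$frac_no_loq))
  manifest <- list(tool = "prmassay", version = pkg_version(),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   inputs = list(quant = quant_path),
                   params = list(cv_threshold = cv_threshold, n_boot = n_boot,
                                 seed = seed),
                   n_peptides = summary$n,
                   median_lod = summary$median_lod,
                   median_loq = summary$median_loq,
                   frac_no_loq = summary$frac_no_loq,
                   outputs = out_csv)
  manifest_path <- manifest_path %||% paste0(out_csv, ".manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(list(fom = fom_tab, summary = summary, manifest = manifest))
}
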