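#' Transition selection policy
#'
#' Encodes the conventions used to pick diagnostic product ions on a
#' nominal-mass instrument: b/y series at fragment charge 1-2, product
#' m/z restricted to the scanned 200-1500 range, ions inside the
#' precursor isolation window excluded, and (optionally) only the third
#' ion through the second-to-last ion of a series considered. At least
#' `min_count` transitions are required for a peptide to be eligible;
#' up to `quant_max` are used for quantification and up to `report_max`
#' are reported.
#'
#' @param min_count minimum passing transitions for eligibility (3).
#' @param quant_max maximum transitions used for quantification (5).
#' @param report_max maximum transitions kept per peptide (9).
#' @param product_mz_min,product_mz_max scanned product m/z range.
#' @param precursor_exclusion_halfwidth half-width (m/z) of the
#'   precursor exclusion band around the isolation center.
#' @param allowed_series fragment ion series letters to keep.
#' @param allowed_fragment_charges fragment charges to keep.
#' @param terminal_trim if `TRUE`, keep only ion indices from 3 to
#'   (peptide length - 2).
#' @return a `transition_policy` object.
#' @export
transition_policy <- function(min_count = 3L, quant_max = 5L, report_max = 9L,
                              product_mz_min = 200, product_mz_max = 1500,
                              precursor_exclusion_halfwidth = 1.0,
                              allowed_series = c("b", "y"),
                              allowed_fragment_charges = c(1L, 2L),
                              terminal_trim = TRUE) {
  if (!(min_count <= quant_max && quant_max <= report_max))
    prm_stop("need min_count <= quant_max <= report_max", "prm_domain_error")
  if (!(product_mz_min < product_mz_max))
    prm_stop("need product_mz_min < product_mz_max", "prm_domain_error")
  structure(list(min_count = as.integer(min_count),
                 quant_max = as.integer(quant_max),
                 report_max = as.integer(report_max),
                 product_mz_min = product_mz_min, product_mz_max = product_mz_max,
                 precursor_exclusion_halfwidth = precursor_exclusion_halfwidth,
                 allowed_series = allowed_series,
                 allowed_fragment_charges = as.integer(allowed_fragment_charges),
                 terminal_trim = isTRUE(terminal_trim)),
            class = "transition_policy")
}

# Core filter: returns the policy-passing subset of a fragment table,
# ordered by descending intensity (ties by ascending m/z), untruncated.
filter_fragments <- function(fragments, bare_sequence, policy, isolation_center) {
  if (is.null(fragments) || nrow(fragments) == 0L) return(fragments)
  lab <- parse_ion_label(fragments$label)
  keep <- !is.na(lab$series) &
    lab$series %in% policy$allowed_series &
    lab$charge %in% policy$allowed_fragment_charges &
    fragments$mz >= policy$product_mz_min &
    fragments$mz <= policy$product_mz_max &
    abs(fragments$mz - isolation_center) > policy$precursor_exclusion_halfwidth
  if (policy$terminal_trim) {
    n <- nchar(bare_sequence)
    keep <- keep & lab$index >= 3L & lab$index <= n - 2L
  }
  out <- fragments[which(keep), , drop = FALSE]
  out[order(-out$intensity, out$mz), , drop = FALSE]
}

entry_fields <- function(entry) {
  # Accept either a one-row peptide_library slice or a plain list.
  if (is.data.frame(entry)) {
    stopifnot(nrow(entry) == 1L)
    list(fragments = entry$fragments[[1]], bare = entry$bare_sequence,
         mz = entry$precursor_mz, pint = entry$precursor_intensity,
         source = entry$source)
  } else {
    list(fragments = entry$fragments, bare = entry$bare_sequence,
         mz = entry$precursor_mz, pint = entry$precursor_intensity %||% NA_real_,
         source = entry$source %||% NA_character_)
  }
}

#' Select diagnostic transitions for one library entry
#'
#' Applies the [transition_policy()] filters and returns up to
#' `report_max` surviving fragments ordered by descending intensity
#' (ties by ascending m/z). An empty result is allowed; eligibility is
#' the caller's decision.
#'
#' @param entry a one-row `peptide_library` slice or an equivalent list
#'   with `fragments`, `bare_sequence`, `precursor_mz`.
#' @param policy a `transition_policy`.
#' @param isolation_center center of the PRM isolation window; defaults
#'   to the entry's precursor m/z.
#' @return fragment data frame (`label`, `mz`, `intensity`).
#' @export
select_transitions <- function(entry, policy = transition_policy(),
                               isolation_center = NULL) {
  f <- entry_fields(entry)
  center <- isolation_center %||% f$mz
  out <- filter_fragments(f$fragments, f$bare, policy, center)
  utils::head(out, policy$report_max)
}

#' Score a DDA library entry
#'
#' The scheduling priority of a DDA (spectrum-library) peptide is its
#' precursor intensity; if that is absent the sum of fragment
#' intensities is used, and a peptide with neither scores 0 with a
#' warning.
#'
#' @param entry a one-row `peptide_library` slice or list.
#' @return non-negative score.
#' @export
score_dda <- function(entry) {
  f <- entry_fields(entry)
  if (is.finite(f$pint)) return(f$pint)
  if (!is.null(f$fragments) && nrow(f$fragments) > 0L)
    return(sum(f$fragments$intensity))
  warning("DDA entry has neither precursor intensity nor fragments; score 0",
          call. = FALSE)
  0
}

#' Score a DIA library entry
#'
#' The priority of a DIA (chromatogram-library) peptide is the intensity
#' of its third-largest fragment ion, following the SRM/PRM convention
#' of requiring at least three transitions. The order statistic is taken
#' over the policy-passing fragments, so the score reflects usable
#' transitions; entries with fewer than `min_count` passing fragments
#' score 0 and are flagged ineligible.
#'
#' @inheritParams select_transitions
#' @return list with `score` and logical `eligible`.
#' @export
score_dia <- function(entry, policy = transition_policy(),
                      isolation_center = NULL) {
  f <- entry_fields(entry)
  center <- isolation_center %||% f$mz
  passing <- filter_fragments(f$fragments, f$bare, policy, center)
  n <- if (is.null(passing)) 0L else nrow(passing)
  if (n < policy$min_count) return(list(score = 0, eligible = FALSE))
  list(score = sort(passing$intensity, decreasing = TRUE)[3L], eligible = TRUE)
}

#' Build ranked scheduling candidates from a library
#'
#' Keeps library entries mapping to at least one resolved target
#' accession (or forced via the inclusion list), drops excluded
#' peptides, scores each entry per its source (DDA: precursor intensity;
#' DIA: third-largest passing fragment), and attaches selected
#' transitions. Output is sorted with forced candidates first, then by
#' descending score; ties break lexicographically on bare sequence then
#' ascending charge, so schedules are reproducible across runs.
#'
#' @param library a `peptide_library`.
#' @param accessions character vector of resolved target accessions
#'   (see [resolve_targets()]).
#' @param policy a `transition_policy`.
#' @param forced bare sequences to force into the assay (bypass
#'   target-protein filtering and, downstream, the protein cap).
#' @param excluded bare sequences to drop.
#' @return a `prm_candidates` data frame with list-columns `proteins`
#'   (credited target accessions) and `transitions`; attributes
#'   `n_excluded` and `missing_forced` record bookkeeping for the
#'   report.
#' @export
build_candidates <- function(library, accessions, policy = transition_policy(),
                             forced = character(0), excluded = character(0)) {
  stopifnot(is.data.frame(library))
  n <- nrow(library)
  excl <- library$bare_sequence %in% excluded
  n_excluded <- sum(excl)
  lib <- library[!excl, , drop = FALSE]

  credited <- lapply(lib$proteins, intersect, x = accessions)
  is_forced <- lib$bare_sequence %in% forced
  keep <- vapply(credited, length, integer(1)) > 0L | is_forced
  lib <- lib[keep, , drop = FALSE]
  credited <- credited[keep]
  is_forced <- is_forced[keep]

  missing_forced <- setdiff(forced, lib$bare_sequence)
  if (length(missing_forced))
    warning(sprintf("forced peptide(s) not found in library: %s",
                    paste(missing_forced, collapse = ", ")), call. = FALSE)

  m <- nrow(lib)
  score <- numeric(m); eligible <- rep(TRUE, m)
  transitions <- vector("list", m)
  for (i in seq_len(m)) {
    entry <- list(fragments = lib$fragments[[i]], bare_sequence = lib$bare_sequence[i],
                  precursor_mz = lib$precursor_mz[i],
                  precursor_intensity = lib$precursor_intensity[i],
                  source = lib$source[i])
    if (identical(lib$source[i], "DDA")) {
      score[i] <- score_dda(entry)
    } else {
      s <- score_dia(entry, policy)
      score[i] <- s$score
      eligible[i] <- s$eligible
    }
    transitions[[i]] <- select_transitions(entry, policy)
  }

  cand <- data.frame(modified_sequence = lib$modified_sequence,
                     bare_sequence = lib$bare_sequence,
                     precursor_charge = lib$precursor_charge,
                     precursor_mz = lib$precursor_mz,
                     retention_time = lib$retention_time,
                     score = score, forced = is_forced,
                     ineligible = !eligible, stringsAsFactors = FALSE)
  cand$proteins <- credited
  cand$transitions <- transitions
  ord <- order(!cand$forced, -cand$score, cand$bare_sequence, cand$precursor_charge)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  class(cand) <- c("prm_candidates", "data.frame")
  attr(cand, "n_excluded") <- n_excluded
  attr(cand, "missing_forced") <- missing_forced
  cand
}

#' Coerce a plain data frame into scheduling candidates
#'
#' Fills defaults for optional columns so the scheduler can be driven
#' directly (e.g. in simulations) without a full library: `forced` and
#' `ineligible` default to `FALSE`, `modified_sequence` to
#' `bare_sequence`, `transitions` to empty, `precursor_mz` to 500.
#'
#' @param df data frame with at least `bare_sequence`,
#'   `precursor_charge`, `retention_time`, `score`, and a `proteins`
#'   list-column.
#' @return a `prm_candidates` data frame sorted for scheduling.
#' @export
as_candidates <- function(df) {
  need <- c("bare_sequence", "precursor_charge", "retention_time", "score", "proteins")
  missing <- setdiff(need, names(df))
  if (length(missing))
    prm_stop(sprintf("missing candidate column(s): %s", paste(missing, collapse = ", ")),
             "prm_schema_error")
  if (is.null(df$modified_sequence)) df$modified_sequence <- df$bare_sequence
  if (is.null(df$forced)) df$forced <- FALSE
  if (is.null(df$ineligible)) df$ineligible <- FALSE
  if (is.null(df$precursor_mz)) df$precursor_mz <- 500
  if (is.null(df$transitions))
    df$transitions <- replicate(nrow(df), data.frame(
      label = character(0), mz = numeric(0), intensity = numeric(0)), simplify = FALSE)
  ord <- order(!df$forced, -df$score, df$bare_sequence, df$precursor_charge)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("prm_candidates", "data.frame")
  df
}
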