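#' Synthetic library configuration
#'
#' Describes the simulated proteome used for testing the workflow end to
#' end with known ground truth: a bank of proteins, each contributing
#' tryptic peptides with log-normal abundances, retention times uniform
#' over the gradient interior, and b/y fragment ions whose third-largest
#' intensity equals the intended abundance (so the DIA ranking score is
#' known exactly by construction).
#'
#' @param n_proteins number of proteins.
#' @param peptides_per_protein peptides per protein.
#' @param gradient `c(start, end)` minutes (default 0-50, matching a
#'   50-minute analytical gradient).
#' @param abundance_meanlog,abundance_sdlog log-normal abundance
#'   parameters (ln-area units; defaults ln(1e5) and 1.5 give the
#'   several-orders-of-magnitude spread typical of MS libraries).
#' @param fragment_range `c(min, max)` fragments per peptide.
#' @param charges precursor charges to draw from.
#' @param allow_missed_cleavage if `TRUE`, ~20% of peptides carry one
#'   internal K/R.
#' @param seed RNG seed; identical seeds give identical libraries.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_proteins = 20L, peptides_per_protein = 5L,
                       gradient = c(0, 50), abundance_meanlog = log(1e5),
                       abundance_sdlog = 1.5, fragment_range = c(6L, 12L),
                       charges = c(2L, 3L), allow_missed_cleavage = FALSE,
                       seed = 1L) {
  if (n_proteins < 1L || peptides_per_protein < 1L)
    prm_stop("counts must be >= 1", "prm_domain_error")
  if (!(gradient[1] < gradient[2]))
    prm_stop("invalid gradient", "prm_domain_error")
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 gradient = gradient, abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 fragment_range = as.integer(fragment_range),
                 charges = as.integer(charges),
                 allow_missed_cleavage = isTRUE(allow_missed_cleavage),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.SIM_DESC_WORDS <- c("granzyme", "interleukin", "kinase", "receptor",
                     "transcription factor", "cytokine", "phosphatase",
                     "transporter")

# One random tryptic peptide: internal residues exclude K/R (zero missed
# cleavages) unless allowed, C-terminal K or R.
random_tryptic <- function(len, allow_missed) {
  internal <- setdiff(names(.RESIDUE_MONO), c("K", "R"))
  aa <- sample(internal, len - 1L, replace = TRUE)
  if (allow_missed && stats::runif(1) < 0.2)
    aa[sample(seq_len(len - 2L), 1L)] <- sample(c("K", "R"), 1L)
  paste0(paste(aa, collapse = ""), sample(c("K", "R"), 1L))
}

#' Generate a synthetic DIA chromatogram library with ground truth
#'
#' Every peptide's fragment set is drawn from the policy-allowed ion
#' space (b/y, index 3 to length-2, product m/z 200-1500, outside the
#' precursor exclusion band) and scaled so the third-largest fragment
#' intensity equals the peptide's drawn abundance; the intended DIA
#' ranking is therefore known exactly. Protein sequences are the
#' concatenation of their peptides, so FASTA resolution and digestion
#' assumptions hold by construction.
#'
#' @param config a [sim_config()].
#' @return list with `library` (a `peptide_library`), `proteins` (an
#'   `accession_index`), and `truth` (data frame with the intended
#'   abundance/score per precursor).
#' @export
generate_library <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    gr <- config$gradient
    lo <- gr[1] + 0.05 * diff(gr)
    hi <- gr[2] - 0.05 * diff(gr)
    entries <- list()
    prot_acc <- sprintf("SIMP%04d", seq_len(config$n_proteins))
    prot_desc <- sprintf("Synthetic %s protein %d",
                         sample(.SIM_DESC_WORDS, config$n_proteins, replace = TRUE),
                         seq_len(config$n_proteins))
    prot_seq <- character(config$n_proteins)
    seen <- character(0)
    for (p in seq_len(config$n_proteins)) {
      peps <- character(config$peptides_per_protein)
      for (j in seq_len(config$peptides_per_protein)) {
        repeat {
          bare <- random_tryptic(sample(9:18, 1L), config$allow_missed_cleavage)
          if (bare %in% seen) next
          charge <- sample(config$charges, 1L)
          mod <- gsub("C", "C[+57.0215]", bare, fixed = TRUE)
          pmz <- precursor_mz(mod, charge)
          ions <- expand.grid(series = c("b", "y"),
                              index = 3:(nchar(bare) - 2L),
                              stringsAsFactors = FALSE)
          ions$mz <- mapply(function(s, k) fragment_mz(bare, s, k), ions$series, ions$index)
          # carbamidomethyl mass on C-containing fragments
          if (grepl("C", bare, fixed = TRUE)) {
            aa <- strsplit(bare, "")[[1]]
            ncs_b <- cumsum(aa == "C")
            ncs_y <- rev(cumsum(rev(aa == "C")))
            nc <- ifelse(ions$series == "b", ncs_b[ions$index],
                         ncs_y[nchar(bare) - ions$index + 1L])
            ions$mz <- ions$mz + 57.0215 * nc
          }
          ions <- ions[ions$mz >= 200 & ions$mz <= 1500 & abs(ions$mz - pmz) > 1.5, ]
          if (nrow(ions) >= 3L) break
        }
        seen <- c(seen, bare)
        peps[j] <- bare
        k <- min(sample(config$fragment_range[1]:config$fragment_range[2], 1L),
                 nrow(ions))
        pick <- ions[sample(nrow(ions), k), , drop = FALSE]
        abundance <- stats::rlnorm(1, config$abundance_meanlog, config$abundance_sdlog)
        raw <- exp(stats::rnorm(k))
        ints <- raw * abundance / sort(raw, decreasing = TRUE)[3L]
        frag <- data.frame(label = sprintf("%s%d^1", pick$series, pick$index),
                           mz = pick$mz, intensity = ints,
                           stringsAsFactors = FALSE)
        frag <- frag[order(frag$mz), , drop = FALSE]
        rownames(frag) <- NULL
        entries[[length(entries) + 1L]] <- list(
          modified_sequence = mod, bare_sequence = bare,
          precursor_charge = charge, precursor_mz = pmz,
          retention_time = stats::runif(1, lo, hi), abundance = abundance,
          accession = prot_acc[p], fragments = frag)
      }
      prot_seq[p] <- paste(peps, collapse = "")
    }

    lib <- data.frame(
      modified_sequence = vapply(entries, `[[`, character(1), "modified_sequence"),
      precursor_charge = vapply(entries, `[[`, integer(1), "precursor_charge"),
      precursor_mz = vapply(entries, `[[`, numeric(1), "precursor_mz"),
      retention_time = vapply(entries, `[[`, numeric(1), "retention_time"),
      precursor_intensity = NA_real_,
      bare_sequence = vapply(entries, `[[`, character(1), "bare_sequence"),
      stringsAsFactors = FALSE)
    lib$proteins <- lapply(entries, function(e) e$accession)
    lib$fragments <- lapply(entries, `[[`, "fragments")
    lib$source <- "DIA"
    class(lib) <- c("peptide_library", "data.frame")

    proteins <- data.frame(accession = prot_acc, description = prot_desc,
                           sequence = prot_seq, stringsAsFactors = FALSE)
    class(proteins) <- c("accession_index", "data.frame")

    truth <- data.frame(
      modified_sequence = lib$modified_sequence,
      precursor_charge = lib$precursor_charge,
      accession = vapply(entries, `[[`, character(1), "accession"),
      abundance = vapply(entries, `[[`, numeric(1), "abundance"),
      retention_time = lib$retention_time, stringsAsFactors = FALSE)

    list(library = lib, proteins = proteins, truth = truth)
  })
}

#' Generate an observed retention-time table with known drift
#'
#' Applies `observed = slope * library_rt + intercept` plus Gaussian
#' jitter, replacing a seeded fraction of rows with uniform gross
#' outliers (mis-picked apexes). Ground truth `(slope, intercept)` is
#' attached as attribute `truth`.
#'
#' @param library a `peptide_library`.
#' @param slope,intercept affine drift (default 1.1 and 2 min, a mild
#'   column-aging drift).
#' @param jitter_sd apex jitter sd in minutes (default 0.1).
#' @param outlier_fraction fraction of rows replaced by uniform
#'   outliers (default 0.1).
#' @param seed RNG seed.
#' @return data frame `modified_sequence`, `precursor_charge`,
#'   `observed_rt` (floored at 0).
#' @export
generate_observed_rt <- function(library, slope = 1.1, intercept = 2.0,
                                 jitter_sd = 0.1, outlier_fraction = 0.1,
                                 seed = 1L) {
  if (nrow(library) == 0L) prm_stop("library is empty", "prm_validation_error")
  with_seed(seed, {
    n <- nrow(library)
    obs <- slope * library$retention_time + intercept +
      stats::rnorm(n, 0, jitter_sd)
    n_out <- round(outlier_fraction * n)
    if (n_out > 0) {
      idx <- sample(n, n_out)
      obs[idx] <- stats::runif(n_out, min(obs), max(obs))
    }
    out <- data.frame(modified_sequence = library$modified_sequence,
                      precursor_charge = library$precursor_charge,
                      observed_rt = pmax(obs, 0), stringsAsFactors = FALSE)
    attr(out, "truth") <- list(slope = slope, intercept = intercept)
    out
  })
}

#' Synthetic calibration-curve configuration
#'
#' Emulates a matrix-matched dilution series: a two-fold serial dilution
#' of the unlabeled foreground into a labeled background (eight nonzero
#' levels spanning just over two orders of magnitude, plus a blank),
#' measured in technical triplicate with a constant relative (CV) noise
#' model around a bilinear mean response.
#'
#' @param true_breakpoint dilution at which signal leaves the noise
#'   floor.
#' @param slope area per unit dilution.
#' @param noise_floor background area level.
#' @param replicate_cv relative sd of replicates (default 0.05).
#' @param dilution_levels dilution fractions, descending, spanning >= 2
#'   orders of magnitude, blank (0) included.
#' @param n_replicates replicates per level (>= 3, matching technical
#'   triplicates).
#' @param seed RNG seed.
#' @return a `curve_sim_config`.
#' @export
curve_sim_config <- function(true_breakpoint = 0.05, slope = 1e6,
                             noise_floor = 1e4, replicate_cv = 0.05,
                             dilution_levels = c(2^-(0:7), 0),
                             n_replicates = 3L, seed = 1L) {
  lv <- sort(dilution_levels, decreasing = TRUE)
  pos <- lv[lv > 0]
  if (length(pos) < 2L || max(pos) / min(pos) < 100)
    prm_stop("dilution levels must span >= 2 orders of magnitude", "prm_domain_error")
  if (n_replicates < 3L)
    prm_stop("n_replicates must be >= 3", "prm_domain_error")
  structure(list(true_breakpoint = true_breakpoint, slope = slope,
                 noise_floor = noise_floor, replicate_cv = replicate_cv,
                 dilution_levels = lv, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "curve_sim_config")
}

#' Generate a synthetic calibration curve
#'
#' Mean response is bilinear in dilution
#' (`noise_floor + slope * max(0, x - breakpoint)`); replicates are
#' Gaussian with sd = `replicate_cv` times the mean, truncated at zero.
#' The generating configuration is attached as attribute `truth`.
#'
#' @param config a [curve_sim_config()].
#' @return data frame `dilution`, `replicate`, `area`.
#' @export
generate_curve <- function(config = curve_sim_config()) {
  stopifnot(inherits(config, "curve_sim_config"))
  with_seed(config$seed, {
    lv <- rep(config$dilution_levels, each = config$n_replicates)
    mu <- config$noise_floor + config$slope * pmax(0, lv - config$true_breakpoint)
    area <- pmax(stats::rnorm(length(lv), mu, config$replicate_cv * mu), 0)
    out <- data.frame(dilution = lv,
                      replicate = rep(seq_len(config$n_replicates),
                                      times = length(config$dilution_levels)),
                      area = area)
    attr(out, "truth") <- config
    out
  })
}
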