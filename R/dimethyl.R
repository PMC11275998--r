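# Mass added by one methyl group (CH2): monoisotopic and nominal.
.METHYL_MONO <- 14.01565
.METHYL_NOMINAL <- 14

methyl_delta <- function(mode = c("monoisotopic", "nominal")) {
  mode <- match.arg(mode)
  if (mode == "monoisotopic") .METHYL_MONO else .METHYL_NOMINAL
}

#' Count dimethyl labeling sites on a peptide
#'
#' Reductive dimethylation labels free amines: the peptide N-terminus
#' plus every lysine side chain, so sites = 1 + #K. Proline N-termini
#' and modified lysines are still counted: the downstream use is a
#' worst-case background-exclusion argument, and overcounting sites can
#' never weaken that check while undercounting could.
#'
#' @param bare_sequence uppercase amino-acid string(s).
#' @return integer number of labeling sites per peptide.
#' @export
#' @examples
#' label_sites("ECESYFK")   # 2
#' label_sites("TQQVIPMVR") # 1
label_sites <- function(bare_sequence) {
  if (any(!nzchar(bare_sequence)))
    prm_stop("empty peptide sequence", "prm_domain_error")
  if (any(grepl("[^A-Z]", bare_sequence)))
    prm_stop("bare sequence must be uppercase amino-acid letters", "prm_domain_error")
  1L + vapply(strsplit(bare_sequence, ""), function(a) sum(a == "K"), integer(1))
}

#' Mass shift from methylation of labeling sites
#'
#' `n_sites * methyls_per_site * delta`, where delta is 14.01565 Da
#' monoisotopic (CH2) or 14 Da nominal. A fully dimethylated amine
#' (2 methyls) shifts by 28 Da nominal.
#'
#' @param n_sites number of labeled sites (>= 0).
#' @param methyls_per_site 1 (incomplete reaction) or 2 (full dimethyl).
#' @param mode `"monoisotopic"` or `"nominal"`.
#' @return mass shift in Da.
#' @export
mass_shift <- function(n_sites, methyls_per_site = 2L,
                       mode = c("monoisotopic", "nominal")) {
  if (any(n_sites < 0)) prm_stop("n_sites must be >= 0", "prm_domain_error")
  if (!all(methyls_per_site %in% c(1L, 2L)))
    prm_stop("methyls_per_site must be 1 or 2", "prm_domain_error")
  n_sites * methyls_per_site * methyl_delta(mode)
}

#' Worst-case precursor m/z shift of a labeled background peptide
#'
#' The smallest possible shift is a single methyl group on a single
#' site: `delta / charge` m/z. If even this worst case clears the
#' isolation half-width, every (partially) labeled form of the peptide
#' falls outside the PRM isolation window.
#'
#' @param bare_sequence peptide (unused in the arithmetic; kept for
#'   interface symmetry with [label_sites()]).
#' @param charge precursor charge (>= 1).
#' @param mode `"monoisotopic"` or `"nominal"`.
#' @return minimum m/z shift.
#' @export
min_precursor_mz_shift <- function(bare_sequence = NULL, charge,
                                   mode = c("monoisotopic", "nominal")) {
  if (any(charge < 1)) prm_stop("charge must be >= 1", "prm_domain_error")
  methyl_delta(mode) / charge
}

#' Validate matched-matrix background exclusion for a schedule
#'
#' For every scheduled target, checks that the worst-case labeled
#' background precursor (single methyl, highest considered charge)
#' shifts by more than half the isolation window, so foreground PRM
#' signals cannot be confused with the dimethyl-labeled background.
#'
#' @param schedule a `prm_schedule` (its config supplies the isolation
#'   width).
#' @param max_charge highest precursor charge considered (default 3).
#' @param mode `"monoisotopic"` or `"nominal"`.
#' @return data frame with one row per target: `compound`,
#'   `worst_charge`, `min_shift_mz`, `half_width_mz`, `margin_mz`,
#'   `pass`.
#' @export
validate_background_exclusion <- function(schedule, max_charge = 3L,
                                          mode = c("monoisotopic", "nominal")) {
  mode <- match.arg(mode)
  tg <- schedule$targets
  half <- schedule$config$isolation_width / 2
  if (is.null(tg) || nrow(tg) == 0L)
    return(data.frame(compound = character(0), worst_charge = integer(0),
                      min_shift_mz = numeric(0), half_width_mz = numeric(0),
                      margin_mz = numeric(0), pass = logical(0)))
  shift <- min_precursor_mz_shift(tg$bare_sequence, max_charge, mode)
  data.frame(compound = paste0(tg$modified_sequence, ".", tg$precursor_charge),
             worst_charge = as.integer(max_charge),
             min_shift_mz = shift, half_width_mz = half,
             margin_mz = shift - half, pass = shift > half,
             stringsAsFactors = FALSE)
}
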