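# Monoisotopic residue masses (Da). Cysteine is the free residue;
# carbamidomethylation is written explicitly in modified sequences as
# C[+57.0215] and applied through the bracket notation.
.RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_WATER  <- 18.010565
.MASS_PROTON <- 1.007276

#' Monoisotopic peptide mass
#'
#' Sums residue masses plus water, plus any bracketed delta masses in the
#' modified sequence (e.g. `"C[+57.0215]"` adds 57.0215 Da).
#'
#' @param modified_sequence peptide string, optionally with bracketed
#'   modification masses.
#' @return monoisotopic mass in Da.
#' @export
peptide_mass <- function(modified_sequence) {
  vapply(modified_sequence, function(seq) {
    bare <- strip_modifications(seq)
    if (!nzchar(bare)) prm_stop("empty peptide sequence", "prm_domain_error")
    aa <- strsplit(bare, "")[[1]]
    unknown <- setdiff(aa, names(.RESIDUE_MONO))
    if (length(unknown))
      prm_stop(sprintf("unknown residue(s): %s", paste(unique(unknown), collapse = ",")),
               "prm_domain_error")
    mods <- regmatches(seq, gregexpr("\\[[^][]*\\]", seq))[[1]]
    dmass <- if (length(mods)) sum(as.numeric(gsub("[][]", "", mods))) else 0
    sum(.RESIDUE_MONO[aa]) + .MASS_WATER + dmass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Precursor m/z of a peptide at a given charge
#' @param modified_sequence peptide string.
#' @param charge precursor charge (>= 1).
#' @return m/z in Thomson.
#' @export
precursor_mz <- function(modified_sequence, charge) {
  if (any(charge < 1)) prm_stop("charge must be >= 1", "prm_domain_error")
  (peptide_mass(modified_sequence) + charge * .MASS_PROTON) / charge
}

# m/z of a b or y fragment (bare sequence, singly/doubly charged).
fragment_mz <- function(bare_sequence, series, index, frag_charge = 1L) {
  aa <- strsplit(bare_sequence, "")[[1]]
  n <- length(aa)
  if (index < 1L || index >= n)
    prm_stop("fragment index out of range", "prm_domain_error")
  if (series == "y") {
    resid <- sum(.RESIDUE_MONO[aa[(n - index + 1L):n]])
    neutral <- resid + .MASS_WATER
  } else if (series == "b") {
    neutral <- sum(.RESIDUE_MONO[aa[1:index]])
  } else prm_stop("series must be 'b' or 'y'", "prm_domain_error")
  (neutral + frag_charge * .MASS_PROTON) / frag_charge
}

# Parse ion labels like "y5^1", "b7", "y12^2" into series/index/charge.
# Unparseable labels yield NA series and are filtered out downstream.
parse_ion_label <- function(labels) {
  m <- regmatches(labels, regexec("^([abcxyz])([0-9]+)(\\^([0-9]+))?$", labels))
  series <- vapply(m, function(p) if (length(p)) p[2] else NA_character_, character(1))
  index <- vapply(m, function(p) if (length(p)) as.integer(p[3]) else NA_integer_, integer(1))
  charge <- vapply(m, function(p) {
    if (!length(p)) return(NA_integer_)
    if (nzchar(p[5])) as.integer(p[5]) else 1L
  }, integer(1))
  data.frame(series = series, index = index, charge = charge,
             stringsAsFactors = FALSE)
}
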