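# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Minimal DIA library TSV: one precursor, three fragment rows by default.
write_dia_fixture <- function(path, rows = NULL) {
  header <- paste(c("ModifiedSequence", "PrecursorCharge", "PrecursorMz",
                    "RetentionTime", "ProteinAccessions", "FragmentLabel",
                    "FragmentMz", "FragmentIntensity"), collapse = "\t")
  if (is.null(rows)) {
    rows <- c(
      "PEPTIDEK\t2\t450.7300\t20.5\tP1\ty4^1\t500.30\t1000",
      "PEPTIDEK\t2\t450.7300\t20.5\tP1\ty5^1\t613.38\t800",
      "PEPTIDEK\t2\t450.7300\t20.5\tP1\tb3^1\t324.16\t500")
  }
  writeLines(c(header, rows), path)
  path
}

write_dda_fixture <- function(path, rows = NULL) {
  header <- paste(c("ModifiedSequence", "PrecursorCharge", "PrecursorMz",
                    "RetentionTime", "ProteinAccessions", "PrecursorIntensity"),
                  collapse = "\t")
  if (is.null(rows)) {
    rows <- c("PEPTIDEK\t2\t450.7300\t20.5\tP1\t1e6",
              "ELVISLIVESK\t2\t614.8600\t30.2\tP2;P3\t2e6")
  }
  writeLines(c(header, rows), path)
  path
}

write_fasta_fixture <- function(path, records = NULL) {
  if (is.null(records)) {
    records <- c(">sp|P1|GRAB_MOUSE Granzyme B", "PEPTIDEKSEQK",
                 ">P2 Interleukin receptor", "ELVISLIVESKAAAK")
  }
  writeLines(records, path)
  path
}

# Fragment table with well-formed labels spaced away from the precursor.
frag_table <- function(intensities, mz = NULL, series = "y",
                       index = NULL, frag_charge = 1L) {
  n <- length(intensities)
  if (is.null(index)) index <- seq(3L, length.out = n)
  if (is.null(mz)) mz <- 300 + 50 * seq_len(n)
  data.frame(label = sprintf("%s%d^%d", series, index, frag_charge),
             mz = mz, intensity = intensities, stringsAsFactors = FALSE)
}

# A synthetic library entry as a plain list (accepted by the ranking API).
make_entry <- function(bare = "ACDEFGHILMNPQSTVWYK", charge = 2L, mz = 600,
                       rt = 20, source = "DIA", precursor_intensity = NA_real_,
                       fragments = frag_table(c(1000, 800, 500, 200))) {
  list(modified_sequence = bare, bare_sequence = bare, precursor_charge = charge,
       precursor_mz = mz, retention_time = rt, precursor_intensity = precursor_intensity,
       proteins = "P1", fragments = fragments, source = source)
}

# Random scheduler instance: a candidate frame drawn directly (scores,
# RTs, protein assignments), bypassing the full library generator so
# large property sweeps stay fast.
random_instance <- function(n, seed, gradient_end = 50, n_proteins = max(2L, n %/% 3L),
                            forced_fraction = 0.05) {
  set.seed(seed)
  prots <- sprintf("PR%03d", seq_len(n_proteins))
  df <- data.frame(
    bare_sequence = sprintf("PEP%05dK", seq_len(n)),
    precursor_charge = sample(2:3, n, replace = TRUE),
    retention_time = runif(n, 0, gradient_end),
    score = runif(n, 1, 1e6),
    forced = runif(n) < forced_fraction,
    stringsAsFactors = FALSE)
  df$proteins <- lapply(seq_len(n), function(i)
    sample(prots, sample(1:2, 1, prob = c(0.9, 0.1))))
  as_candidates(df)
}

random_config <- function(seed, gradient_end = 50) {
  set.seed(seed + 77777L)
  schedule_config(max_density = sample(1:8, 1), gradient_end = gradient_end,
                  window_width = runif(1, 1, 8),
                  per_protein_cap = sample(3:5, 1))
}
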