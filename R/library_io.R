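#' Read a peptide library table
#'
#' Reads the flat TSV library exchange format. Two dialects are
#' supported. The DIA (chromatogram-library) dialect carries one row per
#' fragment ion with columns `ModifiedSequence`, `PrecursorCharge`,
#' `PrecursorMz`, `RetentionTime`, `ProteinAccessions` (semicolon
#' joined), `FragmentLabel`, `FragmentMz`, `FragmentIntensity`. The DDA
#' (spectrum-library) dialect carries one row per precursor with
#' `PrecursorIntensity` instead of the fragment columns; fragment rows
#' may additionally be present using the DIA columns.
#'
#' Rows sharing a (`ModifiedSequence`, `PrecursorCharge`) key are
#' aggregated into a single library entry whose fragment list collects
#' the fragment rows. Conflicting precursor-level fields, or duplicated
#' precursor rows in the DDA dialect, are rejected.
#'
#' @param path path to the TSV file.
#' @param dialect `"DIA"` or `"DDA"`.
#' @return a `peptide_library` data frame with one row per precursor and
#'   list-columns `proteins` (character vectors) and `fragments`
#'   (data frames with `label`, `mz`, `intensity`).
#' @export
read_library <- function(path, dialect = c("DIA", "DDA")) {
  dialect <- match.arg(toupper(dialect), c("DIA", "DDA"))
  if (!file.exists(path)) prm_stop(sprintf("file not found: %s", path), "prm_io_error")
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           colClasses = list(character = "ModifiedSequence"))
  base_cols <- c("ModifiedSequence", "PrecursorCharge", "PrecursorMz",
                 "RetentionTime", "ProteinAccessions")
  frag_cols <- c("FragmentLabel", "FragmentMz", "FragmentIntensity")
  required <- if (dialect == "DIA") c(base_cols, frag_cols)
              else c(base_cols, "PrecursorIntensity")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    prm_stop(sprintf("missing required column(s) for %s dialect: %s",
                     dialect, paste(missing, collapse = ", ")),
             "prm_schema_error")
  if (nrow(tab) == 0L) return(empty_library(dialect))

  has_frag <- all(frag_cols %in% names(tab))
  row_ids <- seq_len(nrow(tab))
  check_nonneg <- function(col) {
    if (!col %in% names(tab)) return(invisible())
    bad <- which(!is.na(tab[[col]]) & tab[[col]] < 0)
    if (length(bad))
      prm_stop(sprintf("negative %s at row %d", col, bad[1]), "prm_validation_error")
  }
  check_nonneg("RetentionTime")
  check_nonneg("FragmentIntensity")
  check_nonneg("PrecursorIntensity")
  bad_mz <- which(!is.na(tab$PrecursorMz) & tab$PrecursorMz <= 0)
  if (length(bad_mz))
    prm_stop(sprintf("non-positive PrecursorMz at row %d", bad_mz[1]),
             "prm_validation_error")

  key <- paste(tab$ModifiedSequence, tab$PrecursorCharge, sep = "\r")
  is_frag_row <- if (has_frag) !is.na(tab$FragmentMz) & nzchar(as.character(tab$FragmentLabel))
                 else rep(FALSE, nrow(tab))

  if (dialect == "DDA") {
    prec_rows <- which(!is_frag_row)
    dup <- duplicated(key[prec_rows])
    if (any(dup)) {
      k <- strsplit(key[prec_rows][dup][1], "\r")[[1]]
      prm_stop(sprintf("duplicate precursor (%s, +%s) in DDA library", k[1], k[2]),
               "prm_duplicate_error")
    }
  }

  ukeys <- unique(key)
  idx_by_key <- split(row_ids, factor(key, levels = ukeys))
  entries <- lapply(idx_by_key, function(rows) {
    sub <- tab[rows, , drop = FALSE]
    uniq_field <- function(col) {
      v <- unique(sub[[col]][!is.na(sub[[col]])])
      if (length(v) > 1L)
        prm_stop(sprintf("inconsistent %s for precursor %s (+%d)", col,
                         sub$ModifiedSequence[1], sub$PrecursorCharge[1]),
                 "prm_validation_error")
      if (length(v)) v else NA
    }
    frag <- if (has_frag) {
      fr <- sub[is_frag_row[rows], , drop = FALSE]
      data.frame(label = as.character(fr$FragmentLabel), mz = fr$FragmentMz,
                 intensity = fr$FragmentIntensity, stringsAsFactors = FALSE)
    } else data.frame(label = character(0), mz = numeric(0), intensity = numeric(0))
    list(
      modified_sequence = sub$ModifiedSequence[1],
      precursor_charge = as.integer(sub$PrecursorCharge[1]),
      precursor_mz = uniq_field("PrecursorMz"),
      retention_time = uniq_field("RetentionTime"),
      precursor_intensity = if ("PrecursorIntensity" %in% names(sub))
        suppressWarnings(as.numeric(uniq_field("PrecursorIntensity"))) else NA_real_,
      proteins = strsplit(as.character(uniq_field("ProteinAccessions")), ";")[[1]],
      fragments = frag
    )
  })

  lib <- data.frame(
    modified_sequence = vapply(entries, `[[`, character(1), "modified_sequence"),
    precursor_charge = vapply(entries, `[[`, integer(1), "precursor_charge"),
    precursor_mz = vapply(entries, `[[`, numeric(1), "precursor_mz"),
    retention_time = vapply(entries, `[[`, numeric(1), "retention_time"),
    precursor_intensity = vapply(entries, `[[`, numeric(1), "precursor_intensity"),
    stringsAsFactors = FALSE
  )
  lib$bare_sequence <- strip_modifications(lib$modified_sequence)
  lib$proteins <- unname(lapply(entries, `[[`, "proteins"))
  lib$fragments <- unname(lapply(entries, `[[`, "fragments"))
  lib$source <- dialect
  rownames(lib) <- NULL
  bad_acc <- which(!vapply(lib$proteins, function(p) length(p) > 0 && all(nzchar(p)), logical(1)))
  if (length(bad_acc))
    prm_stop(sprintf("empty protein accession for precursor %s",
                     lib$modified_sequence[bad_acc[1]]), "prm_validation_error")
  if (dialect == "DIA") {
    nofrag <- which(vapply(lib$fragments, nrow, integer(1)) == 0L)
    if (length(nofrag))
      prm_stop(sprintf("DIA entry without fragment rows: %s (+%d)",
                       lib$modified_sequence[nofrag[1]], lib$precursor_charge[nofrag[1]]),
               "prm_validation_error")
  }
  class(lib) <- c("peptide_library", "data.frame")
  lib
}

empty_library <- function(dialect = "DIA") {
  lib <- data.frame(modified_sequence = character(0), precursor_charge = integer(0),
                    precursor_mz = numeric(0), retention_time = numeric(0),
                    precursor_intensity = numeric(0), bare_sequence = character(0),
                    stringsAsFactors = FALSE)
  lib$proteins <- list()
  lib$fragments <- list()
  lib$source <- character(0)
  class(lib) <- c("peptide_library", "data.frame")
  attr(lib, "dialect") <- dialect
  lib
}

#' Write a peptide library table
#'
#' Serializes a library back to the flat TSV exchange format (see
#' [read_library()]); the inverse of reading, up to numeric formatting
#' (m/z at 6 decimals, retention times and intensities at 4).
#'
#' @param library a `peptide_library`.
#' @param path output path.
#' @param dialect `"DIA"` (fragment rows) or `"DDA"` (precursor rows).
#' @export
write_library <- function(library, path, dialect = c("DIA", "DDA")) {
  dialect <- match.arg(toupper(dialect), c("DIA", "DDA"))
  fmt <- function(x, d) ifelse(is.na(x), "", formatC(x, format = "f", digits = d))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (dialect == "DIA") {
    writeLines(paste(c("ModifiedSequence", "PrecursorCharge", "PrecursorMz",
                       "RetentionTime", "ProteinAccessions", "FragmentLabel",
                       "FragmentMz", "FragmentIntensity"), collapse = "\t"), con)
    for (i in seq_len(nrow(library))) {
      fr <- library$fragments[[i]]
      if (nrow(fr) == 0L)
        prm_stop("cannot write DIA dialect for an entry without fragments",
                 "prm_validation_error")
      writeLines(paste(library$modified_sequence[i], library$precursor_charge[i],
                       fmt(library$precursor_mz[i], 6), fmt(library$retention_time[i], 4),
                       paste(library$proteins[[i]], collapse = ";"),
                       fr$label, fmt(fr$mz, 6), fmt(fr$intensity, 4), sep = "\t"), con)
    }
  } else {
    writeLines(paste(c("ModifiedSequence", "PrecursorCharge", "PrecursorMz",
                       "RetentionTime", "ProteinAccessions", "PrecursorIntensity"),
                     collapse = "\t"), con)
    for (i in seq_len(nrow(library))) {
      writeLines(paste(library$modified_sequence[i], library$precursor_charge[i],
                       fmt(library$precursor_mz[i], 6), fmt(library$retention_time[i], 4),
                       paste(library$proteins[[i]], collapse = ";"),
                       fmt(library$precursor_intensity[i], 4), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a protein FASTA database into an accession index
#'
#' Headers may be UniProt style (`>db|ACC|NAME Description`) or plain
#' (`>ACC Description`); the accession is the second pipe field or the
#' first whitespace-delimited token, and the description is kept
#' verbatim.
#'
#' @param path FASTA file path.
#' @return an `accession_index` data frame with columns `accession`,
#'   `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) prm_stop(sprintf("file not found: %s", path), "prm_io_error")
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  first_tok <- sub("\\s.*$", "", headers)
  acc <- first_tok
  piped <- grepl("^[^|]+\\|[^|]+\\|", first_tok)
  acc[piped] <- vapply(strsplit(first_tok[piped], "|", fixed = TRUE),
                       `[[`, character(1), 2L)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_chr <- toupper(as.character(seqs))
  if (any(!nzchar(seq_chr)))
    prm_stop(sprintf("empty sequence for record %s", acc[!nzchar(seq_chr)][1]),
             "prm_validation_error")
  dup <- duplicated(acc)
  if (any(dup))
    prm_stop(sprintf("duplicate accession: %s", acc[dup][1]), "prm_duplicate_error")
  idx <- data.frame(accession = unname(acc), description = unname(desc),
                    sequence = unname(seq_chr), stringsAsFactors = FALSE)
  class(idx) <- c("accession_index", "data.frame")
  idx
}

#' Write an accession index as FASTA
#' @param index an `accession_index`.
#' @param path output path.
#' @export
write_fasta <- function(index, path) {
  lines <- as.vector(rbind(
    ifelse(nzchar(index$description),
           paste0(">", index$accession, " ", index$description),
           paste0(">", index$accession)),
    index$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a target list
#'
#' The target file holds one accession per line; lines of the form
#' `keyword: <text>` declare case-insensitive description substrings to
#' match instead. `#` starts a comment. Inclusion/exclusion files hold
#' one bare peptide sequence per line.
#'
#' @param targets_path path to the accession/keyword file.
#' @param include_path optional peptide inclusion list.
#' @param exclude_path optional peptide exclusion list.
#' @return a `prm_targets` list with `accessions`, `keywords`, `forced`,
#'   `excluded` character vectors.
#' @export
read_target_list <- function(targets_path, include_path = NULL, exclude_path = NULL) {
  lines <- read_line_list(targets_path)
  kw <- grepl("^keyword\\s*:", lines, ignore.case = TRUE)
  keywords <- trimws(sub("^keyword\\s*:", "", lines[kw], ignore.case = TRUE))
  forced <- if (!is.null(include_path)) toupper(read_line_list(include_path)) else character(0)
  excluded <- if (!is.null(exclude_path)) toupper(read_line_list(exclude_path)) else character(0)
  both <- intersect(forced, excluded)
  if (length(both))
    prm_stop(sprintf("peptide(s) on both inclusion and exclusion lists: %s",
                     paste(both, collapse = ", ")), "prm_validation_error")
  structure(list(accessions = unique(lines[!kw]), keywords = unique(keywords[nzchar(keywords)]),
                 forced = unique(forced), excluded = unique(excluded)),
            class = "prm_targets")
}

#' Resolve a target list against a FASTA accession index
#'
#' Returns the accessions listed explicitly plus those whose description
#' contains any keyword (case-insensitive substring). Listed accessions
#' absent from the index raise a warning, not an error: target lists are
#' curated against moving FASTA versions.
#'
#' @param index an `accession_index` from [read_fasta()].
#' @param targets a `prm_targets` list, or a character vector of
#'   accessions.
#' @return sorted character vector of resolved accessions.
#' @export
resolve_targets <- function(index, targets) {
  if (is.character(targets)) targets <- list(accessions = targets, keywords = character(0))
  if (nrow(index) == 0L) prm_stop("accession index is empty", "prm_validation_error")
  listed <- targets$accessions %||% character(0)
  unknown <- setdiff(listed, index$accession)
  if (length(unknown))
    warning(sprintf("target accession(s) not in FASTA: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  hit <- intersect(listed, index$accession)
  for (kw in targets$keywords %||% character(0)) {
    hit <- union(hit, index$accession[grepl(tolower(kw), tolower(index$description),
                                            fixed = TRUE)])
  }
  sort(unique(hit))
}

#' Write the instrument inclusion list
#'
#' Emits the method-editor CSV with columns (exact order)
#' `Compound,m/z,z,t start (min),t stop (min)`; `Compound` is
#' `<modified sequence>.<charge>`, m/z is printed to 4 decimals, times
#' to 2. Rows are sorted by window start, ties by ascending m/z.
#'
#' @param schedule a `prm_schedule` from [build_schedule()].
#' @param path output CSV path.
#' @export
write_inclusion_list <- function(schedule, path) {
  tg <- schedule$targets
  if (is.null(tg) || nrow(tg) == 0L)
    prm_stop("refusing to write an empty inclusion list", "prm_validation_error")
  ord <- order(tg$window_start, tg$precursor_mz)
  tg <- tg[ord, , drop = FALSE]
  lines <- c("Compound,m/z,z,t start (min),t stop (min)",
             sprintf("%s.%d,%.4f,%d,%.2f,%.2f",
                     tg$modified_sequence, tg$precursor_charge, tg$precursor_mz,
                     tg$precursor_charge, tg$window_start, tg$window_stop))
  tryCatch(writeLines(lines, path),
           error = function(e) prm_stop(sprintf("cannot write %s: %s", path,
                                                conditionMessage(e)), "prm_io_error"))
  invisible(path)
}

#' Read an inclusion list CSV back into a data frame
#' @param path CSV written by [write_inclusion_list()].
#' @return data frame with columns `compound`, `mz`, `z`, `t_start`,
#'   `t_stop`.
#' @export
read_inclusion_list <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Compound", "m/z", "z", "t start (min)", "t stop (min)")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    prm_stop(sprintf("missing inclusion-list column(s): %s",
                     paste(missing, collapse = ", ")), "prm_schema_error")
  data.frame(compound = tab$Compound, mz = tab[["m/z"]], z = tab$z,
             t_start = tab[["t start (min)"]], t_stop = tab[["t stop (min)"]],
             stringsAsFactors = FALSE)
}

#' Write the scheduling report
#'
#' One TSV row per scheduled target (peptide, charge, proteins, score,
#' library and aligned RT, window bounds, transition labels) followed by
#' a `#`-prefixed footer summarizing scheduled and rejected counts and
#' the peak assay density.
#'
#' @param schedule a `prm_schedule`.
#' @param path output TSV path.
#' @export
write_schedule_report <- function(schedule, path) {
  tg <- schedule$targets
  rej <- schedule$rejections
  header <- paste(c("Peptide", "Charge", "Proteins", "Score", "LibraryRT",
                    "AlignedRT", "WindowStart", "WindowStop", "Transitions",
                    "Forced"), collapse = "\t")
  rows <- character(0)
  if (nrow(tg)) {
    rows <- sprintf("%s\t%d\t%s\t%.6g\t%.4f\t%.4f\t%.4f\t%.4f\t%s\t%s",
                    tg$modified_sequence, tg$precursor_charge,
                    vapply(tg$proteins, paste, character(1), collapse = ";"),
                    tg$score, tg$library_rt, tg$aligned_rt,
                    tg$window_start, tg$window_stop,
                    vapply(tg$transitions, function(f)
                      paste(f$label, collapse = ";"), character(1)),
                    ifelse(tg$forced, "yes", "no"))
  }
  count <- function(reason) sum(rej$reason == reason)
  dens <- density_profile(schedule)
  peak <- if (nrow(dens)) max(dens$concurrent) else 0L
  footer <- c(
    sprintf("# candidates_total\t%d", nrow(tg) + nrow(rej)),
    sprintf("# targets_scheduled\t%d", nrow(tg)),
    sprintf("# rejected_density\t%d", count("density")),
    sprintf("# rejected_protein_cap\t%d", count("protein_cap")),
    sprintf("# rejected_ineligible\t%d", count("ineligible")),
    sprintf("# rejected_excluded\t%d", schedule$n_excluded %||% 0L),
    sprintf("# peak_density\t%d", peak)
  )
  tryCatch(writeLines(c(header, rows, footer), path),
           error = function(e) prm_stop(sprintf("cannot write %s: %s", path,
                                                conditionMessage(e)), "prm_io_error"))
  invisible(path)
}

#' Read the observed retention-time table from a recent DIA run
#'
#' TSV with columns `ModifiedSequence`, `PrecursorCharge`, `ObservedRT`
#' (minutes).
#' @param path TSV path.
#' @return data frame `modified_sequence`, `precursor_charge`,
#'   `observed_rt`.
#' @export
read_observed_rt <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("ModifiedSequence", "PrecursorCharge", "ObservedRT")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    prm_stop(sprintf("missing observed-RT column(s): %s",
                     paste(missing, collapse = ", ")), "prm_schema_error")
  if (any(!is.finite(tab$ObservedRT)) || any(tab$ObservedRT < 0))
    prm_stop("ObservedRT must be finite and >= 0", "prm_validation_error")
  data.frame(modified_sequence = as.character(tab$ModifiedSequence),
             precursor_charge = as.integer(tab$PrecursorCharge),
             observed_rt = as.numeric(tab$ObservedRT), stringsAsFactors = FALSE)
}
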