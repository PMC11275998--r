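#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed package error
#'
#' All hard failures in the package carry a condition class under
#' `prm_error` so callers and tests can discriminate failure modes.
#' @noRd
prm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "prm_error")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores (or removes) `.Random.seed` afterwards so seeded generators
#' never perturb the caller's RNG stream. `seed = NULL` leaves the
#' stream alone.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Strip bracketed modification masses from a peptide string
#'
#' `"C[+57.0215]PEPK"` becomes `"CPEPK"`. Used everywhere a bare
#' sequence is compared against inclusion/exclusion lists or digested
#' for labeling-site counts.
#'
#' @param x character vector of modified peptide sequences.
#' @return character vector of bare sequences.
#' @export
#' @examples
#' strip_modifications("AC[+57.0215]DK")
strip_modifications <- function(x) {
  gsub("\\[[^][]*\\]", "", x)
}

# Read a plain-text list file: one token per line, '#' starts a comment.
read_line_list <- function(path) {
  if (!file.exists(path)) prm_stop(sprintf("file not found: %s", path), "prm_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

# Minimal flat TOML-subset parser: `key = value` lines with string,
# numeric or boolean values. No tables or arrays -- enough to mirror the
# CLI flags from a config file.
read_flat_config <- function(path) {
  lines <- read_line_list(path)
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      prm_stop(sprintf("cannot parse config line: %s", ln), "prm_schema_error")
    key <- m[2]
    val <- trimws(m[3])
    if (grepl('^".*"$', val) || grepl("^'.*'$", val)) {
      val <- substr(val, 2L, nchar(val) - 1L)
    } else if (val %in% c("true", "false")) {
      val <- identical(val, "true")
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
    }
    out[[key]] <- val
  }
  out
}
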