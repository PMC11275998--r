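test_that("DIA fragment rows aggregate into one entry per precursor", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dia_fixture(path)
  lib <- read_library(path, "DIA")
  expect_s3_class(lib, "peptide_library")
  expect_equal(nrow(lib), 1L)
  expect_equal(nrow(lib$fragments[[1]]), 3L)
  expect_equal(lib$bare_sequence, "PEPTIDEK")
  expect_equal(lib$proteins[[1]], "P1")
})

test_that("library aggregation conserves fragment rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "AAAAAAK\t2\t400.1\t10\tP1\ty3^1\t350.1\t10",
    "AAAAAAK\t2\t400.1\t10\tP1\ty4^1\t420.1\t20",
    "CCCCCCK\t3\t500.2\t15\tP2\ty3^1\t360.2\t30",
    "CCCCCCK\t3\t500.2\t15\tP2\ty4^1\t430.2\t40",
    "CCCCCCK\t3\t500.2\t15\tP2\ty5^1\t520.2\t50")
  write_dia_fixture(path, rows)
  lib <- read_library(path, "DIA")
  expect_equal(sum(vapply(lib$fragments, nrow, integer(1))), length(rows))
})

test_that("empty file with valid header gives an empty library", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dia_fixture(path, rows = character(0))
  lib <- read_library(path, "DIA")
  expect_equal(nrow(lib), 0L)
})

test_that("schema and validation errors are classed and informative", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("ModifiedSequence\tPrecursorCharge", path)
  expect_error(read_library(path, "DIA"), "PrecursorMz",
               class = "prm_schema_error")
  # negative retention time with row context
  write_dia_fixture(path, "BADPEPK\t2\t400.1\t-3\tP1\ty3^1\t350.1\t10")
  expect_error(read_library(path, "DIA"), "row 1", class = "prm_validation_error")
  # duplicated DDA precursor rows
  write_dda_fixture(path, c("PEPTIDEK\t2\t450.73\t20.5\tP1\t1e6",
                            "PEPTIDEK\t2\t450.73\t20.5\tP1\t2e6"))
  expect_error(read_library(path, "DDA"), class = "prm_duplicate_error")
})

test_that("DDA dialect reads precursor intensities", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dda_fixture(path)
  lib <- read_library(path, "DDA")
  expect_equal(nrow(lib), 2L)
  expect_equal(lib$precursor_intensity, c(1e6, 2e6))
  expect_equal(lib$proteins[[2]], c("P2", "P3"))
  expect_equal(vapply(lib$fragments, nrow, integer(1)), c(0L, 0L))
})

test_that("library TSV round-trips through write_library", {
  sim <- generate_library(sim_config(n_proteins = 3, peptides_per_protein = 3,
                                     seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library(sim$library, path, "DIA")
  back <- read_library(path, "DIA")
  expect_equal(nrow(back), nrow(sim$library))
  expect_equal(back$modified_sequence, sim$library$modified_sequence)
  expect_equal(back$precursor_mz, sim$library$precursor_mz, tolerance = 1e-6)
  expect_equal(sum(vapply(back$fragments, nrow, integer(1))),
               sum(vapply(sim$library$fragments, nrow, integer(1))))
})

test_that("FASTA headers parse for UniProt and plain styles", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_fixture(path)
  idx <- read_fasta(path)
  expect_equal(idx$accession, c("P1", "P2"))
  expect_equal(idx$description, c("Granzyme B", "Interleukin receptor"))
  # duplicate accession
  write_fasta_fixture(path, c(">P1 a", "SEQK", ">P1 b", "SEQR"))
  expect_error(read_fasta(path), class = "prm_duplicate_error")
  # empty sequence
  write_fasta_fixture(path, c(">P1 a", "", ">P2 b", "SEQR"))
  expect_error(read_fasta(path), class = "prm_validation_error")
})

test_that("resolve_targets matches accessions and keywords, is monotone", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_fixture(path)
  idx <- read_fasta(path)
  expect_equal(resolve_targets(idx, c("P1")), "P1")
  expect_warning(r <- resolve_targets(idx, c("P1", "NOPE")), "NOPE")
  expect_equal(r, "P1")
  kw <- list(accessions = character(0), keywords = "granzyme")
  expect_equal(resolve_targets(idx, kw), "P1")
  expect_equal(resolve_targets(idx, list(accessions = character(0),
                                         keywords = character(0))),
               character(0))
  # monotonicity: adding accessions or keywords never shrinks the set
  base <- resolve_targets(idx, list(accessions = "P1", keywords = character(0)))
  more <- resolve_targets(idx, list(accessions = "P1", keywords = "interleukin"))
  expect_true(all(base %in% more))
})

test_that("target list files parse accessions, keywords and peptide lists", {
  tdir <- withr::local_tempdir()
  tf <- file.path(tdir, "targets.txt")
  writeLines(c("P1  # critical", "keyword: granzyme", "# comment", "P2"), tf)
  inc <- file.path(tdir, "inc.txt"); writeLines("PEPTIDEK", inc)
  exc <- file.path(tdir, "exc.txt"); writeLines("BADPEPK", exc)
  tl <- read_target_list(tf, inc, exc)
  expect_equal(tl$accessions, c("P1", "P2"))
  expect_equal(tl$keywords, "granzyme")
  expect_equal(tl$forced, "PEPTIDEK")
  writeLines("PEPTIDEK", exc)
  expect_error(read_target_list(tf, inc, exc), class = "prm_validation_error")
})

test_that("inclusion list format contract holds", {
  cand <- as_candidates(data.frame(
    bare_sequence = c("AAK", "CCK", "DDK"), precursor_charge = 2L,
    retention_time = c(20, 20, 40), score = c(3, 2, 1),
    precursor_mz = c(500.12345, 400.54321, 600.1),
    proteins = I(as.list(sprintf("P%d", 1:3)))))
  sch <- build_schedule(cand, config = schedule_config(max_density = 10,
                                                       gradient_end = 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_inclusion_list(sch, path)
  lines <- readLines(path)
  expect_equal(lines[1], "Compound,m/z,z,t start (min),t stop (min)")
  expect_equal(length(lines), 4L)
  back <- read_inclusion_list(path)
  # round trip within stated precision
  ord <- order(sch$targets$window_start, sch$targets$precursor_mz)
  expect_equal(back$mz, sch$targets$precursor_mz[ord], tolerance = 1e-4)
  expect_equal(back$t_start, sch$targets$window_start[ord], tolerance = 1e-2)
  # equal start times tie-break by ascending m/z
  expect_equal(back$mz[1:2], sort(back$mz[1:2]))
  expect_equal(back$compound[1], "CCK.2")
  # empty schedule refuses to write
  empty <- build_schedule(cand[0, ], config = schedule_config(gradient_end = 50))
  expect_error(write_inclusion_list(empty, path), class = "prm_validation_error")
})

test_that("schedule report rows and footer satisfy bookkeeping identities", {
  cand <- random_instance(40, seed = 91)
  cfg <- schedule_config(max_density = 3, gradient_end = 50)
  sch <- build_schedule(cand, config = cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_schedule_report(sch, path)
  lines <- readLines(path)
  data_rows <- lines[!startsWith(lines, "#")][-1]
  expect_equal(length(data_rows), nrow(sch$targets))
  get_count <- function(key) {
    footer <- lines[startsWith(lines, "#")]
    ln <- footer[startsWith(footer, paste0("# ", key))]
    as.integer(strsplit(ln, "\t")[[1]][2])
  }
  expect_equal(get_count("candidates_total"), nrow(cand))
  expect_equal(get_count("targets_scheduled") + get_count("rejected_density") +
                 get_count("rejected_protein_cap") + get_count("rejected_ineligible"),
               nrow(cand))
  expect_equal(get_count("rejected_density"),
               nrow(cand) - get_count("targets_scheduled") -
                 get_count("rejected_protein_cap") - get_count("rejected_ineligible"))
  # empty schedule: header + all-zero summary
  empty <- build_schedule(cand[0, ], config = cfg)
  write_schedule_report(empty, path)
  lines <- readLines(path)
  expect_equal(sum(!startsWith(lines, "#")), 1L)
  expect_equal(get_count("targets_scheduled"), 0L)
})
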