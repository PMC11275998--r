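cfg50 <- function(...) schedule_config(gradient_end = 50, ...)

test_that("make_window centers, clamps and rejects out-of-gradient apexes", {
  cfg <- cfg50(window_width = 5)
  w <- make_window(c(20, 1, 60), cfg)
  expect_equal(w$start, c(17.5, 0, 57.5))
  expect_equal(w$stop, c(22.5, 3.5, 50))
  expect_equal(w$eligible, c(TRUE, TRUE, FALSE))
})

test_that("single candidate schedules; density cap drops the lowest score", {
  one <- as_candidates(data.frame(bare_sequence = "AAK", precursor_charge = 2L,
                                  retention_time = 25, score = 10,
                                  proteins = I(list("P1"))))
  sch <- build_schedule(one, config = cfg50(max_density = 1))
  expect_equal(nrow(sch$targets), 1L)

  three <- as_candidates(data.frame(
    bare_sequence = c("AAK", "BBK", "CCK"), precursor_charge = 2L,
    retention_time = 25, score = c(30, 20, 10),
    proteins = I(as.list(sprintf("P%d", 1:3)))))
  sch <- build_schedule(three, config = cfg50(max_density = 2))
  expect_setequal(sch$targets$bare_sequence, c("AAK", "BBK"))
  expect_equal(sch$rejections$reason, "density")
  expect_equal(sch$rejections$modified_sequence, "CCK")
})

test_that("per-protein cap keeps the top-scored peptides of a protein", {
  four <- as_candidates(data.frame(
    bare_sequence = c("AAK", "BBK", "CCK", "DDK"), precursor_charge = 2L,
    retention_time = c(5, 15, 25, 35), score = c(40, 30, 20, 10),
    proteins = I(rep(list("P1"), 4))))
  sch <- build_schedule(four, config = cfg50(max_density = 10, per_protein_cap = 3))
  expect_setequal(sch$targets$bare_sequence, c("AAK", "BBK", "CCK"))
  expect_equal(sch$rejections$reason, "protein_cap")
})

test_that("abutting half-open windows share no instant", {
  two <- as_candidates(data.frame(
    bare_sequence = c("AAK", "BBK"), precursor_charge = 2L,
    retention_time = c(12.5, 17.5), score = c(2, 1),
    proteins = I(as.list(c("P1", "P2")))))
  sch <- build_schedule(two, config = cfg50(max_density = 1, window_width = 5))
  expect_equal(nrow(sch$targets), 2L)  # windows [10,15) and [15,20)
  expect_equal(max(density_profile(sch)$concurrent), 1L)
})

test_that("forced candidates bypass the protein cap but not density", {
  df <- data.frame(
    bare_sequence = c("AAK", "BBK", "CCK", "DDK", "FFK"), precursor_charge = 2L,
    retention_time = c(5, 10, 15, 20, 20.5), score = c(50, 40, 30, 20, 10),
    forced = c(rep(FALSE, 4), TRUE),
    proteins = I(rep(list("P1"), 5)))
  sch <- build_schedule(as_candidates(df),
                        config = cfg50(max_density = 10, per_protein_cap = 3))
  # forced FFK schedules despite P1 being at cap after AAK/BBK/CCK
  expect_true("FFK" %in% sch$targets$bare_sequence)
  expect_equal(sch$rejections$modified_sequence, "DDK")
  # but density still binds: same forced peptide in a saturated region
  df$forced <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  df$retention_time <- rep(25, 5)
  df$proteins <- I(as.list(sprintf("P%d", 1:5)))
  sch <- build_schedule(as_candidates(df), config = cfg50(max_density = 1))
  expect_equal(nrow(sch$targets), 1L)
  expect_equal(sch$targets$bare_sequence, "FFK")  # forced ranks first
})

test_that("density_profile sweeps events exactly", {
  mk <- function(rts, width = 5, density = 10) {
    cand <- as_candidates(data.frame(
      bare_sequence = sprintf("P%02dK", seq_along(rts)), precursor_charge = 2L,
      retention_time = rts, score = rev(seq_along(rts)),
      proteins = I(as.list(sprintf("PR%d", seq_along(rts))))))
    build_schedule(cand, config = cfg50(max_density = density, window_width = width))
  }
  expect_equal(max(density_profile(mk(c(10, 30)))$concurrent), 1L)
  prof <- density_profile(mk(rep(25, 4)))
  expect_equal(max(prof$concurrent), 4L)
  empty <- build_schedule(random_instance(2, seed = 1)[0, ],
                          config = cfg50(max_density = 10))
  expect_equal(nrow(density_profile(empty)), 0L)
})

test_that("injection-time budget arithmetic matches instrument settings", {
  expect_equal(max_injection_time(2.0, 10, 0), 200)
  expect_equal(max_injection_time(2.0, 20, 5), 95)
  expect_equal(max_injection_time(2.0, 1, 0), 2000)
  expect_error(max_injection_time(2.0, 0, 0), class = "prm_domain_error")
  # override may exceed the budget, with a warning (high-input tier)
  expect_warning(v <- max_injection_time(2.0, 50, 5, override_ms = 50),
                 "exceeds")
  expect_equal(v, 50)
})

test_that("points_per_peak is a guarded ratio", {
  expect_equal(points_per_peak(15, 2), 7.5)
  expect_equal(points_per_peak(10, 10), 1.0)
  expect_error(points_per_peak(0, 2), class = "prm_domain_error")
})

test_that("greedy matches the brute-force oracle on small instances", {
  for (seed in 1:120) {
    n <- sample(2:12, 1)
    cand <- random_instance(n, seed = 1000 + seed)
    cfg <- random_config(seed)
    sch <- build_schedule(cand, config = cfg)
    orc <- oracle_greedy(cand, cfg)
    expect_equal(sch$targets$bare_sequence, cand$bare_sequence[orc$accepted],
                 info = sprintf("seed %d", seed))
    expect_equal(sch$rejections$reason,
                 orc$reason[setdiff(seq_len(n), orc$accepted)],
                 info = sprintf("seed %d", seed))
  }
})

test_that("density soundness, conservation and monotonicity hold on random instances", {
  for (seed in 1:40) {
    n <- sample(10:120, 1)
    cand <- random_instance(n, seed = 2000 + seed)
    cfg <- random_config(seed)
    sch <- build_schedule(cand, config = cfg)
    prof <- density_profile(sch)
    if (nrow(prof)) expect_lte(max(prof$concurrent), cfg$max_density)
    expect_equal(nrow(sch$targets) + nrow(sch$rejections), n)
    # monotone in max_density
    cfg2 <- cfg; cfg2$max_density <- cfg$max_density + 2L
    expect_gte(nrow(build_schedule(cand, config = cfg2)$targets),
               nrow(sch$targets))
  }
})

test_that("greedy dominance: removing a scheduled target never frees a higher-scored reject", {
  checked <- 0L
  for (seed in 1:40) {
    n <- sample(4:10, 1)
    cand <- random_instance(n, seed = 3000 + seed, forced_fraction = 0)
    cfg <- random_config(seed)
    sch <- build_schedule(cand, config = cfg)
    rej <- sch$rejections
    for (r in which(cand$bare_sequence %in% rej$modified_sequence)) {
      for (s in which(cand$bare_sequence %in% sch$targets$bare_sequence)) {
        if (cand$score[s] >= cand$score[r]) next
        sub <- cand[-s, , drop = FALSE]
        resched <- build_schedule(sub, config = cfg)
        expect_false(cand$bare_sequence[r] %in% resched$targets$bare_sequence)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 0L)
})

test_that("schedules are deterministic: identical inputs, byte-identical lists", {
  cand <- random_instance(80, seed = 4242)
  cfg <- cfg50(max_density = 4)
  s1 <- build_schedule(cand, config = cfg)
  s2 <- build_schedule(cand, config = cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_inclusion_list(s1, f1)
  write_inclusion_list(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tier_assay builds independent non-increasing schedules", {
  cand <- random_instance(300, seed = 5150, n_proteins = 40)
  tiers <- lapply(c(50L, 20L, 10L), function(d) cfg50(max_density = d))
  schedules <- tier_assay(cand, tiers = tiers)
  counts <- vapply(schedules, function(s) nrow(s$targets), integer(1))
  expect_true(all(diff(counts) <= 0))
  # single tier identical to build_schedule
  solo <- tier_assay(cand, tiers = tiers[3])
  expect_equal(solo[[1]]$targets, build_schedule(cand, config = tiers[[3]])$targets)
  # empty bank -> empty schedules
  empty <- tier_assay(cand[0, ], tiers = tiers)
  expect_true(all(vapply(empty, function(s) nrow(s$targets), integer(1)) == 0L))
  # misordered tiers rejected
  expect_error(tier_assay(cand, tiers = rev(tiers)), class = "prm_domain_error")
})
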