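#' Scheduling configuration
#'
#' Bundles the instrument- and assay-level knobs for greedy scheduling:
#' the retention-time window width placed around each target's aligned
#' apex, the hard per-cycle assay density cap, the per-protein peptide
#' cap, the usable gradient bounds, and the cycle-time/isolation
#' settings used for budget arithmetic and background-exclusion checks.
#'
#' @param max_density maximum concurrent targets per cycle (e.g. 50, 20
#'   or 10 for 100/10/1 ng input tiers).
#' @param gradient_end end of the schedulable gradient (minutes).
#' @param window_width retention-time window width (minutes, default 5).
#' @param per_protein_cap maximum non-forced peptides per protein
#'   (default 3; the conventional range is 3-5, override with
#'   `relax_cap_bounds`).
#' @param gradient_start start of the gradient (minutes, default 0).
#' @param cycle_time acquisition cycle time (seconds, default 2).
#' @param routing_overhead_ms per-scan ion-routing overhead (ms,
#'   default 5).
#' @param isolation_width precursor isolation window (m/z, default 2).
#' @param relax_cap_bounds allow `per_protein_cap` outside 3-5.
#' @return a `schedule_config` object.
#' @export
schedule_config <- function(max_density = 10L, gradient_end = 50,
                            window_width = 5.0, per_protein_cap = 3L,
                            gradient_start = 0, cycle_time = 2.0,
                            routing_overhead_ms = 5, isolation_width = 2.0,
                            relax_cap_bounds = FALSE) {
  if (window_width <= 0) prm_stop("window_width must be > 0", "prm_domain_error")
  if (max_density < 1) prm_stop("max_density must be >= 1", "prm_domain_error")
  if (!relax_cap_bounds && (per_protein_cap < 3L || per_protein_cap > 5L))
    prm_stop("per_protein_cap outside 3-5 requires relax_cap_bounds = TRUE",
             "prm_domain_error")
  if (!(gradient_start < gradient_end))
    prm_stop("gradient_start must be < gradient_end", "prm_domain_error")
  structure(list(max_density = as.integer(max_density),
                 window_width = window_width,
                 per_protein_cap = as.integer(per_protein_cap),
                 gradient_start = gradient_start, gradient_end = gradient_end,
                 cycle_time = cycle_time, routing_overhead_ms = routing_overhead_ms,
                 isolation_width = isolation_width),
            class = "schedule_config")
}

#' Place a retention-time window around an aligned apex
#'
#' The window is `[rt - width/2, rt + width/2]` clamped to the gradient
#' bounds without re-extension, so edge windows may be narrower than
#' `window_width`. Apexes outside the gradient are ineligible.
#'
#' @param aligned_rt aligned retention time(s), minutes.
#' @param config a `schedule_config`.
#' @return data frame with `start`, `stop`, `eligible`.
#' @export
make_window <- function(aligned_rt, config) {
  half <- config$window_width / 2
  eligible <- aligned_rt >= config$gradient_start & aligned_rt <= config$gradient_end
  data.frame(start = pmax(aligned_rt - half, config$gradient_start),
             stop = pmin(aligned_rt + half, config$gradient_end),
             eligible = eligible)
}

#' Greedy density-constrained schedule construction
#'
#' Iterates candidates in rank order (forced first, then descending
#' score). A candidate is scheduled iff (i) at least one of its credited
#' target proteins is below `per_protein_cap` -- forced candidates
#' bypass this check -- and (ii) adding its retention-time window keeps
#' the number of concurrent targets at or below `max_density` at every
#' instant. Windows are half-open `[start, stop)`, so abutting windows
#' never share an instant, and density is checked exactly at interval
#' endpoint events rather than on a sampled grid. Scheduling a peptide
#' increments the count of all its credited proteins. Every unscheduled
#' candidate carries a rejection reason (`density`, `protein_cap`, or
#' `ineligible`).
#'
#' @param candidates a `prm_candidates` data frame (see
#'   [build_candidates()] / [as_candidates()]).
#' @param rt_map an `rt_map`; defaults to identity.
#' @param config a `schedule_config`.
#' @return a `prm_schedule` list with `targets`, `rejections`, `config`.
#' @export
build_schedule <- function(candidates, rt_map = rt_identity_map(), config) {
  stopifnot(inherits(config, "schedule_config"))
  cand <- as_candidates(as.data.frame(candidates))
  n <- nrow(cand)
  aligned <- if (n) rt_apply(rt_map, cand$retention_time) else numeric(0)
  win <- make_window(aligned, config)

  accepted <- logical(n)
  reason <- rep(NA_character_, n)
  s_starts <- numeric(0)   # accepted starts, sorted
  s_stops <- numeric(0)    # accepted stops, sorted
  prot_used <- integer(0)  # named per-protein scheduled counts

  for (i in seq_len(n)) {
    if (cand$ineligible[i] || !win$eligible[i]) { reason[i] <- "ineligible"; next }
    prots <- cand$proteins[[i]]
    if (!cand$forced[i] && length(prots)) {
      used <- prot_used[prots]
      used[is.na(used)] <- 0L
      if (all(used >= config$per_protein_cap)) { reason[i] <- "protein_cap"; next }
    }
    s <- win$start[i]; e <- win$stop[i]
    # Exact density check: the max of a step function over [s, e) is
    # attained at s or just after an accepted start inside (s, e).
    pts <- c(s, s_starts[s_starts > s & s_starts < e])
    conc <- findInterval(pts, s_starts) - findInterval(pts, s_stops)
    if (length(conc) && max(conc) + 1L > config$max_density) {
      reason[i] <- "density"; next
    }
    accepted[i] <- TRUE
    s_starts <- sort(c(s_starts, s))
    s_stops <- sort(c(s_stops, e))
    # only non-forced peptides count against the protein cap: forced
    # entries are curation, the cap constrains the automatic selection
    if (!cand$forced[i] && length(prots)) {
      for (p in prots) prot_used[p] <- (if (is.na(prot_used[p])) 0L else prot_used[p]) + 1L
    }
  }

  tg <- cand[accepted, , drop = FALSE]
  targets <- data.frame(modified_sequence = tg$modified_sequence,
                        bare_sequence = tg$bare_sequence,
                        precursor_charge = tg$precursor_charge,
                        precursor_mz = tg$precursor_mz,
                        score = tg$score, library_rt = tg$retention_time,
                        aligned_rt = aligned[accepted],
                        window_start = win$start[accepted],
                        window_stop = win$stop[accepted],
                        forced = tg$forced, stringsAsFactors = FALSE)
  targets$proteins <- tg$proteins
  targets$transitions <- tg$transitions
  rownames(targets) <- NULL
  rejections <- data.frame(modified_sequence = cand$modified_sequence[!accepted],
                           precursor_charge = cand$precursor_charge[!accepted],
                           score = cand$score[!accepted],
                           reason = reason[!accepted], stringsAsFactors = FALSE)
  rownames(rejections) <- NULL
  structure(list(targets = targets, rejections = rejections, config = config,
                 rt_map = rt_map, n_candidates = n,
                 n_excluded = attr(candidates, "n_excluded") %||% 0L),
            class = "prm_schedule")
}

#' Piecewise-constant assay density profile
#'
#' Sweeps the sorted window endpoint events of a schedule and reports
#' the number of concurrent targets after each event time. Windows are
#' half-open, so a stop and a start at the same instant do not overlap.
#'
#' @param schedule a `prm_schedule`.
#' @return data frame with `time` (minutes) and `concurrent` (targets);
#'   zero rows for an empty schedule.
#' @export
density_profile <- function(schedule) {
  tg <- schedule$targets
  if (is.null(tg) || nrow(tg) == 0L)
    return(data.frame(time = numeric(0), concurrent = integer(0)))
  ev <- data.frame(time = c(tg$window_start, tg$window_stop),
                   delta = c(rep(1L, nrow(tg)), rep(-1L, nrow(tg))))
  # At equal times, apply -1 before +1 (half-open convention).
  ev <- ev[order(ev$time, ev$delta), , drop = FALSE]
  agg <- tapply(ev$delta, ev$time, sum)
  times <- as.numeric(names(agg))
  ord <- order(times)
  data.frame(time = times[ord], concurrent = cumsum(as.integer(agg[ord])))
}

#' Per-scan maximum ion injection time from the cycle budget
#'
#' With `density` targets sharing a cycle of `cycle_time` seconds, the
#' per-scan budget is `floor(1000 * cycle_time / density)` ms minus the
#' per-scan ion-routing overhead, floored at 1 ms. An explicit
#' `override_ms` lets the caller exceed the budget (with a warning), as
#' is done at high input where scans rarely fill their injection time.
#'
#' @param cycle_time cycle time in seconds (> 0).
#' @param density targets per cycle (>= 1).
#' @param routing_overhead_ms per-scan routing overhead in ms.
#' @param override_ms optional explicit maxIIT; returned as-is, warning
#'   if it exceeds the budget.
#' @return maximum ion injection time in ms.
#' @export
#' @examples
#' max_injection_time(2, 10, 0)  # 200 ms (1 ng tier)
#' max_injection_time(2, 20, 5)  # 95 ms (10 ng tier)
max_injection_time <- function(cycle_time, density, routing_overhead_ms = 0,
                               override_ms = NULL) {
  if (density < 1) prm_stop("density must be >= 1", "prm_domain_error")
  if (cycle_time <= 0) prm_stop("cycle_time must be > 0", "prm_domain_error")
  budget <- max(floor(1000 * cycle_time / density) - routing_overhead_ms, 1)
  if (!is.null(override_ms)) {
    if (override_ms > budget)
      warning(sprintf("override maxIIT %.0f ms exceeds the %.0f ms cycle budget",
                      override_ms, budget), call. = FALSE)
    return(override_ms)
  }
  budget
}

#' Chromatographic points sampled across a peak
#'
#' `peak_width / cycle_time`; at least 6 points across a peak are needed
#' for reliable peak-area quantification.
#'
#' @param peak_width expected peak width (seconds, > 0).
#' @param cycle_time cycle time (seconds, > 0).
#' @return points per peak (dimensionless).
#' @export
#' @examples
#' points_per_peak(15, 2)  # 7.5
points_per_peak <- function(peak_width, cycle_time) {
  if (peak_width <= 0 || cycle_time <= 0)
    prm_stop("peak_width and cycle_time must be > 0", "prm_domain_error")
  peak_width / cycle_time
}

#' Build one schedule per input tier
#'
#' Re-runs the greedy scheduler on the same candidate bank at each tier
#' configuration (tiers ordered by descending `max_density`, e.g.
#' 50/20/10 targets per cycle for 100/10/1 ng input). Tiers are
#' independent rebuilds, not nested subsets.
#'
#' @param candidates a `prm_candidates` data frame.
#' @param rt_map an `rt_map`.
#' @param tiers list of `schedule_config`s with non-increasing
#'   `max_density`.
#' @return list of `prm_schedule`, one per tier, named by density.
#' @export
tier_assay <- function(candidates, rt_map = rt_identity_map(), tiers) {
  dens <- vapply(tiers, function(cf) cf$max_density, integer(1))
  if (is.unsorted(rev(dens)))
    prm_stop("tiers must be ordered by descending max_density", "prm_domain_error")
  out <- lapply(tiers, function(cf) build_schedule(candidates, rt_map, cf))
  names(out) <- paste0("density", dens)
  out
}

#' @export
print.prm_schedule <- function(x, ...) {
  dens <- density_profile(x)
  cat(sprintf(paste0("<prm_schedule> %d targets of %d candidates ",
                     "(max density %d/%d, window %.1f min, gradient %.1f-%.1f min)\n"),
              nrow(x$targets), x$n_candidates,
              if (nrow(dens)) max(dens$concurrent) else 0L, x$config$max_density,
              x$config$window_width, x$config$gradient_start, x$config$gradient_end))
  if (nrow(x$rejections)) {
    tab <- table(x$rejections$reason)
    cat("  rejected:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
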