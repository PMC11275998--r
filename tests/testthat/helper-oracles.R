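# Independent oracles, deliberately written as plain nested loops with
# none of the package's event-sweep machinery.

# Replays the stated greedy rule directly: iterate candidates in rank
# order; skip if all credited proteins are at cap (unless forced); skip
# if any instant of the window would exceed max density, checking
# concurrency by brute force at every window start point.
oracle_greedy <- function(cand, config) {
  n <- nrow(cand)
  acc_start <- c(); acc_stop <- c(); acc_idx <- c()
  used <- list()
  reason <- rep(NA_character_, n)
  half <- config$window_width / 2
  for (i in seq_len(n)) {
    rt <- cand$retention_time[i]
    if (isTRUE(cand$ineligible[i]) || rt < config$gradient_start ||
        rt > config$gradient_end) { reason[i] <- "ineligible"; next }
    s <- max(rt - half, config$gradient_start)
    e <- min(rt + half, config$gradient_end)
    prots <- cand$proteins[[i]]
    if (!cand$forced[i] && length(prots)) {
      counts <- vapply(prots, function(p) length(used[[p]]), integer(1))
      if (all(counts >= config$per_protein_cap)) { reason[i] <- "protein_cap"; next }
    }
    # brute-force concurrency at every candidate point in [s, e)
    pts <- c(s, acc_start[acc_start > s & acc_start < e])
    violates <- FALSE
    for (p in pts) {
      conc <- 0L
      for (j in seq_along(acc_start)) {
        if (acc_start[j] <= p && p < acc_stop[j]) conc <- conc + 1L
      }
      if (conc + 1L > config$max_density) { violates <- TRUE; break }
    }
    if (violates) { reason[i] <- "density"; next }
    acc_start <- c(acc_start, s); acc_stop <- c(acc_stop, e)
    acc_idx <- c(acc_idx, i)
    if (!cand$forced[i]) for (p in prots) used[[p]] <- c(used[[p]], i)
  }
  list(accepted = acc_idx, reason = reason)
}

# Max concurrency of a set of half-open windows, checked by brute force
# at every start point.
oracle_peak_density <- function(starts, stops) {
  peak <- 0L
  for (p in starts) {
    conc <- sum(starts <= p & p < stops)
    peak <- max(peak, conc)
  }
  peak
}
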