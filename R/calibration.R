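#' Read a calibration-curve quantification table
#'
#' CSV with columns `Peptide`, `Charge`, `Dilution` (foreground
#' fraction of neat, in `[0, 1]`, 0 = blank), `Replicate`, `Area`.
#'
#' @param path CSV path.
#' @return data frame `peptide`, `charge`, `dilution`, `replicate`,
#'   `area`.
#' @export
read_quant_table <- function(path) {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("Peptide", "Charge", "Dilution", "Replicate", "Area")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    prm_stop(sprintf("missing quant column(s): %s", paste(missing, collapse = ", ")),
             "prm_schema_error")
  if (any(tab$Dilution < 0) || any(tab$Area < 0))
    prm_stop("Dilution and Area must be >= 0", "prm_validation_error")
  data.frame(peptide = as.character(tab$Peptide), charge = as.integer(tab$Charge),
             dilution = as.numeric(tab$Dilution), replicate = as.integer(tab$Replicate),
             area = as.numeric(tab$Area), stringsAsFactors = FALSE)
}

#' Bilinear (hockey-stick) fit of a calibration curve
#'
#' Fits mean peak area versus dilution to a flat noise floor joined to a
#' rising linear segment: `y = c` for `x <= x0`, `y = c + m (x - x0)`
#' for `x > x0`, with `m >= 0`. The breakpoint `x0` is found by grid
#' search over `n_knots` log-spaced knots spanning the measured nonzero
#' dilution range, with `c` and `m` refit analytically (least squares on
#' per-level mean areas) at each knot; the SSE-minimizing triple wins,
#' ties going to the smaller breakpoint. Grid search keeps the fit
#' global, deterministic and derivative-free.
#'
#' @param curve data frame with `dilution` and `area` (replicate rows).
#' @param n_knots number of breakpoint knots (default 65).
#' @return a `bilinear_fit` list: `noise_floor`, `breakpoint`, `slope`,
#'   `sse`, `degenerate`, `n_levels`.
#' @export
fit_bilinear <- function(curve, n_knots = 65L) {
  x_all <- curve$dilution
  y_all <- curve$area
  levels <- sort(unique(x_all))
  if (length(levels) < 4L)
    prm_stop("need >= 4 distinct dilution levels", "prm_insufficient_data")
  y <- vapply(levels, function(l) mean(y_all[x_all == l]), numeric(1))
  if (all(y_all == 0)) {
    return(structure(list(noise_floor = 0, breakpoint = min(levels[levels > 0]),
                          slope = 0, sse = 0, degenerate = TRUE,
                          n_levels = length(levels)), class = "bilinear_fit"))
  }
  pos <- levels[levels > 0]
  knots <- exp(seq(log(min(pos)), log(max(pos)), length.out = n_knots))
  best <- NULL
  for (x0 in knots) {
    u <- pmax(0, levels - x0)
    if (all(u == 0)) { m <- 0; c0 <- mean(y) }
    else {
      ub <- mean(u); yb <- mean(y)
      suu <- sum((u - ub)^2)
      m <- if (suu > 0) sum((u - ub) * (y - yb)) / suu else 0
      if (m < 0) m <- 0
      c0 <- yb - m * ub
    }
    sse <- sum((y - (c0 + m * u))^2)
    if (is.null(best) || sse < best$sse - 1e-12 * max(best$sse, 1)) {
      best <- list(noise_floor = c0, breakpoint = x0, slope = m, sse = sse)
    }
  }
  best$degenerate <- !(best$slope > 0)
  best$n_levels <- length(levels)
  structure(best, class = "bilinear_fit")
}

#' Lower limit of detection from a bilinear fit
#'
#' The LoD is the dilution at which the fitted rising segment crosses
#' `noise_floor + 2 * sd(blank replicates)`: the point where signal
#' separates from the background by two standard deviations. With zero
#' blank variance the LoD collapses to the breakpoint. `NA` (undefined)
#' if the rising segment never exceeds that level within the measured
#' range, or if the fit is degenerate.
#'
#' @param curve replicate-level curve data (`dilution`, `area`).
#' @param fit a `bilinear_fit`.
#' @return LoD as a dilution fraction, or `NA`.
#' @export
estimate_lod <- function(curve, fit) {
  if (fit$degenerate) return(NA_real_)
  blanks <- curve$area[curve$dilution == 0]
  if (length(blanks) == 0L) {
    warning("no blank replicates; using sd of the lowest dilution level",
            call. = FALSE)
    lowest <- min(curve$dilution)
    blanks <- curve$area[curve$dilution == lowest]
  }
  sdb <- if (length(blanks) >= 2L) stats::sd(blanks) else {
    warning("single blank replicate; treating blank sd as 0", call. = FALSE)
    0
  }
  lod <- fit$breakpoint + 2 * sdb / fit$slope
  if (lod > max(curve$dilution)) return(NA_real_)
  lod
}

#' Lower limit of quantification by bootstrap CV
#'
#' Walks the measured dilution levels at or above the LoD in ascending
#' order; at each level the replicate areas are resampled with
#' replacement `n_boot` times and the CV of the bootstrap means is
#' taken. The LoQ is the smallest level whose bootstrap CV is at or
#' below `cv_threshold` (snapped to a measured level, the conservative
#' choice). `NA` if no level qualifies -- such peptides are reported as
#' "could not be assigned a LoQ". Deterministic under `seed`; CVs are
#' computed once per level so relaxing the threshold can never raise
#' the LoQ.
#'
#' @param curve replicate-level curve data.
#' @param fit a `bilinear_fit`.
#' @param cv_threshold maximum acceptable CV (default 0.20).
#' @param n_boot bootstrap resamples per level (default 100).
#' @param seed RNG seed for the bootstrap.
#' @param lod LoD to start from; computed via [estimate_lod()] if
#'   `NULL`.
#' @return list with `loq`, `cv_at_loq`, and `level_cvs` (named by
#'   dilution).
#' @export
estimate_loq <- function(curve, fit, cv_threshold = 0.20, n_boot = 100L,
                         seed = NULL, lod = NULL) {
  if (is.null(lod)) lod <- estimate_lod(curve, fit)
  if (is.na(lod))
    return(list(loq = NA_real_, cv_at_loq = NA_real_, level_cvs = numeric(0)))
  levels <- sort(unique(curve$dilution[curve$dilution > 0 &
                                       curve$dilution >= lod - 1e-12]))
  cvs <- with_seed(seed, vapply(levels, function(l) {
    areas <- curve$area[curve$dilution == l]
    if (length(areas) < 2L) {
      warning(sprintf("single replicate at dilution %g; CV undefined", l),
              call. = FALSE)
      return(NA_real_)
    }
    boots <- matrix(sample(areas, n_boot * length(areas), replace = TRUE),
                    nrow = n_boot)
    means <- rowMeans(boots)
    mu <- mean(means)
    if (mu == 0) return(NA_real_)
    stats::sd(means) / mu
  }, numeric(1)))
  names(cvs) <- levels
  ok <- which(!is.na(cvs) & cvs <= cv_threshold)
  if (!length(ok))
    return(list(loq = NA_real_, cv_at_loq = NA_real_, level_cvs = cvs))
  list(loq = levels[ok[1]], cv_at_loq = cvs[ok[1]], level_cvs = cvs)
}

#' Coefficient of variation across replicates
#'
#' Sample standard deviation (n-1 denominator) over the mean. `NA`
#' (undefined) when the mean is zero.
#'
#' @param areas numeric vector of replicate areas (>= 2 values).
#' @return CV as a fraction, or `NA`.
#' @export
replicate_cv <- function(areas) {
  if (length(areas) < 2L) prm_stop("need >= 2 replicates", "prm_insufficient_data")
  mu <- mean(areas)
  if (mu == 0) return(NA_real_)
  stats::sd(areas) / mu
}

#' Per-peptide figures of merit from one calibration curve
#'
#' Convenience wrapper: bilinear fit, LoD, then bootstrap-CV LoQ. The
#' returned object enforces `lod <= loq` whenever both are defined.
#'
#' @inheritParams estimate_loq
#' @return a `figures_of_merit` list: `lod`, `loq`, `slope`,
#'   `noise_floor`, `cv_at_loq`, `status` (`"ok"`, `"no_loq"`,
#'   `"no_lod"`, or `"degenerate"`).
#' @export
figures_of_merit <- function(curve, cv_threshold = 0.20, n_boot = 100L,
                             seed = NULL) {
  fit <- fit_bilinear(curve)
  lod <- estimate_lod(curve, fit)
  lq <- estimate_loq(curve, fit, cv_threshold, n_boot, seed, lod = lod)
  status <- if (fit$degenerate) "degenerate"
            else if (is.na(lod)) "no_lod"
            else if (is.na(lq$loq)) "no_loq"
            else "ok"
  structure(list(lod = lod, loq = lq$loq, slope = fit$slope,
                 noise_floor = fit$noise_floor, breakpoint = fit$breakpoint,
                 cv_at_loq = lq$cv_at_loq, status = status),
            class = "figures_of_merit")
}

#' Assay-level summary of figures of merit
#'
#' Median LoD and LoQ over peptides with defined values, the fraction of
#' peptides that could not be assigned a LoQ, and log10 histogram bins
#' of the LoD/LoQ distributions for reporting.
#'
#' @param fom data frame with columns `lod` and `loq` (one row per
#'   peptide; `NA` = undefined), e.g. from
#'   [run_calibration_pipeline()].
#' @return list with `n`, `median_lod`, `median_loq`,
#'   `frac_no_loq`, `lod_hist`, `loq_hist`.
#' @export
summarize_assay <- function(fom) {
  if (is.null(fom) || nrow(fom) == 0L)
    prm_stop("no peptides to summarize", "prm_insufficient_data")
  log_hist <- function(v) {
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) return(NULL)
    graphics_free <- stats::na.omit(log10(v))
    brk <- pretty(range(graphics_free), n = 10)
    counts <- table(cut(graphics_free, brk, include.lowest = TRUE))
    list(breaks_log10 = brk, counts = as.integer(counts))
  }
  list(n = nrow(fom),
       median_lod = stats::median(fom$lod, na.rm = TRUE),
       median_loq = stats::median(fom$loq, na.rm = TRUE),
       frac_no_loq = mean(is.na(fom$loq)),
       lod_hist = log_hist(fom$lod),
       loq_hist = log_hist(fom$loq))
}
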