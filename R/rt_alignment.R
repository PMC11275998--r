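#' Identity retention-time map
#' @return an `rt_map` with slope 1, intercept 0.
#' @export
rt_identity_map <- function() {
  structure(list(kind = "identity", slope = 1, intercept = 0,
                 n_anchors = 0L, residual_mad = NA_real_),
            class = "rt_map")
}

#' Build retention-time anchors from a recent DIA run
#'
#' Joins library/candidate retention times with the observed-RT table on
#' (modified sequence, charge). When a `score` column is present the
#' `top_n` highest-scoring matches are kept: abundant peptides give the
#' most reliable apexes.
#'
#' @param candidates a `prm_candidates` or `peptide_library` data frame.
#' @param observed data frame from [read_observed_rt()].
#' @param top_n number of anchors to keep (default 200).
#' @return data frame of anchors (`bare_sequence`, `charge`,
#'   `library_rt`, `observed_rt`).
#' @export
make_rt_anchors <- function(candidates, observed, top_n = 200L) {
  key_c <- paste(candidates$modified_sequence, candidates$precursor_charge, sep = "\r")
  key_o <- paste(observed$modified_sequence, observed$precursor_charge, sep = "\r")
  hit <- match(key_c, key_o)
  keep <- which(!is.na(hit))
  if ("score" %in% names(candidates))
    keep <- keep[order(-candidates$score[keep])]
  keep <- utils::head(keep, top_n)
  anchors <- data.frame(
    bare_sequence = strip_modifications(candidates$modified_sequence[keep]),
    charge = candidates$precursor_charge[keep],
    library_rt = candidates$retention_time[keep],
    observed_rt = observed$observed_rt[hit[keep]],
    stringsAsFactors = FALSE)
  anchors[!duplicated(paste(anchors$bare_sequence, anchors$charge)), , drop = FALSE]
}

#' Fit a robust affine retention-time map
#'
#' Estimates observed = slope * library + intercept with the Theil-Sen
#' estimator: slope is the median of all pairwise slopes, intercept the
#' median residual. The median-of-slopes fit tolerates up to ~29% gross
#' outliers, which covers mis-picked apexes in the anchor run. With
#' fewer than `min_anchors` anchors the identity map is returned with a
#' warning, since a poorly supported affine fit is worse than none: the
#' same column re-run drifts approximately linearly, and identity is the
#' no-information limit of that model.
#'
#' @param anchors data frame with `library_rt` and `observed_rt`
#'   (minutes), de-duplicated per peptide.
#' @param min_anchors minimum anchors for an affine fit (default 10).
#' @return an `rt_map` with `slope`, `intercept`, `n_anchors`,
#'   `residual_mad` (minutes).
#' @export
fit_rt_map <- function(anchors, min_anchors = 10L) {
  x <- anchors$library_rt
  y <- anchors$observed_rt
  if (any(!is.finite(x)) || any(!is.finite(y)))
    prm_stop("anchor retention times must be finite", "prm_validation_error")
  n <- length(x)
  if (n < min_anchors) {
    warning(sprintf("only %d anchors (< %d); using identity retention-time map",
                    n, min_anchors), call. = FALSE)
    map <- rt_identity_map()
    map$n_anchors <- n
    if (n > 0) map$residual_mad <- stats::mad(y - x)
    return(map)
  }
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  slopes <- dy[keep] / dx[keep]
  if (!length(slopes)) {
    warning("all anchors share one library RT; using identity map", call. = FALSE)
    map <- rt_identity_map(); map$n_anchors <- n
    return(map)
  }
  slope <- stats::median(slopes)
  if (!is.finite(slope) || slope <= 0) {
    warning("degenerate (non-positive) slope estimate; using identity map",
            call. = FALSE)
    map <- rt_identity_map(); map$n_anchors <- n
    map$residual_mad <- stats::mad(y - x)
    return(map)
  }
  intercept <- stats::median(y - slope * x)
  structure(list(kind = "affine", slope = slope, intercept = intercept,
                 n_anchors = n,
                 residual_mad = stats::mad(y - (slope * x + intercept))),
            class = "rt_map")
}

#' Apply a retention-time map
#'
#' Maps library minutes onto current-column minutes, floored at zero.
#' Monotone increasing for valid (positive-slope) maps.
#'
#' @param map an `rt_map`.
#' @param library_rt numeric vector of library retention times
#'   (minutes).
#' @return mapped retention times (minutes).
#' @export
rt_apply <- function(map, library_rt) {
  pmax(map$slope * library_rt + map$intercept, 0)
}

#' @export
print.rt_map <- function(x, ...) {
  cat(sprintf("<rt_map %s> slope=%.4f intercept=%.3f min, %d anchors, residual MAD=%s min\n",
              x$kind, x$slope, x$intercept, x$n_anchors,
              ifelse(is.na(x$residual_mad), "NA", sprintf("%.3f", x$residual_mad))))
  invisible(x)
}
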