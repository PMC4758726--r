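#' Pipeline configuration
#'
#' Bundles the thresholds of the screening cascade and the quantification
#' base shared by the stability and normalization steps. Defaults are the
#' values used throughout zebrafish developmental reference-gene screens:
#' expression calls at RPKM 0.17, stability limits of max/min ratio < 2 and
#' CV < 0.3, an abundance floor of minimum RPKM > 40, the top 5 candidates
#' carried into annotation filtering, and a quantification base of 2
#' (perfect per-cycle doubling).
#'
#' @param expressed_threshold Minimum RPKM at every stage for a gene to
#'   count as expressed (inclusive boundary). Default 0.17.
#' @param max_min_ratio_limit Upper limit (exclusive) on RPKM_max/min.
#'   Default 2.
#' @param cv_limit Upper limit (exclusive) on the coefficient of variation
#'   (SD / mean). Default 0.3.
#' @param min_rpkm Abundance floor: minimum RPKM across stages must exceed
#'   this (strict). Default 40.
#' @param top_n Number of candidates, ranked by ascending max/min ratio,
#'   carried into the annotation filter. Default 5.
#' @param efficiency_base Amplification base relating CT differences to
#'   fold changes; 2 assumes 100% primer efficiency. Default 2.
#' @param ct_range Plausible CT range; values outside are flagged (not
#'   dropped) during validation. Default c(5, 40) cycles.
#' @param seed Optional integer seed recorded for downstream simulation.
#'
#' @return A list of class `refstab_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$cv_limit
#' @export
pipeline_config <- function(expressed_threshold = 0.17,
                            max_min_ratio_limit = 2,
                            cv_limit = 0.3,
                            min_rpkm = 40,
                            top_n = 5,
                            efficiency_base = 2,
                            ct_range = c(5, 40),
                            seed = NULL) {
  thresholds <- c(expressed_threshold = expressed_threshold,
                  max_min_ratio_limit = max_min_ratio_limit,
                  cv_limit = cv_limit,
                  min_rpkm = min_rpkm,
                  efficiency_base = efficiency_base)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    abort("all thresholds must be finite and > 0")
  }
  if (top_n < 1) abort("`top_n` must be >= 1")
  if (length(ct_range) != 2 || ct_range[1] >= ct_range[2]) {
    abort("`ct_range` must be c(lo, hi) with lo < hi")
  }
  structure(
    list(expressed_threshold = expressed_threshold,
         max_min_ratio_limit = max_min_ratio_limit,
         cv_limit = cv_limit,
         min_rpkm = min_rpkm,
         top_n = as.integer(top_n),
         efficiency_base = efficiency_base,
         ct_range = ct_range,
         seed = seed),
    class = "refstab_config"
  )
}

#' @export
print.refstab_config <- function(x, ...) {
  cat("refstab pipeline configuration\n")
  cat(sprintf("  expressed threshold : RPKM >= %g at every stage\n",
              x$expressed_threshold))
  cat(sprintf("  stability limits    : max/min ratio < %g, CV < %g\n",
              x$max_min_ratio_limit, x$cv_limit))
  cat(sprintf("  abundance floor     : min RPKM > %g\n", x$min_rpkm))
  cat(sprintf("  top-N candidates    : %d\n", x$top_n))
  cat(sprintf("  efficiency base     : %g\n", x$efficiency_base))
  invisible(x)
}
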