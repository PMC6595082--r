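#' Specification of a simulated longitudinal cohort
#'
#' Describes a multi-group cohort with back-to-back ("A" and "B") scan
#' replicates and left/right structures, whose group PVC distributions are
#' parameterised by published group means and SDs (see
#' [method_reference_stats()]).  The generative model partitions each
#' group's variance into a between-subject part and replicate noise:
#'
#' * subject truth: `t_s ~ N(mu_g, sigma_true)` with
#'   `sigma_true^2 = max(sigma_g^2 - sigma_eps^2, 0)`;
#' * scan replicate: `v_{s,scan} = t_s + eps_{s,scan}`,
#'   `eps ~ N(0, sigma_eps)` i.i.d. (so the A-vs-B reproducibility distance
#'   has expectation `sqrt(2) * sigma_eps`, while the pooled group SD stays
#'   `sigma_g`);
#' * sides: `L = v + delta`, `R = v - delta` with
#'   `delta ~ N(0, sigma_side)` per subject-scan (antithetic, so left/right
#'   averaging recovers `v` exactly and the averaging path is exercised
#'   without distorting group statistics).
#'
#' Baseline volumes are drawn uniformly from `volume_range` (mm^3) per
#' subject-side and follow-up volumes derived from the PVC.
#'
#' @param n named integer vector of subjects per group
#'   (default `c(CTRL = 20, MCI = 40, AD = 20)`).
#' @param mu,sigma named numeric vectors of group PVC means / SDs (percent);
#'   defaults are the FreeSurfer rows of [method_reference_stats()].
#' @param method method label stored on the records.
#' @param sigma_eps replicate noise SD (percent), default 1.5.
#' @param sigma_side left/right half-split SD (percent), default 0.5.
#' @param outlier_rate fraction of records replaced by implausible PVCs
#'   beyond +/-25% (default 0) to exercise the exclusion rule.
#' @param volume_range baseline structure volume range, mm^3.
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = c(CTRL = 20L, MCI = 40L, AD = 20L),
                        mu = NULL, sigma = NULL, method = "simulated",
                        sigma_eps = 1.5, sigma_side = 0.5,
                        outlier_rate = 0, volume_range = c(2000, 4000),
                        seed = 1L) {
  if (is.null(names(n)) || any(!nzchar(names(n))))
    stop("'n' must be a named vector of group sizes")
  if (any(n < 2L)) stop("need at least two subjects per group")
  if (is.null(mu) || is.null(sigma)) {
    ref <- method_reference_stats()
    fs <- ref[ref$method == "FreeSurfer", ]
    if (is.null(mu)) mu <- setNames(fs$mu, fs$group)[names(n)]
    if (is.null(sigma)) sigma <- setNames(fs$sigma, fs$group)[names(n)]
  }
  if (!all(names(n) %in% names(mu)) || !all(names(n) %in% names(sigma)))
    stop("'mu' and 'sigma' must cover every group in 'n'")
  if (sigma_eps < 0 || sigma_side < 0) stop("noise SDs must be >= 0")
  if (any(sigma_eps > sigma[names(n)]))
    stop("replicate noise exceeds group SD")
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop("'outlier_rate' must be in [0, 1)")
  structure(list(n = n, mu = mu, sigma = sigma, method = method,
                 sigma_eps = sigma_eps, sigma_side = sigma_side,
                 outlier_rate = outlier_rate, volume_range = volume_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of PVC records
#'
#' Draws a full record table (subject x scan x side) from a
#' [cohort_spec()]'s generative model.  Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return A [cohort_table()] with provenance metadata.
#' @examples
#' tab <- simulate_cohort(cohort_spec(seed = 7))
#' head(subject_pvc(tab))
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  groups <- names(spec$n)
  with_seed(seed, {
    rows <- list()
    sid <- 0L
    for (g in groups) {
      mu_g <- spec$mu[[g]]; sigma_g <- spec$sigma[[g]]
      sigma_true <- sqrt(max(sigma_g^2 - spec$sigma_eps^2, 0))
      for (s in seq_len(spec$n[[g]])) {
        sid <- sid + 1L
        subject <- sprintf("S%03d", sid)
        truth <- rnorm(1, mu_g, sigma_true)
        v_bl <- runif(2, spec$volume_range[1], spec$volume_range[2])  # L, R
        for (scan in c("A", "B")) {
          v <- truth + rnorm(1, 0, spec$sigma_eps)
          delta <- rnorm(1, 0, spec$sigma_side)
          for (side in c("L", "R")) {
            p <- v + if (side == "L") delta else -delta
            vb <- v_bl[if (side == "L") 1 else 2]
            rows[[length(rows) + 1L]] <- data.frame(
              subject_id = subject, group = g, scan = scan, side = side,
              method = spec$method, v_bl = vb, v_fu = vb * (1 + p / 100),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    df <- do.call(rbind, rows)
    if (spec$outlier_rate > 0) {
      hit <- which(runif(nrow(df)) < spec$outlier_rate)
      if (length(hit)) {
        mag <- runif(length(hit), 25, 60) * sample(c(-1, 1), length(hit),
                                                   replace = TRUE)
        df$v_fu[hit] <- df$v_bl[hit] * (1 + mag / 100)
      }
    }
    cohort_table(df, provenance = list(method = spec$method,
                                       dataset = "simulated", seed = seed))
  })
}

#' Bundle a shape, a field, and the expected volume change
#'
#' Builds the complete synthetic input of one longitudinal measurement: the
#' baseline segmentation of a shape, a deformation field on the same grid,
#' and the ground-truth PVC the pipeline should recover.
#'
#' @param shape a [shape_spec()].
#' @param field a [field_spec()].
#' @param ground_truth compute the ground-truth attribute (see
#'   [make_field()]).
#' @return List with elements `seg` ([label_volume()]), `field`
#'   ([displacement_field()]), and `pvc_true` (percent, `NA` if not
#'   requested).
#' @export
end_to_end_fixture <- function(shape, field, ground_truth = TRUE) {
  seg <- make_segmentation(shape)
  fld <- make_field(field, seg, ground_truth = ground_truth)
  list(seg = seg, field = fld,
       pvc_true = if (ground_truth) attr(fld, "pvc_true") else NA_real_)
}
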