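#' Tumor growth inhibition (TGI)
#'
#' Compares fold-growth of a drug arm against the vehicle arm:
#' \deqn{TGI = [1 - (TF/T0)_{A} / (TF/T0)_{V}] \times 100}
#' where TF is tumor size (volume in mm^3, or weight) at the analyzed time
#' point, T0 at the initial time, A the drug arm and V the vehicle arm.
#' TGI is 0 when both arms grow identically, 100 when the drug arm does
#' not grow at all, above 100 on regression below baseline, and negative
#' when the drug arm outgrows the vehicle; values are reported as-is,
#' never clipped. The metric is invariant to rescaling all sizes within an
#' arm (only within-arm fold changes enter).
#'
#' With several animals per arm, per-animal fold changes TF/T0 are
#' averaged (arithmetic mean) within each arm before the ratio of the two
#' arm means is taken.
#'
#' @param drug,vehicle either a single fold change TF/T0, or a list/data
#'   frame with `t0` and `tf` vectors (one entry per animal).
#' @return TGI in percent.
#' @export
tumor_growth_inhibition <- function(drug, vehicle) {
  fa <- arm_fold_growth(drug, "drug")
  fv <- arm_fold_growth(vehicle, "vehicle")
  if (fv <= 0) mc_stop("vehicle arm fold growth must be positive")
  (1 - fa / fv) * 100
}

arm_fold_growth <- function(x, label) {
  if (is.numeric(x) && length(x) >= 1 && is.null(names(x)) && !is.list(x)) {
    ratios <- x
  } else {
    x <- as.list(x)
    if (is.null(x$t0) || is.null(x$tf))
      mc_stop(label, " arm needs t0 and tf (or a fold-change value)")
    if (any(x$t0 <= 0)) mc_stop(label, " arm t0 must be positive")
    if (any(x$tf < 0)) mc_stop(label, " arm tf must be non-negative")
    if (length(x$t0) != length(x$tf))
      mc_stop(label, " arm t0 and tf lengths differ")
    ratios <- x$tf / x$t0
  }
  if (any(!is.finite(ratios)) || any(ratios < 0))
    mc_stop(label, " arm fold growth must be finite and non-negative")
  mean(ratios)
}

#' TGI from a long measurement table
#'
#' @param measurements data frame with columns `animal`, `arm`, `t0`,
#'   `tf`.
#' @param drug_arm,vehicle_arm labels in `arm` identifying the two arms.
#' @param n_boot if > 0, a per-animal bootstrap of the TGI (resampling
#'   animals within arms) with this many replicates.
#' @param conf confidence level for the bootstrap interval.
#' @return List with `tgi` (percent), per-arm summaries, and optionally
#'   `ci` (percentile bootstrap interval).
#' @export
tgi_from_table <- function(measurements, drug_arm, vehicle_arm,
                           n_boot = 0, conf = 0.95) {
  req <- c("animal", "arm", "t0", "tf")
  if (!all(req %in% names(measurements)))
    mc_stop("measurements must have columns: ", paste(req, collapse = ", "))
  pick <- function(a) {
    rows <- measurements[measurements$arm == a, , drop = FALSE]
    if (!nrow(rows)) mc_stop("no measurements for arm '", a, "'")
    rows
  }
  d <- pick(drug_arm); v <- pick(vehicle_arm)
  out <- list(
    tgi = tumor_growth_inhibition(list(t0 = d$t0, tf = d$tf),
                                  list(t0 = v$t0, tf = v$tf)),
    arms = data.frame(
      arm = c(drug_arm, vehicle_arm),
      n = c(nrow(d), nrow(v)),
      mean_fold_growth = c(mean(d$tf / d$t0), mean(v$tf / v$t0))))
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(i) {
      di <- d[sample.int(nrow(d), replace = TRUE), ]
      vi <- v[sample.int(nrow(v), replace = TRUE), ]
      tumor_growth_inhibition(list(t0 = di$t0, tf = di$tf),
                              list(t0 = vi$t0, tf = vi$tf))
    }, numeric(1))
    a <- (1 - conf) / 2
    out$ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  }
  out
}
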