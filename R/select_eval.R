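# Constrained beam selection and plan-quality metrics.

#' Select the top-k beam angles under a minimum separation constraint
#'
#' Greedy descent over the ranking scores: angles are visited in order of
#' decreasing score (ties broken by the lower angle) and accepted only if
#' their circular distance to every already accepted angle is at least
#' `min_sep`; selection stops after `k` acceptances.
#'
#' @param sbeam numeric vector of length 360, scores for angles 0..359.
#' @param k number of angles to select (default 3).
#' @param min_sep minimum pairwise circular separation in degrees
#'   (default 30).
#' @return numeric vector of `k` angles in selection (non-increasing score)
#'   order.
#' @export
select_angles <- function(sbeam, k = 3, min_sep = 30) {
  stopifnot(length(sbeam) == 360)
  angles <- 0:359
  ord <- order(-sbeam, angles)
  chosen <- numeric(0)
  for (i in ord) {
    a <- angles[i]
    if (all(circ_dist(a, chosen) >= min_sep)) {
      chosen <- c(chosen, a)
      if (length(chosen) == k) return(chosen)
    }
  }
  stop("only ", length(chosen), " angle(s) selectable under the ",
       min_sep, " degree separation constraint (", k, " requested)")
}

#' Conformity index of the prescribed isodose volume around the target
#'
#' The prescribed isodose volume (PIV) is the set of voxels at or above the
#' dose grid's `prescription_level`. The default variant is
#' `(TV * PIV) / (TV & PIV)^2` on volumes (voxel counts scaled by voxel
#' volume); the Paddick variant `(TV & PIV)^2 / (TV * PIV)` is its
#' reciprocal. Both equal 1 exactly when PIV coincides with TV. An empty
#' overlap leaves the index undefined and returns `NaN` with a warning.
#'
#' @param tv_mask binary 3D array: the target volume.
#' @param dose a [dose_grid()] aligned to the mask.
#' @param variant `"ratio"` (default) or `"paddick"`.
#' @return scalar conformity index.
#' @export
conformity_index <- function(tv_mask, dose, variant = c("ratio", "paddick")) {
  variant <- match.arg(variant)
  stopifnot(inherits(dose, "dose_grid"),
            identical(dim(tv_mask), dim(dose$dose)))
  tv <- sum(tv_mask == 1)
  if (tv == 0) stop("target volume mask is empty")
  piv_mask <- dose$dose >= dose$prescription_level
  piv <- sum(piv_mask)
  ov <- sum(piv_mask & tv_mask == 1)
  if (ov == 0) {
    warning("target and prescribed isodose volume do not overlap; ",
            "conformity index undefined")
    return(NaN)
  }
  if (variant == "ratio") (tv * piv) / ov^2 else ov^2 / (tv * piv)
}

#' Volume percentage of a structure at or above a dose threshold
#'
#' `v_xgy(dose, mask, x)` is the percentage of the structure's voxels
#' receiving at least `x` (% of prescription) — the V_xGy DVH parameter on
#' the normalized dose scale.
#'
#' @param dose a [dose_grid()].
#' @param mask binary 3D array (non-empty).
#' @param threshold dose threshold in % of prescription.
#' @return volume percentage in \[0, 100\].
#' @export
v_xgy <- function(dose, mask, threshold) {
  stopifnot(inherits(dose, "dose_grid"),
            identical(dim(mask), dim(dose$dose)))
  sel <- mask == 1
  if (!any(sel)) stop("structure mask is empty")
  100 * mean(dose$dose[sel] >= threshold)
}

#' Minimum, mean and maximum dose within a structure
#'
#' @param dose a [dose_grid()].
#' @param mask binary 3D array (non-empty).
#' @return named numeric `c(min =, mean =, max =)` in % of prescription.
#' @export
dose_stats <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"),
            identical(dim(mask), dim(dose$dose)))
  sel <- mask == 1
  if (!any(sel)) stop("structure mask is empty")
  v <- dose$dose[sel]
  c(min = min(v), mean = mean(v), max = max(v))
}

#' Plan-quality summary for a case and dose grid
#'
#' Computes the PGTV conformity index, V_x thresholds for the liver, and
#' min/mean/max dose for every structure.
#'
#' @param case a [patient_case()].
#' @param dose a [dose_grid()] aligned to the case volume.
#' @param v_thresholds thresholds (% of prescription) evaluated on the TLV
#'   (default c(45, 50), the 27 Gy and 30 Gy levels of a 60 Gy
#'   prescription).
#' @param ci_variant passed to [conformity_index()].
#' @return list with `conformity_index`, `v_tlv` (named by threshold), and
#'   `dose_stats` (matrix: structure x min/mean/max).
#' @export
plan_metrics <- function(case, dose, v_thresholds = c(45, 50),
                         ci_variant = "ratio") {
  ci <- conformity_index(case$structures$PGTV, dose, variant = ci_variant)
  vt <- vapply(v_thresholds, function(th)
    v_xgy(dose, case$structures$TLV, th), numeric(1))
  names(vt) <- paste0("V", v_thresholds)
  ds <- t(vapply(names(case$structures), function(nm)
    dose_stats(dose, case$structures[[nm]]), numeric(3)))
  list(conformity_index = ci, v_tlv = vt, dose_stats = ds)
}
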