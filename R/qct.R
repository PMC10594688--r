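# Conventional densitometric metrics. Sign conventions follow clinical
# reporting: MLA stays on the raw (negative) HU scale, so E/I ratios land
# around 0.75-0.90; %LAA values are kept as fractions internally and
# formatted as percentages only in reports.

#' Mean lung attenuation
#'
#' Arithmetic mean HU over the mask voxels.
#'
#' @param v A [ct_volume()].
#' @param m A nonempty [lung_mask()] on the same grid.
#' @return Mean attenuation in HU.
#' @export
mla <- function(v, m) {
  stopifnot(is_ct_volume(v))
  if (!any(m$data)) stop("empty mask: MLA undefined")
  if (!all(dim(v$data) == dim(m$data)))
    stop("volume and mask shapes differ")
  mean(v$data[m$data])
}

#' Lung volume from a mask
#'
#' Voxel count times voxel volume, in litres.
#'
#' @param m A nonempty [lung_mask()].
#' @return Volume in litres.
#' @export
lung_volume <- function(m) {
  n <- sum(m$data)
  if (n == 0) stop("empty mask: volume undefined")
  n * prod(m$spacing) / 1e6          # mm^3 -> litres
}

#' Volume decrease ratio
#'
#' `100 * (V_insp - V_exp) / V_insp`, the percentage of lung volume lost
#' from inspiration to expiration. A negative value (expiratory volume
#' exceeding inspiratory) is returned with a warning: it signals a
#' paradoxical or mislabelled pair.
#'
#' @param vol_insp,vol_exp Lung volumes in litres; `vol_insp` must be
#'   positive.
#' @return VDR in percent.
#' @export
vdr <- function(vol_insp, vol_exp) {
  if (!is.finite(vol_insp) || vol_insp <= 0)
    stop("inspiratory volume must be positive")
  out <- 100 * (vol_insp - vol_exp) / vol_insp
  if (out < 0)
    warning("expiratory volume exceeds inspiratory volume (VDR ",
            signif(out, 3), "%)")
  out
}

#' Attenuation-volume index
#'
#' `(MLA_exp - MLA_insp) / VDR`: the expiratory attenuation rise per
#' percentage point of volume loss, an air-trapping index adjusted for
#' respiratory effort. Undefined when the lung did not shrink.
#'
#' @param mla_exp,mla_insp Mean lung attenuations in HU.
#' @param vdr Volume decrease ratio in percent; must be positive.
#' @return AVI in HU per percent.
#' @export
avi <- function(mla_exp, mla_insp, vdr) {
  if (!is.finite(vdr) || vdr <= 0)
    stop("AVI undefined: VDR must be positive (no or paradoxical volume change)")
  (mla_exp - mla_insp) / vdr
}

#' Expiratory-to-inspiratory MLA ratio
#'
#' `MLA_exp / MLA_insp` on raw HU values; both MLAs are negative in lung,
#' so the ratio is positive and rises with air trapping.
#'
#' @param mla_exp,mla_insp Mean lung attenuations in HU; `mla_insp` must be
#'   nonzero.
#' @return Dimensionless ratio.
#' @export
ei_ratio <- function(mla_exp, mla_insp) {
  if (!is.finite(mla_insp) || mla_insp == 0)
    stop("inspiratory MLA must be nonzero")
  mla_exp / mla_insp
}

#' Normal-density E/I ratio
#'
#' E/I ratio restricted to "seemingly normal" parenchyma on the
#' co-registered pair: voxels with inspiratory HU above `insp_thr` and
#' expiratory HU above `exp_thr` (the PRM-normal set). By default the
#' selection is joint (one region on the registered pair);
#' `selection = "per_scan"` instead averages each scan over its own
#' above-threshold voxels within the joint mask.
#'
#' @param ps A `paired_study` from [build_paired_study()].
#' @param insp_thr,exp_thr HU thresholds, defaults -950 and -856.
#' @param selection `"joint"` (default) or `"per_scan"`.
#' @return Dimensionless ratio.
#' @export
nd_ei_ratio <- function(ps, insp_thr = -950, exp_thr = -856,
                        selection = c("joint", "per_scan")) {
  selection <- match.arg(selection)
  pf <- paired_fields(ps)
  j <- pf$joint
  if (selection == "joint") {
    sel <- j & pf$insp > insp_thr & pf$exp > exp_thr
    if (!any(sel)) stop("no normal-density voxels in the joint mask")
    mean(pf$exp[sel]) / mean(pf$insp[sel])
  } else {
    si <- j & pf$insp > insp_thr
    se <- j & pf$exp > exp_thr
    if (!any(si) || !any(se)) stop("no normal-density voxels in the joint mask")
    mean(pf$exp[se]) / mean(pf$insp[si])
  }
}

#' Low-attenuation-area fraction
#'
#' Fraction of mask voxels strictly below `thr` HU. With the conventional
#' thresholds this measures air trapping (`thr = -856` on the expiratory
#' scan) or emphysema (`thr = -950` on the inspiratory scan).
#'
#' @param v A [ct_volume()].
#' @param m A nonempty [lung_mask()] on the same grid.
#' @param thr HU threshold; strict `<` comparison.
#' @return Fraction in \[0, 1\].
#' @export
laa_fraction <- function(v, m, thr) {
  stopifnot(is_ct_volume(v))
  if (!any(m$data)) stop("empty mask: LAA fraction undefined")
  if (!all(dim(v$data) == dim(m$data)))
    stop("volume and mask shapes differ")
  mean(v$data[m$data] < thr)
}
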