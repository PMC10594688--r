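# Voxel-wise classification of the co-registered pair: the parametric
# response map (PRM) joint-thresholds both scans; the air trapping index
# (ATI) thresholds the expiratory density rise within the sufficiently
# inflated inspiratory band. The two indices intentionally use different
# denominators: PRM fractions are of the whole joint mask, ATI of the
# eligible band only.

PRM_LEGEND <- c(emph = 1L, fsad = 2L, normal = 3L, unclassified = 4L)
ATI_LEGEND <- c(air_trapping = 1L, eligible_no_at = 2L, emph = 3L,
                other = 4L)

#' PRM thresholds
#'
#' @param emph_insp Inspiratory emphysema threshold, default -950 HU.
#' @param at_exp Expiratory air-trapping threshold, default -856 HU; must
#'   exceed `emph_insp`.
#' @return List of class `prm_thresholds`.
#' @export
prm_thresholds <- function(emph_insp = -950, at_exp = -856) {
  if (!(emph_insp < at_exp))
    stop("emph_insp must be below at_exp")
  structure(list(emph_insp = emph_insp, at_exp = at_exp),
            class = "prm_thresholds")
}

#' ATI configuration
#'
#' @param delta Density-rise threshold: a voxel is trapped when
#'   `exp - insp < delta`; default 60 HU.
#' @param insp_low,insp_high Inspiratory eligibility band
#'   `[insp_low, insp_high)`, defaults -950 and -856 HU.
#' @return List of class `ati_config`.
#' @export
ati_config <- function(delta = 60, insp_low = -950, insp_high = -856) {
  if (delta <= 0) stop("'delta' must be positive")
  if (!(insp_low < insp_high)) stop("'insp_low' must be below 'insp_high'")
  structure(list(delta = delta, insp_low = insp_low, insp_high = insp_high),
            class = "ati_config")
}

#' Parametric response map
#'
#' Classifies every joint-mask voxel of the co-registered pair by the
#' fixed thresholds: emphysema when inspiratory HU < `emph_insp` and
#' expiratory HU < `at_exp`; functional small airway disease (fSAD) when
#' inspiratory HU >= `emph_insp` and expiratory HU < `at_exp`; normal when
#' both are at or above their thresholds. The remaining combination
#' (inspiratory below, expiratory above) is reported separately as
#' "unclassified" so the four fractions sum to 1 over the joint mask.
#'
#' @param ps A `paired_study`.
#' @param thr A [prm_thresholds()].
#' @return List with `map` (a [label_map()]: 1 = emph, 2 = fsad,
#'   3 = normal, 4 = unclassified) and `fractions` (named, of joint-mask
#'   voxels).
#' @export
prm_classify <- function(ps, thr = prm_thresholds()) {
  pf <- paired_fields(ps)
  j <- which(pf$joint)
  if (length(j) == 0L) stop("empty joint mask")
  insp <- pf$insp[j]; exp <- pf$exp[j]
  cls <- integer(length(j))
  low_i <- insp < thr$emph_insp
  low_e <- exp < thr$at_exp
  cls[low_i & low_e] <- PRM_LEGEND[["emph"]]
  cls[!low_i & low_e] <- PRM_LEGEND[["fsad"]]
  cls[!low_i & !low_e] <- PRM_LEGEND[["normal"]]
  cls[low_i & !low_e] <- PRM_LEGEND[["unclassified"]]
  lab <- array(0L, dim(pf$joint))
  lab[j] <- cls
  fr <- vapply(PRM_LEGEND, function(k) mean(cls == k), 0)
  list(map = label_map(lab, pf$grid, PRM_LEGEND), fractions = fr)
}

#' Air trapping index map
#'
#' On the co-registered pair, the eligible set is the joint-mask voxels
#' whose inspiratory HU lies in `[insp_low, insp_high)` ("sufficiently
#' inflated" parenchyma). A voxel is trapped when its signed expiratory
#' density rise `exp - insp` is below `delta`. ATI is the trapped fraction
#' of the eligible set; the emphysema fraction (inspiratory HU <
#' `insp_low`) of the whole joint mask is reported alongside.
#'
#' @param ps A `paired_study`.
#' @param cfg An [ati_config()].
#' @return List with `map` (a [label_map()]: 1 = air trapping,
#'   2 = eligible without trapping, 3 = emphysema, 4 = other parenchyma),
#'   `ati` and `emph` fractions.
#' @export
ati_map <- function(ps, cfg = ati_config()) {
  pf <- paired_fields(ps)
  j <- which(pf$joint)
  if (length(j) == 0L) stop("empty joint mask")
  insp <- pf$insp[j]; exp <- pf$exp[j]
  eligible <- insp >= cfg$insp_low & insp < cfg$insp_high
  if (!any(eligible)) stop("no eligible inspiratory parenchyma in the band")
  trapped <- eligible & (exp - insp) < cfg$delta
  emph <- insp < cfg$insp_low
  cls <- rep(ATI_LEGEND[["other"]], length(j))
  cls[eligible] <- ATI_LEGEND[["eligible_no_at"]]
  cls[trapped] <- ATI_LEGEND[["air_trapping"]]
  cls[emph] <- ATI_LEGEND[["emph"]]
  lab <- array(0L, dim(pf$joint))
  lab[j] <- cls
  list(map = label_map(lab, pf$grid, ATI_LEGEND),
       ati = sum(trapped) / sum(eligible),
       emph = mean(emph))
}

#' Render a classified slice overlay
#'
#' Writes (or returns) an axial/coronal/sagittal slice of the CT volume in
#' grayscale with the label-map classes colour-coded on top.
#'
#' @param ps A `paired_study` (the analysis-frame CT is used as backdrop).
#' @param map A [label_map()] on the analysis grid.
#' @param slice_axis 1, 2 or 3: the array axis sliced.
#' @param slice_index Slice number along that axis (1-based, in range).
#' @param palette Named vector of colours, one per legend class; defaults
#'   to a PRM-style palette.
#' @param path Optional PNG output path; when `NULL` the RGB array is only
#'   returned.
#' @param alpha Overlay opacity in \[0, 1\], default 0.6.
#' @param window HU display window for the backdrop,
#'   default `c(-1024, 200)`.
#' @return Invisibly, the `h x w x 3` RGB array (also written to `path`
#'   if given).
#' @export
render_overlay <- function(ps, map, slice_axis = 3,
                           slice_index, palette = NULL, path = NULL,
                           alpha = 0.6, window = c(-1024, 200)) {
  pf <- paired_fields(ps)
  d <- dim(pf$insp)
  if (!slice_axis %in% 1:3) stop("'slice_axis' must be 1, 2 or 3")
  if (slice_index < 1 || slice_index > d[slice_axis])
    stop("slice index ", slice_index, " out of range 1..", d[slice_axis])
  if (is.null(palette)) {
    palette <- c("#D7263D", "#F4A100", "#2E933C", "#4464AD")[
      seq_along(map$legend)]
    names(palette) <- names(map$legend)
  }
  if (!all(names(map$legend) %in% names(palette)))
    stop("palette must name every legend class")
  take <- function(a) {
    sl <- switch(slice_axis, a[slice_index, , ], a[, slice_index, ],
                 a[, , slice_index])
    t(sl)[rev(seq_len(ncol(sl))), , drop = FALSE]   # image-style rows
  }
  bg <- take(pf$insp)
  bg <- (pmin(pmax(bg, window[1]), window[2]) - window[1]) /
    (window[2] - window[1])
  lab <- take(map$data)
  rgb <- array(rep(bg, 3), c(dim(bg), 3))
  for (nm in names(map$legend)) {
    code <- map$legend[[nm]]
    sel <- lab == code
    if (!any(sel)) next
    col <- grDevices::col2rgb(palette[[nm]]) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[sel] <- (1 - alpha) * plane[sel] + alpha * col[ch]
      rgb[, , ch] <- plane
    }
  }
  attr(rgb, "legend") <- palette[names(map$legend)]
  if (!is.null(path)) png::writePNG(rgb, path)
  invisible(rgb)
}
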