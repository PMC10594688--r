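# The user-facing entry point: fit the whole quantification to one
# inspiratory/expiratory pair and return a classed result. All numbers in
# the object come from the exported per-metric functions; this layer only
# wires them together.

#' Quantify air trapping on a paired inspiratory/expiratory study
#'
#' Runs the full per-subject pipeline: (optional) threshold segmentation
#' when no masks are given, expiration-to-inspiration affine registration,
#' conventional densitometry (MLA, lung volumes, VDR, AVI, E/I, ND E/I,
#' %LAA), the voxel-wise parametric response map and the air trapping
#' index map.
#'
#' @param insp,exp Inspiratory and expiratory [ct_volume()] objects.
#' @param insp_mask,exp_mask Optional [lung_mask()] objects; computed with
#'   [segment_lungs_threshold()] when `NULL`.
#' @param config A [registration_config()].
#' @param prm [prm_thresholds()] for the response map.
#' @param ati [ati_config()] for the air trapping index.
#' @param laa_on_registered Compute the expiratory LAA fraction on the
#'   registered pair instead of the native expiratory scan; default
#'   `FALSE` (registration-free summary, conventional practice).
#' @param transform Optional precomputed [affine_transform()]; skips
#'   registration.
#' @return Object of class `paired_qct` with elements `study` (the
#'   co-registered `paired_study`), `metrics` (named list of scalars),
#'   `prm`, `ati` (label maps + fractions), and the configurations used.
#'   `coef()` returns the metrics as a named vector; `plot()` renders a
#'   map overlay.
#' @examples
#' ph <- make_paired_phantom(phantom_spec(noise_sd = 0))
#' fit <- paired_qct(ph$insp, ph$exp, ph$insp_mask, ph$exp_mask,
#'                   transform = ph$truth$motion)
#' coef(fit)["prm_fsad"]
#' @export
paired_qct <- function(insp, exp, insp_mask = NULL, exp_mask = NULL,
                       config = registration_config(),
                       prm = prm_thresholds(), ati = ati_config(),
                       laa_on_registered = FALSE, transform = NULL) {
  if (is.null(insp_mask)) insp_mask <- segment_lungs_threshold(insp)
  if (is.null(exp_mask)) exp_mask <- segment_lungs_threshold(exp)
  ps <- build_paired_study(insp, insp_mask, exp, exp_mask, config,
                           transform = transform)
  prm_res <- prm_classify(ps, prm)
  ati_res <- ati_map(ps, ati)

  mla_insp <- mla(insp, insp_mask)
  mla_exp <- mla(exp, exp_mask)
  vol_insp <- lung_volume(insp_mask)
  vol_exp <- lung_volume(exp_mask)
  vdr_v <- vdr(vol_insp, vol_exp)
  metrics <- list(
    mla_insp = mla_insp, mla_exp = mla_exp,
    vol_insp = vol_insp, vol_exp = vol_exp,
    vdr = vdr_v,
    avi = if (vdr_v > 0) avi(mla_exp, mla_insp, vdr_v) else NA_real_,
    ei_ratio = ei_ratio(mla_exp, mla_insp),
    nd_ei_ratio = nd_ei_ratio(ps, prm$emph_insp, prm$at_exp),
    laa_exp_856 = if (laa_on_registered) {
      pf <- paired_fields(ps)
      mean(pf$exp[pf$joint] < prm$at_exp)
    } else laa_fraction(exp, exp_mask, prm$at_exp),
    laa_ins_950 = laa_fraction(insp, insp_mask, prm$emph_insp),
    prm_emph = unname(prm_res$fractions["emph"]),
    prm_fsad = unname(prm_res$fractions["fsad"]),
    prm_normal = unname(prm_res$fractions["normal"]),
    prm_unclassified = unname(prm_res$fractions["unclassified"]),
    ati = ati_res$ati
  )
  structure(list(study = ps, metrics = metrics, prm = prm_res,
                 ati = ati_res,
                 config = list(registration = config, prm = prm, ati = ati,
                               laa_on_registered = laa_on_registered)),
            class = "paired_qct")
}

#' @export
coef.paired_qct <- function(object, ...) {
  unlist(object$metrics)
}

#' @export
print.paired_qct <- function(x, ...) {
  m <- x$metrics
  cat("Paired-CT air trapping quantification\n")
  cat(sprintf("  lung volume: %.2f L insp, %.2f L exp (VDR %.1f%%)\n",
              m$vol_insp, m$vol_exp, m$vdr))
  cat(sprintf("  MLA: %.1f HU insp, %.1f HU exp; E/I %.3f, ND E/I %.3f, AVI %s\n",
              m$mla_insp, m$mla_exp, m$ei_ratio, m$nd_ei_ratio,
              if (is.na(m$avi)) "n/a" else sprintf("%.2f", m$avi)))
  cat(sprintf("  %%LAA: exp<-856 %.1f%%, insp<-950 %.1f%%\n",
              100 * m$laa_exp_856, 100 * m$laa_ins_950))
  cat(sprintf("  PRM: emph %.1f%%, fSAD %.1f%%, normal %.1f%%, unclassified %.1f%%\n",
              100 * m$prm_emph, 100 * m$prm_fsad, 100 * m$prm_normal,
              100 * m$prm_unclassified))
  cat(sprintf("  ATI: %.1f%% of the -950..-856 HU inspiratory band\n",
              100 * m$ati))
  invisible(x)
}

#' @export
summary.paired_qct <- function(object, ...) {
  print(object)
  print(object$study)
  invisible(object$metrics)
}

#' @describeIn paired_qct Render a PRM or ATI overlay slice.
#' @param x A `paired_qct` object.
#' @param method `"prm"` or `"ati"`.
#' @param slice_axis,slice_index Slice selection as in [render_overlay()];
#'   the middle slice of axis 3 by default.
#' @param ... Passed to [render_overlay()].
#' @export
plot.paired_qct <- function(x, method = c("prm", "ati"), slice_axis = 3,
                            slice_index = NULL, ...) {
  method <- match.arg(method)
  map <- if (method == "prm") x$prm$map else x$ati$map
  d <- dim(map$data)
  if (is.null(slice_index)) slice_index <- ceiling(d[slice_axis] / 2)
  rgb <- render_overlay(x$study, map, slice_axis, slice_index, ...)
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(c(0, 1), c(0, 1), type = "n", axes = FALSE, xlab = "",
                 ylab = "", main = paste(toupper(method), "overlay, slice",
                                         slice_index))
  graphics::rasterImage(rgb, 0, 0, 1, 1)
  invisible(x)
}
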