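# Synthetic paired-CT phantoms with known composition and known
# inter-phase motion, plus a cohort simulator. The phantom is a body
# ellipsoid (+40 HU) holding two lung ellipsoids in a -1000 HU air box;
# the lung is partitioned into compact "emph", "fsad" and "normal"
# compartments with exact voxel-count fractions. The expiratory phase is
# generated analytically in its own frame by evaluating the inspiratory
# geometry at motion-transformed coordinates, so the pipeline must
# register it back — the same path clinical data take. Every metric the
# pipeline computes has a closed-form oracle in `truth`.

#' Tissue class table for phantoms
#'
#' Defaults emulate parenchyma as reported in quantitative-CT practice:
#' normal lung around -890 HU at inspiration rising by about 150 HU on a
#' proper exhale; air-trapped (fSAD) lung in the same inspiratory band but
#' rising by far less than 60 HU, so its expiratory density stays well
#' below the -856 HU threshold; emphysema below -950 HU at inspiration
#' and still below -856 HU at expiration. Classes are laid out from a
#' disease focus outward in table order (see [make_paired_phantom()]).
#'
#' @param name,fraction,insp_mean,exp_delta Vectors of equal length:
#'   class label, lung volume fraction (summing to 1), inspiratory mean HU
#'   and expiratory HU rise.
#' @return A data frame with one row per class.
#' @export
phantom_classes <- function(name = c("emph", "fsad", "normal"),
                            fraction = c(0.05, 0.20, 0.75),
                            insp_mean = c(-980, -920, -890),
                            exp_delta = c(10, 10, 150)) {
  if (abs(sum(fraction) - 1) > 1e-9)
    stop("class fractions must sum to 1")
  data.frame(name = name, fraction = fraction, insp_mean = insp_mean,
             exp_delta = exp_delta, stringsAsFactors = FALSE)
}

#' Phantom specification
#'
#' @param shape Grid dimensions, default `c(64, 64, 48)`.
#' @param spacing Voxel size in mm, default `c(2.5, 2.5, 2.5)`.
#' @param body_hu Soft-tissue HU of the body ellipsoid, default 40.
#' @param classes Tissue classes, a [phantom_classes()] table.
#' @param motion [affine_transform()] mapping expiratory-frame points to
#'   inspiratory-frame points, or `NULL` for identity (no motion). See
#'   [exhale_motion()] for a realistic default exhale.
#' @param noise_sd Independent Gaussian HU noise per voxel and phase,
#'   default 10; 0 disables noise.
#' @param texture_amp Amplitude (HU) of a smooth deterministic parenchymal
#'   texture field shared between phases (it moves with the tissue, the
#'   way vessels and septa do, and is what makes the phases registrable);
#'   bounded so class HU stay within their threshold bands, so planted
#'   fractions remain exact at zero noise. Default 20; 0 disables.
#' @param seed RNG seed for the noise, default 1.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 48), spacing = c(2.5, 2.5, 2.5),
                         body_hu = 40, classes = phantom_classes(),
                         motion = NULL, noise_sd = 10, texture_amp = 20,
                         seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), length(spacing) == 3L,
            all(spacing > 0), noise_sd >= 0, texture_amp >= 0)
  if (!is.null(motion) && !inherits(motion, "affine_transform"))
    stop("'motion' must be an affine_transform or NULL")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 body_hu = body_hu, classes = classes, motion = motion,
                 noise_sd = noise_sd, texture_amp = texture_amp,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth bounded texture: mean of three sinusoidal products with
# incommensurate wavevectors (|T| <= amp), evaluated at inspiratory-frame
# physical points so it rides along with the tissue under motion.
phantom_texture <- function(pts, amp) {
  if (amp == 0) return(numeric(nrow(pts)))
  k1 <- 2 * pi / c(23, 31, 27); k2 <- 2 * pi / c(37, 19, 43)
  k3 <- 2 * pi / c(17, 41, 29); k4 <- 2 * pi / c(9, 12.5, 10.5)
  s1 <- sin(pts %*% k1 + 0.7) * sin(pts %*% (k2 / 2) + 2.1)
  s2 <- sin(pts %*% k2 + 1.3) * sin(pts %*% (k3 / 2) + 0.4)
  s3 <- sin(pts %*% k3 + 2.9) * sin(pts %*% (k1 / 2) + 1.8)
  s4 <- sin(pts %*% k4 + 0.3) * sin(pts %*% (k4[c(2, 3, 1)] / 1.7) + 1.1)
  amp * drop(s1 + s2 + s3 + s4) / 4
}

#' A realistic exhale motion for phantoms
#'
#' Uniform contraction of the thorax about its centre (expiration holds
#' less volume), optionally with a small translation. The returned
#' transform maps expiratory-frame points to inspiratory-frame points, as
#' [phantom_spec()] expects, so a `scale` of 0.88 means expiratory lung
#' linear dimensions are 88% of inspiratory ones (a volume decrease ratio
#' near 32%).
#'
#' @param spec A [phantom_spec()] (supplies the centre).
#' @param scale Linear contraction factor, default 0.88.
#' @param shift Expiratory-frame translation in mm, default
#'   `c(2, -1, 1.5)`.
#' @return An [affine_transform()].
#' @export
exhale_motion <- function(spec, scale = 0.88, shift = c(2, -1, 1.5)) {
  ctr <- (spec$shape - 1) / 2 * spec$spacing
  # exp point p maps to insp point: q = (p - ctr)/scale + ctr - shift/scale
  affine_transform(diag(3) / scale, -as.numeric(shift) / scale, ctr)
}

inside_ellipsoid <- function(pts, ctr, semi) {
  rowSums(sweep(sweep(pts, 2, ctr), 2, semi, `/`)^2) <= 1
}

# Geometry helpers shared by both phases: everything is evaluated at
# arbitrary physical points of the inspiratory frame.
phantom_geometry <- function(spec) {
  ext <- (spec$shape - 1) * spec$spacing
  ctr <- ext / 2
  body_semi <- ext * c(0.44, 0.40, 0.46)
  lung_semi <- ext * c(0.15, 0.23, 0.33)
  lung_ctr <- list(ctr + c(-0.22, 0, 0) * ext[1],
                   ctr + c(0.22, 0, 0) * ext[1])
  list(ctr = ctr, body_semi = body_semi, lung_semi = lung_semi,
       lung_ctr = lung_ctr)
}

phantom_lung_membership <- function(pts, geo) {
  inside_ellipsoid(pts, geo$lung_ctr[[1]], geo$lung_semi) |
    inside_ellipsoid(pts, geo$lung_ctr[[2]], geo$lung_semi)
}

# Class layout key: distance from a disease focus inside the left lung.
# Classes are assigned in table order from the focus outward (emphysema
# core, fSAD shell, normal rest), so compartments are compact — low
# surface-to-volume keeps interpolation mixing at class boundaries from
# dominating the planted fractions under motion. Boundaries are fixed
# from the inspiratory grid so planted fractions are exact voxel counts.
phantom_class_key <- function(pts, geo) {
  # the coordinate term breaks exact distance ties (symmetric voxel
  # pairs) so the count partition and the continuous boundaries agree
  sqrt(rowSums(sweep(pts, 2, geo$lung_ctr[[1]])^2)) +
    1e-7 * (pts[, 1] + pts[, 2] / 1e3 + pts[, 3] / 1e6)
}

#' Generate a paired inspiratory/expiratory phantom study
#'
#' Builds the inspiratory volume on the spec's grid, partitions the lung
#' into the spec's tissue classes with exact voxel-count fractions, and
#' generates the expiratory volume analytically in the expiratory frame
#' (inspiratory geometry evaluated at motion-transformed points, plus each
#' class's expiratory HU rise). Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `insp`, `insp_mask`, `exp`, `exp_mask` (the phantom
#'   study) and `truth`: per-class voxel counts, planted fractions, the
#'   applied motion and closed-form oracle values for every metric the
#'   pipeline computes (zero-noise expectations).
#' @export
make_paired_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  ext <- (spec$shape - 1) * spec$spacing
  geom <- list(spacing = spec$spacing, origin = c(0, 0, 0),
               orientation = diag(3))
  idx <- arrayInd(seq_len(prod(spec$shape)), spec$shape)
  pts <- voxel_to_physical(geom, idx)

  lung <- phantom_lung_membership(pts, geo)
  body <- inside_ellipsoid(pts, geo$ctr, geo$body_semi)
  if (!any(lung)) stop("phantom lung compartments are empty")

  # exact-count compartment partition of the inspiratory lung
  key <- phantom_class_key(pts[lung, , drop = FALSE], geo)
  ord <- order(key)
  n_lung <- sum(lung)
  cl <- spec$classes
  # largest-remainder apportionment: achieved fractions within 1/n_lung
  # of the nominal ones
  exact <- cl$fraction * n_lung
  counts <- floor(exact)
  rem <- n_lung - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  class_idx <- integer(n_lung)
  class_idx[ord] <- rep.int(seq_len(nrow(cl)), counts)
  # continuous compartment boundaries (key midpoints) for expiratory evaluation
  cuts <- cumsum(counts)
  sorted_key <- key[ord]
  bounds <- vapply(cuts[-length(cuts)], function(k)
    (sorted_key[k] + sorted_key[min(k + 1, n_lung)]) / 2, 0)

  class_at <- function(p) {
    k <- phantom_class_key(p, geo)
    findInterval(k, bounds) + 1L
  }

  insp_dat <- array(-1000, spec$shape)
  insp_dat[body] <- spec$body_hu
  insp_dat[lung] <- cl$insp_mean[class_idx] +
    phantom_texture(pts[lung, , drop = FALSE], spec$texture_amp)
  insp_mask_dat <- array(lung, spec$shape)

  motion <- if (is.null(spec$motion))
    affine_transform(center = geo$ctr) else spec$motion
  qts <- transform_points(motion, pts)
  lung_e <- phantom_lung_membership(qts, geo)
  body_e <- inside_ellipsoid(qts, geo$ctr, geo$body_semi)
  exp_dat <- array(-1000, spec$shape)
  exp_dat[body_e] <- spec$body_hu
  ce <- integer(0); tex_e <- numeric(0)
  if (any(lung_e)) {
    qle <- qts[lung_e, , drop = FALSE]
    ce <- class_at(qle)
    tex_e <- phantom_texture(qle, spec$texture_amp)
    exp_dat[lung_e] <- cl$insp_mean[ce] + cl$exp_delta[ce] + tex_e
  }
  exp_mask_dat <- array(lung_e, spec$shape)
  tex_i <- phantom_texture(pts[lung, , drop = FALSE], spec$texture_amp)
  k <- nrow(cl)
  texsum_i <- vapply(seq_len(k), function(j) sum(tex_i[class_idx == j]), 0)
  texsum_e <- vapply(seq_len(k), function(j) sum(tex_e[ce == j]), 0)
  counts_e <- tabulate(ce, nbins = k)

  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(spec$seed)
    insp_dat <- insp_dat + stats::rnorm(length(insp_dat), 0, spec$noise_sd)
    exp_dat <- exp_dat + stats::rnorm(length(exp_dat), 0, spec$noise_sd)
  }

  insp <- ct_volume(insp_dat, spec$spacing, orientation = diag(3))
  exp <- ct_volume(exp_dat, spec$spacing, orientation = diag(3))
  list(insp = insp,
       insp_mask = lung_mask(insp_mask_dat, insp),
       exp = exp,
       exp_mask = lung_mask(exp_mask_dat, exp),
       truth = phantom_truth(spec, counts, counts_e, texsum_i, texsum_e,
                             motion))
}

# Closed-form zero-noise oracle for every pipeline metric. Class means
# and counts come from the design; the (bounded) texture field never
# crosses a classification threshold, so it contributes only its exact
# per-class sums to the attenuation averages.
phantom_truth <- function(spec, counts, counts_e, texsum_i, texsum_e,
                          motion, thr = prm_thresholds(),
                          ati = ati_config()) {
  cl <- spec$classes
  n_lung <- sum(counts); n_e <- sum(counts_e)
  fr <- counts / n_lung
  mu_i <- cl$insp_mean
  mu_e <- cl$insp_mean + cl$exp_delta
  detM <- det(motion$matrix)           # exp -> insp expansion factor
  vol_insp <- n_lung * prod(spec$spacing) / 1e6
  vol_exp <- n_e * prod(spec$spacing) / 1e6
  mla_insp <- sum(counts * mu_i + texsum_i) / n_lung
  mla_exp <- sum(counts_e * mu_e + texsum_e) / n_e
  vdr_v <- 100 * (1 - vol_exp / vol_insp)
  is_emph_i <- mu_i < thr$emph_insp
  is_low_e <- mu_e < thr$at_exp
  prm <- c(emph = sum(fr[is_emph_i & is_low_e]),
           fsad = sum(fr[!is_emph_i & is_low_e]),
           normal = sum(fr[!is_emph_i & !is_low_e]),
           unclassified = sum(fr[is_emph_i & !is_low_e]))
  nd_sel <- !is_emph_i & !is_low_e
  eligible <- mu_i >= ati$insp_low & mu_i < ati$insp_high
  trapped <- eligible & cl$exp_delta < ati$delta
  fr_e <- if (n_e > 0) counts_e / n_e else fr
  list(
    class_counts = stats::setNames(counts, cl$name),
    fractions = stats::setNames(fr, cl$name),
    motion = motion, det_motion = detM,
    mla_insp = mla_insp, mla_exp = mla_exp,
    vol_insp = vol_insp, vol_exp = vol_exp,
    vdr = vdr_v,
    avi = if (vdr_v > 0) (mla_exp - mla_insp) / vdr_v else NA_real_,
    ei_ratio = mla_exp / mla_insp,
    nd_ei_ratio = if (any(nd_sel))
      sum(counts[nd_sel] * mu_e[nd_sel] + texsum_i[nd_sel]) /
        sum(counts[nd_sel] * mu_i[nd_sel] + texsum_i[nd_sel])
    else NA_real_,
    laa_exp_856 = sum(fr_e[mu_e < -856]),
    laa_ins_950 = sum(fr[mu_i < -950]),
    prm = prm,
    ati = if (any(eligible)) sum(fr[trapped]) / sum(fr[eligible])
      else NA_real_
  )
}

#' Cohort simulation specification
#'
#' Per-group multivariate-normal moments for the QCT metrics and
#' spirometry of a case-control cohort. Defaults reproduce a chemical
#' warfare exposure case-control study of published scale: 46 cases and
#' 27 controls, patient-group air-trapping fractions around 0.2-0.35, and
#' percent-predicted spirometry depressed in the cases.
#'
#' @param n_case,n_control Group sizes, defaults 46 and 27.
#' @param mean_case,mean_control,sd_case,sd_control Named numeric vectors
#'   over the same variables.
#' @param correlation Shared within-group correlation matrix (variables in
#'   the same order), or `NULL` for the default structure.
#' @param smoking_rate_case Probability a case smokes, default 8/46;
#'   controls never smoke.
#' @param seed RNG seed, default 1.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case = 46, n_control = 27,
                        mean_case = NULL, mean_control = NULL,
                        sd_case = NULL, sd_control = NULL,
                        correlation = NULL,
                        smoking_rate_case = 8 / 46, seed = 1) {
  def_mean_case <- c(ei_ratio = 0.85, nd_ei_ratio = 0.86, avi = 3.38,
                     prm_emph = 0.10, laa_ins_950 = 0.29, prm_fsad = 0.23,
                     laa_exp_856 = 0.32, ati = 0.35,
                     fvc = 72.73, fev1 = 79.84, fev1_fvc = 79.81,
                     mmef = 82.90, age = 53.78, bmi = 26.57)
  def_mean_control <- c(ei_ratio = 0.77, nd_ei_ratio = 1.23, avi = 3.87,
                        prm_emph = 0.05, laa_ins_950 = 0.27,
                        prm_fsad = 0.16, laa_exp_856 = 0.21, ati = 0.24,
                        fvc = 92.11, fev1 = 91.42, fev1_fvc = 88.56,
                        mmef = 89.87, age = 52.33, bmi = 26.24)
  def_sd_case <- c(ei_ratio = 0.08, nd_ei_ratio = 0.56, avi = 1.33,
                   prm_emph = 0.11, laa_ins_950 = 0.08, prm_fsad = 0.08,
                   laa_exp_856 = 0.13, ati = 0.15,
                   fvc = 20.78, fev1 = 24.23, fev1_fvc = 10.93,
                   mmef = 37.31, age = 9.43, bmi = 4.00)
  def_sd_control <- c(ei_ratio = 0.05, nd_ei_ratio = 1.88, avi = 0.83,
                      prm_emph = 0.02, laa_ins_950 = 0.09, prm_fsad = 0.03,
                      laa_exp_856 = 0.05, ati = 0.05,
                      fvc = 15.90, fev1 = 14.89, fev1_fvc = 11.97,
                      mmef = 12.50, age = 12.55, bmi = 2.27)
  mean_case <- if (is.null(mean_case)) def_mean_case else mean_case
  mean_control <- if (is.null(mean_control)) def_mean_control
    else mean_control
  sd_case <- if (is.null(sd_case)) def_sd_case else sd_case
  sd_control <- if (is.null(sd_control)) def_sd_control else sd_control
  vars <- names(mean_case)
  if (is.null(vars) || !identical(vars, names(mean_control)) ||
      !identical(vars, names(sd_case)) || !identical(vars, names(sd_control)))
    stop("mean/sd vectors must share the same variable names")
  if (is.null(correlation)) correlation <- default_cohort_correlation(vars)
  correlation <- as.matrix(correlation)
  if (!all(dim(correlation) == length(vars)) ||
      max(abs(correlation - t(correlation))) > 1e-8)
    stop("'correlation' must be a symmetric matrix over the variables")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("'correlation' is not positive semi-definite")
  stopifnot(n_case >= 2, n_control >= 2)
  structure(list(n_case = n_case, n_control = n_control, vars = vars,
                 mean_case = mean_case, mean_control = mean_control,
                 sd_case = sd_case, sd_control = sd_control,
                 correlation = correlation,
                 smoking_rate_case = smoking_rate_case,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Moderate within-group structure: air-trapping metrics rise together and
# track spirometric obstruction negatively; spirometry indices co-vary.
default_cohort_correlation <- function(vars) {
  at <- intersect(c("prm_fsad", "laa_exp_856", "ati", "ei_ratio"), vars)
  emph <- intersect(c("prm_emph", "laa_ins_950"), vars)
  spiro <- intersect(c("fvc", "fev1", "fev1_fvc", "mmef"), vars)
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_block <- function(a, b, r) {
    for (i in a) for (j in b) if (i != j) R[i, j] <<- R[j, i] <<- r
  }
  set_block(at, at, 0.55)
  set_block(emph, emph, 0.45)
  set_block(at, emph, 0.30)
  set_block(spiro, spiro, 0.60)
  set_block(at, spiro, -0.35)
  set_block(emph, spiro, -0.20)
  R
}

#' Simulate a case-control cohort table
#'
#' Draws each group from a multivariate normal with the spec's moments,
#' truncated to each variable's domain (fractions to \[0, 1\], ratios and
#' percent-predicted spirometry to positive values) by redrawing
#' out-of-domain entries. Deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with `subject_id`, `group` (factor case/control),
#'   `smoking` (0/1) and one column per spec variable.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  draw_group <- function(n, mu, sd) {
    D <- diag(sd, nrow = length(sd))
    Sigma <- D %*% spec$correlation %*% D
    x <- MASS::mvrnorm(n, mu, Sigma)
    colnames(x) <- spec$vars
    lo <- ifelse(spec$vars %in% c("prm_emph", "prm_fsad", "laa_exp_856",
                                  "laa_ins_950", "ati"), 0,
                 ifelse(spec$vars %in% c("age", "bmi"), -Inf, 1e-6))
    hi <- ifelse(spec$vars %in% c("prm_emph", "prm_fsad", "laa_exp_856",
                                  "laa_ins_950", "ati"), 1, Inf)
    # truncation by whole-row rejection: redrawing single elements would
    # break the joint dependence exactly at the high-leverage tail points
    for (it in 1:100) {
      bad <- which(rowSums(sweep(x, 2, lo, `<`) |
                             sweep(x, 2, hi, `>`)) > 0)
      if (length(bad) == 0) break
      redraw <- MASS::mvrnorm(n, mu, Sigma)
      x[bad, ] <- redraw[seq_along(bad), , drop = FALSE]
    }
    x <- pmin(pmax(x, matrix(lo, nrow(x), ncol(x), byrow = TRUE)),
              matrix(hi, nrow(x), ncol(x), byrow = TRUE))
    x
  }
  xc <- draw_group(spec$n_case, spec$mean_case, spec$sd_case)
  xk <- draw_group(spec$n_control, spec$mean_control, spec$sd_control)
  n <- spec$n_case + spec$n_control
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = factor(rep(c("case", "control"),
                       c(spec$n_case, spec$n_control)),
                   levels = c("control", "case")),
    smoking = c(stats::rbinom(spec$n_case, 1, spec$smoking_rate_case),
                integer(spec$n_control)),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(rbind(xc, xk)))
}
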