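# Expiration-to-inspiration alignment: 3-D affine registration driven by
# a Mattes-style mutual-information metric (32-bin joint histogram with
# linear Parzen windows), evaluated on voxels sampled inside the fixed
# lung mask, optimised coarse-to-fine over a block-mean image pyramid
# with a quasi-Newton (BFGS) optimiser. Everything is deterministic given
# the configuration's sampling seed.

#' Registration configuration
#'
#' @param pyramid Integer downsampling factors, coarse to fine
#'   (default `c(4, 2, 1)`).
#' @param max_iter Optimiser iteration cap per pyramid level (default 200).
#' @param n_samples Number of fixed-mask voxels sampled for the metric at
#'   each level (default 16000; all voxels if fewer).
#' @param bins Histogram bins per image for mutual information (default 32).
#' @param seed Sampling seed making the metric deterministic (default 42).
#' @param direction `"insp_frame"` (default): expiration is resampled into
#'   the inspiratory frame; `"exp_frame"` swaps the roles.
#' @param interpolation Intensity interpolation used when resampling the
#'   moving CT: `"nearest"` (default, keeping HU values crisp so joint
#'   thresholding is not blurred across tissue edges) or `"linear"`.
#'   Masks always use nearest-neighbour.
#' @param on_nonconvergence `"warn"` (default) or `"error"` when the final
#'   level hits the iteration cap.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(pyramid = c(4, 2, 1), max_iter = 200,
                                n_samples = 16000, bins = 32, seed = 42,
                                direction = c("insp_frame", "exp_frame"),
                                interpolation = c("nearest", "linear"),
                                on_nonconvergence = c("warn", "error")) {
  structure(list(pyramid = as.integer(pyramid),
                 max_iter = as.integer(max_iter),
                 n_samples = as.integer(n_samples), bins = as.integer(bins),
                 seed = as.integer(seed),
                 direction = match.arg(direction),
                 interpolation = match.arg(interpolation),
                 on_nonconvergence = match.arg(on_nonconvergence)),
            class = "registration_config")
}

# Trilinear (or nearest) sampling of a gridded volume at physical points.
# Returns list(values, valid); invalid points get `fill`.
sample_volume <- function(data, geom, pts, interpolation = "linear",
                          fill = -1024) {
  idx <- physical_to_voxel(geom, pts)
  d <- dim(data)
  n <- nrow(idx)
  out <- rep(fill, n)
  if (interpolation == "nearest") {
    ri <- round(idx)
    valid <- ri[, 1] >= 1 & ri[, 1] <= d[1] & ri[, 2] >= 1 &
      ri[, 2] <= d[2] & ri[, 3] >= 1 & ri[, 3] <= d[3]
    lin <- ri[valid, 1] + (ri[valid, 2] - 1) * d[1] +
      (ri[valid, 3] - 1) * d[1] * d[2]
    out[valid] <- data[lin]
    return(list(values = out, valid = valid))
  }
  valid <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
    idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  if (any(valid)) {
    p <- idx[valid, , drop = FALSE]
    i0 <- pmin(pmax(floor(p), 1), rep(pmax(d - 1L, 1L), each = nrow(p)))
    i0 <- matrix(i0, ncol = 3)
    f <- p - i0
    # singleton axes: collapse to the only voxel with zero offset
    s1 <- d[1]; s2 <- d[1] * d[2]
    ox <- if (d[1] > 1) 1 else { f[, 1] <- 0; 0 }
    oy <- if (d[2] > 1) s1 else { f[, 2] <- 0; 0 }
    oz <- if (d[3] > 1) s2 else { f[, 3] <- 0; 0 }
    base <- i0[, 1] + (i0[, 2] - 1) * s1 + (i0[, 3] - 1) * s2
    v000 <- data[base];            v100 <- data[base + ox]
    v010 <- data[base + oy];       v110 <- data[base + ox + oy]
    v001 <- data[base + oz];       v101 <- data[base + ox + oz]
    v011 <- data[base + oy + oz];  v111 <- data[base + ox + oy + oz]
    fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
    out[valid] <-
      (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                    fy * ((1 - fx) * v010 + fx * v110)) +
      fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
              fy * ((1 - fx) * v011 + fx * v111))
  }
  list(values = out, valid = valid)
}

# Weighted histogram accumulation.
tabulate_w <- function(idx, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# Mattes-style mutual information with linear Parzen windows.
mattes_mi <- function(f, m, f_range, m_range, bins = 32) {
  n <- length(f)
  if (n < 10) return(0)
  uf <- (f - f_range[1]) / max(f_range[2] - f_range[1], 1e-9) * (bins - 1)
  um <- (m - m_range[1]) / max(m_range[2] - m_range[1], 1e-9) * (bins - 1)
  uf <- pmin(pmax(uf, 0), bins - 1)
  um <- pmin(pmax(um, 0), bins - 1)
  i0 <- pmin(floor(uf), bins - 2); wf <- uf - i0
  j0 <- pmin(floor(um), bins - 2); wm <- um - j0
  H <- numeric(bins * bins)
  for (di in 0:1) for (dj in 0:1) {
    w <- (if (di == 0) 1 - wf else wf) * (if (dj == 0) 1 - wm else wm)
    idx <- (i0 + di) * bins + (j0 + dj) + 1
    H <- H + tabulate_w(idx, w, bins * bins)
  }
  P <- H / sum(H)
  Pm <- matrix(P, bins, bins, byrow = TRUE)   # row = fixed bin
  pf <- rowSums(Pm); pm <- colSums(Pm)
  nz <- Pm > 0
  sum(Pm[nz] * log(Pm[nz] / (pf[row(Pm)[nz]] * pm[col(Pm)[nz]])))
}

# Binary 6-neighbour erosion, `iters` times. Used to restrict metric
# sampling to interior lung: boundary voxels interpolate across the
# lung/body edge and bias the metric toward over-contraction.
erode_mask <- function(m, iters = 1) {
  d <- dim(m)
  shift <- function(a, ax, s) {
    i <- lapply(d, seq_len)
    i[[ax]] <- pmin(pmax(i[[ax]] + s, 1L), d[ax])
    do.call(`[`, c(list(a), i))
  }
  for (k in seq_len(iters)) {
    out <- m
    out[c(1, d[1]), , ] <- FALSE
    out[, c(1, d[2]), ] <- FALSE
    out[, , c(1, d[3])] <- FALSE
    for (ax in 1:3) for (s in c(-1L, 1L)) out <- out & shift(m, ax, s)
    m <- out
  }
  m
}

# Separable Gaussian smoothing by shifted-array accumulation, used on
# the finest pyramid level (coarser levels are already smoothed by the
# block mean). Cuts the voxel-noise floor of the metric while structure
# coarser than ~2 voxels survives.
smooth_volume_3d <- function(a, sigma = 0.7) {
  r <- max(1L, ceiling(2 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  d <- dim(a)
  for (ax in 1:3) {
    out <- array(0, d)
    for (k in -r:r) {
      i <- lapply(d, seq_len)
      i[[ax]] <- pmin(pmax(i[[ax]] + k, 1L), d[ax])   # replicate edges
      out <- out + w[k + r + 1] * do.call(`[`, c(list(a), i))
    }
    a <- out
  }
  a
}

# Block-mean downsampling of a volume by integer factor f (crops partial
# edge blocks). For masks, pass threshold to re-binarise.
downsample_volume <- function(data, geom, f) {
  if (f == 1L) return(list(data = data, geom = geom))
  d <- dim(data)
  nd <- d %/% f
  a <- data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
            drop = FALSE]
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(f^3, prod(nd))
  out <- array(colMeans(a), nd)
  geom2 <- list(spacing = geom$spacing * f,
                origin = geom$origin +
                  drop(geom$orientation %*% (geom$spacing * (f - 1) / 2)),
                orientation = geom$orientation)
  list(data = out, geom = geom2)
}

#' Affine registration by mutual information
#'
#' Estimates the 3-D affine transform mapping moving-frame physical points
#' to fixed-frame points, by maximising the mutual information between the
#' fixed image and the transformed moving image over voxels sampled inside
#' `fixed_mask`. Optimisation is multiresolution (coarse-to-fine block-mean
#' pyramid), initialised by centre-of-mass alignment of the two masks, with
#' a translation-only warm-up at the coarsest level followed by full
#' 12-parameter refinement. Deterministic given `config`.
#'
#' @param fixed,moving [ct_volume()] objects.
#' @param fixed_mask,moving_mask Nonempty [lung_mask()] objects on the
#'   respective grids.
#' @param config A [registration_config()].
#' @return An [affine_transform()] mapping moving to fixed physical
#'   coordinates, with attributes `mi_initial`, `mi_final` (metric on the
#'   finest level's samples) and `iterations`.
#' @export
register_affine <- function(fixed, moving, fixed_mask, moving_mask,
                            config = registration_config()) {
  stopifnot(is_ct_volume(fixed), is_ct_volume(moving))
  if (!any(fixed_mask$data) || !any(moving_mask$data))
    stop("registration masks must be nonempty")
  ctr <- mask_centroid(fixed_mask)
  t0 <- mask_centroid(moving_mask) - ctr
  # intensity range for the moving histogram from lung voxels only:
  # including body/air would make the bins far too coarse to resolve
  # parenchymal structure (values outside clamp into the edge bins)
  m_range <- range(moving$data[moving_mask$data])
  bins <- config$bins

  # parameters p: fixed->moving map g(x) = (I + A) (x - ctr) + ctr + t0 + s
  g_map <- function(p, pts) {
    A <- diag(3) + matrix(p[1:9], 3, 3)
    sweep(sweep(pts, 2, ctr) %*% t(A), 2, ctr + t0 + p[10:12], `+`)
  }

  p <- rep(0, 12)
  iterations <- 0L
  conv <- 0L
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  mi_initial <- NA_real_
  samp <- erode_mask(fixed_mask$data, 2)
  if (sum(samp) < 500) samp <- fixed_mask$data
  for (lv in seq_along(config$pyramid)) {
    f <- config$pyramid[lv]
    if (f == 1L) {
      fx <- list(data = smooth_volume_3d(fixed$data), geom = grid_of(fixed))
      mv <- list(data = smooth_volume_3d(moving$data),
                 geom = grid_of(moving))
    } else {
      fx <- downsample_volume(fixed$data, grid_of(fixed), f)
      mv <- downsample_volume(moving$data, grid_of(moving), f)
    }
    fm <- downsample_volume(samp + 0, grid_of(fixed_mask), f)
    sel <- which(fm$data > 0.5)
    if (length(sel) < 50) sel <- which(fm$data > 0)
    if (length(sel) > config$n_samples)
      sel <- sort(sample(sel, config$n_samples))
    # jittered (off-grid) sampling positions: sampling exactly at voxel
    # centres makes the metric dip at grid-aligned transforms, because
    # only fractional offsets average interpolation noise
    jidx <- arrayInd(sel, dim(fx$data)) +
      matrix(stats::runif(3 * length(sel), -0.5, 0.5), ncol = 3)
    pts <- voxel_to_physical(fx$geom, jidx)
    smf <- sample_volume(fx$data, fx$geom, pts, "linear")
    keep <- smf$valid
    pts <- pts[keep, , drop = FALSE]
    fvals <- smf$values[keep]
    f_range <- range(fvals)
    # keep the joint histogram populated: fewer bins at coarse levels
    bins_lv <- max(8L, min(bins, floor(sqrt(length(sel) / 5))))

    neg_mi <- function(par, sub = seq_len(12), base = p) {
      pp <- base; pp[sub] <- par
      sm <- sample_volume(mv$data, mv$geom, g_map(pp, pts), "linear")
      if (sum(sm$valid) < 10) return(0)
      -mattes_mi(fvals[sm$valid], sm$values[sm$valid], f_range, m_range,
                 bins_lv)
    }

    # one optimisation chain: translation refinement, a sweep over
    # uniform scale about the current estimate (exhale motion is
    # scale-dominated), simplex refinement of the full affine, and a
    # quasi-Newton polish with finite-difference steps wide enough to see
    # past voxel-scale metric wiggle
    run_chain <- function(p0) {
      o <- stats::optim(p0[10:12], neg_mi, sub = 10:12, base = p0,
                        method = "Nelder-Mead",
                        control = list(maxit = config$max_iter,
                                       parscale = rep(2, 3),
                                       reltol = 1e-9))
      p0[10:12] <- o$par
      nev <- o$counts[["function"]]
      deltas <- seq(-0.25, 0.25, by = 0.025)
      mis <- vapply(deltas, function(s) {
        pp <- p0; pp[c(1, 5, 9)] <- pp[c(1, 5, 9)] + s
        neg_mi(pp, base = p0)
      }, 0)
      p0[c(1, 5, 9)] <- p0[c(1, 5, 9)] + deltas[which.min(mis)]
      o <- stats::optim(p0, neg_mi, base = p0, method = "Nelder-Mead",
                        control = list(maxit = 3L * config$max_iter,
                                       parscale = c(rep(0.05, 9),
                                                    rep(2, 3)),
                                       reltol = 1e-9))
      p0 <- o$par
      nev <- nev + o$counts[["function"]]
      o <- stats::optim(p0, neg_mi, base = p0, method = "BFGS",
                        control = list(maxit = config$max_iter,
                                       parscale = c(rep(0.01, 9),
                                                    rep(1, 3)),
                                       ndeps = rep(0.25, 12),
                                       reltol = 1e-10))
      list(p = o$par, value = o$value, evals = nev + o$counts[["function"]],
           convergence = o$convergence)
    }

    res <- run_chain(p)
    if (lv == length(config$pyramid) && lv > 1L) {
      # texture that drives the metric at full resolution dies under
      # heavy downsampling, so coarse levels can hand over a contracted
      # local basin; a fresh full-resolution capture guards against that
      res2 <- run_chain(rep(0, 12))
      if (res2$value < res$value) res <- res2
    }
    p <- res$p
    iterations <- iterations + res$evals
    conv <- res$convergence

    if (lv == length(config$pyramid)) {
      # fine polish: per-parameter sweeps (the scale and shear directions
      # are shallow, and curvature-based steps under-converge there)
      # alternated with simplex refinement, twice
      for (round in 1:2) {
        for (ax in 1:12) {
          fine <- if (ax <= 9) seq(-0.03, 0.03, by = 0.005)
            else seq(-1.5, 1.5, by = 0.25)
          mis <- vapply(fine, function(s) {
            pp <- p; pp[ax] <- pp[ax] + s
            neg_mi(pp)
          }, 0)
          p[ax] <- p[ax] + fine[which.min(mis)]
          iterations <- iterations + length(fine)
        }
        o <- stats::optim(p, neg_mi, method = "Nelder-Mead",
                          control = list(maxit = 3L * config$max_iter,
                                         parscale = c(rep(0.02, 9),
                                                      rep(1, 3)),
                                         reltol = 1e-10))
        p <- o$par
        iterations <- iterations + o$counts[["function"]]
      }
      sm0 <- sample_volume(mv$data, mv$geom, g_map(rep(0, 12), pts),
                           "linear")
      mi_initial <- mattes_mi(fvals[sm0$valid], sm0$values[sm0$valid],
                              f_range, m_range, bins_lv)
      mi_final <- -o$value
    }
  }
  if (conv == 1L) {
    msg <- sprintf(
      "registration hit the iteration cap (%d) at the finest level; final MI %.5f",
      config$max_iter, mi_final)
    if (config$on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  A <- diag(3) + matrix(p[1:9], 3, 3)
  if (abs(det(A)) < 1e-8) stop("registration produced a singular transform")
  fwd <- affine_transform(A, t0 + p[10:12], ctr)  # fixed -> moving
  out <- invert_transform(fwd)                    # moving -> fixed
  attr(out, "mi_initial") <- mi_initial
  attr(out, "mi_final") <- mi_final
  attr(out, "iterations") <- iterations
  out
}

#' Resample a volume, mask or label map through an affine transform
#'
#' Produces the input expressed on `reference`'s grid: each reference voxel
#' takes the value of the input at the inverse-transformed physical
#' location. Masks and label maps always use nearest-neighbour; CT volumes
#' use `interpolation`. Out-of-field voxels are filled with -1024 HU
#' (volumes) or 0 (masks/labels).
#'
#' @param v `ct_volume`, `lung_mask` or `label_map` to resample.
#' @param t [affine_transform()] mapping `v`'s frame to `reference`'s frame.
#' @param reference `ct_volume` (or mask) supplying the output grid.
#' @param interpolation `"linear"` (default) or `"nearest"`; ignored for
#'   masks/labels.
#' @return An object of the same class as `v` on `reference`'s grid.
#' @export
resample <- function(v, t, reference,
                     interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  geom_ref <- grid_of(reference)
  d_ref <- dim_of(reference)
  idx <- arrayInd(seq_len(prod(d_ref)), d_ref)
  pts <- voxel_to_physical(geom_ref, idx)
  src <- transform_points(invert_transform(t), pts)
  if (is_ct_volume(v)) {
    sm <- sample_volume(v$data, grid_of(v), src, interpolation,
                        fill = -1024)
    ct_volume(array(sm$values, d_ref), geom_ref$spacing, geom_ref$origin,
              geom_ref$orientation)
  } else if (is_lung_mask(v)) {
    sm <- sample_volume(v$data + 0, grid_of(v), src, "nearest", fill = 0)
    lung_mask(array(sm$values != 0, d_ref),
              list(spacing = geom_ref$spacing, origin = geom_ref$origin,
                   orientation = geom_ref$orientation, data = reference$data))
  } else if (is_label_map(v)) {
    sm <- sample_volume(v$data + 0, grid_of(v), src, "nearest", fill = 0)
    label_map(array(as.integer(sm$values), d_ref),
              list(spacing = geom_ref$spacing, origin = geom_ref$origin,
                   orientation = geom_ref$orientation, data = reference$data),
              legend = v$legend)
  } else stop("'v' must be a ct_volume, lung_mask or label_map")
}

#' Build a co-registered inspiratory/expiratory study
#'
#' Registers the expiratory scan to the inspiratory frame (the default
#' direction) with [register_affine()], resamples the expiratory CT
#' (configured interpolation) and its mask (nearest-neighbour) onto the
#' inspiratory grid, and assembles the paired study on which all
#' voxel-wise metrics are computed. With `direction = "exp_frame"` the
#' roles are swapped and the inspiratory scan is resampled instead.
#'
#' @param insp,exp [ct_volume()] inspiratory/expiratory scans.
#' @param insp_mask,exp_mask Matching [lung_mask()] objects.
#' @param config A [registration_config()].
#' @param transform Optional precomputed [affine_transform()] (moving to
#'   fixed); skips registration when supplied.
#' @return A list of class `paired_study`: the inputs, `transform`,
#'   `exp_in_insp` / `exp_mask_in_insp` (or `insp_in_exp` twins), and
#'   `joint_mask` (fixed mask AND resampled moving mask).
#' @export
build_paired_study <- function(insp, insp_mask, exp, exp_mask,
                               config = registration_config(),
                               transform = NULL) {
  swap <- config$direction == "exp_frame"
  fixed <- if (swap) exp else insp
  fixed_mask <- if (swap) exp_mask else insp_mask
  moving <- if (swap) insp else exp
  moving_mask <- if (swap) insp_mask else exp_mask
  if (is.null(transform))
    transform <- register_affine(fixed, moving, fixed_mask, moving_mask,
                                 config)
  mov_in_fix <- resample(moving, transform, fixed, config$interpolation)
  mov_mask_in_fix <- resample(moving_mask, transform, fixed)
  joint <- lung_mask(fixed_mask$data & mov_mask_in_fix$data, fixed)
  if (!any(joint$data))
    stop("joint lung mask is empty after registration")
  ps <- list(insp = insp, insp_mask = insp_mask, exp = exp,
             exp_mask = exp_mask, transform = transform,
             direction = config$direction, joint_mask = joint)
  if (swap) {
    ps$insp_in_exp <- mov_in_fix
    ps$insp_mask_in_exp <- mov_mask_in_fix
  } else {
    ps$exp_in_insp <- mov_in_fix
    ps$exp_mask_in_insp <- mov_mask_in_fix
  }
  structure(ps, class = "paired_study")
}

# The two co-registered HU fields (inspiratory, expiratory) on the
# analysis grid, plus the joint mask.
paired_fields <- function(ps) {
  if (ps$direction == "exp_frame")
    list(insp = ps$insp_in_exp$data, exp = ps$exp$data,
         joint = ps$joint_mask$data, grid = ps$exp)
  else
    list(insp = ps$insp$data, exp = ps$exp_in_insp$data,
         joint = ps$joint_mask$data, grid = ps$insp)
}

#' @export
print.paired_study <- function(x, ...) {
  cat("Paired inspiratory/expiratory CT study\n")
  cat("  analysis frame:", if (x$direction == "exp_frame") "expiratory"
      else "inspiratory", "\n")
  d <- dim(x$joint_mask$data)
  cat(sprintf("  grid %d x %d x %d, joint mask %d voxels\n",
              d[1], d[2], d[3], sum(x$joint_mask$data)))
  if (!is.null(attr(x$transform, "mi_final")))
    cat(sprintf("  registration MI %.4f -> %.4f\n",
                attr(x$transform, "mi_initial"),
                attr(x$transform, "mi_final")))
  invisible(x)
}
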