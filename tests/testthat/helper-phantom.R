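# Shared fixture builders. All synthetic, generated at test time.

# Tiny paired study on identical grids with a supplied identity transform;
# insp/exp HU arrays given directly. Masks default to everything.
tiny_paired_study <- function(insp_hu, exp_hu, mask = NULL) {
  insp <- ct_volume(insp_hu)
  exp <- ct_volume(exp_hu)
  if (is.null(mask)) mask <- array(TRUE, dim(insp_hu))
  m <- lung_mask(mask, insp)
  build_paired_study(insp, m, exp, lung_mask(mask, exp),
                     transform = affine_transform())
}

# Noise-free, texture-free phantom: oracle comparisons must be exact.
exact_phantom <- function(classes = phantom_classes(), motion = NULL,
                          shape = c(40, 40, 32)) {
  make_paired_phantom(phantom_spec(shape = shape, classes = classes,
                                   motion = motion, noise_sd = 0,
                                   texture_amp = 0))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Brute-force voxel-by-voxel PRM/ATI/LAA counting, written as an explicit
# loop so it shares nothing with the vectorised implementation.
brute_force_prm <- function(insp, exp, joint, emph_thr = -950,
                            at_thr = -856) {
  n <- c(emph = 0, fsad = 0, normal = 0, unclassified = 0, total = 0)
  for (i in which(joint)) {
    vi <- insp[i]; ve <- exp[i]
    n["total"] <- n["total"] + 1
    if (vi < emph_thr && ve < at_thr) n["emph"] <- n["emph"] + 1
    else if (vi >= emph_thr && ve < at_thr) n["fsad"] <- n["fsad"] + 1
    else if (vi >= emph_thr && ve >= at_thr) n["normal"] <- n["normal"] + 1
    else n["unclassified"] <- n["unclassified"] + 1
  }
  n[1:4] / n[["total"]]
}

brute_force_ati <- function(insp, exp, joint, delta = 60, lo = -950,
                            hi = -856) {
  at <- 0; elig <- 0
  for (i in which(joint)) {
    vi <- insp[i]
    if (vi >= lo && vi < hi) {
      elig <- elig + 1
      if (exp[i] - vi < delta) at <- at + 1
    }
  }
  at / elig
}
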