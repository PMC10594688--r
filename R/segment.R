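# Rule-based lung segmentation for phantoms and mask-less studies. The
# clinical route is an externally supplied parenchyma mask (load_mask);
# this fallback thresholds air-like voxels, removes external air by
# border-connectivity, drops small components and fills internal holes.
# No airway-tree exclusion is attempted.

# 6-connected component labelling by iterative minimum-label propagation
# with pointer jumping. Returns an integer array, 0 = background, labels
# renumbered 1..k in decreasing component size.
label_components_3d <- function(mask) {
  dims <- dim(mask)
  n <- prod(dims)
  lab <- integer(n)
  fg <- which(mask)
  if (length(fg) == 0L) return(array(0L, dims))
  lab[fg] <- fg
  strides <- c(1L, dims[1], dims[1] * dims[2])
  # Precompute neighbour linear indices for foreground voxels per direction
  coord <- arrayInd(fg, dims)
  nb <- vector("list", 6)
  k <- 0L
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    k <- k + 1L
    ok <- if (s == 1L) coord[, ax] < dims[ax] else coord[, ax] > 1L
    cand <- fg[ok] + s * strides[ax]
    keep <- lab[cand] != 0L
    nb[[k]] <- cbind(fg[ok][keep], cand[keep])
  }
  nb <- do.call(rbind, nb)
  repeat {
    changed <- FALSE
    # propagate min label across neighbour pairs
    m <- pmin(lab[nb[, 1]], lab[nb[, 2]])
    upd <- m < lab[nb[, 1]]
    if (any(upd)) {
      # multiple pairs can target one voxel; aggregate by min
      tgt <- nb[upd, 1]; val <- m[upd]
      o <- order(tgt, val)
      tgt <- tgt[o]; val <- val[o]
      first <- !duplicated(tgt)
      lab[tgt[first]] <- val[first]
      changed <- TRUE
    }
    # path compression: labels are linear indices, so lab[lab] is a hop
    l2 <- lab[lab[fg]]
    if (any(l2 != lab[fg])) { lab[fg] <- l2; changed <- TRUE }
    if (!changed) break
  }
  # compress fully
  repeat {
    l2 <- lab[lab[fg]]
    if (all(l2 == lab[fg])) break
    lab[fg] <- l2
  }
  sizes <- sort(table(lab[fg]), decreasing = TRUE)
  renum <- integer(n)
  renum[as.integer(names(sizes))] <- seq_along(sizes)
  out <- integer(n)
  out[fg] <- renum[lab[fg]]
  array(out, dims)
}

border_labels <- function(lab) {
  dims <- dim(lab)
  u <- c(lab[1, , ], lab[dims[1], , ], lab[, 1, ], lab[, dims[2], ],
         lab[, , 1], lab[, , dims[3]])
  setdiff(unique(u), 0L)
}

# Fill cavities: background components not connected to the volume border.
fill_holes_3d <- function(mask) {
  bg <- label_components_3d(!mask)
  hole <- bg != 0L & !(bg %in% border_labels(bg))
  mask | array(hole, dim(mask))
}

#' Threshold-based lung segmentation
#'
#' Fallback parenchyma segmenter: selects voxels below `air_threshold`,
#' removes air connected to the volume border (the air surrounding the
#' body), discards connected components smaller than
#' `min_component_fraction` of the largest remaining one, and fills
#' internal holes (vessels, noise) in the kept components. Deterministic
#' given its inputs. Intended for phantoms and studies without an external
#' mask; it does not attempt to exclude the trachea and main bronchi, so
#' clinical masks should come from a dedicated segmenter via [load_mask()].
#'
#' @param v A [ct_volume()] containing both body and air voxels.
#' @param air_threshold HU below which a voxel counts as air-like lung;
#'   default -320 HU, the usual lung/soft-tissue separation point.
#' @param min_component_fraction Components smaller than this fraction of
#'   the largest component are dropped (default 0.01).
#' @return A [lung_mask()] on `v`'s grid.
#' @export
segment_lungs_threshold <- function(v, air_threshold = -320,
                                    min_component_fraction = 0.01) {
  stopifnot(is_ct_volume(v))
  cand <- v$data < air_threshold
  if (!any(cand))
    stop("no voxels below ", air_threshold,
         " HU: nothing lung-like to segment")
  lab <- label_components_3d(cand)
  drop <- border_labels(lab)
  lab[lab %in% drop] <- 0L
  if (!any(lab != 0L))
    stop("all air-like voxels touch the volume border; no lung component")
  sizes <- table(lab[lab != 0L])
  keep <- as.integer(names(sizes)[sizes >= min_component_fraction *
                                    max(sizes)])
  m <- array(lab %in% keep, dim(lab))
  lung_mask(fill_holes_3d(m), v)
}
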