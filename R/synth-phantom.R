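#' Toy 3D region atlas for topography phantoms
#'
#' Builds axis-aligned binary region masks on a shared grid: a brain box whose
#' outer 4-voxel rim is "cortex", a central ventricle box, and disjoint
#' brainstem and cerebellum boxes near the bottom. Geometry is schematic by
#' design — it exists to give the location rules unambiguous ground truth,
#' not to mimic anatomy.
#'
#' @param dim Grid dimensions (voxels). Default c(48, 48, 48).
#' @param voxel_size Isotropic voxel edge length (mm). Default 1.
#' @return A `region_atlas` list of logical arrays `ventricles`, `cortex`,
#'   `brainstem`, `cerebellum`, plus `brain`, `dim`, `voxel_size` and the box
#'   extents (`boxes`).
#' @export
phantom_atlas <- function(dim = c(48L, 48L, 48L), voxel_size = 1) {
  stopifnot(length(dim) == 3, all(dim >= 32), voxel_size > 0)
  mk <- function(box) {
    a <- array(FALSE, dim)
    a[box[1]:box[2], box[3]:box[4], box[5]:box[6]] <- TRUE
    a
  }
  boxes <- list(
    brain      = c(3, dim[1] - 2, 3, dim[2] - 2, 3, dim[3] - 2),
    inner      = c(7, dim[1] - 6, 7, dim[2] - 6, 7, dim[3] - 6),
    ventricles = c(21, 28, 19, 30, 21, 28),
    brainstem  = c(21, 28, 14, 22, 8, 14),
    cerebellum = c(14, 34, 26, 40, 8, 14))
  brain <- mk(boxes$brain)
  cortex <- brain & !mk(boxes$inner)
  structure(list(ventricles = mk(boxes$ventricles), cortex = cortex,
                 brainstem = mk(boxes$brainstem),
                 cerebellum = mk(boxes$cerebellum),
                 brain = brain, dim = dim, voxel_size = voxel_size,
                 boxes = boxes),
            class = "region_atlas")
}

#' Phantom lesion specifications covering every location class
#'
#' Each row requests one cuboid lesion: its intended location class, extents
#' (voxels) and how many of its layers along the placement axis should fall
#' inside the relevant region (`overlap_layers`), from which the generator
#' realizes a target overlap fraction. Includes one sub-threshold 26-voxel
#' lesion and one borderline case.
#'
#' @return Tibble of lesion specs consumed by [gen_phantom_masks()].
#' @export
default_phantom_lesions <- function() {
  tibble::tribble(
    ~intended_location, ~lx, ~ly, ~lz, ~overlap_layers, ~shift,
    "periventricular",   16,   8,   8,              1L,      0L, # 1/16 = 6.25% contact
    "periventricular",    8,   8,   8,              2L,     12L, # 25% contact
    "juxtacortical",     10,   8,   8,              3L,      0L, # 30% in cortex
    "juxtacortical",      8,   6,   6,              4L,     12L, # 50% in cortex
    "brainstem",          6,   6,   6,              4L,      0L, # 67% in brainstem
    "cerebellum",         6,   8,   6,              5L,      0L, # 83% in cerebellum
    "deep_wm",            6,   6,   6,              0L,      0L,
    "deep_wm",            2,  13,   1,              0L,     10L, # 26 voxels: sub-threshold
    "deep_wm",            3,   3,   3,              0L,     20L) # 27 voxels: boundary kept
}

# analytic overlap fractions implied by a spec (independent of voxel masks):
# layers inside the region (or its 1-voxel contact zone) / layers along the
# placement axis (x everywhere except cerebellum, whose lesions straddle the
# +y face)
intended_fractions <- function(spec) {
  nvox <- spec$lx * spec$ly * spec$lz
  axis_len <- if (spec$intended_location == "cerebellum") spec$ly else spec$lx
  frac <- spec$overlap_layers / axis_len
  list(
    pv = if (spec$intended_location == "periventricular") frac else 0,
    cortex = if (spec$intended_location == "juxtacortical") frac else 0,
    infra = if (spec$intended_location %in% c("brainstem", "cerebellum")) frac else 0,
    n_voxels = nvox)
}

#' Generate phantom lesion label volumes with known topography truth
#'
#' Places each requested cuboid lesion deterministically against the relevant
#' atlas region so that `overlap_layers / lx` of its volume lies inside the
#' region (for periventricular lesions, inside the 1-voxel contact zone of the
#' ventricles — layer 1 abuts, further layers overlap). Ground-truth location
#' labels are derived analytically from the intended fractions and the
#' classification rules (> 5% ventricle contact, then > 20% cortex, then
#' > 50% brainstem+cerebellum, else deep white matter), independently of the
#' voxel-counting code in the topography module.
#'
#' @param lesions Spec tibble as from [default_phantom_lesions()]; zero rows
#'   give an all-zero volume and empty truth table.
#' @param atlas A [phantom_atlas()].
#' @param min_volume Sub-threshold flag cutoff (mm^3). Default 27.
#' @param borderline_margin Truth rows whose decisive fraction lies within
#'   this margin of a rule threshold are flagged `borderline`. Default 0.02.
#' @return List: `lesion_volume` (integer label array, one id per lesion),
#'   `atlas`, and `truth` tibble (lesion id, intended/true location,
#'   fractions, volume, `sub_threshold`, `borderline`).
#' @export
gen_phantom_masks <- function(lesions = default_phantom_lesions(),
                              atlas = phantom_atlas(), min_volume = 27,
                              borderline_margin = 0.02) {
  dm <- atlas$dim
  vol <- array(0L, dm)
  if (nrow(lesions) == 0) {
    return(list(lesion_volume = vol, atlas = atlas,
                truth = tibble(lesion_id = integer(0),
                               intended_location = character(0),
                               true_location = character(0),
                               frac_ventricle = numeric(0),
                               frac_cortex = numeric(0),
                               frac_infratentorial = numeric(0),
                               volume_mm3 = numeric(0),
                               sub_threshold = logical(0),
                               borderline = logical(0))))
  }
  bx <- atlas$boxes
  truth <- list()
  deep_cursor <- 0
  for (i in seq_len(nrow(lesions))) {
    sp <- lesions[i, ]
    k <- sp$overlap_layers
    # placement: box extends along +x (or +y for cerebellum) away from the
    # region face, with `k` layers inside the region / contact zone
    if (sp$intended_location == "periventricular") {
      # k layers inside the ventricle contact zone (the 1-voxel dilation plus
      # the ventricle itself); shift = 0 places on the +x face, otherwise -x
      yr <- (bx$ventricles[3] + 1):(bx$ventricles[3] + sp$ly)
      zr <- (bx$ventricles[5] + 1):(bx$ventricles[5] + sp$lz)
      if (sp$shift == 0L) {
        x0 <- bx$ventricles[2] + 2 - k
        rng <- list(x0:(x0 + sp$lx - 1), yr, zr)
      } else {
        x1 <- bx$ventricles[1] - 2 + k
        rng <- list((x1 - sp$lx + 1):x1, yr, zr)
      }
    } else if (sp$intended_location == "juxtacortical") {
      # cortex occupies x in [brain_lo, inner_lo - 1]; k layers inside cortex
      x0 <- bx$inner[1] - k
      rng <- list(x0:(x0 + sp$lx - 1),
                  (12 + sp$shift):(11 + sp$shift + sp$ly),
                  30:(29 + sp$lz))
    } else if (sp$intended_location == "brainstem") {
      x0 <- bx$brainstem[2] + 1 - k
      rng <- list(x0:(x0 + sp$lx - 1),
                  (bx$brainstem[3] + 1):(bx$brainstem[3] + sp$ly),
                  (bx$brainstem[5] + 1):(bx$brainstem[5] + sp$lz))
    } else if (sp$intended_location == "cerebellum") {
      y0 <- bx$cerebellum[4] + 1 - k
      rng <- list(16:(15 + sp$lx),
                  y0:(y0 + sp$ly - 1),
                  (bx$cerebellum[5] + 1):(bx$cerebellum[5] + sp$lz))
    } else { # deep_wm: well inside the inner box, away from all regions
      x0 <- 34
      y0 <- 8 + deep_cursor
      deep_cursor <- deep_cursor + max(sp$ly, 2) + 2
      rng <- list(x0:(x0 + sp$lx - 1), y0:(y0 + sp$ly - 1), 30:(29 + sp$lz))
    }
    if (any(sapply(seq_len(3), function(d) rng[[d]][length(rng[[d]])] > dm[d] ||
                   rng[[d]][1] < 1))) {
      abort(sprintf("Lesion %d does not fit in the phantom volume.", i))
    }
    sub <- vol[rng[[1]], rng[[2]], rng[[3]]]
    if (any(sub != 0L)) abort(sprintf("Lesion %d collides with an earlier lesion.", i))
    vol[rng[[1]], rng[[2]], rng[[3]]] <- i
    fr <- intended_fractions(sp)
    vox_mm3 <- atlas$voxel_size^3
    true_loc <- if (fr$pv > 0.05) "periventricular"
      else if (fr$cortex > 0.20) "juxtacortical"
      else if (fr$infra > 0.50) "infratentorial" else "deep_wm"
    decisive <- max(fr$pv, fr$cortex, fr$infra)
    borderline <- any(abs(c(fr$pv - 0.05, fr$cortex - 0.20, fr$infra - 0.50)) <
                        borderline_margin)
    truth[[i]] <- tibble(
      lesion_id = i, intended_location = sp$intended_location,
      true_location = true_loc,
      frac_ventricle = fr$pv, frac_cortex = fr$cortex,
      frac_infratentorial = fr$infra,
      volume_mm3 = fr$n_voxels * vox_mm3,
      sub_threshold = fr$n_voxels * vox_mm3 < min_volume,
      borderline = borderline)
  }
  list(lesion_volume = vol, atlas = atlas, truth = dplyr::bind_rows(truth))
}

#' Write phantom volumes as NIfTI-1 files
#'
#' @param phantom Output of [gen_phantom_masks()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- phantom$atlas$voxel_size
  paths <- character(0)
  wr <- function(arr, name) {
    p <- file.path(dir, paste0(name, ".nii"))
    img <- RNifti::asNifti(arr * 1L, pixdim = rep(vs, 3))
    RNifti::writeNifti(img, p)
    p
  }
  paths <- c(wr(phantom$lesion_volume, "lesions"),
             wr(phantom$atlas$ventricles, "ventricles"),
             wr(phantom$atlas$cortex, "cortex"),
             wr(phantom$atlas$brainstem, "brainstem"),
             wr(phantom$atlas$cerebellum, "cerebellum"))
  invisible(paths)
}
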