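neighbor_offsets <- function(connectivity = 26) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord %in% 1:2, "26" = ord %in% 1:3,
                 abort("`connectivity` must be 6, 18 or 26."))
  off[keep, , drop = FALSE]
}

#' Label connected components of a binary 3D lesion mask
#'
#' Components are found under 26-connectivity by default (voxels sharing a
#' face, edge or corner belong together), the convention that merges lesions
#' touching only diagonally; 6 and 18 are available.
#'
#' @param mask Binary 3D array (0/1 or logical).
#' @param voxel_size Voxel edge length(s) in mm (scalar or length 3).
#' @param connectivity 6, 18 or 26 (default).
#' @return A `lesion_components` tibble: `lesion_id`, `n_voxels`,
#'   `volume_mm3`, `voxels` (list-column of linear voxel indices); attributes
#'   `dim`, `voxel_size`.
#' @export
label_components <- function(mask, voxel_size = 1, connectivity = 26) {
  if (length(dim(mask)) != 3) abort("`mask` must be a 3D array.")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) abort("`mask` must be binary.")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  dm <- dim(mask)
  fg <- which(mask != 0)
  empty <- tibble(lesion_id = integer(0), n_voxels = integer(0),
                  volume_mm3 = numeric(0), voxels = list())
  attr(empty, "dim_vol") <- dm
  attr(empty, "voxel_size") <- voxel_size
  if (length(fg) == 0) {
    class(empty) <- c("lesion_components", class(empty))
    return(empty)
  }
  rank <- array(0L, dm)
  rank[fg] <- seq_along(fg)
  co <- arrayInd(fg, dm)
  off <- neighbor_offsets(connectivity)
  # half the offsets suffice for an undirected edge list
  off <- off[off[, 1] + 3 * off[, 2] + 9 * off[, 3] > 0, , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(off))) {
    nb <- sweep(co, 2, off[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dm[1] + (nb[ok, 3] - 1) * dm[1] * dm[2]
    nb_rank <- rank[nb_lin]
    src <- which(ok)[nb_rank > 0]
    if (length(src) > 0) edges[[length(edges) + 1]] <-
        cbind(src, nb_rank[nb_rank > 0])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  memb <- igraph::components(g)$membership
  vox_mm3 <- prod(voxel_size)
  out <- tibble(lesion_id = sort(unique(memb))) |>
    dplyr::mutate(voxels = purrr::map(.data$lesion_id, ~ fg[memb == .x]),
                  n_voxels = purrr::map_int(.data$voxels, length),
                  volume_mm3 = .data$n_voxels * vox_mm3) |>
    dplyr::select("lesion_id", "n_voxels", "volume_mm3", "voxels")
  attr(out, "dim_vol") <- dm
  attr(out, "voxel_size") <- voxel_size
  class(out) <- c("lesion_components", class(out))
  out
}

#' Components of an integer phantom label volume
#'
#' Convenience wrapper: treats each positive label of
#' [gen_phantom_masks()]'s output as one lesion (labels are already
#' components).
#'
#' @param label_volume Integer 3D array, 0 = background.
#' @param voxel_size Voxel edge length(s), mm.
#' @return A `lesion_components` tibble as in [label_components()].
#' @export
components_from_labels <- function(label_volume, voxel_size = 1) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  ids <- sort(unique(label_volume[label_volume > 0]))
  out <- tibble(lesion_id = as.integer(ids)) |>
    dplyr::mutate(voxels = purrr::map(.data$lesion_id,
                                      ~ which(label_volume == .x)),
                  n_voxels = purrr::map_int(.data$voxels, length),
                  volume_mm3 = .data$n_voxels * prod(voxel_size)) |>
    dplyr::select("lesion_id", "n_voxels", "volume_mm3", "voxels")
  attr(out, "dim_vol") <- dim(label_volume)
  attr(out, "voxel_size") <- voxel_size
  class(out) <- c("lesion_components", class(out))
  out
}

#' Morphological dilation of a binary 3D mask
#'
#' @param mask Logical/binary 3D array.
#' @param connectivity Structuring element: 6, 18 or 26 (default) neighbors.
#' @param iterations Number of 1-voxel dilations.
#' @return Logical array.
#' @export
dilate_mask <- function(mask, connectivity = 26, iterations = 1) {
  dm <- dim(mask)
  out <- mask != 0
  off <- neighbor_offsets(connectivity)
  for (it in seq_len(iterations)) {
    fg <- which(out)
    if (length(fg) == 0) break
    co <- arrayInd(fg, dm)
    acc <- out
    for (i in seq_len(nrow(off))) {
      nb <- sweep(co, 2, off[i, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      acc[nb[ok, , drop = FALSE]] <- TRUE
    }
    out <- acc
  }
  out
}

#' Region-overlap fractions for lesion components
#'
#' For each component computes the fraction of its voxels (i) in direct
#' contact with the lateral ventricles — operationalized as lying within a
#' 1-voxel 26-neighborhood dilation of the ventricle mask, since
#' periventricular lesions abut rather than overlap CSF — (ii) inside the
#' cortex mask, and (iii) inside brainstem and cerebellum.
#'
#' @param components A `lesion_components` tibble.
#' @param atlas A [phantom_atlas()] or any list of binary arrays
#'   `ventricles`, `cortex`, `brainstem`, `cerebellum` on the same grid.
#' @param contact_dilation Voxels of ventricle dilation defining "contact".
#' @return `components` with columns `frac_ventricle`, `frac_cortex`,
#'   `frac_brainstem`, `frac_cerebellum`, `frac_infratentorial`.
#' @export
overlap_fractions <- function(components, atlas, contact_dilation = 1) {
  dm <- attr(components, "dim_vol")
  for (nm in c("ventricles", "cortex", "brainstem", "cerebellum")) {
    if (!identical(dim(atlas[[nm]]), as.integer(dm)) &&
        !identical(dim(atlas[[nm]]), dm)) {
      abort(sprintf("Atlas mask `%s` is not on the lesion grid.", nm))
    }
  }
  vent <- dilate_mask(atlas$ventricles, iterations = contact_dilation)
  frac_of <- function(vox, m) mean(m[vox] != 0)
  components |>
    dplyr::mutate(
      frac_ventricle = purrr::map_dbl(.data$voxels, frac_of, m = vent),
      frac_cortex = purrr::map_dbl(.data$voxels, frac_of, m = atlas$cortex),
      frac_brainstem = purrr::map_dbl(.data$voxels, frac_of, m = atlas$brainstem),
      frac_cerebellum = purrr::map_dbl(.data$voxels, frac_of, m = atlas$cerebellum),
      frac_infratentorial = .data$frac_brainstem + .data$frac_cerebellum)
}

#' Rule-based lesion location from overlap fractions
#'
#' Applies the location rules in fixed precedence with strict inequalities:
#' periventricular if the ventricle-contact fraction exceeds 5%; else
#' juxtacortical if more than 20% of the volume touches or lies within the
#' cortex; else infratentorial if more than 50% lies in brainstem or
#' cerebellum (jointly; sub-labelled by the larger share, ties to brainstem);
#' else deep white matter.
#'
#' @param data Tibble with `frac_ventricle`, `frac_cortex`,
#'   `frac_infratentorial` (and, for the sub-label, `frac_brainstem` /
#'   `frac_cerebellum`), e.g. from [overlap_fractions()].
#' @param thresholds Named vector of rule thresholds.
#' @return `data` with `location` and `sublocation` columns.
#' @export
classify_location <- function(data,
                              thresholds = c(periventricular = 0.05,
                                             juxtacortical = 0.20,
                                             infratentorial = 0.50)) {
  has_sub <- all(c("frac_brainstem", "frac_cerebellum") %in% names(data))
  data |>
    dplyr::mutate(
      location = dplyr::case_when(
        .data$frac_ventricle > thresholds[["periventricular"]] ~ "periventricular",
        .data$frac_cortex > thresholds[["juxtacortical"]] ~ "juxtacortical",
        .data$frac_infratentorial > thresholds[["infratentorial"]] ~ "infratentorial",
        TRUE ~ "deep_wm"),
      sublocation = if (has_sub) {
        dplyr::if_else(.data$location == "infratentorial",
                       dplyr::if_else(.data$frac_cerebellum > .data$frac_brainstem,
                                      "cerebellum", "brainstem"),
                       .data$location)
      } else .data$location)
}

#' Per-lesion feature table from components and metric maps
#'
#' Keeps components with volume at least `min_volume` (lesions smaller than
#' 27 mm^3 are excluded by default; a 27 mm^3 lesion is retained) and averages
#' each metric map over each lesion's voxels. An empty result is a typed
#' empty table, not an error.
#'
#' @param components A classified `lesion_components` tibble (with
#'   `location`).
#' @param metric_maps Named list of 3D arrays on the lesion grid.
#' @param min_volume Minimum lesion volume (mm^3). Default 27.
#' @param patient_id Optional patient id carried into the table.
#' @return Lesion feature tibble: `patient_id`, `lesion_id`, `location`,
#'   `volume_mm3`, one column per metric.
#' @export
summarize_lesions <- function(components, metric_maps, min_volume = 27,
                              patient_id = NA_character_) {
  dm <- attr(components, "dim_vol")
  for (nm in names(metric_maps)) {
    if (!identical(as.integer(dim(metric_maps[[nm]])), as.integer(dm))) {
      abort(sprintf("Metric map `%s` is not on the lesion grid.", nm))
    }
  }
  kept <- components |> dplyr::filter(.data$volume_mm3 >= min_volume)
  base <- tibble(patient_id = rep(patient_id, nrow(kept)),
                 lesion_id = kept$lesion_id,
                 location = if ("location" %in% names(kept)) kept$location
                            else NA_character_,
                 volume_mm3 = kept$volume_mm3)
  for (nm in names(metric_maps)) {
    base[[nm]] <- purrr::map_dbl(kept$voxels,
                                 ~ mean(metric_maps[[nm]][.x]))
  }
  base
}
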