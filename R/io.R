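#' Read / write lesion feature tables as TSV
#'
#' Tab-separated with a header row; columns `patient_id`, `lesion_id`,
#' `location`, `volume_mm3`, one column per diffusion metric (diffusivities
#' in 1e-3 mm^2/s) and, once typed, `type`.
#'
#' @param path File path.
#' @param lesions Lesion tibble.
#' @return `read_lesion_table()`: a tibble; `write_lesion_table()`: `path`,
#'   invisibly.
#' @export
read_lesion_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_lesion_table
#' @export
write_lesion_table <- function(lesions, path) {
  readr::write_tsv(lesions, path)
  invisible(path)
}

#' Serialize / restore a fitted typing model as structured text
#'
#' YAML with the feature names, standardization means/SDs, standardized
#' centroids and the cluster-to-label map — everything needed for
#' out-of-sample assignment.
#'
#' @param model A `lesion_cluster_model`.
#' @param path File path (YAML).
#' @return `write_cluster_model()`: `path` invisibly;
#'   `read_cluster_model()`: a `lesion_cluster_model` (without training-row
#'   types).
#' @export
write_cluster_model <- function(model, path) {
  yaml::write_yaml(list(
    features = model$features,
    center_mean = as.list(setNames(model$center_mean, model$features)),
    center_sd = as.list(setNames(model$center_sd, model$features)),
    centroids = lapply(seq_len(nrow(model$centroids)),
                       function(i) as.numeric(model$centroids[i, ])),
    label_map = as.list(model$label_map),
    k = model$k), path)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  y <- yaml::read_yaml(path)
  centroids <- do.call(rbind, lapply(y$centroids, as.numeric))
  colnames(centroids) <- y$features
  structure(list(features = y$features,
                 center_mean = unlist(y$center_mean)[y$features],
                 center_sd = unlist(y$center_sd)[y$features],
                 centroids = centroids,
                 label_map = setNames(unlist(y$label_map), names(y$label_map)),
                 type = NULL, k = y$k, n = NA_integer_),
            class = "lesion_cluster_model")
}

#' Read / write 3D metric or mask volumes as NIfTI-1
#'
#' Thin wrappers over RNifti keeping voxel size in the header.
#'
#' @param arr 3D array.
#' @param path File path (`.nii` / `.nii.gz`).
#' @param voxel_size Voxel edge length(s), mm.
#' @return `write_volume()`: `path` invisibly; `read_volume()`: array with a
#'   `voxel_size` attribute.
#' @export
write_volume <- function(arr, path, voxel_size = 1) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = voxel_size), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[seq_len(3)]
  out
}
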