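
# Spatial masks are 3D logical/0-1 arrays, optionally carrying an
# attr "pixdim" (voxel size in mm) used for mm geometry. NIfTI files are read
# and written through RNifti.

as_mask <- function(x, name = "mask") {
  if (is.character(x)) x <- RNifti::readNifti(x)
  a <- as.array(x) != 0
  if (length(dim(a)) != 3L)
    stop_(sprintf("'%s' must be a 3D volume", name))
  if (inherits(x, "niftiImage"))
    attr(a, "pixdim") <- RNifti::pixdim(x)[1:3]
  else if (!is.null(attr(x, "pixdim")))
    attr(a, "pixdim") <- attr(x, "pixdim")
  a
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_("masks are on different grids: ",
          paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  pa <- attr(a, "pixdim"); pb <- attr(b, "pixdim")
  if (!is.null(pa) && !is.null(pb) && max(abs(pa - pb)) > 1e-6)
    stop_("masks have different voxel sizes")
  invisible(TRUE)
}

#' Jaccard spatial similarity of two binary masks
#'
#' Intersection-over-union of active voxels: J = |A and B| / |A or B|.
#'
#' @param a,b binary 3D arrays (or NIfTI paths/images) on the same grid
#' @return J in [0, 1]
#' @examples
#' a <- array(0, c(4, 4, 1)); a[1:2, 1, 1] <- 1
#' b <- array(0, c(4, 4, 1)); b[2:3, 1, 1] <- 1
#' jaccard_index(a, b)  # 1/3
#' @export
jaccard_index <- function(a, b) {
  a <- as_mask(a, "a"); b <- as_mask(b, "b")
  check_same_grid(a, b)
  if (!any(a) || !any(b))
    stop_("empty mask: Jaccard similarity is undefined")
  sum(a & b) / sum(a | b)
}

#' Assign component maps to template networks by Jaccard similarity
#'
#' Each component is assigned to the template with which its Jaccard index is
#' highest, provided J reaches \code{j_min}; otherwise it is left unassigned
#' (and excluded downstream). When two or more components are best described
#' by the same template, the union of their maps is scored against that
#' template: if the combined map exceeds every individual J, a single combined
#' assignment replaces them, otherwise they are kept as distinct assignments.
#'
#' @param components named list of binary masks (ICA component maps)
#' @param templates named list of binary masks (template network regions)
#' @param j_min minimum Jaccard index for an assignment (default 0.15)
#' @return data frame with columns component, template, jaccard, combined,
#'   accepted; the full component x template J matrix is attached as
#'   attribute \code{"jaccard_matrix"}
#' @export
assign_networks <- function(components, templates, j_min = 0.15) {
  if (!length(components) || !length(templates))
    stop_("need at least one component and one template")
  if (is.null(names(components)))
    names(components) <- paste0("IC", seq_along(components))
  if (is.null(names(templates)))
    names(templates) <- paste0("template", seq_along(templates))
  components <- lapply(components, as_mask)
  templates <- lapply(templates, as_mask)

  J <- matrix(0, length(components), length(templates),
              dimnames = list(names(components), names(templates)))
  for (i in seq_along(components))
    for (j in seq_along(templates))
      J[i, j] <- jaccard_index(components[[i]], templates[[j]])

  best <- apply(J, 1, which.max)
  best_j <- J[cbind(seq_len(nrow(J)), best)]
  out <- data.frame(component = names(components),
                    template = colnames(J)[best],
                    jaccard = best_j,
                    combined = FALSE,
                    accepted = best_j >= j_min,
                    stringsAsFactors = FALSE)

  # merge rule: components sharing an accepted best template
  for (tpl in unique(out$template[out$accepted])) {
    idx <- which(out$template == tpl & out$accepted & !out$combined)
    if (length(idx) < 2) next
    union_mask <- Reduce(`|`, components[out$component[idx]])
    j_union <- jaccard_index(union_mask, templates[[tpl]])
    if (j_union > max(out$jaccard[idx])) {
      comb <- data.frame(component = paste(out$component[idx], collapse = "+"),
                         template = tpl, jaccard = j_union, combined = TRUE,
                         accepted = j_union >= j_min, stringsAsFactors = FALSE)
      out <- rbind(out[-idx, , drop = FALSE], comb)
    }
  }
  rownames(out) <- NULL
  attr(out, "jaccard_matrix") <- J
  out
}

#' Build peak-sphere ROIs inside suprathreshold clusters
#'
#' For each labeled cluster of a thresholded statistical map, spheres of
#' \code{radius_mm} are placed around the strongest peaks (up to
#' \code{max_peaks_per_cluster} per cluster, ranked by statistic value, ties
#' broken by voxel index) and intersected with the cluster's suprathreshold
#' voxels, so ROIs only contain voxels present in the group-level statistics.
#' A voxel belongs to a sphere when its center lies within \code{radius_mm}
#' of the peak coordinate (Euclidean mm distance).
#'
#' @param clusters integer-labeled 3D array (0 = background) of
#'   suprathreshold cluster membership
#' @param peaks data frame with columns \code{x,y,z} (voxel indices, 1-based),
#'   \code{value} (statistic) and \code{cluster} (label in \code{clusters})
#' @param radius_mm sphere radius in mm
#' @param max_peaks_per_cluster maximum ROIs per cluster
#' @param voxel_mm length-3 voxel size in mm (taken from the array's
#'   \code{pixdim} attribute when present)
#' @return list of ROI specs: \code{id}, \code{cluster}, \code{peak} (voxel
#'   indices), \code{voxels} (matrix of voxel indices), \code{n_voxels}
#' @export
build_rois <- function(clusters, peaks, radius_mm = 5,
                       max_peaks_per_cluster = 3,
                       voxel_mm = attr(clusters, "pixdim") %||% c(1, 1, 1)) {
  check_number(radius_mm, "radius_mm", lower = 1e-9)
  check_number(max_peaks_per_cluster, "max_peaks_per_cluster", lower = 1,
               integer = TRUE)
  clusters <- as.array(clusters)
  dims <- dim(clusters)
  need <- c("x", "y", "z", "value", "cluster")
  if (!all(need %in% names(peaks)))
    stop_("'peaks' needs columns ", paste(need, collapse = ", "))
  if (any(peaks$x < 1 | peaks$x > dims[1] | peaks$y < 1 | peaks$y > dims[2] |
          peaks$z < 1 | peaks$z > dims[3]))
    stop_("peak coordinate outside the volume grid")

  rois <- list()
  for (cl in sort(unique(peaks$cluster))) {
    pk <- peaks[peaks$cluster == cl, , drop = FALSE]
    lin <- (pk$z - 1) * dims[1] * dims[2] + (pk$y - 1) * dims[1] + pk$x
    pk <- pk[order(-pk$value, lin), , drop = FALSE]
    pk <- pk[seq_len(min(nrow(pk), max_peaks_per_cluster)), , drop = FALSE]
    cl_vox <- which(clusters == cl, arr.ind = TRUE)
    if (!nrow(cl_vox)) stop_(sprintf("cluster %s has no voxels", cl))
    cl_mm <- sweep(cl_vox, 2, voxel_mm, `*`)
    for (p in seq_len(nrow(pk))) {
      peak_mm <- c(pk$x[p], pk$y[p], pk$z[p]) * voxel_mm
      d2 <- colSums((t(cl_mm) - peak_mm)^2)
      inside <- cl_vox[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
      id <- sprintf("cl%s_peak%d", cl, p)
      if (!nrow(inside)) {
        warning(sprintf("ROI %s empty after cluster intersection; dropped", id),
                call. = FALSE)
        next
      }
      rois[[id]] <- list(id = id, cluster = cl,
                         peak = c(x = pk$x[p], y = pk$y[p], z = pk$z[p]),
                         voxels = inside, n_voxels = nrow(inside))
    }
  }
  rois
}

#' Exclude ROIs with insufficient signal coverage across subjects
#'
#' An ROI is excluded when the fraction of subjects with zero signal coverage
#' exceeds \code{max_missing_fraction} (strict inequality). A second,
#' stricter rule used for graph harmonization — drop any node where at least
#' one subject has no signal — is available via
#' \code{max_missing_fraction = 0} with \code{strict = FALSE}.
#'
#' @param coverage subjects x ROI matrix of voxel counts (or any non-negative
#'   signal-coverage measure); column names identify ROIs
#' @param max_missing_fraction exclusion threshold on the zero-coverage
#'   subject fraction (default 0.15)
#' @param strict logical; \code{TRUE} (default) excludes only when the
#'   fraction strictly exceeds the threshold
#' @return list with \code{retained} (ROI ids), \code{excluded} (data frame:
#'   roi, missing_fraction)
#' @export
coverage_filter <- function(coverage, max_missing_fraction = 0.15,
                            strict = TRUE) {
  if (!is.matrix(coverage) || is.null(colnames(coverage)))
    stop_("'coverage' must be a subjects x ROI matrix with ROI column names")
  if (anyNA(coverage))
    stop_("'coverage' has missing counts for some subject x ROI pairs")
  frac <- colMeans(coverage == 0)
  excl <- if (strict) frac > max_missing_fraction else frac >= max_missing_fraction
  list(retained = colnames(coverage)[!excl],
       excluded = data.frame(roi = colnames(coverage)[excl],
                             missing_fraction = unname(frac[excl]),
                             stringsAsFactors = FALSE))
}

#' Simulate component maps at a target Jaccard similarity
#'
#' Builds one synthetic binary component map per label of a template atlas by
#' removing region voxels and adding voxels from just outside the region so
#' that the Jaccard index against the template region hits
#' \code{target_jaccard} (within 0.05). Fixture generator for validating the
#' network-assignment stage against known ground truth.
#'
#' @param template integer-labeled 3D array (0 = background)
#' @param target_jaccard target similarity in (0, 1]
#' @param seed integer seed for the voxel draws
#' @return named list of binary masks (one per label, names \code{compL});
#'   each carries attributes \code{"template_label"} and
#'   \code{"achieved_jaccard"}
#' @export
simulate_component_maps <- function(template, target_jaccard, seed = 1L) {
  check_number(target_jaccard, "target_jaccard", lower = 1e-9, upper = 1)
  template <- as.array(template)
  labels <- sort(setdiff(unique(as.vector(template)), 0))
  if (!length(labels)) stop_("template has no labeled regions")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  out <- list()
  for (lab in labels) {
    region <- template == lab
    n <- sum(region)
    if (target_jaccard >= 1) {
      mask <- region
    } else {
      # remove r region voxels and add a outside voxels:
      # J = (n - r) / (n + a); split the mismatch between both operations
      a <- round(0.5 * n * (1 / target_jaccard - 1))
      r <- round(n - target_jaccard * (n + a))
      if (r < 0 || r >= n)
        stop_(sprintf("region %s too small (%d voxels) for target J = %.2f",
                      lab, n, target_jaccard))
      mask <- region
      if (r > 0) {
        idx <- which(region)
        mask[sample(idx, r)] <- FALSE
      }
      if (a > 0) {
        shell <- dilate_shell(region)
        outside <- which(shell & template == 0)
        if (length(outside) < a) outside <- which(!region)
        mask[sample(outside, a)] <- TRUE
      }
      achieved <- sum(mask & region) / sum(mask | region)
      if (abs(achieved - target_jaccard) > 0.05)
        stop_(sprintf("region %s: achieved J = %.3f misses target %.2f",
                      lab, achieved, target_jaccard))
    }
    m <- mask
    attr(m, "pixdim") <- attr(template, "pixdim")
    attr(m, "template_label") <- lab
    attr(m, "achieved_jaccard") <- sum(m & region) / sum(m | region)
    out[[paste0("comp", lab)]] <- m
  }
  out
}

# 6-connectivity dilation shell (voxels adjacent to the region, outside it)
dilate_shell <- function(region) {
  d <- dim(region)
  shell <- array(FALSE, d)
  shift <- function(a, dim, by) {
    out <- array(FALSE, d)
    if (dim == 1) {
      if (by > 0) out[-1, , ] <- a[-d[1], , ] else out[-d[1], , ] <- a[-1, , ]
    } else if (dim == 2) {
      if (by > 0) out[, -1, ] <- a[, -d[2], ] else out[, -d[2], ] <- a[, -1, ]
    } else {
      if (by > 0) out[, , -1] <- a[, , -d[3]] else out[, , -d[3]] <- a[, , -1]
    }
    out
  }
  for (dim in 1:3) for (by in c(-1, 1)) shell <- shell | shift(region, dim, by)
  shell & !region
}

#' Write a binary mask as gzipped NIfTI
#'
#' @param mask binary 3D array (voxel size taken from its \code{pixdim}
#'   attribute when present)
#' @param path output path (e.g. \code{mask.nii.gz})
#' @param voxel_mm length-3 voxel size in mm
#' @return \code{path}, invisibly
#' @export
write_mask_nifti <- function(mask, path,
                             voxel_mm = attr(mask, "pixdim") %||% c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
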