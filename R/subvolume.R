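#' Scatter per-voxel probabilities into a 3D probability map
#'
#' Places classifier posterior probabilities back onto the image grid.
#' In-mask voxels without a probability (e.g. excluded during
#' preprocessing) are left `NaN`; voxels outside the mask are `NaN` as
#' well.
#'
#' @param probabilities Numeric vector of `P(low BV)`.
#' @param voxel_index Linear (1-based) indices into the 3D grid, one per
#'   probability; all must fall inside the mask.
#' @param tumor_mask Logical 3D mask defining the grid and tumor extent.
#' @return A 3D array of class `dce_prob_map` with probabilities inside
#'   the mask and `NaN` elsewhere; attribute `n_unassigned` counts in-mask
#'   voxels that received no probability.
#' @export
assemble_maps <- function(probabilities, voxel_index, tumor_mask) {
  stopifnot(length(probabilities) == length(voxel_index),
            is.array(tumor_mask))
  if (!all(tumor_mask[voxel_index])) {
    stop("assemble_maps: voxel index outside the tumor mask", call. = FALSE)
  }
  map <- array(NaN, dim(tumor_mask))
  map[voxel_index] <- probabilities
  n_un <- sum(tumor_mask) - length(unique(voxel_index))
  structure(map, class = c("dce_prob_map", class(map)),
            n_unassigned = n_un)
}

# 3D connected-component labeling on a logical array via the voxel
# adjacency graph. connectivity 6 = faces only, 26 = full neighborhood.
label_components <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L), length(dim(mask)) == 3L)
  dm <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, dm)
  if (length(idx) == 0L) return(labels)
  coord <- arrayInd(idx, dm)
  pos <- integer(prod(dm))
  pos[idx] <- seq_along(idx)   # voxel -> node id

  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  }
  # half of the offsets suffice for an undirected graph
  keep <- offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 | (offs$dy == 0 & offs$dx > 0)))
  offs <- offs[keep, ]

  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nx <- coord[, 1] + offs$dx[r]
    ny <- coord[, 2] + offs$dy[r]
    nz <- coord[, 3] + offs$dz[r]
    ok <- nx >= 1 & nx <= dm[1] & ny >= 1 & ny <= dm[2] & nz >= 1 & nz <= dm[3]
    if (!any(ok)) next
    nb <- (nz[ok] - 1L) * dm[1] * dm[2] + (ny[ok] - 1L) * dm[1] + nx[ok]
    hit <- mask[nb]
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <-
      rbind(which(ok)[hit], pos[nb[hit]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  }
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

#' Extract the low blood-volume subvolume from a probability map
#'
#' Binarizes the probability map at a strict `> threshold`, labels
#' connected components of the low-BV voxels, and discards components
#' smaller than the minimum volume (the clinical 1-cc exclusion). `NaN`
#' probabilities count as below threshold.
#'
#' @param prob_map 3D probability map (e.g. from [assemble_maps()]), or a
#'   logical/0-1 array interpreted directly as a low-BV mask.
#' @param threshold Probability threshold (default 0.5, strict).
#' @param min_volume_cc Minimum component volume in cubic centimetres
#'   (default 1.0).
#' @param connectivity 6 or 26 (default 26, the full 3D neighborhood).
#' @param voxel_dims_mm Voxel edge lengths in mm (length 3).
#' @return An object of class `dce_subvolume`: list with the binary `mask`,
#'   the component inventory tibble `components` (`id`, `n_voxels`,
#'   `volume_cc`, `kept`), `voxel_dims_mm` and the filter settings.
#' @export
extract_subvolume <- function(prob_map, threshold = 0.5, min_volume_cc = 1.0,
                              connectivity = 26L,
                              voxel_dims_mm = c(1.56, 1.56, 1.5)) {
  stopifnot(length(dim(prob_map)) == 3L, length(voxel_dims_mm) == 3L)
  if (is.logical(prob_map)) {
    bin <- prob_map
  } else {
    bin <- !is.na(prob_map) & !is.nan(prob_map) & prob_map > threshold
  }
  vol_mm3 <- prod(voxel_dims_mm)
  labels <- label_components(bin, connectivity = connectivity)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  comp <- tibble::tibble(
    id = ids,
    n_voxels = vapply(ids, function(i) sum(labels == i), integer(1))
  )
  comp$volume_cc <- comp$n_voxels * vol_mm3 / 1000
  comp$kept <- comp$volume_cc >= min_volume_cc
  mask <- array(FALSE, dim(bin))
  for (i in comp$id[comp$kept]) mask[labels == i] <- TRUE
  structure(list(mask = mask, components = comp,
                 voxel_dims_mm = voxel_dims_mm,
                 threshold = threshold, min_volume_cc = min_volume_cc,
                 connectivity = connectivity),
            class = "dce_subvolume")
}

#' @export
print.dce_subvolume <- function(x, ...) {
  kept <- x$components[x$components$kept, ]
  cat("<dce_subvolume> ", sum(x$mask), " voxels in ", nrow(kept),
      " component(s) >= ", x$min_volume_cc, " cc (",
      nrow(x$components) - nrow(kept), " removed)\n", sep = "")
  invisible(x)
}

#' Voxel classification accuracy
#'
#' Percentage of voxels whose predicted label agrees with the reference.
#'
#' @param predicted,reference Equal-length label vectors.
#' @return Accuracy in percent.
#' @export
voxel_accuracy <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) == 0L) {
    stop("voxel_accuracy: labels must be nonempty and of equal length",
         call. = FALSE)
  }
  100 * mean(predicted == reference)
}

#' Dice similarity coefficient between two masks
#'
#' `DSC(G, R) = 2 |G intersect R| / (|G| + |R|)`, the standard spatial
#' overlap measure between two segmentations; 0.7 or greater is
#' conventionally regarded as excellent overlap. If both masks are empty
#' the coefficient is undefined and `NaN` is returned with a warning.
#'
#' @param g,r Logical arrays on the same grid (or `dce_subvolume` objects).
#' @return Scalar in `[0, 1]`, or `NaN` when both masks are empty.
#' @export
dice <- function(g, r) {
  if (inherits(g, "dce_subvolume")) g <- g$mask
  if (inherits(r, "dce_subvolume")) r <- r$mask
  if (!identical(dim(g), dim(r))) {
    stop("dice: masks are on different grids", call. = FALSE)
  }
  ng <- sum(g); nr <- sum(r)
  if (ng + nr == 0L) {
    warning("dice: both masks are empty; coefficient undefined (NaN)")
    return(NaN)
  }
  2 * sum(g & r) / (ng + nr)
}
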