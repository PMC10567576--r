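# Object-based colocalization: curved adhesions are defined as objects in
# the intersection of the ITGb5 and FCHo2 masks, focal adhesions as objects
# in the intersection of the ITGb5 and vinculin masks, in 2D images or 3D
# confocal stacks.

.binarize <- function(x, threshold) {
  if (identical(threshold, "moments")) x > as.numeric(moments_threshold(x))
  else x > threshold
}

.object_table <- function(lab, min_size) {
  n <- max(lab)
  if (n == 0L) return(data.frame(id = integer(), size = integer()))
  sizes <- tabulate(lab[lab > 0L], n)
  keep <- which(sizes >= min_size)
  dm <- dim(lab)
  rows <- lapply(seq_along(keep), function(k) {
    idx <- which(lab == keep[k], arr.ind = TRUE)
    ct <- colMeans(idx)
    if (length(dm) == 2L)
      data.frame(id = k, size = sizes[keep[k]], cy = ct[1], cx = ct[2])
    else
      data.frame(id = k, size = sizes[keep[k]], cy = ct[1], cx = ct[2], cz = ct[3])
  })
  if (length(rows) == 0L) {
    if (length(dm) == 2L) data.frame(id = integer(), size = integer(),
                                     cy = numeric(), cx = numeric())
    else data.frame(id = integer(), size = integer(), cy = numeric(),
                    cx = numeric(), cz = numeric())
  } else do.call(rbind, rows)
}

#' Object-based colocalization of two 2D channels
#'
#' Each channel is auto-thresholded (Tsai moments method by default), the
#' binary masks are intersected, 8-connected components are labelled and
#' components smaller than `min_size` pixels (default 10) are discarded.
#'
#' @param channel_a,channel_b registered intensity matrices of equal shape.
#' @param min_size minimum object area in pixels.
#' @param threshold `"moments"` or a numeric vector of length 2 giving fixed
#'   thresholds for the two channels.
#' @return list with `objects` (data frame: id, size, centroid), `count`,
#'   `mean_size` (`NA` when no objects) and the filtered label image
#'   `labels`. An empty intersection yields `count = 0`, not an error.
#' @export
coloc_2d <- function(channel_a, channel_b, min_size = 10L, threshold = "moments") {
  stopifnot(identical(dim(channel_a), dim(channel_b)))
  thr <- if (is.numeric(threshold)) as.list(threshold) else list(threshold, threshold)
  inter <- .binarize(channel_a, thr[[1]]) & .binarize(channel_b, thr[[2]])
  lab <- label_components(inter, connectivity = 8L)
  obj <- .object_table(lab, min_size)
  keepmap <- integer(max(lab, 1L))
  if (nrow(obj)) {
    sizes <- tabulate(lab[lab > 0L], max(lab))
    keepmap[which(sizes >= min_size)] <- seq_len(nrow(obj))
  }
  labf <- lab
  labf[lab > 0L] <- keepmap[lab[lab > 0L]]
  list(objects = obj, count = nrow(obj),
       mean_size = if (nrow(obj)) mean(obj$size) else NA_real_,
       labels = labf)
}

#' Object-based colocalization of two 3D stacks
#'
#' As [coloc_2d()] but with a per-stack global threshold, 26-connected
#' labelling and a default size filter of 25 voxels. Connectivity treats
#' voxels isotropically; anisotropic voxel sizes are flagged in the output
#' metadata, not corrected.
#'
#' @param stack_a,stack_b registered 3D arrays of equal shape.
#' @param min_size minimum object volume in voxels.
#' @param threshold `"moments"` or numeric length 2.
#' @param voxel_size recorded `c(dx, dy, dz)` in micrometres (metadata).
#' @return as [coloc_2d()], plus `voxel_size` and `anisotropic` flag.
#' @export
coloc_3d <- function(stack_a, stack_b, min_size = 25L, threshold = "moments",
                     voxel_size = c(1, 1, 1)) {
  stopifnot(identical(dim(stack_a), dim(stack_b)), length(dim(stack_a)) == 3L)
  thr <- if (is.numeric(threshold)) as.list(threshold) else list(threshold, threshold)
  inter <- .binarize(stack_a, thr[[1]]) & .binarize(stack_b, thr[[2]])
  lab <- label_components(inter, connectivity = 26L)
  obj <- .object_table(lab, min_size)
  list(objects = obj, count = nrow(obj),
       mean_size = if (nrow(obj)) mean(obj$size) else NA_real_,
       voxel_size = voxel_size,
       anisotropic = length(unique(voxel_size)) > 1L)
}

#' Per-cell census of curved and focal adhesions
#'
#' Curved adhesions = ITGb5 x FCHo2 colocalization objects; focal adhesions
#' = ITGb5 x vinculin colocalization objects, computed with identical
#' thresholds and size filters for an unbiased comparison. Works on 2D
#' matrices or 3D arrays.
#'
#' @param itgb5,fcho2,vinculin registered intensity images/stacks.
#' @param cell_labels optional integer label image assigning pixels/voxels
#'   to cells; an object belongs to the cell containing its centroid
#'   (label 0 = unassigned). `NULL` treats the field as one cell.
#' @param min_size minimum object size (default 10 px in 2D, 25 voxels in
#'   3D).
#' @param threshold `"moments"` or numeric length 2, shared by both class
#'   definitions.
#' @return list with `per_cell` data frame (`cell`, `class`, `count`,
#'   `mean_size`) and the two object tables.
#' @export
adhesion_census <- function(itgb5, fcho2, vinculin, cell_labels = NULL,
                            min_size = NULL, threshold = "moments") {
  is3d <- length(dim(itgb5)) == 3L
  if (is.null(min_size)) min_size <- if (is3d) 25L else 10L
  co <- if (is3d) coloc_3d else coloc_2d
  curved <- co(itgb5, fcho2, min_size = min_size, threshold = threshold)
  focal <- co(itgb5, vinculin, min_size = min_size, threshold = threshold)
  assign_cell <- function(obj) {
    if (nrow(obj) == 0L) return(integer(0))
    if (is.null(cell_labels)) return(rep(1L, nrow(obj)))
    if (is3d) cell_labels[cbind(round(obj$cy), round(obj$cx), round(obj$cz))]
    else cell_labels[cbind(round(obj$cy), round(obj$cx))]
  }
  cells <- if (is.null(cell_labels)) 1L else sort(unique(cell_labels[cell_labels > 0L]))
  rows <- list()
  for (cls in c("curved", "focal")) {
    obj <- get(cls)$objects
    cid <- assign_cell(obj)
    for (cc in cells) {
      sel <- cid == cc
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cc, class = cls, count = sum(sel),
        mean_size = if (any(sel)) mean(obj$size[sel]) else NA_real_)
    }
  }
  list(per_cell = do.call(rbind, rows), curved = curved, focal = focal)
}
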