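#' Maximum-intensity z-projection
#'
#' Pixelwise maximum across the planes of a stack.
#'
#' @param stack an `image_stack` (list with `planes`) or a plain list of
#'   equally-sized matrices.
#' @return a single matrix.
#' @export
max_z_projection <- function(stack) {
  planes <- if (inherits(stack, "image_stack")) stack$planes else stack
  if (!is.list(planes)) planes <- list(planes)
  if (length(planes) < 1) stop("max_z_projection: needs >= 1 plane")
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("max_z_projection: plane shapes differ")
  Reduce(pmax, planes)
}

#' Intensity-window binarization
#'
#' Mirrors the batch macro step: intensities are clipped and rescaled to the
#' window `[min_thresh, max_thresh]`, then pixels at or above `level` of the
#' rescaled range become foreground.
#'
#' @param image numeric matrix (intensities on \[0, 1\] or integer scale).
#' @param min_thresh,max_thresh intensity window; must satisfy
#'   `min_thresh < max_thresh` and lie within the image's representable
#'   range.
#' @param level binarization level on the rescaled \[0, 1\] scale
#'   (default 0.5).
#' @return logical mask matrix.
#' @export
binarize <- function(image, min_thresh, max_thresh, level = 0.5) {
  if (!is.matrix(image) || !is.numeric(image)) stop("binarize: image must be a numeric matrix")
  if (!is.finite(min_thresh) || !is.finite(max_thresh) || min_thresh >= max_thresh)
    stop("binarize: need finite min_thresh < max_thresh")
  rng_hi <- max(1, max(image))
  if (min_thresh < 0 || max_thresh > rng_hi)
    stop("binarize: thresholds outside the image intensity range [0, ",
         format(rng_hi), "]")
  resc <- (image - min_thresh) / (max_thresh - min_thresh)
  resc <- pmin(pmax(resc, 0), 1)
  resc >= level
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels across the two diagonal adjacencies with a small union-find.
label_components8 <- function(mask) {
  storage.mode(mask) <- "double"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Percent innervation from a binary mask
#'
#' Area fraction of stained fibers: regions are delineated from the mask
#' (8-connected components, after dropping specks below `min_region_px`),
#' closed, and their areas summed; the result is `100 * area / total pixels`.
#' Invariant to 90-degree rotation and to plane order upstream.
#'
#' @param mask logical (or 0/1) matrix.
#' @param min_region_px speck-rejection size in px (default 0: keep all).
#' @param fill_holes close enclosed background holes inside regions
#'   (default FALSE).
#' @return percentage in \[0, 100\].
#' @export
percent_innervation <- function(mask, min_region_px = 0, fill_holes = FALSE) {
  if (length(mask) == 0) stop("percent_innervation: empty image")
  if (is.logical(mask)) mask <- mask * 1
  if (!all(mask %in% c(0, 1))) stop("percent_innervation: mask must be binary")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (min_region_px > 0) {
    lab <- label_components8(m > 0)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_region_px)
    m <- matrix(as.numeric(lab %in% keep), nrow(m), ncol(m))
  }
  if (fill_holes) {
    f <- EBImage::fillHull(EBImage::Image(m))
    m <- matrix(as.numeric(f > 0), nrow(m), ncol(m))
  }
  100 * sum(m) / length(m)
}

#' Count stained cells by size-filtered connected components
#'
#' Labels 8-connected foreground regions and keeps those whose pixel area
#' lies inside the size criteria (inclusive), mirroring the batch
#' region-circling step with pre-determined size limits.
#'
#' @param mask logical (or 0/1) matrix.
#' @param size_criteria_px length-2 positive interval `(min_px, max_px)`.
#' @param image_id optional identifier carried on the result.
#' @return data.frame of class `region_set` (region, area, cx, cy, xmin,
#'   xmax, ymin, ymax) with attributes `count` and `image_id`.
#' @export
count_cells <- function(mask, size_criteria_px, image_id = NA_character_) {
  if (is.logical(mask)) mask <- mask * 1
  if (!all(mask %in% c(0, 1))) stop("count_cells: mask must be binary")
  if (length(size_criteria_px) != 2 || any(size_criteria_px <= 0) ||
      size_criteria_px[1] > size_criteria_px[2])
    stop("count_cells: size_criteria_px must be a positive interval")
  lab <- label_components8(mask > 0)
  n <- max(lab)
  if (n == 0) {
    out <- data.frame(region = integer(0), area = integer(0),
                      cx = numeric(0), cy = numeric(0),
                      xmin = integer(0), xmax = integer(0),
                      ymin = integer(0), ymax = integer(0))
  } else {
    idx <- which(lab > 0, arr.ind = TRUE)
    l <- lab[lab > 0]
    area <- tabulate(l, n)
    cx <- tapply(idx[, 1], l, mean)
    cy <- tapply(idx[, 2], l, mean)
    out <- data.frame(region = seq_len(n), area = area,
                      cx = as.numeric(cx), cy = as.numeric(cy),
                      xmin = as.integer(tapply(idx[, 1], l, min)),
                      xmax = as.integer(tapply(idx[, 1], l, max)),
                      ymin = as.integer(tapply(idx[, 2], l, min)),
                      ymax = as.integer(tapply(idx[, 2], l, max)))
    out <- out[out$area >= size_criteria_px[1] &
                 out$area <= size_criteria_px[2], , drop = FALSE]
    out$region <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  class(out) <- c("region_set", "data.frame")
  attr(out, "count") <- nrow(out)
  attr(out, "image_id") <- image_id
  out
}

#' CD45-to-peripherin cell ratio for one section
#'
#' Ratio of immune-cell (CD45+) to neuron (peripherin+) region counts from
#' the same section; NA with a warning when there are no peripherin regions.
#'
#' @param cd45,prph `region_set`s from [count_cells()] on the two channels of
#'   the same section.
#' @return single numeric ratio (or NA).
#' @export
cd45_prph_ratio <- function(cd45, prph) {
  ida <- attr(cd45, "image_id"); idb <- attr(prph, "image_id")
  if (!is.na(ida) && !is.na(idb) && ida != idb)
    stop("cd45_prph_ratio: region sets come from different sections (",
         ida, " vs ", idb, ")")
  nprph <- nrow(prph)
  if (nprph == 0) {
    warning("no peripherin+ regions; ratio undefined (NA)")
    return(NA_real_)
  }
  nrow(cd45) / nprph
}
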