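# Nucleus-to-nucleus distance statistics between immune phenotypes and
# tumour cells. The effective score of a phenotype is the fraction of its
# cells with at least one tumour cell within a closed radius (d <= r);
# the effective density is the count of such tumour-proximal cells per
# mm^2. Pairs are never formed across ROIs, and counts are pooled over all
# of a patient's tumour-core ROIs before the single division. The default
# fast route is an exact KD-tree nearest-neighbour search (FNN); a brute
# force O(n*m) route is kept as the oracle. No edge correction is applied
# for cells near ROI borders (a known bias, documented).

#' Euclidean pairwise distance matrix
#'
#' @param a,b two-column matrices (x, y in um).
#' @return `nrow(a)` x `nrow(b)` matrix of Euclidean distances; empty input
#'   yields an empty matrix.
#' @export
#' @examples
#' pairwise_distances(rbind(c(0, 0)), rbind(c(3, 4)))
pairwise_distances <- function(a, b) {
  a <- .as_xy(a); b <- .as_xy(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(matrix(numeric(), nrow(a), nrow(b)))
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

.as_xy <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0) return(matrix(numeric(), 0, 2))
  if (ncol(m) != 2) stop("expected a two-column (x, y) matrix",
                         call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Distance from each immune cell to its nearest tumour cell
#'
#' @param immune_xy,tumour_xy two-column coordinate matrices in um (same ROI
#'   frame; never mix ROIs).
#' @param method `"kdtree"` (exact accelerated search, default) or
#'   `"brute"` (O(n*m) oracle).
#' @return Numeric vector of nearest distances, one per immune cell; all
#'   `NA` when there is no tumour cell.
#' @export
nearest_tumour_distance <- function(immune_xy, tumour_xy,
                                    method = c("kdtree", "brute")) {
  method <- match.arg(method)
  immune_xy <- .as_xy(immune_xy); tumour_xy <- .as_xy(tumour_xy)
  n <- nrow(immune_xy)
  if (n == 0) return(numeric(0))
  if (nrow(tumour_xy) == 0) return(rep(NA_real_, n))
  if (method == "kdtree")
    as.numeric(FNN::knnx.dist(tumour_xy, immune_xy, k = 1,
                              algorithm = "kd_tree"))
  else
    .cpp_min_dist(immune_xy, tumour_xy)
}

#' Effective score of an immune phenotype around tumour cells
#'
#' Fraction of immune cells "paired" with a tumour cell, i.e. having at
#' least one tumour cell within `radius_um` (closed interval, d <= r) in
#' the same ROI. `xy` inputs are lists of per-ROI coordinate matrices so
#' pooling is paired-and-total counts across ROIs followed by one
#' division. With zero immune cells the score is missing (`NA`), never 0.
#'
#' @param immune_xy,tumour_xy single two-column matrices, or lists of
#'   matrices (one per ROI, immune and tumour lists aligned).
#' @param radius_um pairing radius in um (> 0); the study design uses 10,
#'   20 and 30.
#' @param method see [nearest_tumour_distance()].
#' @return List: `n_immune`, `n_paired`, `effective_score`.
#' @export
#' @examples
#' im <- rbind(c(0, 0), c(15, 0), c(100, 100), c(30, 0))
#' tu <- rbind(c(10, 0), c(50, 50), c(12, 0))
#' effective_score(im, tu, 20)$effective_score # 0.75
effective_score <- function(immune_xy, tumour_xy, radius_um,
                            method = c("kdtree", "brute")) {
  stopifnot(is.numeric(radius_um), radius_um > 0)
  method <- match.arg(method)
  if (!is.list(immune_xy)) immune_xy <- list(immune_xy)
  if (!is.list(tumour_xy)) tumour_xy <- list(tumour_xy)
  stopifnot(length(immune_xy) == length(tumour_xy))
  n_immune <- 0L; n_paired <- 0L
  for (k in seq_along(immune_xy)) {
    d <- nearest_tumour_distance(immune_xy[[k]], tumour_xy[[k]], method)
    n_immune <- n_immune + length(d)
    n_paired <- n_paired + sum(!is.na(d) & d <= radius_um)
  }
  list(n_immune = n_immune, n_paired = n_paired,
       effective_score = if (n_immune > 0) n_paired / n_immune else
         NA_real_)
}

#' Effective density of an immune phenotype around tumour cells
#'
#' Absolute number of tumour-proximal immune cells (at least one tumour
#' cell within `radius_um`, default 20 um) per mm^2 of the pooled area.
#' Always bounded above by the plain density of the same phenotype on the
#' same ROI set.
#'
#' @inheritParams effective_score
#' @param area_mm2 pooled area of the ROI set (> 0).
#' @return Effective density in cells/mm^2.
#' @export
effective_density <- function(immune_xy, tumour_xy, radius_um = 20,
                              area_mm2, method = c("kdtree", "brute")) {
  stopifnot(is.numeric(area_mm2))
  if (area_mm2 <= 0) stop("area_mm2 must be positive", call. = FALSE)
  es <- effective_score(immune_xy, tumour_xy, radius_um, method)
  es$n_paired / area_mm2
}

# split per-ROI coordinates of a patient's cells: immune of one phenotype
# vs tumour cells, TC ROIs only by default
.patient_roi_xy <- function(data, registry, phenotype, patient_id,
                            roi_class = "TC") {
  rois <- data$rois[data$rois$patient_id == patient_id &
                    data$rois$roi_class == roi_class, , drop = FALSE]
  cells <- data$cells[data$cells$roi_id %in% rois$roi_id, , drop = FALSE]
  hits <- assign_phenotypes(cells, registry[phenotype])[, 1]
  immune <- lapply(rois$roi_id, function(rid) {
    sel <- cells$roi_id == rid & hits
    cbind(cells$x_um[sel], cells$y_um[sel])
  })
  tumour <- lapply(rois$roi_id, function(rid) {
    sel <- cells$roi_id == rid & cells$is_tumour_cell
    cbind(cells$x_um[sel], cells$y_um[sel])
  })
  list(rois = rois, immune = immune, tumour = tumour)
}

#' Long-format spatial statistics table
#'
#' Per patient and phenotype: effective score at each requested radius,
#' effective density, and nearest-tumour-cell distance summaries, computed
#' on tumour-core ROIs with counts pooled across the patient's ROIs.
#' ROIs without tumour cells contribute immune cells whose nearest
#' distances are missing; those cells still count in the effective-score
#' denominator (they are unpaired by definition).
#'
#' @param data a `tiic_cell_data` object.
#' @param registry a `phenotype_registry`.
#' @param phenotypes rule names to compute (default: whole registry).
#' @param radii_um pairing radii; default `c(10, 20, 30)`.
#' @param density_radius_um radius used for the effective density (default
#'   20 um).
#' @param roi_class ROI class to restrict to; default `"TC"` (tumour core).
#' @param method see [nearest_tumour_distance()].
#' @return data.frame with one row per patient x phenotype x radius:
#'   `n_immune`, `n_paired`, `effective_score`, `effective_density`
#'   (only at `density_radius_um`, else `NA`), `area_mm2`,
#'   `mean_nearest_um`, `median_nearest_um`.
#' @export
spatial_table <- function(data, registry, phenotypes = names(registry),
                          radii_um = c(10, 20, 30),
                          density_radius_um = 20, roi_class = "TC",
                          method = c("kdtree", "brute")) {
  method <- match.arg(method)
  patients <- unique(data$rois$patient_id)
  out <- list()
  for (pid in patients) {
    if (!any(data$rois$patient_id == pid &
             data$rois$roi_class == roi_class)) next
    for (ph in phenotypes) {
      s <- .patient_roi_xy(data, registry, ph, pid, roi_class)
      area <- sum(.roi_area(s$rois, "all"))
      nn <- unlist(lapply(seq_along(s$immune), function(k)
        nearest_tumour_distance(s$immune[[k]], s$tumour[[k]], method)))
      for (r in radii_um) {
        es <- effective_score(s$immune, s$tumour, r, method)
        out[[length(out) + 1L]] <- data.frame(
          patient_id = pid, phenotype = ph, roi_class = roi_class,
          radius_um = r, n_immune = es$n_immune, n_paired = es$n_paired,
          effective_score = es$effective_score,
          effective_density = if (r == density_radius_um)
            es$n_paired / area else NA_real_,
          area_mm2 = area,
          mean_nearest_um = if (length(nn) && any(!is.na(nn)))
            mean(nn, na.rm = TRUE) else NA_real_,
          median_nearest_um = if (length(nn) && any(!is.na(nn)))
            median(nn, na.rm = TRUE) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
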