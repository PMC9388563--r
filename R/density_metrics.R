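# Region- and compartment-resolved cell densities. All ROIs of one class
# from one patient form a cluster: counts and areas are pooled over the
# cluster before the single division (never an average of per-ROI
# densities).

.roi_area <- function(rois, compartment) {
  nominal <- rois$width_um * rois$height_um / 1e6
  tum <- rois$area_tumour_mm2
  str <- rois$area_stroma_mm2
  fallback <- is.na(tum) | is.na(str)
  switch(compartment,
    tumour_nest = ifelse(fallback, NA_real_, tum),
    stroma = ifelse(fallback, NA_real_, str),
    # "all" uses segmented tumour+stroma area when provided, else the
    # nominal stamp area (flagged upstream in QC)
    all = ifelse(fallback, nominal, tum + str),
    stop("unknown compartment: ", compartment, call. = FALSE))
}

#' Per-patient pooled cell density
#'
#' Density of one phenotype for one patient over all their ROIs of a class:
#' total phenotype count in the pooled ROIs (optionally restricted to the
#' tumour-nest or stroma compartment) divided by the pooled area in mm^2.
#' For `compartment = "all"` the area is the segmented tumour + stroma area
#' when available, else the nominal stamp area (930 x 700 um = 0.651 mm^2
#' per field).
#'
#' @param data a `tiic_cell_data` object.
#' @param phenotype rule name present in `registry`.
#' @param registry a `phenotype_registry`.
#' @param patient_id patient to compute for.
#' @param roi_class one of `"TC"`, `"IM"`, `"N"`.
#' @param compartment `"all"` (default), `"tumour_nest"` or `"stroma"`.
#' @return One-row data.frame: `patient_id`, `phenotype`, `roi_class`,
#'   `compartment`, `count`, `area_mm2`, `density` (cells/mm^2).
#' @export
patient_density <- function(data, phenotype, registry, patient_id,
                            roi_class = "TC", compartment = "all") {
  stopifnot(inherits(data, "tiic_cell_data"),
            roi_class %in% .ROI_CLASSES)
  rois <- data$rois[data$rois$patient_id == patient_id &
                    data$rois$roi_class == roi_class, , drop = FALSE]
  if (nrow(rois) == 0)
    stop("no ", roi_class, " ROI for patient ", patient_id, call. = FALSE)
  areas <- .roi_area(rois, compartment)
  if (anyNA(areas))
    stop("compartment '", compartment, "' requires segmented areas, ",
         "absent for patient ", patient_id, call. = FALSE)
  area <- sum(areas)
  if (area <= 0)
    stop("pooled area is zero for patient ", patient_id,
         " (", roi_class, "/", compartment, ")", call. = FALSE)
  cells <- data$cells[data$cells$roi_id %in% rois$roi_id, , drop = FALSE]
  if (compartment != "all")
    cells <- cells[cells$compartment == compartment, , drop = FALSE]
  hits <- assign_phenotypes(cells, registry[phenotype])
  count <- sum(hits[, 1])
  data.frame(patient_id = patient_id, phenotype = phenotype,
             roi_class = roi_class, compartment = compartment,
             count = count, area_mm2 = area, density = count / area,
             stringsAsFactors = FALSE)
}

#' Long-format density table
#'
#' [patient_density()] over every patient and every requested phenotype /
#' ROI class / compartment combination. Combinations without ROIs of the
#' requested class are silently omitted (not every patient has every
#' region annotated).
#'
#' @inheritParams patient_density
#' @param phenotypes character vector of rule names (default: whole
#'   registry).
#' @param roi_classes subset of TC/IM/N.
#' @param compartments subset of all/tumour_nest/stroma.
#' @return data.frame of density records in long format.
#' @export
density_table <- function(data, registry, phenotypes = names(registry),
                          roi_classes = "TC", compartments = "all") {
  patients <- unique(data$rois$patient_id)
  out <- list()
  for (pid in patients) for (rc in roi_classes) {
    has <- any(data$rois$patient_id == pid & data$rois$roi_class == rc)
    if (!has) next
    for (cp in compartments) for (ph in phenotypes) {
      out[[length(out) + 1L]] <-
        patient_density(data, ph, registry, pid, rc, cp)
    }
  }
  do.call(rbind, out)
}

#' Dichotomise patients at the two-thirds quantile
#'
#' Splits per-patient values into `"high"` (strictly above the empirical
#' two-thirds quantile, type-1/inverse-CDF definition) and `"low"` (at or
#' below it, so ties at the cut go low). With all-distinct values the high
#' group has `n - ceiling(2n/3)` members. `NA` values stay `NA`.
#'
#' @param values named numeric vector (names = patient ids).
#' @return Named character vector of `"high"`/`"low"` (NA preserved).
#' @export
#' @examples
#' dichotomise_tertile(setNames(1:9, paste0("P", 1:9)))
dichotomise_tertile <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3)
    stop("need >= 3 non-missing values to dichotomise", call. = FALSE)
  cut <- quantile(values[ok], 2 / 3, type = 1, names = FALSE)
  out <- ifelse(values > cut, "high", "low")
  out[!ok] <- NA_character_
  if (!is.null(names(values))) names(out) <- names(values)
  out
}
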