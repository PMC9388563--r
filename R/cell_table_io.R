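# Reading, validating and writing the per-cell, per-ROI and per-patient
# tables every downstream stage consumes. Input layout mirrors inForm-style
# per-cell exports: one row per segmented nucleus, binary marker columns.

.CELL_REQUIRED <- c("cell_id", "patient_id", "roi_id", "roi_class",
                    "compartment", "x_um", "y_um", "is_tumour_cell")
.ROI_OPTIONAL <- c("width_um", "height_um", "area_tumour_mm2",
                   "area_stroma_mm2")

#' Read and validate per-cell tables
#'
#' Reads one or more delimited (CSV/TSV, sniffed by [data.table::fread()])
#' per-cell tables exported from image analysis, validates them against a
#' marker panel, and aggregates per-ROI metadata. Mandatory columns:
#' `cell_id`, `patient_id`, `roi_id`, `roi_class` (TC/IM/N), `compartment`
#' (tumour_nest/stroma), `x_um`, `y_um`, `is_tumour_cell`, plus one binary
#' column per panel marker. Optional per-row ROI metadata (`width_um`,
#' `height_um`, `area_tumour_mm2`, `area_stroma_mm2`), constant within an
#' ROI, is lifted into the ROI table; when segmentation areas are absent the
#' nominal 930 x 700 um stamp area is used downstream and the fallback is
#' flagged in the QC report.
#'
#' Marker columns not named by the panel are rejected, as are non-binary
#' marker values, missing/non-finite coordinates and duplicate cell ids
#' (the only deduplication performed for overlapping fields).
#'
#' @param paths character vector of file paths; multiple files (e.g. one per
#'   ROI stamp) are concatenated.
#' @param panel a panel configuration from [default_panel()].
#' @return A list of class `tiic_cell_data` with elements `cells`
#'   (data.frame, one row per cell), `rois` (data.frame, one row per ROI)
#'   and `qc` (list: row counts by ROI class and compartment, area-fallback
#'   flag).
#' @export
read_cell_table <- function(paths, panel = default_panel()) {
  stopifnot(is.character(paths), length(paths) >= 1)
  for (p in paths)
    if (!file.exists(p)) stop("cell table not found: ", p, call. = FALSE)
  tabs <- lapply(paths, function(p) {
    as.data.frame(data.table::fread(p, na.strings = c("", "NA")))
  })
  raw <- data.table::rbindlist(tabs, use.names = TRUE, fill = FALSE)
  raw <- as.data.frame(raw)
  validate_cell_table(raw, panel)
}

#' Validate an in-memory cell table
#'
#' The validation core behind [read_cell_table()]; useful when cells are
#' produced programmatically (e.g. by [simulate_cohort()]).
#'
#' @param raw data.frame in the cell-table layout.
#' @inheritParams read_cell_table
#' @return A `tiic_cell_data` list; see [read_cell_table()].
#' @export
validate_cell_table <- function(raw, panel = default_panel()) {
  markers <- panel$markers
  missing_cols <- setdiff(c(.CELL_REQUIRED, markers), names(raw))
  if (length(missing_cols))
    stop("cell table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra_markers <- setdiff(names(raw),
                           c(.CELL_REQUIRED, .ROI_OPTIONAL, markers))
  if (length(extra_markers))
    stop("unknown marker column(s) not in panel '", panel$name, "': ",
         paste(extra_markers, collapse = ", "), call. = FALSE)

  if (anyDuplicated(raw$cell_id)) {
    dup <- raw$cell_id[duplicated(raw$cell_id)][1]
    stop("duplicate cell_id: ", dup, call. = FALSE)
  }
  for (col in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop("non-finite or negative ", col, " at row(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    raw[[col]] <- v
  }
  if (!all(raw$roi_class %in% .ROI_CLASSES))
    stop("roi_class must be one of ", paste(.ROI_CLASSES, collapse = "/"),
         call. = FALSE)
  if (!all(raw$compartment %in% .COMPARTMENTS))
    stop("compartment must be one of ",
         paste(.COMPARTMENTS, collapse = "/"), call. = FALSE)
  for (m in c(markers, "is_tumour_cell")) {
    v <- raw[[m]]
    if (is.logical(v)) {
      if (anyNA(v))
        stop("non-binary value in column '", m, "' at row ",
             which(is.na(v))[1], call. = FALSE)
      next
    }
    ok <- v %in% c(0, 1, "0", "1", "TRUE", "FALSE", "true", "false")
    if (!all(ok))
      stop("non-binary value in column '", m, "' at row ",
           which(!ok)[1], call. = FALSE)
    raw[[m]] <- v %in% c(1, "1", "TRUE", "true")
  }

  roi_cols <- intersect(.ROI_OPTIONAL, names(raw))
  area_fallback <- !all(c("area_tumour_mm2", "area_stroma_mm2") %in% roi_cols)
  rois <- unique(raw[, c("roi_id", "patient_id", "roi_class", roi_cols),
                     drop = FALSE])
  if (anyDuplicated(rois$roi_id))
    stop("ROI metadata not constant within roi_id: ",
         rois$roi_id[duplicated(rois$roi_id)][1], call. = FALSE)
  if (!"width_um" %in% names(rois)) rois$width_um <- .STAMP_WIDTH_UM
  if (!"height_um" %in% names(rois)) rois$height_um <- .STAMP_HEIGHT_UM
  if (area_fallback) {
    # nominal stamp area, split later as a single "all" compartment
    rois$area_tumour_mm2 <- NA_real_
    rois$area_stroma_mm2 <- NA_real_
  } else {
    tot <- rois$width_um * rois$height_um / 1e6
    bad <- rois$area_tumour_mm2 + rois$area_stroma_mm2 > tot + 1e-9
    if (any(bad))
      stop("segmented areas exceed field area for ROI: ",
           rois$roi_id[bad][1], call. = FALSE)
  }
  rownames(rois) <- NULL

  cells <- raw[, c(.CELL_REQUIRED, markers)]
  qc <- list(
    n_cells = nrow(cells),
    n_rois = nrow(rois),
    cells_per_roi_class = table(factor(cells$roi_class, .ROI_CLASSES)),
    cells_per_compartment = table(factor(cells$compartment, .COMPARTMENTS)),
    area_fallback = area_fallback
  )
  structure(list(cells = cells, rois = rois, qc = qc, panel = panel),
            class = "tiic_cell_data")
}

#' @export
print.tiic_cell_data <- function(x, ...) {
  cat("<tiic_cell_data>", x$qc$n_cells, "cells in", x$qc$n_rois,
      "ROIs,", length(unique(x$cells$patient_id)), "patient(s)\n")
  print(x$qc$cells_per_roi_class)
  invisible(x)
}

#' Write a cell table to disk
#'
#' Inverse of [read_cell_table()]: joins ROI metadata back onto the cells
#' and writes a single CSV that round-trips through [read_cell_table()].
#'
#' @param data a `tiic_cell_data` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(data, path) {
  stopifnot(inherits(data, "tiic_cell_data"))
  out <- merge(data$cells,
               data$rois[, c("roi_id", setdiff(names(data$rois),
                                               c("roi_id", "patient_id",
                                                 "roi_class")))],
               by = "roi_id", sort = FALSE)
  ord <- c(.CELL_REQUIRED, data$panel$markers,
           intersect(.ROI_OPTIONAL, names(out)))
  data.table::fwrite(out[, ord], path, na = "")
  invisible(path)
}

#' Read a per-patient clinical table
#'
#' Columns: `patient_id`, `ebv` (pos/neg), `mmr` (dMMR/pMMR), `cps`
#' (non-negative), `her2` (pos/neg), `response` (CR/PR/SD/PD or empty for
#' missing), `os_months`/`iros_months`/`irpfs_months`,
#' `os_event`/`iros_event`/`irpfs_event` (0/1), `cohort`
#' (training/validation). A derived logical `responder` column encodes the
#' RECIST responder definition (CR or PR); patients with missing response
#' keep `responder = NA` and remain usable for survival analysis.
#'
#' @param path CSV file.
#' @return data.frame of validated clinical records.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path,
                               call. = FALSE)
  cl <- as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
  validate_clinical_table(cl)
}

#' Validate an in-memory clinical table
#' @param cl data.frame in the clinical layout; see [read_clinical_table()].
#' @return validated data.frame with derived `responder`.
#' @export
validate_clinical_table <- function(cl) {
  req <- c("patient_id", "ebv", "mmr", "cps", "her2", "response",
           "os_months", "os_event", "iros_months", "iros_event",
           "irpfs_months", "irpfs_event", "cohort")
  miss <- setdiff(req, names(cl))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cl$patient_id)) stop("duplicate patient_id",
                                         call. = FALSE)
  chk <- function(col, levels) {
    v <- cl[[col]]
    if (!all(v %in% levels | is.na(v)))
      stop("invalid value in '", col, "'; allowed: ",
           paste(levels, collapse = "/"), call. = FALSE)
  }
  chk("ebv", c("pos", "neg")); chk("mmr", c("dMMR", "pMMR"))
  chk("her2", c("pos", "neg")); chk("response", c("CR", "PR", "SD", "PD"))
  chk("cohort", c("training", "validation"))
  if (any(cl$cps < 0, na.rm = TRUE)) stop("cps must be non-negative",
                                          call. = FALSE)
  cl$responder <- ifelse(is.na(cl$response), NA, cl$response %in% c("CR", "PR"))
  cl
}

#' Write and read back patient feature tables
#'
#' `write_features()` writes a per-patient feature data.frame to CSV with
#' missing values as explicit empty cells (never 0); `read_features()` reads
#' it back. The pair round-trips losslessly.
#'
#' @param features data.frame, one row per patient.
#' @param path CSV file.
#' @return `write_features()`: `path`, invisibly. `read_features()`: the
#'   data.frame.
#' @export
write_features <- function(features, path) {
  stopifnot(is.data.frame(features))
  data.table::fwrite(features, path, na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path,
                               call. = FALSE)
  as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
}
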