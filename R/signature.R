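# The four-feature TIIC signature: densities of CD4+FoxP3-PD-L1+,
# CD8+PD-1-LAG-3- and CD68+STING+ cells plus the effective score of
# CD8+PD-1+LAG-3- T cells, optionally combined with EBV / MMR / PD-L1 CPS.
# The prognostic score weights each signature feature by its univariate
# Cox hazard ratio and splits patients at the cohort median.

#' Canonical signature feature definitions
#'
#' The fixed order and provenance of the four core TIIC-signature features.
#' `es_cd8_pd1pos_lag3neg` is an effective score whose radius is
#' configurable (default 20 um); the three densities are tumour-core,
#' all-compartment densities.
#'
#' @return data.frame with columns `feature`, `kind`
#'   (density/effective_score), `phenotype`.
#' @export
signature_features <- function() {
  data.frame(
    feature = c("d_cd4_foxp3neg_pdl1pos", "d_cd8_pd1neg_lag3neg",
                "d_cd68_stingpos", "es_cd8_pd1pos_lag3neg"),
    kind = c("density", "density", "density", "effective_score"),
    phenotype = c("CD4+PD-L1+FoxP3-", "CD8+PD-1-LAG-3-", "CD68+STING+",
                  "CD8+PD-1+LAG-3-"),
    stringsAsFactors = FALSE)
}

#' Build the TIIC signature matrix
#'
#' Assembles the per-patient 4-feature signature vector (fixed canonical
#' order) from a density table and a spatial table, optionally appending
#' the clinical covariates EBV (pos = 1), MMR (dMMR = 1) and PD-L1 CPS for
#' the combined signature. Patients missing any component keep `NA` in
#' that slot and are flagged incomplete.
#'
#' @param density_tbl output of [density_table()] covering the three
#'   density phenotypes on TC/all.
#' @param spatial_tbl output of [spatial_table()] covering
#'   `CD8+PD-1+LAG-3-`.
#' @param clinical validated clinical data.frame (required when
#'   `combined = TRUE`).
#' @param combined append EBV/MMR/CPS?
#' @param radius_um effective-score radius to pull from `spatial_tbl`
#'   (default 20).
#' @return data.frame, one row per patient: `patient_id`, the feature
#'   columns, and logical `complete`.
#' @export
build_signature <- function(density_tbl, spatial_tbl, clinical = NULL,
                            combined = FALSE, radius_um = 20) {
  sf <- signature_features()
  dsub <- density_tbl[density_tbl$roi_class == "TC" &
                      density_tbl$compartment == "all", , drop = FALSE]
  ssub <- spatial_tbl[spatial_tbl$radius_um == radius_um, , drop = FALSE]
  patients <- sort(unique(c(dsub$patient_id, ssub$patient_id)))
  out <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sf))) {
    if (sf$kind[i] == "density") {
      src <- dsub[dsub$phenotype == sf$phenotype[i], ]
      if (nrow(src) == 0)
        stop("density table lacks phenotype '", sf$phenotype[i],
             "' (TC/all); is it in the registry?", call. = FALSE)
      v <- src$density[match(patients, src$patient_id)]
    } else {
      src <- ssub[ssub$phenotype == sf$phenotype[i], ]
      if (nrow(src) == 0)
        stop("spatial table lacks phenotype '", sf$phenotype[i],
             "' at radius ", radius_um, " um", call. = FALSE)
      v <- src$effective_score[match(patients, src$patient_id)]
    }
    out[[sf$feature[i]]] <- v
  }
  if (combined) {
    if (is.null(clinical))
      stop("combined signature requires the clinical table", call. = FALSE)
    idx <- match(patients, clinical$patient_id)
    out$ebv <- as.numeric(clinical$ebv[idx] == "pos")
    out$mmr <- as.numeric(clinical$mmr[idx] == "dMMR")
    out$cps <- clinical$cps[idx]
  }
  out$complete <- complete.cases(out[, setdiff(names(out),
                                               c("patient_id", "complete")),
                                     drop = FALSE])
  out
}

#' HR-weighted prognostic score
#'
#' Fits a univariate Cox proportional-hazards model per signature feature
#' (via [cox_fit()]), uses each hazard ratio as that feature's weight, and
#' scores every patient by the weighted sum of the raw feature values
#' (features are deliberately not rescaled; an optional z-scaling switch
#' exists but defaults off). Patients are split into high/low at the
#' scoring cohort's median score (configurable cut-point). Weights may be
#' fitted on one cohort and applied to another by passing them explicitly.
#'
#' @param signature output of [build_signature()] (core 4 features;
#'   incomplete patients are dropped with a message).
#' @param survival_data data.frame with `patient_id`, `time`, `event` for
#'   the weight-fitting cohort (ignored when `weights` given).
#' @param weights optional named numeric vector of per-feature hazard
#'   ratios to reuse (e.g. fitted on the training cohort).
#' @param cut cut-point for the high/low split: `"median"` (default) or a
#'   number.
#' @param scale z-score features before weighting (default `FALSE`).
#' @return List of class `tiic_prognostic_score`: `weights` (HR per
#'   feature with CI and p when fitted here), `scores` (data.frame
#'   `patient_id`, `score`, `group`), `cut_value`.
#' @export
prognostic_score <- function(signature, survival_data = NULL,
                             weights = NULL, cut = "median",
                             scale = FALSE) {
  feats <- signature_features()$feature
  miss <- setdiff(feats, names(signature))
  if (length(miss))
    stop("signature lacks feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sig <- signature[signature$complete %in% TRUE |
                   complete.cases(signature[, feats]), , drop = FALSE]
  if (nrow(sig) < nrow(signature))
    message(nrow(signature) - nrow(sig),
            " incomplete patient(s) dropped from scoring")
  X <- as.matrix(sig[, feats])
  if (scale) X <- base::scale(X)
  fitted <- NULL
  if (is.null(weights)) {
    if (is.null(survival_data))
      stop("either survival_data (to fit weights) or weights required",
           call. = FALSE)
    idx <- match(sig$patient_id, survival_data$patient_id)
    if (anyNA(idx))
      stop("survival data missing for patient(s): ",
           paste(head(sig$patient_id[is.na(idx)], 3), collapse = ", "),
           call. = FALSE)
    sd_ <- cbind(survival_data[idx, c("time", "event")],
                 as.data.frame(if (scale) X else sig[, feats]))
    fitted <- cox_fit(sd_, feats, adjustment = "univariate")
    weights <- setNames(fitted$hr, fitted$covariate)
  }
  weights <- weights[feats]
  if (anyNA(weights))
    stop("weights must cover all four signature features", call. = FALSE)
  score <- as.numeric(X %*% weights)
  cut_value <- if (identical(cut, "median")) median(score) else
    as.numeric(cut)
  group <- ifelse(score > cut_value, "high", "low")
  structure(list(
    weights = weights, weight_fits = fitted,
    scores = data.frame(patient_id = sig$patient_id, score = score,
                        group = group, stringsAsFactors = FALSE),
    cut_value = cut_value),
    class = "tiic_prognostic_score")
}

#' @export
print.tiic_prognostic_score <- function(x, ...) {
  cat("<tiic_prognostic_score> HR weights:\n")
  print(round(x$weights, 3))
  cat("cut:", signif(x$cut_value, 4), "-",
      sum(x$scores$group == "high"), "high /",
      sum(x$scores$group == "low"), "low\n")
  invisible(x)
}
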