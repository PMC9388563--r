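# Descriptive and comparative cohort statistics: Pearson chi-square
# without continuity correction (the convention matching the published
# baseline tables this package validates against), Mann-Whitney U,
# Kruskal-Wallis with Dunn's post-hoc comparisons, the PD-L1 combined
# positive score, and the section-to-section reproducibility coefficient
# of variation.

#' Pearson chi-square test for a contingency table
#'
#' Pearson chi-square *without* Yates continuity correction, df =
#' (r-1)(c-1). No continuity correction is applied because the published
#' baseline-characteristics p-values this package reproduces match the
#' uncorrected statistic.
#'
#' @param table integer matrix, at least 2 x 2.
#' @return List: `statistic`, `df`, `p`.
#' @export
#' @examples
#' chi_square(matrix(c(15, 10, 19, 12, 3, 0), nrow = 3))
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column marginal", call. = FALSE)
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = as.numeric(ct$statistic), df = as.integer(ct$parameter),
       p = as.numeric(ct$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. Small tie-free samples
#' (n * m <= 400) use the exact distribution; otherwise the normal
#' approximation with tie correction (no continuity correction) is used.
#'
#' @param a,b numeric samples.
#' @return List: `U` (statistic for sample `a`), `p`, `exact` (logical).
#' @export
#' @examples
#' mann_whitney(1:3, 4:6)$p # exact: 0.1
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  exact <- length(a) * length(b) <= 400 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = FALSE))
  list(U = as.numeric(wt$statistic), p = as.numeric(wt$p.value),
       exact = exact)
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Kruskal-Wallis H with tie correction, followed by Dunn's pairwise
#' z-tests on mean ranks with a multiplicity adjustment over all pairs
#' (Bonferroni by default, matching the Dunn-Bonferroni convention).
#'
#' @param groups named list of numeric vectors (e.g. densities in TC, IM,
#'   N), each non-empty.
#' @param p_adjust adjustment method for the pairwise p-values (see
#'   [stats::p.adjust()]).
#' @return List: `statistic`, `df`, `p` (omnibus), and `pairs` — a
#'   data.frame `group1`, `group2`, `z`, `p_unadjusted`, `p_adjusted`.
#' @export
kruskal_dunn <- function(groups, p_adjust = "bonferroni") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0))
    stop("all groups must be non-empty", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1) { # every observation tied: no evidence
    combos <- utils::combn(names(groups), 2)
    return(list(statistic = 0, df = length(groups) - 1L, p = 1,
                pairs = data.frame(group1 = combos[1, ],
                                   group2 = combos[2, ],
                                   z = 0, p_unadjusted = 1, p_adjusted = 1,
                                   stringsAsFactors = FALSE)))
  }
  kw <- kruskal.test(x, g)

  # Dunn's z on mean ranks with the tie-corrected variance
  n <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)
  sizes <- tapply(rk, g, length)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  combos <- utils::combn(names(groups), 2)
  z <- p_un <- numeric(ncol(combos))
  for (k in seq_len(ncol(combos))) {
    i <- combos[1, k]; j <- combos[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[i]] + 1 / sizes[[j]]))
    z[k] <- (mean_rank[[i]] - mean_rank[[j]]) / se
    p_un[k] <- 2 * pnorm(-abs(z[k]))
  }
  list(statistic = as.numeric(kw$statistic),
       df = as.integer(kw$parameter), p = as.numeric(kw$p.value),
       pairs = data.frame(group1 = combos[1, ], group2 = combos[2, ],
                          z = z, p_unadjusted = p_un,
                          p_adjusted = pmin(1, stats::p.adjust(p_un,
                                                               p_adjust)),
                          stringsAsFactors = FALSE))
}

#' PD-L1 combined positive score
#'
#' CPS = 100 x (PD-L1-positive tumour cells + PD-L1-positive lymphocytes +
#' PD-L1-positive macrophages) / viable tumour cells. Lymphocytes are
#' cells positive for CD8, CD4 or CD20; macrophages are CD68-positive;
#' PD-L1-positive neutrophils (CD66b) and other cells are excluded from
#' the numerator. Also assigns the conventional CPS band.
#'
#' @param cells cell data.frame with `is_tumour_cell`, `PD-L1` and lineage
#'   marker columns.
#' @return List: `cps`, `band` (one of `"<1"`, `"1-5"`, `"5-10"`,
#'   `">=10"`), `n_tumour`, `n_positive`.
#' @export
compute_cps <- function(cells) {
  n_tumour <- sum(cells$is_tumour_cell)
  if (n_tumour == 0) stop("no tumour cells; CPS undefined", call. = FALSE)
  pdl1 <- cells[["PD-L1"]]
  if (is.null(pdl1)) stop("cells lack a PD-L1 column", call. = FALSE)
  lym <- (cells$CD8 | cells$CD4 | cells$CD20) & !cells$is_tumour_cell
  mac <- cells$CD68 & !cells$is_tumour_cell
  n_pos <- sum(pdl1 & (cells$is_tumour_cell | lym | mac))
  cps <- 100 * n_pos / n_tumour
  band <- if (cps < 1) "<1" else if (cps < 5) "1-5" else
    if (cps < 10) "5-10" else ">=10"
  list(cps = cps, band = band, n_tumour = n_tumour, n_positive = n_pos)
}

#' Section-to-section reproducibility (coefficient of variation)
#'
#' CV = sample standard deviation / mean of per-section densities, per
#' case and phenotype; the intra-patient variance check for staining and
#' ROI-selection consistency.
#'
#' @param densities data.frame with columns `case`, `phenotype`,
#'   `density` (one row per section).
#' @return data.frame: `case`, `phenotype`, `n_sections`, `mean`, `sd`,
#'   `cv` (`NA` with a flag when the mean is 0).
#' @export
reproducibility_cv <- function(densities) {
  stopifnot(all(c("case", "phenotype", "density") %in% names(densities)))
  sp <- split(densities, densities[, c("case", "phenotype")], drop = TRUE)
  out <- lapply(sp, function(d) {
    if (nrow(d) < 2)
      stop("need >= 2 sections per case/phenotype", call. = FALSE)
    m <- mean(d$density); s <- sd(d$density)
    data.frame(case = d$case[1], phenotype = d$phenotype[1],
               n_sections = nrow(d), mean = m, sd = s,
               cv = if (m > 0) s / m else NA_real_,
               undefined = m <= 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Baseline contingency tables of the motivating gastric-cancer cohort
#'
#' Transcribed baseline-characteristic counts of the published 80-patient
#' gastric-cancer immunotherapy cohort this package's defaults emulate:
#' training (n = 44) vs validation (n = 15) contingency tables for the
#' treated patients with known response, plus whole-cohort totals. Used by
#' the worked examples and the acceptance checks; columns are cohorts,
#' rows are characteristic levels.
#'
#' @return Named list of integer matrices (`sex`, `ecog`,
#'   `differentiation`, `lauren`, `mmr`, `ebv`) plus scalar counts
#'   `n_total`, `n_male`, `n_treated_known_response`, `n_responders`.
#' @export
gc_baseline_tables <- function() {
  m <- function(v, nr, rn) matrix(v, nrow = nr,
                                  dimnames = list(rn,
                                                  c("training",
                                                    "validation")))
  list(
    sex = m(c(35, 9, 10, 5), 2, c("male", "female")),
    ecog = m(c(27, 17, 10, 5), 2, c("0", "1")),
    differentiation = m(c(9, 17, 18, 8, 1, 6), 3,
                        c("moderate", "moderate-poor", "poor")),
    lauren = m(c(15, 10, 19, 12, 3, 0), 3,
               c("intestinal", "diffused", "mixed")),
    mmr = m(c(37, 7, 14, 1), 2, c("pMMR", "dMMR")),
    ebv = m(c(8, 36, 1, 14), 2, c("pos", "neg")),
    n_total = 80L, n_male = 61L,
    n_treated_known_response = 59L, n_responders = 19L)
}
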