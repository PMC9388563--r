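one_pop_cfg <- function(lambda, beta = 0, clustering = "poisson",
                        tumour = 300, seed = 1) {
  simulation_config(
    n_patients = 1L, rois_per_patient = c(TC = 1L, IM = 0L, N = 0L),
    populations = list(list(name = "cd8", positive = "CD8",
                            lambda = lambda, beta = beta)),
    tumour_lambda = c(TC = tumour, IM = 0, N = 0),
    clustering = clustering, seed = seed)
}

test_that("Poisson immune counts match the intensity x area law", {
  cfg <- one_pop_cfg(100)
  set.seed(81)
  counts <- replicate(500, sum(!simulate_roi(cfg, "TC")$cells$
                                 is_tumour_cell))
  # lambda * area = 100 * 0.651 = 65.1
  expect_lt(abs(mean(counts) - 65.1), 4 * sqrt(65.1) / sqrt(500) * 4)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.25) # Poisson-like
})

test_that("full attraction pins the effective score at 1", {
  cfg <- one_pop_cfg(300, beta = 1, tumour = 200)
  set.seed(82)
  sim <- simulate_roi(cfg, "TC")
  im <- as.matrix(sim$cells[!sim$cells$is_tumour_cell,
                            c("x_um", "y_um")])
  tu <- as.matrix(sim$cells[sim$cells$is_tumour_cell,
                            c("x_um", "y_um")])
  es <- effective_score(im, tu, 20)
  expect_gte(es$effective_score, 0.95)
})

test_that("beta = 0 matches the Poisson void-probability closed form", {
  lam_t <- 300 # tumour cells per mm^2
  cfg <- one_pop_cfg(400, beta = 0, tumour = lam_t)
  set.seed(83)
  pooled <- c(0L, 0L)
  for (k in 1:40) {
    sim <- simulate_roi(cfg, "TC")
    im <- as.matrix(sim$cells[!sim$cells$is_tumour_cell,
                              c("x_um", "y_um")])
    tu <- as.matrix(sim$cells[sim$cells$is_tumour_cell,
                              c("x_um", "y_um")])
    es <- effective_score(im, tu, 20)
    pooled <- pooled + c(es$n_paired, es$n_immune)
  }
  want <- 1 - exp(-lam_t * 1e-6 * pi * 20^2)
  expect_lt(abs(pooled[1] / pooled[2] - want), 0.04)
})

test_that("generated marker states recover the generating population", {
  cfg <- simulation_config(n_patients = 1L,
                           rois_per_patient = c(TC = 1L, IM = 0L, N = 0L),
                           seed = 5)
  set.seed(84)
  sim <- simulate_roi(cfg, "TC")
  cells <- sim$cells[!sim$cells$is_tumour_cell, ]
  # each immune cell matches exactly one generating signature
  gen <- phenotype_registry(lapply(cfg$populations, function(p)
    phenotype_rule(p$positive,
                   setdiff(default_panel()$markers, p$positive),
                   name = p$name)))
  hits <- assign_phenotypes(cells, gen)
  expect_true(all(rowSums(hits) == 1))
  # tumour cells carry only PD-L1 (if anything)
  tum <- sim$cells[sim$cells$is_tumour_cell, ]
  other <- setdiff(default_panel()$markers, "PD-L1")
  expect_false(any(as.matrix(tum[, other])))
})

test_that("the pipeline recovers generating density and effective score", {
  # 100 ROIs of one patient: relative error < 10% at lambda >= 50
  cfg <- one_pop_cfg(100, beta = 0, tumour = 400, seed = 7)
  cfg$rois_per_patient <- c(TC = 100L, IM = 0L, N = 0L)
  cfg$n_patients <- 1L
  st <- simulate_cohort(cfg)
  reg <- phenotype_registry(list(phenotype_rule("CD8")))
  dens <- density_table(st$data, reg)
  expect_lt(abs(dens$density / 100 - 1), 0.1)
  spat <- spatial_table(st$data, reg, radii_um = 20)
  want <- 1 - exp(-400e-6 * pi * 400)
  expect_lt(abs(spat$effective_score / want - 1), 0.1)
})

test_that("a full cohort simulation is deterministic and coherent", {
  cfg <- simulation_config(n_patients = 5L,
                           rois_per_patient = c(TC = 2L, IM = 1L, N = 1L),
                           seed = 22)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$data$cells, s2$data$cells)
  expect_identical(s1$clinical, s2$clinical)

  expect_equal(nrow(s1$clinical), 5)
  expect_equal(s1$data$qc$n_rois, 20)
  expect_true(all(s1$clinical$cps >= 0))
  expect_true(all(s1$clinical$os_months > 0))
  expect_equal(s1$clinical$responder, s1$clinical$response %in%
                 c("CR", "PR"))
  # signature realised for every patient
  expect_equal(nrow(s1$signature), 5)
  expect_true(all(s1$signature$complete))
  # cohort split mirrors the 44/60 training fraction
  expect_equal(sum(s1$clinical$cohort == "training"), round(5 * 44 / 60))
})

test_that("planted response coefficients drive label-feature coupling", {
  cfg <- simulation_config(
    n_patients = 40L, rois_per_patient = c(TC = 2L, IM = 0L, N = 0L),
    response_model = list(intercept = 0,
                          coef = c(d_cd4_foxp3neg_pdl1pos = 3,
                                   d_cd8_pd1neg_lag3neg = 0,
                                   d_cd68_stingpos = 0,
                                   es_cd8_pd1pos_lag3neg = 0)),
    seed = 31)
  st <- simulate_cohort(cfg)
  # responders must be enriched in high-CD4 patients
  or_tab <- screen_features(
    st$signature["d_cd4_foxp3neg_pdl1pos"],
    as.numeric(st$clinical$responder))
  expect_gt(or_tab$or, 1)
})
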