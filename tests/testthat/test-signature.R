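# build a small density/spatial table pair by hand
fake_tables <- function(ids, d1, d2, d3, es, radius = 20) {
  sf <- signature_features()
  dens <- do.call(rbind, lapply(1:3, function(i)
    data.frame(patient_id = ids, phenotype = sf$phenotype[i],
               roi_class = "TC", compartment = "all", count = 1,
               area_mm2 = 1, density = list(d1, d2, d3)[[i]],
               stringsAsFactors = FALSE)))
  spat <- data.frame(patient_id = ids, phenotype = sf$phenotype[4],
                     roi_class = "TC", radius_um = radius,
                     n_immune = 10, n_paired = round(10 * es),
                     effective_score = es, stringsAsFactors = FALSE)
  list(dens = dens, spat = spat)
}

test_that("the signature assembles in canonical order", {
  ft <- fake_tables("P1", 5.0, 80.0, 12.0, 0.4)
  sig <- build_signature(ft$dens, ft$spat)
  expect_equal(names(sig), c("patient_id", "d_cd4_foxp3neg_pdl1pos",
                             "d_cd8_pd1neg_lag3neg", "d_cd68_stingpos",
                             "es_cd8_pd1pos_lag3neg", "complete"))
  expect_equal(as.numeric(sig[1, 2:5]), c(5, 80, 12, 0.4))
  expect_true(sig$complete)
})

test_that("the combined signature appends EBV, MMR and CPS", {
  ft <- fake_tables(c("P1", "P2"), c(5, 6), c(80, 70), c(12, 1),
                    c(0.4, 0.2))
  clin <- validate_clinical_table(data.frame(
    patient_id = c("P1", "P2"), ebv = c("pos", "neg"),
    mmr = c("pMMR", "dMMR"), cps = c(15, 2), her2 = "neg",
    response = "PR", os_months = 10, os_event = 1, iros_months = 8,
    iros_event = 1, irpfs_months = 5, irpfs_event = 1,
    cohort = "training", stringsAsFactors = FALSE))
  sig <- build_signature(ft$dens, ft$spat, clinical = clin,
                         combined = TRUE)
  expect_equal(setdiff(names(sig), c("patient_id", "complete")),
               c(signature_features()$feature, "ebv", "mmr", "cps"))
  expect_equal(sig$ebv, c(1, 0))
  expect_equal(sig$mmr, c(0, 1))
  expect_error(build_signature(ft$dens, ft$spat, combined = TRUE),
               "clinical")
})

test_that("missing components propagate and flag the patient", {
  ft <- fake_tables(c("P1", "P2"), c(5, 6), c(80, 70), c(12, 1),
                    c(0.4, NA)) # P2 had zero CD8+PD-1+LAG-3- cells
  sig <- build_signature(ft$dens, ft$spat)
  expect_true(is.na(sig$es_cd8_pd1pos_lag3neg[2]))
  expect_equal(sig$complete, c(TRUE, FALSE))
})

test_that("the prognostic score is the HR-weighted sum", {
  ft <- fake_tables(paste0("P", 1:4), c(1, 0, 2, 1), c(2, 1, 0, 2),
                    c(0, 1, 1, 0), c(1, 0, 0.5, 0.2))
  sig <- build_signature(ft$dens, ft$spat)
  w <- setNames(c(2, 0.5, 1.5, 3), signature_features()$feature)
  ps <- prognostic_score(sig, weights = w)
  # x = (1, 2, 0, 1), HR = (2, 0.5, 1.5, 3) -> 6
  expect_equal(ps$scores$score[1], 6)
  # identity weights reduce to the plain sum
  ones <- setNames(rep(1, 4), signature_features()$feature)
  ps1 <- prognostic_score(sig, weights = ones)
  expect_equal(ps1$scores$score,
               rowSums(sig[, signature_features()$feature]))
  # linearity in the feature vector for fixed weights
  ft2 <- fake_tables(paste0("P", 1:4), 2 * c(1, 0, 2, 1), 2 * c(2, 1, 0, 2),
                     2 * c(0, 1, 1, 0), 2 * c(1, 0, 0.5, 0.2))
  ps2 <- prognostic_score(build_signature(ft2$dens, ft2$spat), weights = w)
  expect_equal(ps2$scores$score, 2 * ps$scores$score)
})

test_that("median split balances groups to within one patient", {
  set.seed(41)
  for (n in c(8, 9, 20)) {
    ft <- fake_tables(sprintf("P%02d", 1:n), runif(n), runif(n), runif(n),
                      runif(n))
    ps <- prognostic_score(build_signature(ft$dens, ft$spat),
                           weights = setNames(rep(1, 4),
                                              signature_features()$feature))
    expect_lte(abs(sum(ps$scores$group == "high") -
                     sum(ps$scores$group == "low")), 1)
  }
})

test_that("fitted weights recover a planted prognostic feature", {
  set.seed(42)
  n <- 200
  ids <- sprintf("P%03d", 1:n)
  x <- matrix(rnorm(n * 4), n, 4)
  ft <- fake_tables(ids, x[, 1], x[, 2], x[, 3], plogis(x[, 4]))
  sig <- build_signature(ft$dens, ft$spat)
  X <- as.matrix(sig[, signature_features()$feature])
  # feature 3 carries true log-HR ln(2); the others are null
  t_ev <- rexp(n, 0.05 * exp(log(2) * X[, 3]))
  cens <- runif(n, 10, 40)
  surv <- data.frame(patient_id = ids, time = pmax(pmin(t_ev, cens), 1e-3),
                     event = as.numeric(t_ev <= cens))
  ps <- prognostic_score(sig, surv)
  w <- ps$weights
  expect_gt(w["d_cd68_stingpos"], max(w[c(1, 2, 4)]))
  # the high-score group must do worse
  idx <- match(ps$scores$patient_id, surv$patient_id)
  lr <- logrank_test(surv$time[idx], surv$event[idx], ps$scores$group)
  expect_lt(lr$p, 0.05)
})

test_that("the weighted score beats single features on concordance", {
  set.seed(43)
  feats <- signature_features()$feature
  concs <- replicate(20, {
    n <- 150
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, feats))
    lp <- 0.5 * X[, 1] + 0.4 * X[, 2] + 0.3 * X[, 3] + 0.4 * X[, 4]
    t_ev <- rexp(n, 0.05 * exp(lp))
    cens <- runif(n, 10, 60)
    time <- pmax(pmin(t_ev, cens), 1e-3); event <- as.numeric(t_ev <= cens)
    w <- exp(vapply(feats, function(f)
      cox_fit(data.frame(time = time, event = event,
                         x = X[, f]), "x")$coef, 0))
    score <- as.numeric(X %*% w)
    conc <- function(v) survival::concordance(
      survival::Surv(time, event) ~ v, reverse = TRUE)$concordance
    c(score = conc(score), vapply(feats, function(f) conc(X[, f]), 0))
  })
  avg <- rowMeans(concs)
  expect_gt(avg["score"], max(avg[-1]))
})
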