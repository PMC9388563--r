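# Shared fixtures built in code: toy cell tables and small panels.

toy_panel <- function() default_panel(c("CD8", "PD-1", "LAG-3", "TIM-3"),
                                      name = "toy-cd8")

# a minimal valid cell table data.frame; markers default to the full panel
toy_cell_df <- function(n = 3, patient = "P1", roi = "P1_TC_1",
                        roi_class = "TC", markers = .toy_markers(),
                        x = seq_len(n) * 10, y = seq_len(n) * 5,
                        tumour = rep(FALSE, n)) {
  df <- data.frame(cell_id = paste0(roi, "_c", seq_len(n)),
                   patient_id = patient, roi_id = roi,
                   roi_class = roi_class, compartment = "stroma",
                   x_um = x, y_um = y, is_tumour_cell = tumour,
                   stringsAsFactors = FALSE)
  for (m in names(markers)) df[[m]] <- rep_len(markers[[m]], n)
  df
}

.toy_markers <- function() {
  ms <- setNames(as.list(rep(FALSE, length(default_panel()$markers))),
                 default_panel()$markers)
  ms$CD8 <- TRUE
  ms
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# random censored survival dataset
random_surv <- function(n, rate = 0.1, cens = 0.05) {
  t_ev <- rexp(n, rate)
  t_c <- rexp(n, cens)
  data.frame(time = pmin(t_ev, t_c), event = as.numeric(t_ev <= t_c))
}

# hand-coded product-limit estimator (oracle, independent of survival pkg)
km_oracle <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    d <- sum(time == tt[i] & event == 1)
    r <- sum(time >= tt[i])
    s <- s * (1 - d / r)
    surv[i] <- s
  }
  list(time = tt, surv = surv)
}

# exact two-sided Mann-Whitney p by full enumeration (oracle)
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  us <- apply(idx, 2, function(i) {
    sum(rank(pooled)[i]) - n * (n + 1) / 2
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
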