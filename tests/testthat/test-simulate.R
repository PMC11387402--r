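test_that("simulation is deterministic given the configuration", {
  cfg <- simulation_config(seed = 17)
  s1 <- simulate_ald_study(cfg)
  s2 <- simulate_ald_study(cfg)
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$hct, s2$hct)
  expect_identical(s1$xci, s2$xci)
  # a different seed changes the data
  s3 <- simulate_ald_study(simulation_config(seed = 18))
  expect_false(identical(s1$abundance, s3$abundance))
  expect_error(simulation_config(seed = 1, nonsense = 2), "Unknown")
})

test_that("planted chain-length effects surface through the pipeline", {
  study <- simulate_ald_study(simulation_config(seed = 3))
  cohort <- study$cohort
  ald <- cohort$sample_id[cohort$group %in% c("CALD", "noCALD")]
  ctrl <- cohort$sample_id[cohort$group == "control"]
  v <- volcano(study$abundance, ald, ctrl, groups = c("ALD", "control"))
  counts <- attr(v, "counts")
  expect_gt(counts[["elevated"]], 20)
  # elevated lipids sit beyond the class hinge (VLCFA region)
  truth <- study$truth
  elev <- v$lipid[v$label == "elevated"]
  hinge <- truth$n[match(elev, truth$lipid)] -
    c(LPC = 20, CE = 20, PC = 40, DG = 40, SM = 40,
      TG = 60)[truth$class_code[match(elev, truth$lipid)]]
  expect_true(all(hinge > 0))
  # CALD separates further from controls than noCALD does
  cald <- cohort$sample_id[cohort$group == "CALD"]
  nocald <- cohort$sample_id[cohort$group == "noCALD"]
  v2 <- compare_lipids(study$abundance, cald, nocald)
  lpc30 <- "LPC(30:0)"
  expect_gt(v2$fc[v2$lipid == lpc30], 1)
})

test_that("planted effect size is recovered within 10%", {
  beta_true <- 0.12
  grid <- tibble::tibble(class_code = "LPC", n = rep(21:40, 2),
                         d = rep(0:1, each = 20), n0 = 20, d_max = 2)
  grid$lipid <- lipid_name(grid$class_code, grid$n, grid$d)
  cfg <- simulation_config(
    seed = 29, lipid_grid = grid, noise_cv = 0.2,
    beta = c(control = 0, noCALD = beta_true, CALD = beta_true)
  )
  groups <- stats::setNames(rep(c("noCALD", "control"), each = 20),
                            c(sprintf("a%02d", 1:20), sprintf("b%02d", 1:20)))
  ab <- simulate_abundance(cfg, groups)
  res <- compare_lipids(ab, names(groups)[1:20], names(groups)[21:40])
  x <- pmax(0, grid$n - 20) * (1 - grid$d / 2)
  beta_hat <- stats::coef(stats::lm(res$log2fc ~ 0 + x))[[1]]
  expect_lt(abs(beta_hat - beta_true) / beta_true, 0.10)
})

test_that("feature-level simulation annotates and quantifies back", {
  grid <- default_lipid_grid()
  grid <- grid[grid$class_code %in% c("LPC", "TG"), ]
  cfg <- simulation_config(seed = 41, lipid_grid = grid,
                           ppm_jitter_sd = 1e-9)
  groups <- stats::setNames(rep(c("CALD", "control"), each = 4),
                            paste0("s", 1:8))
  ab <- simulate_abundance(cfg, groups)
  sim <- simulate_features(cfg, ab)
  hits <- annotate_features(sim$features, sim$catalog, tol_ppm = 5)
  acc <- hits[hits$accepted, ]
  # zero-jitter round trip: every feature recovers its generating species
  expect_identical(acc$name[match(sim$features$feature_id,
                                  acc$feature_id)], ab$lipid)
  # and semi-quantification reproduces the abundances exactly
  ab2 <- semiquantify(sim$features, hits, sim$is_areas,
                      internal_standards())
  expect_equal(as.matrix(ab2[, paste0("s", 1:8)]),
               as.matrix(ab[, paste0("s", 1:8)]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("X-inactivation coupling hits its correlation target", {
  cfg <- simulation_config(seed = 10)
  # no noise: perfectly linear
  x0 <- simulate_xci(cfg, sigma = 0)
  expect_equal(cor(x0$xci_fraction, x0$lpc26), 1)
  # calibrated: mean sample r over replicates near the 0.79 target
  rs <- vapply(1:300, function(i) {
    x <- simulate_xci(cfg, rep_seed = i)
    cor(x$xci_fraction, x$lpc26)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.79), 0.03)
})

test_that("post-transplant decay: plateaus above reference, k recoverable", {
  cfg <- simulation_config(seed = 2)
  s <- simulate_hct(cfg)
  truth <- attr(s, "truth")
  expect_true(all(truth$P > cfg$control_upper_lpc26))
  expect_identical(length(unique(s$patient_id)), 12L)
  fit <- fit_hct_decay(s)
  k_hat <- glance(fit)$k
  expect_lt(abs(k_hat - cfg$hct_k) / cfg$hct_k, 0.15)
  # near-instant decay pins values at the plateau
  fast <- simulation_config(seed = 2, hct_k = 50, hct_k_sdlog = 1e-6,
                            hct_noise_cv = 1e-6)
  sf <- simulate_hct(fast)
  tf <- attr(sf, "truth")
  post <- sf[sf$months > 0, ]
  expect_equal(post$value,
               tf$P[match(post$patient_id, tf$patient_id)],
               tolerance = 1e-3)
})

test_that("synthetic targeted biomarkers reproduce the study couplings", {
  study <- simulate_ald_study(simulation_config(seed = 12))
  t <- study$targeted
  # C26:0 tracks LPC(26:0) with the calibrated rank correlation
  rho <- correlate(t$lpc26, t$c26, "spearman")$estimate
  expect_gt(rho, 0.55); expect_lt(rho, 0.85)
  # patient groups are ordered: CALD > noCALD > control on average
  m <- tapply(t$lpc26, t$group, mean)
  expect_gt(m[["CALD"]], m[["noCALD"]])
  expect_gt(m[["noCALD"]], m[["control"]])
  # healthy controls sit mostly under the upper reference limit
  expect_gt(mean(t$lpc26[t$group == "control"] <= 72), 0.9)
})
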