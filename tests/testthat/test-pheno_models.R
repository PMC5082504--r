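test_that("vial construction applies the 24-h exclusion and assay rules", {
  rec <- data.frame(ril_id = "r1", vial_id = "v1", date = "d1", assay = "dcv",
                    day = c(1, 1, 5, 7))
  v <- build_vial_phenotypes(rec)
  expect_equal(v$value, 6)
  expect_equal(v$n_flies, 2L)

  recs <- data.frame(ril_id = "r1", vial_id = "v1", date = "d1",
                     assay = "sigma", infected = c(rep(1, 14), rep(0, 6)))
  expect_equal(build_vial_phenotypes(recs)$value, 0.7)

  # survivors at the window end enter at the bound, or are dropped on request
  recc <- data.frame(ril_id = "r1", vial_id = "v1", date = "d1", assay = "dcv",
                     day = c(5, NA), censored = c(FALSE, TRUE))
  expect_equal(build_vial_phenotypes(recc)$value, 10)
  expect_equal(build_vial_phenotypes(recc, include_censored = FALSE)$value, 5)

  # a vial losing all flies is dropped with a warning
  rec2 <- data.frame(ril_id = "r1", vial_id = c("v1", "v1", "v2"),
                     date = "d1", assay = "dcv", day = c(1, 1, 8))
  expect_warning(v2 <- build_vial_phenotypes(rec2), "dropped")
  expect_equal(v2$vial_id, "v2")

  expect_error(build_vial_phenotypes(
    data.frame(ril_id = "r", vial_id = "v", date = "d",
               assay = c("dcv", "sigma"), day = 2)), "mix assays")
})

test_that("constant phenotypes give a degenerate baseline fit", {
  v <- data.frame(ril_id = rep(c("a", "b"), each = 3),
                  date = rep(c("d1", "d2", "d3"), 2), value = 4.2)
  fit <- fit_baseline(v)
  expect_equal(fit$beta, 4.2)
  expect_equal(fit$sigma2_ril + fit$sigma2_date + fit$sigma2_resid, 0)
  expect_true(all(ril_blups(fit)$blup == 0))
})

test_that("REML matches balanced-ANOVA method-of-moments closed forms", {
  # 2 dates x 10 RILs x 2 vials, fully crossed and balanced
  set.seed(42)
  n_date <- 2; n_ril <- 10; n_rep <- 1
  d <- expand.grid(date = paste0("d", 1:n_date), ril_id = paste0("r", 1:n_ril))
  dd <- rnorm(n_date, 0, 1)
  rr <- rnorm(n_ril, 0, 3)
  d$value <- 10 + dd[as.integer(factor(d$date))] +
    rr[as.integer(factor(d$ril_id))] + rnorm(nrow(d), 0, 1)
  fit <- fit_baseline(d)

  # method-of-moments from the two-way ANOVA expected mean squares
  y <- matrix(d$value, n_date, n_ril)  # dates x rils
  mse_fit <- anova(lm(value ~ date + ril_id, d))
  ms <- mse_fit$`Mean Sq`
  s2e <- ms[3]
  s2r <- (ms[2] - s2e) / n_date
  s2d <- (ms[1] - s2e) / n_ril
  expect_equal(fit$sigma2_resid, s2e, tolerance = 1e-6)
  expect_equal(fit$sigma2_ril, s2r, tolerance = 1e-6)
  expect_equal(fit$sigma2_date, s2d, tolerance = 1e-6)
  expect_equal(fit$beta, mean(d$value), tolerance = 1e-6)
})

test_that("repeatability arithmetic is exact for all non-negative variances", {
  mk <- function(a, b) structure(list(sigma2_ril = a, sigma2_resid = b,
                                      sigma2_date = 0, fit = NULL),
                                 class = "model_fit")
  set.seed(1)
  for (i in 1:25) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10)
    expect_equal(repeatability(mk(a, b))$R, a / (a + b))
  }
  expect_equal(repeatability(mk(3, 3))$R, 0.5)
  expect_equal(repeatability(mk(2, 0))$R, 1)
  expect_error(repeatability(mk(0, 0)), "undefined")
})

test_that("profile-likelihood intervals usually cover a known repeatability", {
  set.seed(8)
  cover <- logical(10)
  for (i in seq_along(cover)) {
    n_ril <- 120
    u <- rnorm(n_ril, 0, sqrt(3))  # true R = 3 / (3 + 1) = 0.75
    v <- data.frame(ril_id = rep(sprintf("r%03d", 1:n_ril), 2),
                    date = rep(sprintf("d%02d", 1:5), length.out = 2 * n_ril),
                    value = 8 + rep(u, 2) + rnorm(2 * n_ril, 0, 1))
    v$value <- v$value + rnorm(5, 0, 1)[as.integer(factor(v$date))]
    r <- repeatability(fit_baseline(v))
    expect_equal(r$ci_method, "profile")
    expect_true(r$R_ci_95[1] < r$R && r$R < r$R_ci_95[2])
    cover[i] <- r$R_ci_95[1] <= 0.75 && 0.75 <= r$R_ci_95[2]
  }
  expect_gte(sum(cover), 7)
})

test_that("BLUPs match the closed-form shrinkage in a balanced one-way design", {
  set.seed(9)
  k <- 3; n_ril <- 15
  v <- data.frame(ril_id = rep(paste0("r", sprintf("%02d", 1:n_ril)), each = k),
                  date = "d1",
                  value = rep(rnorm(n_ril, 0, 2), each = k) + rnorm(n_ril * k))
  fit <- suppressWarnings(fit_baseline(v))
  lam <- fit$sigma2_ril / (fit$sigma2_ril + fit$sigma2_resid / k)
  ybar <- tapply(v$value, v$ril_id, mean)
  expected <- lam * (ybar - fit$beta)
  bl <- ril_blups(fit)
  expect_equal(bl$blup, as.numeric(expected[bl$ril_id]), tolerance = 1e-8)
  # shrunken deviations sum to ~0
  expect_lt(abs(sum(bl$blup)), 1e-6)
})

test_that("BLUPs are invariant to vial order", {
  cfg <- quick_config(n_ril = 40, seed = 12)
  panel <- simulate_panel(cfg)
  v <- simulate_vials(plant_genetic_values(panel, list()), cfg)
  b1 <- ril_blups(fit_baseline(v))
  set.seed(99)
  v2 <- v[sample.int(nrow(v)), , drop = FALSE]
  b2 <- ril_blups(fit_baseline(v2))
  expect_equal(setNames(b1$blup, b1$ril_id), setNames(b2$blup, b2$ril_id),
               tolerance = 1e-8)
})

test_that("QTL-corrected BLUPs behave as the covariate demands", {
  cfg <- quick_config(n_ril = 60, seed = 13)
  panel <- simulate_panel(cfg)
  v <- simulate_vials(plant_genetic_values(panel, list()), cfg)
  b0 <- ril_blups(fit_baseline(v))

  # a covariate constant across RILs is absorbed by the grand mean
  const <- setNames(rep("res", 60), panel$ril_ids)
  bc <- blups_corrected(v, const)
  expect_equal(setNames(bc$blup, bc$ril_id), setNames(b0$blup, b0$ril_id),
               tolerance = 1e-8)

  # an orthogonal (phenotype-independent) covariate changes BLUPs little
  set.seed(77)
  rnd <- setNames(sample(c("a", "b"), 60, replace = TRUE), panel$ril_ids)
  br <- blups_corrected(v, rnd)
  expect_gt(cor(b0$blup[match(br$ril_id, b0$ril_id)], br$blup), 0.98)

  # missing covariate entries drop those RILs with a warning
  expect_warning(bm <- blups_corrected(v, rnd[1:55]), "dropped")
  expect_equal(nrow(bm), 55)
})

test_that("variance explained is near zero for an orthogonal covariate and
           invariant to order-preserving relabelling", {
  cfg <- quick_config(n_ril = 80, seed = 14)
  panel <- simulate_panel(cfg)
  v <- simulate_vials(plant_genetic_values(panel, list()), cfg)
  set.seed(3)
  rnd <- setNames(sample(c("a", "b"), 80, replace = TRUE), panel$ril_ids)
  ctl <- mcmc_control(3000, 500, 5)
  ve <- variance_explained(v, rnd, ctl, seed = 21)
  expect_lt(abs(ve$proportion), 0.05)
  expect_true(ve$converged)

  v2 <- v
  v2$date <- paste0("batch_", v2$date)
  v2$ril_id <- paste0("line_", v2$ril_id)
  rnd2 <- setNames(rnd, paste0("line_", names(rnd)))
  ve2 <- variance_explained(v2, rnd2, ctl, seed = 21)
  expect_equal(ve$proportion, ve2$proportion)
})

test_that("joint effect model with one QTL matches the marginal REML fit", {
  q <- planted_qtl("2L", 500, split_5v3, effect = 3, id = "q1")
  st <- simulate_study(quick_config(n_ril = 100, qtl = list(q), seed = 15))
  row <- which(st$panel$grid$arm == "2L" & st$panel$grid$pos_kb == 500)
  z <- as.numeric(st$panel$founder_idx[row, ] >= 6)  # true resistant carriers
  rp <- setNames(z, st$panel$ril_ids)

  eff <- effect_sizes_joint(st$vials, list(q1 = rp),
                            mcmc_control(3000, 500, 5), seed = 5,
                            units = "days")
  # the Wald column comes from the marginal REML fit; reproduce it directly
  dat <- st$vials
  dat$rp <- rp[dat$ril_id]
  fit <- lme4::lmer(value ~ rp + (1 | date) + (1 | ril_id), dat, REML = TRUE)
  b <- lme4::fixef(fit)[["rp"]]
  se <- unname(sqrt(diag(as.matrix(vcov(fit))))[2])
  expect_equal(eff$wald_p, 2 * pnorm(-abs(b / se)), tolerance = 1e-8)
  # posterior median close to the REML coefficient, interval covers truth
  expect_lt(abs(eff$effect - b), 4 * se)
  expect_true(eff$ci_lo <= 3 && 3 <= eff$ci_hi)
  expect_equal(eff$units, "days")

  # an added zero-effect covariate covers 0; near-duplicate columns flagged
  set.seed(31)
  z0 <- setNames(runif(100), st$panel$ril_ids)
  eff2 <- effect_sizes_joint(st$vials, list(q1 = rp, null_cov = z0),
                             mcmc_control(3000, 500, 5), seed = 6)
  z0r <- eff2[eff2$qtl_id == "null_cov", ]
  expect_true(z0r$ci_lo <= 0 && 0 <= z0r$ci_hi)
  expect_warning(
    effect_sizes_joint(st$vials, list(q1 = rp, q1b = rp),
                       mcmc_control(500, 100, 2), seed = 7),
    "collinear")
})
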