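test_that("constant BLUPs give zero F and LOD everywhere", {
  set.seed(1)
  P <- random_prob_rows(20, 4)
  y <- setNames(rep(2.5, 20), rownames(P))
  sp <- position_lod(y, P)
  expect_equal(sp$F, 0)
  expect_equal(sp$lod, 0)

  panel <- simulate_panel(quick_config(n_ril = 20, seed = 2))
  sc <- genome_scan(setNames(rep(1, 20), panel$ril_ids), panel)
  expect_true(all(sc$lod == 0))
})

test_that("position LOD equals the normal-equations oracle on random instances", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    k <- sample(2:4, 1)
    P <- random_prob_rows(n, k)
    y <- setNames(rnorm(n), rownames(P))
    got <- position_lod(y, P)
    expect_equal(got$lod, oracle_lod(y, P), tolerance = 1e-9)
    # df reflects the k active founders (+intercept absorbs one)
    expect_equal(got$df_num, k - 1)
  }
})

test_that("LOD is invariant to affine transforms of the BLUPs", {
  set.seed(4)
  panel <- simulate_panel(quick_config(n_ril = 50, seed = 4))
  y <- setNames(rnorm(50), panel$ril_ids)
  s1 <- genome_scan(y, panel)
  s2 <- genome_scan(-3.7 * y + 11, panel)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-9)
  expect_equal(s1$F, s2$F, tolerance = 1e-9)
})

test_that("scan results do not depend on RIL ordering", {
  panel <- simulate_panel(quick_config(n_ril = 40, seed = 6))
  set.seed(10)
  y <- setNames(rnorm(40), panel$ril_ids)
  s1 <- genome_scan(y, panel)
  s2 <- genome_scan(y[sample.int(40)], panel)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-12)
})

test_that("a planted founder signal is localized to within two grid steps", {
  panel <- simulate_panel(quick_config(n_ril = 150, n_pairs = 300, seed = 16))
  target <- 57  # grid row of the planted signal
  set.seed(8)
  y <- prob_rows(panel, target)[, 1] + rnorm(150, 0, 0.1)
  sc <- genome_scan(setNames(y, panel$ril_ids), panel)
  pk <- scan_peak(sc)
  expect_equal(pk$arm, panel$grid$arm[target])
  expect_lte(abs(pk$pos_kb - panel$grid$pos_kb[target]), 20)
})

test_that("permutation null is reproducible and threshold/p-value follow the
           order-statistic conventions", {
  panel <- simulate_panel(quick_config(n_ril = 30, seed = 18))
  y <- setNames(rnorm(30), panel$ril_ids)
  n1 <- permutation_null(y, panel, n_perm = 25, seed = 42)
  n2 <- permutation_null(y, panel, n_perm = 25, seed = 42)
  expect_identical(n1$max_lod, n2$max_lod)
  expect_length(n1$max_lod, 25)
  expect_true(all(n1$max_lod >= 0))

  null <- structure(list(n_perm = 100, max_lod = as.numeric(1:100), seed = 1),
                    class = "permutation_null")
  expect_equal(genomewide_threshold(null, 0.05), 96)
  expect_equal(genomewide_threshold(null, 1), 1)
  expect_error(genomewide_threshold(null, 0.001), "resolution")
  # monotone decreasing in alpha
  set.seed(5)
  rnd <- structure(list(n_perm = 200, max_lod = rexp(200), seed = 1),
                   class = "permutation_null")
  alphas <- c(0.01, 0.05, 0.1, 0.5, 1)
  thr <- vapply(alphas, function(a) genomewide_threshold(rnd, a), numeric(1))
  expect_true(all(diff(thr) <= 0))

  expect_equal(genomewide_pvalue(null, 1000), 1 / 101)
  expect_equal(genomewide_pvalue(null, 0), 1)
  obs <- c(0, 5, 50, 500)
  ps <- vapply(obs, function(o) genomewide_pvalue(null, o), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("null maximum LOD grows stochastically with the number of positions", {
  panel <- simulate_panel(sim_config(
    n_ril = 60, grid = genome_grid(tiny_arms(1, len_kb = 10000, len_cM = 50), 10),
    n_pairs = 120, seed = 20))
  y <- setNames(rnorm(60), panel$ril_ids)
  n_small <- permutation_null(y, panel, 200, seed = 1, rows = seq_len(100))
  n_large <- permutation_null(y, panel, 200, seed = 1, rows = seq_len(1000))
  expect_gt(mean(n_large$max_lod), mean(n_small$max_lod))
})

test_that("interval logic matches closed forms on constructed profiles", {
  # delta-like profile: both intervals collapse to the single grid step
  pos <- seq(10, 500, by = 10)
  lod <- rep(0, length(pos))
  lod[25] <- 10
  iv <- mprqtl:::interval_from_profile(pos, lod, 0.95, 2)
  expect_equal(iv$bayes_ci, c(pos[25], pos[25]))
  expect_equal(iv$lod_drop_ci, c(pos[25], pos[25]))

  # exact quadratic profile: LOD-drop endpoints at x0 +- sqrt(drop/c)
  x0 <- 250; cc <- 0.001; L <- 8
  lodq <- L - cc * (pos - x0)^2
  ivq <- mprqtl:::interval_from_profile(pos, lodq, 0.95, 2)
  expect_equal(ivq$peak_kb, x0)
  half <- sqrt(2 / cc)
  expect_lte(abs(ivq$lod_drop_ci[1] - (x0 - half)), 10)
  expect_lte(abs(ivq$lod_drop_ci[2] - (x0 + half)), 10)
})

test_that("refined intervals bracket a planted QTL peak", {
  q <- planted_qtl("2L", 500, split_5v3, effect = 5, id = "q1")
  st <- simulate_study(quick_config(n_ril = 150, n_pairs = 300,
                                    qtl = list(q), seed = 22))
  bl <- ril_blups(fit_baseline(st$vials))
  iv <- refine_interval(bl, st$panel, "2L", window = c(200, 800))
  expect_lte(abs(iv$peak_kb - 500), 20)
  expect_true(iv$bayes_ci[1] <= iv$peak_kb && iv$peak_kb <= iv$bayes_ci[2])
  expect_true(iv$lod_drop_ci[1] <= iv$peak_kb &&
              iv$peak_kb <= iv$lod_drop_ci[2])
  expect_warning(refine_interval(bl, st$panel, "2L", window = c(500, 800)),
                 "edge")
})

test_that("covariate scans measure a position's increment over the covariate", {
  q1 <- planted_qtl("2L", 500, split_5v3, effect = 6, id = "q1")
  q2 <- planted_qtl("2R", 700, c(rep("resistant", 4), rep("susceptible", 4)),
                    effect = 1.5, id = "q2")
  st <- simulate_study(quick_config(n_ril = 250, n_pairs = 400,
                                    qtl = list(q1, q2), seed = 23))
  bl <- ril_blups(fit_baseline(st$vials))
  row1 <- which(st$panel$grid$arm == "2L" & st$panel$grid$pos_kb == 500)
  rp1 <- setNames(as.numeric(st$panel$founder_idx[row1, ] >= 6),
                  st$panel$ril_ids)
  sc <- genome_scan(bl, st$panel, covariate = rp1)
  pk <- scan_peak(sc)
  expect_equal(pk$arm, "2R")
  expect_lte(abs(pk$pos_kb - 700), 20)
  # the covariate's own position no longer dominates
  expect_lt(sc$lod[row1], pk$lod)
})
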