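test_that("TE = NDE + NIE identically and NIE matches the product oracle", {
  b <- small_bundle(seed = 81, n_families = 200, n_probes = 120)
  sp <- mediation_spec("alcohol_g_d", "cg06690548")
  r <- estimate_mediation(b, sp)
  expect_equal(r$te, r$nde + r$nie, tolerance = 1e-12)
  # independent regression fits as the product-of-coefficients oracle
  fr <- epimediate:::mediation_frame(b, sp)
  a1 <- coef(lm(fr$M ~ fr$A + fr$C))[2]
  t2 <- coef(lm(fr$Y ~ fr$A + fr$M + fr$C))[3]
  expect_equal(r$nie,
               unname(a1 * t2 * (r$contrast["a"] - r$contrast["a_star"])),
               tolerance = 1e-10)
  t1 <- coef(lm(fr$Y ~ fr$A + fr$M + fr$C))[2]
  expect_equal(r$nde,
               unname(t1 * (r$contrast["a"] - r$contrast["a_star"])),
               tolerance = 1e-10)
})

test_that("swapping the contrast negates all three effects", {
  b <- small_bundle(seed = 82, n_families = 150, n_probes = 100)
  sp1 <- mediation_spec("alcohol_g_d", "cg06690548", contrast = c(5, 20))
  sp2 <- mediation_spec("alcohol_g_d", "cg06690548", contrast = c(20, 5))
  r1 <- estimate_mediation(b, sp1)
  r2 <- estimate_mediation(b, sp2)
  expect_equal(r1$te, -r2$te, tolerance = 1e-12)
  expect_equal(r1$nde, -r2$nde, tolerance = 1e-12)
  expect_equal(r1$nie, -r2$nie, tolerance = 1e-12)
})

test_that("rescaling the exposure with a rescaled contrast leaves effects unchanged", {
  b <- small_bundle(seed = 83, n_families = 150, n_probes = 100)
  r1 <- estimate_mediation(b, mediation_spec("alcohol_g_d", "cg06690548",
                                             contrast = c(0, 10)))
  # grams/day -> percent energy at fixed 2000 kcal: x7/20 rescale
  b2 <- b
  for (ex in names(b2$exposures))
    b2$exposures[[ex]][, "alcohol_g_d"] <-
      b2$exposures[[ex]][, "alcohol_g_d"] * 7 / 20
  r2 <- estimate_mediation(b2, mediation_spec("alcohol_g_d", "cg06690548",
                                              contrast = c(0, 10 * 7 / 20)))
  expect_equal(r1$nie, r2$nie, tolerance = 1e-8)
  expect_equal(r1$nde, r2$nde, tolerance = 1e-8)
})

test_that("bootstrap is deterministic under a seed and stable in n_boot", {
  b <- small_bundle(seed = 84, n_families = 120, n_probes = 80)
  sp <- mediation_spec("alcohol_g_d", "cg06690548")
  r1 <- bootstrap_mediation(b, sp, n_boot = 200, seed = 7)
  r2 <- bootstrap_mediation(b, sp, n_boot = 200, seed = 7)
  expect_identical(r1$ci_nie, r2$ci_nie)
  expect_identical(r1$boot, r2$boot)
  r4 <- bootstrap_mediation(b, sp, n_boot = 400, seed = 8)
  # doubling replicates moves percentile endpoints by < the Monte-Carlo SE
  mc_se <- sd(r1$boot[, "nie"]) * 3 / sqrt(200)
  expect_lt(abs(r1$ci_nie[1] - r4$ci_nie[1]), 4 * mc_se)
  expect_lt(abs(r1$ci_nie[2] - r4$ci_nie[2]), 4 * mc_se)
  expect_true(r1$ci_nie[1] <= r1$nie && r1$nie <= r1$ci_nie[2])
})

test_that("cluster bootstrap over singleton families equals iid bootstrap", {
  b <- small_bundle(seed = 85, n_families = 100, n_probes = 80,
                    family_size = c(min = 0, max = 0))  # founders only
  sp <- mediation_spec("alcohol_g_d", "cg06690548")
  fr <- epimediate:::mediation_frame(b, sp)
  # families of size 2 here (two founders); rebuild with per-sample families
  b$phenotypes$fam <- b$phenotypes$sample_id
  r <- suppressWarnings(bootstrap_mediation(b, sp, n_boot = 50, seed = 11))
  # manual iid bootstrap under the same seed policy
  fr <- epimediate:::mediation_frame(b, sp)
  a <- r$contrast["a"]; a_star <- r$contrast["a_star"]
  set.seed(11L)
  manual <- t(vapply(seq_len(50), function(i) {
    idx <- sample.int(length(fr$A), replace = TRUE)
    epimediate:::med_point(fr$A[idx], fr$M[idx], fr$Y[idx],
                           fr$C[idx, , drop = FALSE], FALSE, a, a_star,
                           colMeans(fr$C))[1:3]
  }, c(te = 0, nde = 0, nie = 0)))
  expect_equal(unname(r$boot[, "nie"]), unname(manual[, "nie"]),
               tolerance = 1e-12)
})

test_that("a null mediator keeps NIE near zero with covering intervals", {
  hits <- 0
  for (seed in 1:12) {
    cfg <- sim_config(n_families = 150, n_probes = 60, mediators = NULL,
                      n_mediator_probes = 2, alpha1 = 0, theta2 = -0.5,
                      seed = 900 + seed)
    b <- add_cell_pcs(suppressMessages(simulate_cohort(cfg)))
    r <- bootstrap_mediation(b, mediation_spec("alcohol_g_d", "cgSIM00001"),
                             n_boot = 150, seed = seed)
    if (r$ci_nie[1] <= 0 && 0 <= r$ci_nie[2]) hits <- hits + 1
  }
  expect_gte(hits, 10)  # ~95% coverage of zero, allow Monte-Carlo slack
})

test_that("interaction test has power when planted and flags constant mediators", {
  cfg <- sim_config(n_families = 500, n_probes = 60, theta3 = 0.15,
                    seed = 86)
  b <- add_cell_pcs(suppressMessages(simulate_cohort(cfg)))
  p <- interaction_test(b, mediation_spec("alcohol_g_d", "cg06690548"))
  expect_lt(p, 0.001)
  # constant mediator
  b$methylation[, "cg03725309"] <- 0.5
  p2 <- interaction_test(b, mediation_spec("alcohol_g_d", "cg03725309"))
  expect_true(is.na(p2))
  expect_equal(attr(p2, "note"), "untestable")
})

test_that("the interaction p-value is well calibrated under theta3 = 0", {
  ps <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_families = 120, n_probes = 50, seed = 700 + seed)
    b <- add_cell_pcs(suppressMessages(simulate_cohort(cfg)))
    interaction_test(b, mediation_spec("alcohol_g_d", "cg06690548"))
  }, numeric(1))
  # crude uniformity check: no mass collapse at either end
  expect_gt(mean(ps > 0.05), 0.5)
  expect_lt(min(ps), 0.9)
})

test_that("grid mediation recovers opposite alcohol/carbohydrate NIE signs", {
  b <- small_bundle(seed = 87, n_families = 500, n_probes = 300)
  g <- mediation_grid(b, c("alcohol_g_d", "carb_pct_energy"),
                      mediators = c("cg06690548", "cg14476101"),
                      n_boot = 150, seed = 87,
                      mutual_adjustment = c(alcohol_g_d = "carb_pct_energy",
                                            carb_pct_energy = "alcohol_g_d"))
  nie_alc <- g$nie[g$exposure == "alcohol_g_d"]
  nie_carb <- g$nie[g$exposure == "carb_pct_energy"]
  expect_true(all(nie_alc > 0))   # hypomethylation -> higher TG
  expect_true(all(nie_carb < 0))  # opposite planted direction
  expect_true(all(g$p_interaction > 1e-4))  # no planted interaction
})

test_that("mutual adjustment leaves independently planted effects significant", {
  b <- small_bundle(seed = 88, n_families = 500, n_probes = 300)
  plain <- mediation_grid(b, "alcohol_g_d", "cg06690548",
                          n_boot = 150, seed = 88)
  adj <- mediation_grid(b, "alcohol_g_d", "cg06690548",
                        n_boot = 150, seed = 88,
                        mutual_adjustment = c(alcohol_g_d = "carb_pct_energy"))
  expect_true(plain$significant && adj$significant)
  expect_equal(plain$nie, adj$nie, tolerance = 0.3)
})

test_that("drink-type exposures run through the same machinery", {
  b <- small_bundle(seed = 89, n_families = 200, n_probes = 100)
  g <- mediation_grid(b, "beer_serv_wk", "cg06690548", n_boot = 120,
                      seed = 89)
  expect_equal(nrow(g), 1)
  expect_true(is.finite(g$nie))
  expect_error(mediation_grid(b, "mead_serv_wk", "cg06690548",
                              n_boot = 120, seed = 89), "unknown exposure")
})

test_that("mediation preconditions are enforced", {
  b <- small_bundle(seed = 90, n_families = 100, n_probes = 60)
  expect_error(mediation_spec("alcohol_g_d", "alcohol_g_d"), "differ")
  expect_error(mediation_spec("alcohol_g_d", "cg1", contrast = c(2, 2)),
               "differ")
  sp <- mediation_spec("alcohol_g_d", "cg06690548")
  b$phenotypes$lipid_med <- 1L  # nobody left off medication
  expect_error(estimate_mediation(b, sp), "30 complete cases")
})
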