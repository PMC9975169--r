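test_that("Bonferroni thresholds reproduce the standard reported values", {
  thr <- bonferroni_threshold(0.05, 170)
  expect_equal(as.numeric(thr), 0.05 / 170)
  expect_equal(attr(thr, "display"), 3e-4)
  thr <- bonferroni_threshold(0.05, 11)
  expect_equal(as.numeric(thr), 0.004545455, tolerance = 1e-6)
  expect_equal(attr(thr, "display"), 0.0045)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("meff equals M for independent variables and 1 for collinear pairs", {
  set.seed(61)
  # exactly independent: orthogonalized columns
  X <- qr.Q(qr(matrix(rnorm(400 * 20), 400, 20)))
  me <- effective_tests(X)
  expect_equal(me$meff, 20, tolerance = 1e-10)
  # perfectly collinear pair
  x <- rnorm(100)
  me2 <- effective_tests(cbind(x, 2 * x + 1))
  expect_equal(me2$meff, 1, tolerance = 1e-10)
})

test_that("meff matches the independent eigen-oracle on random panels", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 500
    X <- matrix(rnorm(n * 50), n, 50)
    X[, 1:10] <- X[, 1:10] + rnorm(n) * 1.5  # correlated block
    me <- effective_tests(X)
    expect_equal(me$meff, oracle_meff(X), tolerance = 1e-8)
    expect_equal(sum(me$eigenvalues), 50, tolerance = 1e-6)
  }
})

test_that("meff matches the closed form for equicorrelated variables", {
  rho <- 0.35; M <- 12
  C <- matrix(rho, M, M); diag(C) <- 1
  lam <- c(1 + (M - 1) * rho, rep(1 - rho, M - 1))
  expected <- sum(ifelse(lam >= 1, 1, 0) + lam - floor(lam))
  # feed data with exactly this correlation via its Cholesky square root
  X <- chol(C)  # rows give a small sample with exact correlation structure
  set.seed(62)
  Z <- matrix(rnorm(4000 * M), 4000, M) %*% chol(C)
  me <- effective_tests(Z)
  expect_equal(me$meff, expected, tolerance = 0.02)
})

test_that("meff is invariant to variable order and scale", {
  set.seed(63)
  X <- matrix(rnorm(300 * 15), 300, 15)
  X[, 1:5] <- X[, 1:5] + rnorm(300)
  m1 <- effective_tests(X)$meff
  m2 <- effective_tests(X[, sample(15)])$meff
  m3 <- effective_tests(sweep(X, 2, runif(15, 0.1, 10), `*`))$meff
  expect_equal(m1, m2, tolerance = 1e-10)
  expect_equal(m1, m3, tolerance = 1e-10)
})

test_that("raising a block's internal correlation never raises meff", {
  set.seed(64)
  n <- 2000; M <- 20
  meffs <- vapply(c(0.1, 0.4, 0.7, 0.9), function(rho) {
    C <- diag(M)
    C[1:10, 1:10] <- rho; diag(C) <- 1
    Z <- matrix(rnorm(n * M), n, M) %*% chol(C)
    effective_tests(Z)$meff
  }, numeric(1))
  expect_true(all(diff(meffs) < 0))
})

test_that("zero-variance variables are excluded with a warning", {
  set.seed(65)
  X <- cbind(matrix(rnorm(200), 100, 2), flat = rep(3, 100))
  expect_warning(me <- effective_tests(X), "zero-variance")
  expect_equal(me$n_variables, 2L)
})

test_that("uncorrelated significant probes all represent themselves", {
  set.seed(66)
  m <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("cg", 1:5)))
  summ <- list(significant_probes = colnames(m),
               results = data.frame(predictor_id = colnames(m),
                                    p = c(1e-9, 2e-9, 3e-9, 4e-9, 5e-9)))
  reps <- select_representative_loci(summ, m, r_threshold = 0.8)
  expect_setequal(reps, colnames(m))
})

test_that("a tight correlation cluster is represented by its lowest p probe", {
  set.seed(67)
  base <- rnorm(500)
  m <- cbind(a = base + rnorm(500, 0, 0.1),
             b = base + rnorm(500, 0, 0.1),
             c = base + rnorm(500, 0, 0.1))
  summ <- list(significant_probes = c("a", "b", "c"),
               results = data.frame(predictor_id = c("a", "b", "c"),
                                    p = c(1e-8, 1e-10, 1e-9)))
  reps <- select_representative_loci(summ, m, r_threshold = 0.8)
  expect_identical(as.character(reps), "b")
})

test_that("28 probes in 19 correlation blocks give exactly 19 representatives", {
  # constructed fixture: block sizes summing to 28 across 19 clusters
  sizes <- c(rep(2, 9), rep(1, 10))  # 9 pairs + 10 singletons = 28 probes
  stopifnot(sum(sizes) == 28, length(sizes) == 19)
  set.seed(68)
  n <- 400
  cols <- list()
  for (k in seq_along(sizes)) {
    shared <- rnorm(n)
    for (j in seq_len(sizes[k]))
      cols[[length(cols) + 1]] <- shared + rnorm(n, 0, 0.15)
  }
  m <- do.call(cbind, cols)
  colnames(m) <- sprintf("cg%07d", seq_len(28))
  summ <- list(significant_probes = colnames(m),
               results = data.frame(predictor_id = colnames(m),
                                    p = 10^-runif(28, 8, 20)))
  reps <- select_representative_loci(summ, m, r_threshold = 0.8)
  expect_length(reps, 19)
  cl <- attr(reps, "clusters")
  expect_equal(length(unique(cl)), 19)
})

test_that("run_ewas detects a planted probe and treats duplicates equally", {
  b <- small_bundle(seed = 69, n_families = 250, n_probes = 200)
  # duplicate the strongest mediator probe under a new name
  b$methylation <- cbind(b$methylation,
                         cgDUP0001 = b$methylation[, "cg00574958"])
  b$annotation <- rbind(b$annotation,
                        data.frame(probe_id = "cgDUP0001", chromosome = "11",
                                   position = 68607623L, gene = "CPT1A",
                                   genic_region = "5UTR",
                                   cpg_relation = "N_Shore"))
  ew <- run_ewas(b, analysis_set = "All", threshold = 1e-4)
  r <- ew$results
  expect_equal(r$p[r$predictor_id == "cg00574958"],
               r$p[r$predictor_id == "cgDUP0001"], tolerance = 1e-10)
  expect_true("cg00574958" %in% ew$significant_probes)
  beta <- r$beta[r$predictor_id == "cg00574958"]
  expect_lt(beta, 0)  # planted effect is negative
  expect_error(run_ewas(b, threshold = 2), "threshold")
})

test_that("count_and_rank matches a brute-force tally and dedupes pairs", {
  grid <- list(grid = data.frame(
    response_id = c("d1", "d1", "d2"),
    predictor_id = c("alcohol", "alcohol", "carb"),
    exam = c("exam7", "exam8", "exam8"),
    analysis_set = "All",
    p = c(1e-5, 1e-6, 0.5),
    significant = c(TRUE, TRUE, FALSE)))
  out <- count_and_rank(grid)
  expect_equal(sum(out$totals$total), 2)
  expect_equal(out$unique_pairs$unique_pairs, 1)
  expect_equal(out$ranking$n_associations[out$ranking$predictor_id == "alcohol"], 2)
  # empty grid
  grid$grid$significant <- FALSE
  out0 <- count_and_rank(grid)
  expect_equal(sum(out0$totals$total), 0)
  expect_equal(nrow(out0$unique_pairs), 0)
})

test_that("map_exposures books the NoLipidMed sample size correctly", {
  b <- small_bundle(seed = 70, n_families = 100, n_probes = 60)
  g <- map_exposures(b, dms_list = colnames(b$methylation)[1],
                     exposure_vars = c("alcohol_g_d", "carb_pct_energy"),
                     analysis_sets = "NoLipidMed", exams = "exam8")
  expect_true(all(g$grid$n == sum(b$phenotypes$lipid_med == 0)))
  expect_warning(
    map_exposures(b, colnames(b$methylation)[1], exams = c("exam8", "exam9"),
                  exposure_vars = "alcohol_g_d",
                  analysis_sets = "NoLipidMed"),
    "exam9")
})

test_that("planted longitudinal alcohol effect is significant at every exam", {
  b <- small_bundle(seed = 71, n_families = 400, n_probes = 250)
  g <- map_exposures(b, dms_list = "cg06690548",
                     analysis_sets = "All")
  cells <- g$grid[g$grid$predictor_id == "alcohol_g_d", ]
  expect_equal(nrow(cells), 4)
  # methylation is measured at the reference exam; persistence rho = 0.8
  # keeps earlier-exam alcohol associated with it
  expect_true(all(cells$significant))
  expect_true(all(cells$beta < 0))
})

test_that("expression association recovers deterministic linkage", {
  b <- small_bundle(seed = 72, n_families = 80, n_probes = 60)
  ids <- b$phenotypes$sample_id[b$phenotypes$lipid_med == 0]
  b$expression <- cbind(TESTGENE = -b$methylation[ids, "cg06690548"])
  rownames(b$expression) <- ids
  r <- dms_expression_assoc(b, "cg06690548", "TESTGENE")
  expect_equal(r$beta, -1, tolerance = 1e-6)
  expect_lt(r$p, 1e-100)
  expect_error(dms_expression_assoc(b, "cg06690548", "NOPE"), "not found")
})

test_that("planted negative expression coupling is recovered in sign", {
  cfg <- sim_config(n_families = 200, n_probes = 100, seed = 73)
  b <- suppressMessages(simulate_cohort(cfg, expression = TRUE))
  b <- add_cell_pcs(b)
  coup <- attr(b$expression, "coupling")
  tr <- names(coup)[coup < 0][1:3]
  for (t in tr) {
    probe <- sub(".*_(cg.*)$", "\\1", t)
    r <- dms_expression_assoc(b, probe, t)
    expect_lt(r$beta, 0)
  }
})
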