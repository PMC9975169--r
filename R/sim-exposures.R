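#' Generate a longitudinal block-correlated exposure panel
#'
#' Latent standard-normal scores are drawn with equicorrelated blocks
#' (within-block correlation `exposure_block_rho`) and propagated across
#' exams by a stationary AR(1) with coefficient `exam_autocorrelation`, so
#' the cross-sectional correlation structure is identical at every exam.
#' Named dietary/lifestyle variables are deterministic transforms of their
#' latent score: alcohol (g/day) is zero-inflated gamma with a point mass at
#' zero, drink types (servings/week) are zero-inflated gamma, carbohydrate
#' (% energy) is a clamped linear transform, total energy is lognormal,
#' smoking is mostly zero, and remaining variables stay on the latent
#' z-score scale.
#'
#' @param ped pedigree from [generate_pedigree()] (defines the samples)
#' @param cfg a [sim_config()] object
#' @return an `exposure_panel`: named list (one data.frame per exam, rows =
#'   samples) with attributes `exams`, `sample_id`, and `categories`
#' @export
generate_exposures <- function(ped, cfg) {
  n <- nrow(ped)
  p <- cfg$n_exposures
  rho <- cfg$exposure_block_rho
  phi <- cfg$exam_autocorrelation
  blocks <- block_assignment(cfg$exposure_block_sizes, p)

  draw_panel <- function() {
    # equicorrelated blocks: z = sqrt(rho) * shared + sqrt(1-rho) * unique
    z <- matrix(rnorm(n * p), n, p)
    if (rho > 0) {
      for (b in unique(blocks[blocks > 0])) {
        cols <- which(blocks == b)
        shared <- rnorm(n)
        z[, cols] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, cols]
      }
    }
    z
  }

  labs <- exam_labels(cfg$n_exams)
  latents <- vector("list", cfg$n_exams)
  latents[[1]] <- draw_panel()
  for (t in seq_len(cfg$n_exams)[-1]) {
    innov <- draw_panel()
    latents[[t]] <- phi * latents[[t - 1]] +
      if (phi < 1) sqrt(1 - phi^2) * innov else 0
  }

  nm <- exposure_names(p)
  panel <- lapply(latents, function(z) {
    d <- as.data.frame(transform_latents(z, nm, cfg))
    rownames(d) <- ped$id
    d
  })
  names(panel) <- labs
  structure(panel,
            exams = labs,
            sample_id = ped$id,
            categories = exposure_categories(nm),
            class = "exposure_panel")
}

# The first ten panel columns are named variables with a fixed, realistic
# correlation layout: alcohol and the four drink types form one block,
# carbohydrate and total sugar another; total energy, smoking and physical
# activity are independent. `sizes` lays out equicorrelated blocks over the
# remaining generic variables.
block_assignment <- function(sizes, p) {
  b <- integer(p)  # 0 = unblocked (independent)
  b[1:5] <- 1L     # alcohol + drink types
  b[6:7] <- 2L     # carbohydrate + total sugar
  i <- 11L
  for (k in seq_along(sizes)) {
    b[i:(i + sizes[k] - 1L)] <- k + 2L
    i <- i + sizes[k]
  }
  b
}

# first variables of the panel are named dietary/lifestyle measures; the
# drink types share the alcohol block so that drink-type mediation runs see
# realistically correlated exposures
exposure_names <- function(p) {
  named <- c("alcohol_g_d", "beer_serv_wk", "redwine_serv_wk",
             "whitewine_serv_wk", "liquor_serv_wk",
             "carb_pct_energy", "total_sugar_g_d",
             "total_energy_kcal", "smoking_cig_d", "phys_activity")
  if (p < length(named)) stop("n_exposures too small for named variables")
  c(named, sprintf("expo_%03d", seq_len(p - length(named))))
}

exposure_categories <- function(nm) {
  cat <- rep("nutrient", length(nm))
  cat[grepl("serv_wk$", nm)] <- "food_item"
  cat[nm %in% c("smoking_cig_d", "phys_activity")] <- "lifestyle"
  cat[nm == "total_energy_kcal"] <- "energy"
  cat[grepl("^expo_", nm)] <- rep_len(c("nutrient", "food_item",
                                        "food_group"), sum(grepl("^expo_", nm)))
  setNames(cat, nm)
}

# map latent z-scores to observed exposure scales; deterministic in z so
# the AR(1) persistence carries through to the observed variables
transform_latents <- function(z, nm, cfg) {
  colnames(z) <- nm
  u <- pnorm(z)
  zi_gamma <- function(uu, p0, shape, scale) {
    out <- numeric(length(uu))
    pos <- uu >= p0
    out[pos] <- qgamma((uu[pos] - p0) / (1 - p0), shape = shape,
                       scale = scale)
    out
  }
  z[, "alcohol_g_d"] <- zi_gamma(u[, "alcohol_g_d"], cfg$alcohol_zero_prob,
                                 shape = 1.2, scale = 12)
  for (v in c("beer_serv_wk", "redwine_serv_wk", "whitewine_serv_wk",
              "liquor_serv_wk"))
    z[, v] <- zi_gamma(u[, v], 0.5, shape = 1, scale = 3)
  z[, "carb_pct_energy"] <- clamp(50 + 7 * z[, "carb_pct_energy"], 1, 99)
  z[, "total_sugar_g_d"] <- zi_gamma(u[, "total_sugar_g_d"], 0, 4, 25)
  z[, "total_energy_kcal"] <- exp(log(2000) + 0.22 * z[, "total_energy_kcal"])
  z[, "smoking_cig_d"] <- zi_gamma(u[, "smoking_cig_d"], 0.8, 1.5, 8)
  z[, "phys_activity"] <- 30 + 5 * z[, "phys_activity"]
  z
}
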