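# Synthetic-cohort generator: a single latent frailty factor plus per-pair
# shared residuals (a Gaussian copula with one-factor structure). Binary
# items fire when their latent crosses the normal quantile matching the
# target prevalence; ordinal items use two quantile thresholds. This is
# the simplest structure that can reproduce at once (a) the published item
# prevalences, (b) the near-duplicate cross-scale item pairs correlating
# far above their row-mates, and (c) a high total-score correlation.

#' Latent threshold matching a target prevalence
#'
#' Returns the threshold tau such that a standard-normal latent exceeds
#' tau with probability `p`: tau = qnorm(1 - p).
#'
#' @param p Prevalence in (0, 1).
#' @return Numeric threshold.
#' @export
calibrate_threshold <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("prevalence must be in (0, 1)", call. = FALSE)
  stats::qnorm(1 - p)
}

new_sim_item <- function(name, scale, type, loading, prevalence = NULL,
                         probs = NULL) {
  list(name = name, scale = scale, type = type, loading = loading,
       prevalence = prevalence, probs = probs)
}

#' Build a simulation specification
#'
#' @param n Cohort size.
#' @param seed Integer seed; equal specs generate byte-identical cohorts.
#' @param items List of item definitions (`name`, `scale` = `"zfs"` or
#'   `"msega"`, `type` = `"binary"` or `"ordinal3"`, `loading` on the
#'   latent frailty factor, and `prevalence` or `probs`).
#' @param twin_pairs List of `list(zfs=, msega=, rho=)` residual couplings
#'   between near-duplicate items on the two scales.
#' @param demographics Named list of `c(mean, sd)` pairs for numeric
#'   fields, plus `p_female` and `age_loading`.
#' @return Validated list of class `sim_spec`.
#' @export
sim_spec <- function(n, seed, items, twin_pairs = list(),
                     demographics = list()) {
  spec <- structure(list(n = as.integer(n), seed = as.integer(seed),
                         items = items, twin_pairs = twin_pairs,
                         demographics = demographics),
                    class = "sim_spec")
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.na(spec$n) || spec$n < 1) stop("cohort size must be >= 1", call. = FALSE)
  if (is.na(spec$seed)) stop("seed must be an integer", call. = FALSE)
  item_names <- vapply(spec$items, `[[`, character(1), "name")
  if (anyDuplicated(item_names)) stop("duplicate item names", call. = FALSE)
  rho_by_item <- stats::setNames(numeric(length(item_names)), item_names)
  for (pair in spec$twin_pairs) {
    for (member in c(pair$zfs, pair$msega)) {
      if (!member %in% item_names) {
        stop("twin pair references unknown item: ", member, call. = FALSE)
      }
      rho_by_item[member] <- rho_by_item[member] + pair$rho^2
    }
    if (pair$rho < 0 || pair$rho >= 1) {
      stop("twin coupling rho must be in [0, 1)", call. = FALSE)
    }
  }
  for (item in spec$items) {
    if (item$loading < 0 || item$loading >= 1) {
      stop("loading for '", item$name, "' must be in [0, 1)", call. = FALSE)
    }
    if (item$loading^2 + rho_by_item[item$name] >= 1) {
      stop("loading^2 + sum(rho^2) must be < 1 for item '", item$name, "'",
           call. = FALSE)
    }
    if (item$type == "binary") {
      if (is.null(item$prevalence) || item$prevalence <= 0 ||
          item$prevalence >= 1) {
        stop("binary item '", item$name, "' needs prevalence in (0, 1)",
             call. = FALSE)
      }
    } else if (item$type == "ordinal3") {
      p <- item$probs
      if (is.null(p) || length(p) != 3 || any(p <= 0) ||
          abs(sum(p) - 1) > 1e-9) {
        stop("ordinal item '", item$name,
             "' needs 3 positive probabilities summing to 1", call. = FALSE)
      }
    } else {
      stop("unknown item type: ", item$type, call. = FALSE)
    }
  }
  invisible(spec)
}

#' Default simulation specification
#'
#' Marginal targets come from the published validation cohort: the six
#' binary item prevalences are the exact printed fractions of 102, and the
#' thirteen ordinal items use category probabilities chosen to match the
#' published reference-scale total (mean 5.61, frail prevalence about
#' 19.6\%) for an ambulatory 65+ population. Twin couplings place each
#' near-duplicate cross-scale pair (weight loss/nutrition, home
#' aid/provenance, memory/cognition, polypharmacy/medications,
#' balance/mobility, lives-alone/provenance) well above its row-mates.
#' Loadings and couplings were tuned once with the bundled calibration
#' script (`scripts/calibrate_sim.R`) so the simulated total-score
#' correlation sits near the published 0.81.
#'
#' @param n Cohort size (default 102, the study's size).
#' @param seed RNG seed (default 20210904).
#' @return A [sim_spec()].
#' @export
default_spec <- function(n = 102L, seed = 20210904L) {
  zfs <- list(
    new_sim_item("weight_loss",  "zfs", "binary", loading = 0.55, prevalence = 6 / 102),
    new_sim_item("monopodal",    "zfs", "binary", loading = 0.75, prevalence = 55 / 102),
    new_sim_item("lives_alone",  "zfs", "binary", loading = 0.55, prevalence = 45 / 102),
    new_sim_item("home_aid",     "zfs", "binary", loading = 0.75, prevalence = 25 / 102),
    new_sim_item("memory",       "zfs", "binary", loading = 0.70, prevalence = 35 / 102),
    new_sim_item("polypharmacy", "zfs", "binary", loading = 0.65, prevalence = 46 / 102))
  msega <- list(
    new_sim_item("age",                  "msega", "ordinal3", loading = 0.55, probs = c(0.45, 0.40, 0.15)),
    new_sim_item("provenance",           "msega", "ordinal3", loading = 0.60, probs = c(0.75, 0.20, 0.05)),
    new_sim_item("medications",          "msega", "ordinal3", loading = 0.65, probs = c(0.45, 0.33, 0.22)),
    new_sim_item("mood",                 "msega", "ordinal3", loading = 0.55, probs = c(0.68, 0.25, 0.07)),
    new_sim_item("perception_of_health", "msega", "ordinal3", loading = 0.60, probs = c(0.68, 0.25, 0.07)),
    new_sim_item("fall_6_months",        "msega", "ordinal3", loading = 0.55, probs = c(0.83, 0.12, 0.05)),
    new_sim_item("nutrition",            "msega", "ordinal3", loading = 0.55, probs = c(0.90, 0.07, 0.03)),
    new_sim_item("sicknesses",           "msega", "ordinal3", loading = 0.60, probs = c(0.50, 0.37, 0.13)),
    new_sim_item("iadl",                 "msega", "ordinal3", loading = 0.78, probs = c(0.70, 0.19, 0.11)),
    new_sim_item("mobility",             "msega", "ordinal3", loading = 0.78, probs = c(0.64, 0.26, 0.10)),
    new_sim_item("continence",           "msega", "ordinal3", loading = 0.55, probs = c(0.78, 0.13, 0.09)),
    new_sim_item("meals",                "msega", "ordinal3", loading = 0.60, probs = c(0.82, 0.13, 0.05)),
    new_sim_item("cognition",            "msega", "ordinal3", loading = 0.65, probs = c(0.66, 0.24, 0.10)))
  pairs <- list(
    list(zfs = "weight_loss",  msega = "nutrition",   rho = 0.65),
    list(zfs = "home_aid",     msega = "provenance",  rho = 0.60),
    list(zfs = "memory",       msega = "cognition",   rho = 0.60),
    list(zfs = "polypharmacy", msega = "medications", rho = 0.65),
    list(zfs = "monopodal",    msega = "mobility",    rho = 0.50),
    list(zfs = "lives_alone",  msega = "provenance",  rho = 0.45))
  demographics <- list(
    age = c(mean = 76, sd = 8), weight_kg = c(mean = 74, sd = 15),
    height_cm = c(mean = 166, sd = 9), charlson = c(mean = 4.11, sd = 1.81),
    adl = c(mean = 5.83, sd = 0.35), iadl = c(mean = 7.04, sd = 1.68),
    n_medications = c(mean = 4.3, sd = 3.0),
    p_female = 55 / 102, age_loading = 0.35)
  sim_spec(n = n, seed = seed, items = c(zfs, msega), twin_pairs = pairs,
           demographics = demographics)
}

#' Generate a synthetic cohort
#'
#' Per patient a latent frailty factor f ~ N(0, 1) is drawn; each item's
#' latent is loading * f + sum(rho * shared twin residual) + a residual
#' scaled so the latent has unit variance. Binary items fire above the
#' prevalence-calibrated threshold; ordinal items are cut at two
#' thresholds. Items are sampled in a fixed documented order (latent
#' factor, twin residuals in pair order, then items in spec order, then
#' demographics), each as a block of n draws, so appending an item never
#' perturbs earlier columns under the same seed. Demographic fields are
#' independent of the factor except age (small positive loading: frailty
#' rises with age) and the medication count, which is driven by the
#' polypharmacy item's latent so polypharmacy-positive patients carry
#' more prescriptions.
#'
#' @param spec A [sim_spec()].
#' @return Cohort data frame (see [read_cohort()] for the column layout).
#' @examples
#' cohort <- generate_cohort(default_spec(n = 50, seed = 1))
#' head(cohort_scores(cohort))
#' @export
generate_cohort <- function(spec) {
  validate_sim_spec(spec)
  n <- spec$n
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  f <- stats::rnorm(n)
  pair_resid <- lapply(spec$twin_pairs, function(p) stats::rnorm(n))

  item_names <- vapply(spec$items, `[[`, character(1), "name")
  latents <- list()
  values <- list()
  for (item in spec$items) {
    eps <- stats::rnorm(n)
    lam <- item$loading
    rho_terms <- 0
    rho_sq <- 0
    for (k in seq_along(spec$twin_pairs)) {
      pair <- spec$twin_pairs[[k]]
      if (item$name %in% c(pair$zfs, pair$msega)) {
        rho_terms <- rho_terms + pair$rho * pair_resid[[k]]
        rho_sq <- rho_sq + pair$rho^2
      }
    }
    lat <- lam * f + rho_terms + sqrt(1 - lam^2 - rho_sq) * eps
    latents[[item$name]] <- lat
    if (item$type == "binary") {
      values[[item$name]] <- as.integer(lat > calibrate_threshold(item$prevalence))
    } else {
      cuts <- stats::qnorm(cumsum(item$probs[1:2]))
      values[[item$name]] <- as.integer(lat > cuts[1]) + as.integer(lat > cuts[2])
    }
  }

  dem <- spec$demographics
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (item in spec$items) {
    prefix <- if (item$scale == "zfs") "zfs_" else "msega_"
    out[[paste0(prefix, item$name)]] <- values[[item$name]]
  }
  if (length(dem)) {
    lam_age <- dem$age_loading %||% 0.35
    age_lat <- lam_age * f + sqrt(1 - lam_age^2) * stats::rnorm(n)
    out$age <- round(dem$age[["mean"]] + dem$age[["sd"]] * age_lat)
    out$sex <- ifelse(stats::runif(n) < (dem$p_female %||% 0.5), "F", "M")
    out$weight_kg <- round(stats::rnorm(n, dem$weight_kg[["mean"]],
                                        dem$weight_kg[["sd"]]))
    out$height_cm <- round(stats::rnorm(n, dem$height_cm[["mean"]],
                                        dem$height_cm[["sd"]]))
    out$adl <- pmin(6, pmax(4, round(
      stats::rnorm(n, dem$adl[["mean"]], dem$adl[["sd"]]), 1)))
    out$iadl <- pmin(8, pmax(0, round(
      stats::rnorm(n, dem$iadl[["mean"]], dem$iadl[["sd"]]), 1)))
    med_lat <- if ("polypharmacy" %in% item_names) latents[["polypharmacy"]]
               else stats::rnorm(n)
    out$n_medications <- pmax(0, round(
      dem$n_medications[["mean"]] + dem$n_medications[["sd"]] * med_lat))
    out$charlson <- pmax(0, round(
      stats::rnorm(n, dem$charlson[["mean"]], dem$charlson[["sd"]]), 2))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
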