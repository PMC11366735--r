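# Moment-calibrated truncated-normal cohort simulation.
#
# Published cohort summaries give mean, SD and range per feature; the
# generator fits the parent (mu, sigma) of a normal truncated to the printed
# range so that the truncated law attains the printed mean and SD, then
# samples by inverse CDF. For some printed triples the SD exceeds what any
# truncated normal on that interval can attain (the lower-truncation limit
# law is exponential, whose SD equals mean - lower); those laws are
# calibrated to the exact mean and the largest feasible SD (sd_mode "cap").

# Stable truncated-normal moments of N(mu, sigma) restricted to [lower, upper].
tn_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  # mass in [a, b]; switch to upper-tail differences when both cuts are far right
  Z <- if (a > 5) {
    stats::pnorm(a, lower.tail = FALSE) - stats::pnorm(b, lower.tail = FALSE)
  } else {
    stats::pnorm(b) - stats::pnorm(a)
  }
  da <- if (is.finite(a)) stats::dnorm(a) else 0
  db <- if (is.finite(b)) stats::dnorm(b) else 0
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  lam <- (da - db) / Z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (ada - bdb) / Z - lam^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for the parent mu giving a truncated mean of target, at fixed
# sigma. The bracket is capped so the standardized cuts stay within
# +/- max_alpha, where the closed-form moments are numerically exact;
# returns NULL when the target mean is not reachable inside that region
# (extreme tilts, relevant only while probing infeasible SD targets).
tn_solve_mu <- function(sigma, lower, upper, target_mean, max_alpha = 33) {
  f <- function(mu) tn_moments(mu, sigma, lower, upper)$mean - target_mean
  mu_min <- if (is.finite(lower)) lower - max_alpha * sigma else
    upper - max_alpha * sigma
  mu_max <- if (is.finite(upper)) upper + max_alpha * sigma else
    lower + max_alpha * sigma
  lo <- max(target_mean - sigma, mu_min)
  hi <- min(target_mean + sigma, mu_max)
  step <- sigma
  for (i in 1:200) {
    val <- f(lo)
    if (!is.finite(val)) return(NULL)
    if (val <= 0) break
    if (lo <= mu_min) return(NULL)
    step <- step * 2
    lo <- max(lo - step, mu_min)
  }
  step <- sigma
  for (i in 1:200) {
    val <- f(hi)
    if (!is.finite(val)) return(NULL)
    if (val >= 0) break
    if (hi >= mu_max) return(NULL)
    step <- step * 2
    hi <- min(hi + step, mu_max)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12 * max(1, abs(target_mean)))$root
}

#' Calibrate a truncated normal law to a printed mean and SD
#'
#' Finds the parent location and scale `(mu, sigma)` of a normal
#' distribution truncated to `[lower, upper]` whose truncated mean and SD
#' equal the targets. The mean equation is solved exactly (nested root
#' finding on the closed-form truncated moments); the SD equation is solved
#' by monotone search in `sigma`.
#'
#' Some (mean, sd, range) triples are infeasible for the truncated-normal
#' family: with a finite lower bound the SD cannot exceed (mean - lower)
#' (the exponential limit), and a finite upper bound tightens this further.
#' In `sd_mode = "strict"` an infeasible pair is an error naming the
#' maximal feasible SD; in `sd_mode = "cap"` the mean is matched exactly
#' and the SD is set to the largest feasible value.
#'
#' @param target_mean,target_sd Moments the truncated law must attain;
#'   `lower < target_mean < upper`, `target_sd > 0`.
#' @param lower,upper Truncation bounds (may be infinite).
#' @param sd_mode `"strict"` (error on infeasible SD) or `"cap"`.
#' @return A `calibrated_law` list: `family`, `mu`, `sigma`, `lower`,
#'   `upper`, `target_mean`, `target_sd`, `realized_mean`, `realized_sd`,
#'   and `sd_capped` (TRUE when the SD target was infeasible and capped).
#' @export
calibrate_truncated_normal <- function(target_mean, target_sd, lower, upper,
                                       sd_mode = c("strict", "cap")) {
  sd_mode <- match.arg(sd_mode)
  if (!(lower < target_mean && target_mean < upper)) {
    abort("target_mean must lie strictly inside (lower, upper)",
          class = "lesiondx_calibration_error")
  }
  if (!is.finite(target_sd) || target_sd <= 0) {
    abort("target_sd must be positive", class = "lesiondx_calibration_error")
  }

  law <- function(mu, sigma, capped) {
    mom <- tn_moments(mu, sigma, lower, upper)
    structure(
      list(
        family = "truncated_normal", mu = mu, sigma = sigma,
        lower = lower, upper = upper,
        target_mean = target_mean, target_sd = target_sd,
        realized_mean = mom$mean, realized_sd = mom$sd, sd_capped = capped
      ),
      class = "calibrated_law"
    )
  }

  # no effective truncation: parent parameters are the targets
  if (!is.finite(lower) && !is.finite(upper)) {
    return(law(target_mean, target_sd, FALSE))
  }
  a0 <- (lower - target_mean) / target_sd
  b0 <- (upper - target_mean) / target_sd
  if (a0 < -8.5 && b0 > 8.5) {
    return(law(target_mean, target_sd, FALSE))
  }

  g <- function(sigma) {
    mu <- tn_solve_mu(sigma, lower, upper, target_mean)
    if (is.null(mu)) return(NA_real_)
    tn_moments(mu, sigma, lower, upper)$sd - target_sd
  }
  # geometric search upward in sigma (truncated sd grows with sigma at
  # fixed mean); stop at a sign change, or at the numerical-stability edge
  # when the SD target is infeasible for the family
  sigma_lo <- 1e-3 * target_sd
  sigma <- target_sd
  g_prev <- g(sigma_lo)
  sigma_prev <- sigma_lo
  root <- NULL
  for (i in 1:80) {
    val <- g(sigma)
    if (!is.finite(val)) break
    if (val >= 0) {
      root <- stats::uniroot(g, c(sigma_prev, sigma),
                             tol = 1e-12 * target_sd)$root
      break
    }
    sigma_prev <- sigma
    g_prev <- val
    sigma <- sigma * 1.6
  }
  if (is.null(root)) {
    mu_hi <- tn_solve_mu(sigma_prev, lower, upper, target_mean)
    max_sd <- tn_moments(mu_hi, sigma_prev, lower, upper)$sd
    if (sd_mode == "strict") {
      abort(
        sprintf(
          paste0("target_sd %.4g is infeasible for a truncated normal on ",
                 "[%.4g, %.4g] with mean %.4g; maximal feasible sd is ",
                 "approximately %.4g"),
          target_sd, lower, upper, target_mean, max_sd
        ),
        class = "lesiondx_calibration_error"
      )
    }
    return(law(mu_hi, sigma_prev, TRUE))
  }
  out <- law(tn_solve_mu(root, lower, upper, target_mean), root, FALSE)
  stopifnot(
    abs(out$realized_mean - target_mean) <= 1e-6 * max(1, abs(target_mean)),
    abs(out$realized_sd - target_sd) <= 1e-6 * max(1, target_sd)
  )
  out
}

#' Sample from a calibrated truncated normal law
#'
#' Inverse-CDF sampling; every draw lies inside `[lower, upper]`. Uses the
#' upper-tail parametrization of the normal quantile function when the
#' truncation region sits in the far right tail of the parent, which keeps
#' heavily capped laws numerically exact.
#'
#' @param n Number of draws.
#' @param law A `calibrated_law` from [calibrate_truncated_normal()].
#' @return A numeric vector of length `n`.
#' @export
sample_truncated_normal <- function(n, law) {
  a <- (law$lower - law$mu) / law$sigma
  b <- (law$upper - law$mu) / law$sigma
  x <- if (stats::pnorm(a) > 0.5) {
    q_hi <- stats::pnorm(a, lower.tail = FALSE)
    q_lo <- stats::pnorm(b, lower.tail = FALSE)
    u <- stats::runif(n, q_lo, q_hi)
    law$mu + law$sigma * stats::qnorm(u, lower.tail = FALSE)
  } else {
    u <- stats::runif(n, stats::pnorm(a), stats::pnorm(b))
    law$mu + law$sigma * stats::qnorm(u)
  }
  pmin(pmax(x, law$lower), law$upper)
}

entity_parameters <- function(entity) {
  if (entity == "mGB") {
    list(
      lesion_count_law = c(mean = 3.6, sd = 1.5, lower = 2, upper = 7),
      laws = list(
        diameter_mm = c(24.8, 16.0, 2, 83),
        edema_mm = c(6.6, 8.4, 0, 40),
        nearest_lesion_distance_mm = c(14.0, 14.4, 1, 73),
        adc_ratio_tumor = c(1.05, 0.35, 0, Inf),
        adc_ratio_edema_5mm = c(1.79, 0.54, 0, Inf),
        adc_ratio_edema_10mm = c(2.07, 0.54, 0, Inf),
        adc_ratio_edema_20mm = c(2.28, 0.50, 0, Inf),
        flair_ratio_tumor = c(1.56, 0.29, 0, Inf),
        flair_ratio_edema_5mm = c(1.80, 0.30, 0, Inf),
        flair_ratio_edema_10mm = c(1.80, 0.27, 0, Inf),
        flair_ratio_edema_20mm = c(1.78, 0.27, 0, Inf)
      ),
      morphology_probs = c(solid = 25, cystic_solid = 25, cystic = 65,
                           cortical_infiltration = 66, stripe_or_tree = 0,
                           extra_axial_nodular = 0) / 181,
      location_probs = stats::setNames(
        c(48, 22, 40, 8, 18, 0, 4, 1, 22, 2, 6, 5, 4, 1, 0, 0) / 181,
        LOCATION_LEVELS
      ),
      subtype_probs = c(multifocal = 38, multicentric = 12) / 50,
      contrast_enhancing_prob = 139 / 181,
      flair_connected_prob = 114 / 181,
      perfusion_available_prob = 37 / 50,
      typical_curve_prob_given_perfusion = 0,
      rcbv_increased_prob = 85 / 134,
      swi_available_prob = 14 / 50,
      swi_hemorrhage_prob = 7 / 51,
      swi_vascularization_prob = 4 / 51
    )
  } else {
    list(
      lesion_count_law = c(mean = 3.8, sd = 2.4, lower = 2, upper = 10),
      laws = list(
        diameter_mm = c(18.8, 14.3, 1, 64),
        edema_mm = c(6.6, 8.3, 0, 44),
        nearest_lesion_distance_mm = c(19.4, 14.7, 1, 83),
        adc_ratio_tumor = c(0.89, 0.36, 0, Inf),
        adc_ratio_edema_5mm = c(2.10, 1.04, 0, Inf),
        adc_ratio_edema_10mm = c(2.23, 0.92, 0, Inf),
        adc_ratio_edema_20mm = c(2.30, 0.77, 0, Inf),
        flair_ratio_tumor = c(1.71, 0.48, 0, Inf),
        flair_ratio_edema_5mm = c(1.92, 0.92, 0, Inf),
        flair_ratio_edema_10mm = c(2.03, 0.81, 0, Inf),
        flair_ratio_edema_20mm = c(2.04, 0.69, 0, Inf)
      ),
      morphology_probs = c(solid = 139, cystic_solid = 3, cystic = 11,
                           cortical_infiltration = 3, stripe_or_tree = 28,
                           extra_axial_nodular = 3) / 187,
      location_probs = stats::setNames(
        c(46, 13, 23, 12, 9, 7, 14, 12, 24, 4, 12, 1, 0, 14, 1, 2) / 194,
        LOCATION_LEVELS
      ),
      subtype_probs = c(PCNSL = 38, SCNSL = 12) / 50,
      contrast_enhancing_prob = 165 / 187,
      flair_connected_prob = 92 / 187,
      perfusion_available_prob = 17 / 50,
      typical_curve_prob_given_perfusion = 23 / 73,
      rcbv_increased_prob = 40 / 73,
      swi_available_prob = 10 / 50,
      swi_hemorrhage_prob = 12 / 33,
      swi_vascularization_prob = 17 / 33
    )
  }
}

#' Default generator configuration for one entity
#'
#' All numeric targets equal the published per-entity summaries: lesion
#' counts per patient, lesion diameter, edema extent and inter-lesion
#' distance with their printed mean/SD/range; ADC and FLAIR ratios of tumor
#' and perilesional tissue at 5/10/20 mm with their printed mean/SD (range
#' unbounded above, positive below); morphology and location probabilities
#' equal to the printed proportions renormalized to sum to 1; and the
#' printed modality and flag frequencies (e.g. perfusion available in 37/50
#' mGB and 17/50 mCNSL patients; typical-curve probability 0 for mGB and
#' 23/73 per perfusion lesion for mCNSL).
#'
#' @param entity `"mGB"` or `"mCNSL"`.
#' @param n_patients Number of patients to simulate (default 50, the study
#'   group size).
#' @param seed Integer RNG seed stored in the configuration.
#' @return A `generator_config` list consumed by [sample_cohort()].
#' @export
default_config <- function(entity = c("mGB", "mCNSL"), n_patients = 50,
                           seed = 1L) {
  entity <- match.arg(entity)
  params <- entity_parameters(entity)
  cfg <- c(list(entity = entity, n_patients = as.integer(n_patients),
                seed = as.integer(seed)), params)
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  if (is.null(config$n_patients) || config$n_patients < 1) {
    abort("n_patients must be a positive count", class = "lesiondx_config_error")
  }
  for (tab in list(config$morphology_probs, config$location_probs,
                   config$subtype_probs)) {
    if (abs(sum(tab) - 1) > 1e-9) {
      abort("probability tables must sum to 1", class = "lesiondx_config_error")
    }
  }
  all_laws <- c(list(config$lesion_count_law), unname(config$laws))
  for (l in all_laws) {
    if (!(l[3] < l[1] && l[1] < l[4]) || l[2] <= 0) {
      abort("each law needs lower < mean < upper and sd > 0",
            class = "lesiondx_config_error")
    }
  }
  invisible(config)
}

with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Sample a labeled synthetic cohort
#'
#' Draws a cohort from a [default_config()]-style configuration:
#' lesion counts per patient from the calibrated, integer-rounded,
#' bound-clamped count law; continuous features from the calibrated
#' truncated-normal laws; categories from the probability tables; modality
#' flags drawn only where the modality is available. The three perilesional
#' ratios of each lesion are sorted in ascending distance order (the
#' published gradients increase with distance in every group). Features are
#' otherwise drawn independently within a lesion.
#'
#' @param config A `generator_config`.
#' @param seed Optional override of `config$seed`.
#' @return A valid cohort table; identical seeds give identical cohorts.
#'   The caller's RNG state is left untouched.
#' @export
sample_cohort <- function(config, seed = NULL) {
  validate_config(config)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  with_preserved_seed(seed, {
    n_pat <- config$n_patients
    cl <- config$lesion_count_law
    count_law <- calibrate_truncated_normal(cl[1], cl[2], cl[3], cl[4],
                                            sd_mode = "cap")
    k <- pmin(pmax(round(sample_truncated_normal(n_pat, count_law)),
                   cl[3]), cl[4])
    k <- as.integer(k)
    n_les <- sum(k)
    pat_idx <- rep(seq_len(n_pat), times = k)

    draws <- lapply(config$laws, function(l) {
      law <- calibrate_truncated_normal(l[1], l[2], l[3], l[4], sd_mode = "cap")
      sample_truncated_normal(n_les, law)
    })
    # enforce the monotone perilesional gradient within each lesion
    sort3 <- function(a, b, c) {
      m <- matrix(c(a, b, c), ncol = 3)
      m <- t(apply(m, 1, sort))
      list(m[, 1], m[, 2], m[, 3])
    }
    adc <- sort3(draws$adc_ratio_edema_5mm, draws$adc_ratio_edema_10mm,
                 draws$adc_ratio_edema_20mm)
    fl <- sort3(draws$flair_ratio_edema_5mm, draws$flair_ratio_edema_10mm,
                draws$flair_ratio_edema_20mm)

    perfusion_pat <- stats::runif(n_pat) < config$perfusion_available_prob
    swi_pat <- stats::runif(n_pat) < config$swi_available_prob
    perfusion <- perfusion_pat[pat_idx]
    swi <- swi_pat[pat_idx]

    draw_flag <- function(avail, p) {
      out <- rep(NA, n_les)
      out[avail] <- stats::runif(sum(avail)) < p
      out
    }

    subtype_pat <- sample(names(config$subtype_probs), n_pat, replace = TRUE,
                          prob = config$subtype_probs)

    cohort <- tibble(
      patient_id = sprintf("%s_S%04d", config$entity, pat_idx),
      entity = config$entity,
      subtype = subtype_pat[pat_idx],
      perfusion_available = perfusion,
      swi_available = swi,
      lesion_id = unlist(lapply(k, seq_len)),
      diameter_mm = draws$diameter_mm,
      morphology = sample(names(config$morphology_probs), n_les,
                          replace = TRUE, prob = config$morphology_probs),
      location = sample(names(config$location_probs), n_les,
                        replace = TRUE, prob = config$location_probs),
      edema_mm = draws$edema_mm,
      nearest_lesion_distance_mm = draws$nearest_lesion_distance_mm,
      flair_connected = stats::runif(n_les) < config$flair_connected_prob,
      contrast_enhancing = stats::runif(n_les) < config$contrast_enhancing_prob,
      adc_ratio_tumor = draws$adc_ratio_tumor,
      adc_ratio_edema_5mm = adc[[1]],
      adc_ratio_edema_10mm = adc[[2]],
      adc_ratio_edema_20mm = adc[[3]],
      flair_ratio_tumor = draws$flair_ratio_tumor,
      flair_ratio_edema_5mm = fl[[1]],
      flair_ratio_edema_10mm = fl[[2]],
      flair_ratio_edema_20mm = fl[[3]],
      rcbv_increased = draw_flag(perfusion, config$rcbv_increased_prob),
      typical_curve = draw_flag(perfusion,
                                config$typical_curve_prob_given_perfusion),
      swi_hemorrhage = draw_flag(swi, config$swi_hemorrhage_prob),
      swi_vascularization = draw_flag(swi, config$swi_vascularization_prob)
    )
    as_cohort(cohort, provenance = sprintf("synthetic seed=%d", seed))
  })
}

#' Sample a two-entity study-style cohort
#'
#' Convenience wrapper drawing one mGB and one mCNSL block with default
#' configurations and binding them into a single labeled cohort.
#'
#' @param n_mgb,n_mcnsl Patients per entity.
#' @param seed Integer seed; the two entity blocks use `seed` and
#'   `seed + 1`.
#' @return A valid cohort table containing both entities.
#' @export
sample_study_cohort <- function(n_mgb = 50, n_mcnsl = 50, seed = 1L) {
  seed <- as.integer(seed)
  gb <- sample_cohort(default_config("mGB", n_patients = n_mgb, seed = seed))
  ly <- sample_cohort(default_config("mCNSL", n_patients = n_mcnsl,
                                     seed = seed + 1L))
  as_cohort(dplyr::bind_rows(gb, ly),
            provenance = sprintf("synthetic seed=%d", seed))
}
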