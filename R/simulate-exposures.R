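#' Exposure specification
#'
#' Describes one environmental risk factor: its distribution for the
#' synthetic generator, the per-unit coding scale used in the analysis
#' (e.g. age at first full-term pregnancy analyzed per 5 years), the
#' eligibility stratum in which the exposure is defined, and any extra
#' covariates the interaction model must adjust for (e.g. former use of the
#' corresponding menopausal hormone therapy).
#'
#' @param name column name in the phenotype table.
#' @param type one of `"continuous"`, `"binary"`, `"ordinal"`.
#' @param scale positive divisor applied to the raw value (continuous
#'   exposures only): the stored column is `raw / scale`.
#' @param eligibility one of `"all"`, `"parous_only"`,
#'   `"premenopausal_only"`, `"postmenopausal_only"`.
#' @param extra_covariates character vector of additional adjustment
#'   columns that must exist in the phenotype table when this exposure is
#'   tested.
#' @param mean,sd mean and sd of the raw continuous exposure.
#' @param prevalence Bernoulli probability for binary exposures.
#' @param probs category probabilities for ordinal exposures
#'   (coded 1, 2, 3, 4 as an integer trend).
#' @return An object of class `exposure_spec`.
#' @export
exposure_spec <- function(name, type = c("continuous", "binary", "ordinal"),
                          scale = 1, eligibility = "all",
                          extra_covariates = character(),
                          mean = 0, sd = 1, prevalence = 0.5,
                          probs = c(0.25, 0.25, 0.25, 0.25)) {
  type <- match.arg(type)
  if (scale <= 0) stop("scale must be positive")
  eligibility <- match.arg(eligibility, c("all", "parous_only",
                                          "premenopausal_only",
                                          "postmenopausal_only"))
  structure(list(name = name, type = type, scale = scale,
                 eligibility = eligibility,
                 extra_covariates = extra_covariates,
                 mean = mean, sd = sd, prevalence = prevalence,
                 probs = probs / sum(probs)),
            class = "exposure_spec")
}

#' Default set of 14 breast-cancer-style risk factors
#'
#' Exposures mirror the established breast cancer risk factor set: age at
#' first full-term pregnancy (per 5 years, parous women), lifetime alcohol
#' (per 10 g/day), age at menarche (per 2 years), pre- and postmenopausal
#' BMI (per 5 kg/m^2, within menopausal stratum), ever breastfed and
#' breastfeeding duration (per 12 months, parous women), height (per 5 cm),
#' oral contraceptive use, parity, number of full-term births (ordinal
#' 1/2/3/4+), current smoking, and current estrogen-only / estrogen plus
#' progestogen MHT use (postmenopausal women, adjusted for former use of
#' the corresponding MHT). Means, SDs and prevalences approximate values
#' typical of large European-ancestry breast cancer studies.
#'
#' @return Named list of [exposure_spec()] objects.
#' @export
default_exposure_specs <- function() {
  specs <- list(
    exposure_spec("age_first_ftp", "continuous", scale = 5,
                  eligibility = "parous_only", mean = 24.8, sd = 4.6),
    exposure_spec("alcohol_gday", "continuous", scale = 10, mean = 6.1, sd = 8),
    exposure_spec("age_menarche", "continuous", scale = 2, mean = 13.0, sd = 1.6),
    exposure_spec("bmi_premenopausal", "continuous", scale = 5,
                  eligibility = "premenopausal_only", mean = 25.5, sd = 5.3),
    exposure_spec("bmi_postmenopausal", "continuous", scale = 5,
                  eligibility = "postmenopausal_only", mean = 26.6, sd = 5.2),
    exposure_spec("ever_breastfed", "binary", eligibility = "parous_only",
                  prevalence = 0.78),
    exposure_spec("breastfeeding_months", "continuous", scale = 12,
                  eligibility = "parous_only", mean = 8.7, sd = 9),
    exposure_spec("height_cm", "continuous", scale = 5, mean = 163.8, sd = 6.5),
    exposure_spec("oc_ever", "binary", prevalence = 0.59),
    exposure_spec("parous", "binary", prevalence = 0.87),
    exposure_spec("n_births", "ordinal", eligibility = "parous_only",
                  probs = c(0.17, 0.42, 0.25, 0.16)),
    exposure_spec("smoking_current", "binary", prevalence = 0.14),
    exposure_spec("mht_e_current", "binary",
                  eligibility = "postmenopausal_only",
                  extra_covariates = "former_mht_e", prevalence = 0.16),
    exposure_spec("mht_ep_current", "binary",
                  eligibility = "postmenopausal_only",
                  extra_covariates = "former_mht_ep", prevalence = 0.15)
  )
  names(specs) <- vapply(specs, function(s) s$name, "")
  specs
}

#' Add synthetic exposure columns to a phenotype table
#'
#' Generates each exposure according to its spec (continuous normal, binary
#' Bernoulli, ordinal categorical 1/2/3/4+ coded as an integer trend),
#' divides continuous values by the coding scale, and blanks the exposure
#' (`NA`) outside its eligibility stratum so that restricted analyses
#' (parous-only, menopausal-status-specific) operate on the correct
#' complete cases. Eligibility flags `parous` and `postmenopausal`, and
#' former-MHT-use indicators among postmenopausal women, are generated
#' first when absent.
#'
#' @param table phenotype data.frame (one row per sample).
#' @param specs list of [exposure_spec()] objects with distinct names.
#' @param seed integer seed.
#' @return `table` with exposure and eligibility columns appended.
#' @export
make_exposures <- function(table, specs, seed = 1) {
  nm <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("exposure specs must name distinct columns")
  n <- nrow(table)
  withr::with_seed(seed, {
    if (is.null(table$parous)) {
      table$parous <- stats::rbinom(n, 1, 0.87)
    }
    if (is.null(table$postmenopausal)) {
      table$postmenopausal <- stats::rbinom(n, 1, 0.68)
    }
    for (flag in c("former_mht_e", "former_mht_ep")) {
      if (is.null(table[[flag]])) {
        table[[flag]] <- ifelse(table$postmenopausal == 1,
                                stats::rbinom(n, 1, 0.12), 0L)
      }
    }
    for (s in specs) {
      if (s$name %in% c("parous", "postmenopausal") &&
          !is.null(table[[s$name]])) next
      val <- switch(s$type,
        continuous = stats::rnorm(n, s$mean, s$sd) / s$scale,
        binary = stats::rbinom(n, 1, s$prevalence),
        ordinal = sample.int(length(s$probs), n, replace = TRUE,
                             prob = s$probs)
      )
      eligible <- switch(s$eligibility,
        all = rep(TRUE, n),
        parous_only = table$parous == 1,
        premenopausal_only = table$postmenopausal == 0,
        postmenopausal_only = table$postmenopausal == 1
      )
      val[!eligible] <- NA
      table[[s$name]] <- val
    }
  })
  table
}
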