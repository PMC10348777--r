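# Mixed-effects logistic regression of suboptimal re-triage.
#
# The model is a binomial GLMM on the logit scale: fixed effects for the
# patient covariates and the sending center's RTCC, crossed random
# intercepts for sending center and calendar year (centers persist across
# years, so the grouping is crossed, not nested). Estimation is lme4's
# Laplace approximation; intervals are Wald on the log-odds scale,
# exponentiated to odds ratios.

#' Specification of the suboptimality model
#'
#' @param fixed Fixed-effect covariate columns. The default is the full
#'   analysis set; reduced sets (e.g. `c("sex", "rtcc_id")`) are useful for
#'   simulation studies.
#' @param random Random-intercept grouping columns, default sending center
#'   and year (crossed).
#' @param references Named vector of reference levels; defaults: age 18-24,
#'   male, white, non-Hispanic, self-pay, all-transport mechanism, torso,
#'   injury severity 16-25, CENTRAL RTCC.
#' @param year_as_trend If `TRUE`, year enters as a standardized fixed
#'   linear trend instead of a random intercept.
#' @return List of class `retriage_model_spec`.
#' @export
model_spec <- function(fixed = c("age_band", "sex", "race", "ethnicity",
                                 "insurance", "mechanism", "body_region",
                                 "riss_band", "rtcc_id"),
                       random = c("sending_facility_id", "year"),
                       references = c(age_band = "18-24", sex = "MALE",
                                      race = "WHITE", ethnicity = "NON_HISPANIC",
                                      insurance = "SELF_PAY",
                                      mechanism = "ALL_TRANSPORT",
                                      body_region = "TORSO",
                                      riss_band = "16-25", rtcc_id = "CENTRAL"),
                       year_as_trend = FALSE) {
  structure(list(fixed = fixed, random = random, references = references,
                 year_as_trend = year_as_trend),
            class = "retriage_model_spec")
}

#' Fit the mixed-effects logistic regression of suboptimality
#'
#' @param events Labeled (and, for raw records, encoded) events; the outcome
#'   is `optimality == "SUBOPTIMAL"`, or an existing 0/1 `suboptimal`
#'   column.
#' @param spec A [model_spec()].
#' @param conf_level Wald confidence level, default 0.95.
#' @param ... Passed to [lme4::glmer()].
#' @return Object of class `retriage_glmm`: the lme4 fit, a tidy
#'   `coefficients` tibble (`term`, `variable`, `level`, `estimate`, `se`,
#'   `or`, `ci_lower`, `ci_upper`, `p_value`), `random_effects` variances,
#'   and convergence diagnostics. Fewer than two centers or years, or a
#'   constant outcome, is an error; quasi-complete separation triggers a
#'   warning naming the coefficient.
#' @export
fit_suboptimality_model <- function(events, spec = model_spec(),
                                    conf_level = 0.95, ...) {
  ev <- tibble::as_tibble(events)
  if (!"suboptimal" %in% names(ev)) {
    ev$suboptimal <- as.integer(ev$optimality == "SUBOPTIMAL")
  }
  if (length(unique(ev$suboptimal)) < 2L) {
    stop("outcome is constant; the suboptimality model cannot be fitted",
         call. = FALSE)
  }
  if ("sending_facility_id" %in% spec$random &&
      length(unique(ev$sending_facility_id)) < 2L) {
    stop("at least two sending centers are required", call. = FALSE)
  }
  if ("year" %in% spec$random && length(unique(ev$year)) < 2L) {
    stop("at least two years are required", call. = FALSE)
  }

  fixed <- intersect(spec$fixed, names(ev))
  var_levels <- list()
  for (v in fixed) {
    f <- droplevels(factor(ev[[v]]))
    ref <- spec$references[[v]]
    if (!is.null(ref) && ref %in% levels(f)) f <- stats::relevel(f, ref)
    ev[[v]] <- f
    var_levels[[v]] <- levels(f)
  }
  fixed <- fixed[vapply(var_levels[fixed], length, 1L) > 1L]

  rand <- spec$random
  rhs <- fixed
  if (spec$year_as_trend) {
    ev$year_std <- as.numeric(scale(as.numeric(as.character(ev$year))))
    rhs <- c(rhs, "year_std")
    rand <- setdiff(rand, "year")
  }
  for (g in rand) ev[[g]] <- factor(ev[[g]])
  fml <- as.formula(paste(
    "suboptimal ~", paste(c(rhs, sprintf("(1 | %s)", rand)), collapse = " + ")))

  fit <- lme4::glmer(fml, data = ev, family = stats::binomial(),
                     control = lme4::glmerControl(optimizer = "bobyqa"), ...)
  opt_code <- fit@optinfo$conv$opt
  messages <- unlist(fit@optinfo$conv$lme4$messages)
  if (!is.null(opt_code) && opt_code != 0) {
    stop("GLMM optimizer failed to converge (code ", opt_code, "): ",
         paste(messages, collapse = "; "), call. = FALSE)
  }

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  zval <- beta / se
  sep <- names(beta)[abs(beta) > 10 | se > 20]
  if (length(sep)) {
    warning("possible complete separation for coefficient(s): ",
            paste(sep, collapse = ", "), call. = FALSE)
  }

  term_var <- term_level <- rep(NA_character_, length(beta))
  for (i in seq_along(beta)) {
    tn <- names(beta)[i]
    for (v in fixed) {
      if (startsWith(tn, v) && nchar(tn) > nchar(v)) {
        term_var[i] <- v
        term_level[i] <- substring(tn, nchar(v) + 1L)
        break
      }
    }
  }
  coefs <- tibble::tibble(
    term = names(beta), variable = term_var, level = term_level,
    estimate = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    ci_lower = exp(unname(beta) - zq * se),
    ci_upper = exp(unname(beta) + zq * se),
    p_value = 2 * pnorm(-abs(unname(zval))))

  vc <- as.data.frame(lme4::VarCorr(fit))
  random_effects <- tibble::tibble(group = vc$grp, variance = vc$vcov,
                                   sd = vc$sdcor)

  structure(list(fit = fit, coefficients = coefs,
                 random_effects = random_effects,
                 var_levels = var_levels, references = spec$references,
                 converged = TRUE, messages = messages,
                 n = nrow(ev), conf_level = conf_level),
            class = "retriage_glmm")
}

#' @export
print.retriage_glmm <- function(x, ...) {
  cat("<retriage_glmm> binomial logit GLMM, n =", x$n, "\n")
  cat("random-intercept variances:\n")
  for (i in seq_len(nrow(x$random_effects))) {
    cat(sprintf("  %s: %.4f\n", x$random_effects$group[i],
                x$random_effects$variance[i]))
  }
  cf <- x$coefficients
  cat("fixed effects (OR [", 100 * x$conf_level, "% CI]):\n", sep = "")
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("  %-28s %6.2f [%5.2f-%6.2f]  p=%.3g\n", cf$term[i], cf$or[i],
                cf$ci_lower[i], cf$ci_upper[i], cf$p_value[i]))
  }
  if (length(x$messages)) cat("notes:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' Coefficient table in report layout
#'
#' One row per covariate level including marked reference rows, mirroring
#' the usual published predictor-table layout.
#'
#' @param model A [fit_suboptimality_model()] result.
#' @param digits Rounding for OR and CI columns.
#' @return Tibble: `variable`, `level`, `or`, `ci_lower`, `ci_upper`,
#'   `p_value`, `reference` (logical).
#' @export
coefficient_table <- function(model, digits = 2) {
  stopifnot(inherits(model, "retriage_glmm"))
  cf <- model$coefficients
  rows <- list()
  for (v in names(model$var_levels)) {
    lv <- model$var_levels[[v]]
    ref <- lv[1]
    rows[[v]] <- tibble::tibble(
      variable = v, level = lv, reference = lv == ref) |>
      dplyr::left_join(cf[cf$variable %in% v, c("level", "or", "ci_lower",
                                                "ci_upper", "p_value")],
                       by = "level")
  }
  out <- dplyr::bind_rows(rows)
  out$or <- round(out$or, digits)
  out$ci_lower <- round(out$ci_lower, digits)
  out$ci_upper <- round(out$ci_upper, digits)
  out
}

#' Simulate a dataset from the suboptimality GLMM
#'
#' Test harness for parameter recovery: draws center and year random
#' intercepts, computes logits from known coefficients, and samples
#' outcomes. Deterministic under `seed`.
#'
#' @param n Number of events.
#' @param true_betas Named log-odds vector: `"(Intercept)"` plus names of
#'   the form `"variable=LEVEL"` (validated against
#'   [covariate_effect_names()]).
#' @param center_sigma,year_sigma Random-intercept standard deviations.
#' @param n_centers Number of sending centers (assigned to RTCCs
#'   round-robin).
#' @param years Calendar years.
#' @param rtccs RTCC labels.
#' @param marginals Coded covariate marginals, default
#'   [default_covariate_marginals()].
#' @param seed Integer seed.
#' @return Tibble of events with coded covariates, `sending_facility_id`,
#'   `year`, `rtcc_id`, `suboptimal` and `optimality`; the generating
#'   parameters are attached as attributes `true_betas`, `center_sigma`,
#'   `year_sigma`.
#' @export
simulate_glmm_dataset <- function(n, true_betas, center_sigma = 0.5,
                                  year_sigma = 0.25, n_centers = 100,
                                  years = 2009:2018,
                                  rtccs = retriage_vocabulary()$rtcc,
                                  marginals = default_covariate_marginals(),
                                  seed = 1L) {
  bad <- setdiff(names(true_betas), covariate_effect_names(rtccs))
  if (length(bad)) {
    stop("unknown coefficient name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  centers <- sprintf("C%03d", seq_len(n_centers))
  center_rtcc <- setNames(rep_len(rtccs, n_centers), centers)
  b_center <- setNames(rnorm(n_centers, 0, center_sigma), centers)
  b_year <- setNames(rnorm(length(years), 0, year_sigma), as.character(years))

  draw <- function(p, k) sample(names(p), k, replace = TRUE, prob = p)
  ev <- tibble::tibble(
    sending_facility_id = sample(centers, n, replace = TRUE),
    year = sample(years, n, replace = TRUE),
    age_band = draw(marginals$age_band, n),
    sex = draw(marginals$sex, n),
    race = draw(marginals$race, n),
    ethnicity = draw(marginals$ethnicity, n),
    insurance = draw(marginals$insurance, n),
    mechanism = draw(marginals$mechanism, n),
    body_region = draw(marginals$body_region, n),
    riss_band = draw(marginals$riss_band, n)
  )
  ev$rtcc_id <- unname(center_rtcc[ev$sending_facility_id])

  eta <- rep(0, n)
  for (nm in names(true_betas)) {
    if (nm == "(Intercept)") {
      eta <- eta + true_betas[[nm]]
    } else {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      eta <- eta + true_betas[[nm]] * (ev[[parts[1]]] == parts[2])
    }
  }
  eta <- eta + b_center[ev$sending_facility_id] + b_year[as.character(ev$year)]
  ev$suboptimal <- rbinom(n, 1L, plogis(eta))
  ev$optimality <- ifelse(ev$suboptimal == 1L, "SUBOPTIMAL", "OPTIMAL")
  attr(ev, "true_betas") <- true_betas
  attr(ev, "center_sigma") <- center_sigma
  attr(ev, "year_sigma") <- year_sigma
  ev
}
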