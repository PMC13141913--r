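#' Gaussian linear mixed model on log abundance
#'
#' Fits log-abundance against the fixed covariates with a random intercept
#' per infant time series, the design used to test the effect of the
#' phage-enrichment treatment while respecting the individuality of each
#' infant: log(Y_ij) = b0 + b_treatment * treatment (+ further terms) + R_j
#' + e_ij, with R_j ~ N(0, sd^2). REML fit; Wald z p-values for the fixed
#' effects.
#'
#' @param response Numeric vector of log-transformed abundances.
#' @param meta data.frame with \code{infant_id} and the fixed-effect columns.
#' @param fixed_terms Character vector of fixed-effect column names
#'   (default \code{"treatment"}).
#' @return An \code{lmm_result} (see \code{\link{lmm_result}}).
#' @export
fit_abundance_lmm <- function(response, meta, fixed_terms = "treatment") {
  stopifnot(length(response) == nrow(meta), all(is.finite(response)))
  if (length(unique(meta$infant_id)) < 2) stop("need >= 2 infant groups")
  dat <- cbind(meta, .y = response)
  form <- stats::as.formula(paste(".y ~", paste(fixed_terms, collapse = "+"),
                                  "+ (1 | infant_id)"))
  fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE))
  lmm_result(fit, model_family = "gaussian_log", n_obs = nrow(dat))
}

#' Binomial mixed model on presence/absence
#'
#' Logistic mixed model of phage presence with a per-infant random
#' intercept: logit P(Y_ij = 1) = b0 + b_treatment * treatment +
#' b_delivery * delivery + b_age * age + R_j. Complete separation or other
#' non-convergence is flagged in the result rather than raised.
#'
#' @param presence 0/1 response vector; both classes must be present.
#' @param meta data.frame with \code{infant_id} and the fixed-effect columns.
#' @param fixed_terms Character vector of fixed-effect column names.
#' @return An \code{lmm_result}.
#' @export
fit_presence_glmm <- function(presence, meta,
                              fixed_terms = c("treatment", "delivery", "age_months")) {
  stopifnot(length(presence) == nrow(meta))
  if (length(unique(presence)) < 2) stop("response constant: single class")
  dat <- cbind(meta, .y = presence)
  form <- stats::as.formula(paste(".y ~", paste(fixed_terms, collapse = "+"),
                                  "+ (1 | infant_id)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = dat, family = stats::binomial())))
  lmm_result(fit, model_family = "binomial", n_obs = nrow(dat))
}

#' Mixed-model result container
#'
#' Normalises a fitted \code{lme4} model into the coefficient table the
#' reporting layer consumes.
#'
#' @param fit A fitted \code{merMod}.
#' @param model_family \code{"gaussian_log"} or \code{"binomial"}.
#' @param n_obs Number of observations.
#' @return List of class \code{lmm_result}: \code{coefficients} (data.frame
#'   with \code{term}, \code{estimate}, \code{std_error}, \code{p_value}),
#'   \code{random_intercept_sd}, \code{model_family}, \code{n_obs},
#'   \code{converged}, \code{fit} (the underlying model).
#' @export
lmm_result <- function(fit, model_family, n_obs) {
  co <- stats::coef(summary(fit))
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc$sdcor[vc$grp == "infant_id" & vc$var1 == "(Intercept)"][1]
  msgs <- fit@optinfo$conv$lme4$messages
  singular <- lme4::isSingular(fit, tol = 1e-4)
  converged <- is.null(msgs) && fit@optinfo$conv$opt == 0
  out <- list(
    coefficients = data.frame(term = rownames(co), estimate = unname(est),
                              std_error = unname(se), p_value = unname(p),
                              stringsAsFactors = FALSE),
    random_intercept_sd = ri_sd,
    model_family = model_family,
    n_obs = n_obs,
    converged = converged,
    singular = singular,
    fit = fit
  )
  class(out) <- "lmm_result"
  out
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Mixed model (%s), %d obs, random-intercept sd = %.3f%s\n",
              x$model_family, x$n_obs, x$random_intercept_sd,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.lmm_result <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Per-group mixed-model screen with BH correction
#'
#' Fits the presence GLMM (or abundance LMM) separately for each phage group
#' (e.g. each viral family) and adjusts the p-values of the term of interest
#' across groups with Benjamini-Hochberg.
#'
#' @param mat samples x groups matrix (presence 0/1 or log abundance).
#' @param meta Sample metadata aligned with rows.
#' @param term Coefficient name to extract (matched by prefix against the
#'   model-matrix column, e.g. \code{"treatment"}).
#' @param family \code{"binomial"} or \code{"gaussian"}.
#' @param fixed_terms Fixed-effect columns.
#' @return data.frame: \code{group}, \code{estimate}, \code{std_error},
#'   \code{p_value}, \code{p_adjusted}, \code{converged}, \code{skipped}.
#' @export
screen_groups <- function(mat, meta, term = "treatment",
                          family = c("binomial", "gaussian"),
                          fixed_terms = c("treatment", "delivery", "age_months")) {
  family <- match.arg(family)
  rows <- lapply(colnames(mat), function(g) {
    y <- mat[, g]
    res <- tryCatch({
      m <- if (family == "binomial") fit_presence_glmm(y, meta, fixed_terms)
           else fit_abundance_lmm(y, meta, fixed_terms)
      co <- m$coefficients
      hit <- grep(paste0("^", term), co$term)[1]
      data.frame(group = g, estimate = co$estimate[hit],
                 std_error = co$std_error[hit], p_value = co$p_value[hit],
                 converged = m$converged, skipped = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(group = g, estimate = NA_real_, std_error = NA_real_,
                 p_value = NA_real_, converged = FALSE, skipped = TRUE,
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[c("group", "estimate", "std_error", "p_value", "p_adjusted",
        "converged", "skipped")]
}

#' Cohort bookkeeping totals
#'
#' Validates and totals a sample-metadata table: overall sample and infant
#' counts plus subgroup counts by age window, delivery mode and treatment.
#'
#' @param meta Validated metadata (see \code{\link{validate_sample_meta}}).
#' @return Named list of integer counts.
#' @export
cohort_totals <- function(meta) {
  meta <- validate_sample_meta(meta)
  list(
    n_samples = nrow(meta),
    n_infants = length(unique(meta$infant_id)),
    by_age = as.list(table(meta$age_months)),
    by_delivery = as.list(table(meta$delivery)),
    by_treatment = as.list(table(meta$treatment)),
    infants_by_delivery = lapply(split(meta$infant_id, meta$delivery),
                                 function(x) length(unique(x)))
  )
}
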