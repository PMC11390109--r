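# Conditional logistic step-selection model. The fixed-effects likelihood,
# gradient and Hessian are implemented directly (log-sum-exp stabilized);
# individual random slopes use the Poisson reformulation of the conditional
# logit fitted with glmmTMB (stratum intercepts as random effects with their
# variance fixed at a large constant).

#' Design terms of the step-selection model
#'
#' Main effects of TRI, distance to ridge, step length and week, the two-way
#' products of the terrain variables with step length and week, the
#' step-length-by-week product, and the two three-way products of each
#' terrain variable with step length and week. All on the z-scale; there is
#' no intercept (absorbed by the stratum conditioning).
#'
#' @return character vector of term names.
#' @export
ssf_terms <- function() {
  c("tri", "dist_ridge", "step_length", "week",
    "tri_step", "dist_step", "tri_week", "dist_week", "step_week",
    "tri_step_week", "dist_step_week")
}

#' Build the model matrices from a z-scored stratified dataset
#'
#' @param strata data frame with `z_tri`, `z_dist_ridge`, `z_step_length`,
#'   `z_week`, `used`, `stratum_id`, `individual_id`.
#' @return list with the fixed-effects matrix `X` (columns [ssf_terms()]),
#'   `used` indicator, `stratum` and `individual` grouping vectors.
#' @export
build_design <- function(strata) {
  need <- c("z_tri", "z_dist_ridge", "z_step_length", "z_week",
            "used", "stratum_id", "individual_id")
  miss <- setdiff(need, names(strata))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  t <- strata$z_tri; d <- strata$z_dist_ridge
  l <- strata$z_step_length; w <- strata$z_week
  X <- cbind(tri = t, dist_ridge = d, step_length = l, week = w,
             tri_step = t * l, dist_step = d * l,
             tri_week = t * w, dist_week = d * w, step_week = l * w,
             tri_step_week = t * l * w, dist_step_week = d * l * w)
  list(X = X, used = as.integer(strata$used),
       stratum = as.integer(factor(strata$stratum_id)),
       individual = as.character(strata$individual_id))
}

# Stratum-conditioned negative log-likelihood, gradient and Hessian at beta.
# Log-sum-exp stabilization throughout; `idx` caches the row split by stratum.
clogit_nll <- function(beta, X, used, stratum, idx, want_hessian = FALSE) {
  eta <- drop(X %*% beta)
  mx <- vapply(idx, function(i) max(eta[i]), numeric(1))
  w <- exp(eta - mx[stratum])
  sumw <- drop(rowsum(w, stratum))
  nll <- -(sum(eta[used == 1L]) - sum(log(sumw) + mx))
  p <- w / sumw[stratum]
  grad <- colSums(p * X) - colSums(X[used == 1L, , drop = FALSE])
  out <- list(nll = nll, grad = grad, p = p)
  if (want_hessian) {
    Mu <- rowsum(p * X, stratum)
    out$hessian <- crossprod(sqrt(p) * X) - crossprod(Mu)
  }
  out
}

# Columns constant within every stratum carry no information under the
# conditional likelihood (e.g. the week main effect).
stratum_constant_cols <- function(X, stratum, tol = 1e-10) {
  n_s <- drop(rowsum(rep(1, nrow(X)), stratum))
  sums <- rowsum(X, stratum)
  sq <- rowsum(X^2, stratum)
  v <- sq / n_s - (sums / n_s)^2
  apply(v, 2, max) < tol
}

#' Fit the fixed-effects conditional logistic step-selection model
#'
#' Maximizes the stratum-conditioned likelihood
#' `prod_s exp(beta' x_used) / sum_j exp(beta' x_j)` by Newton iterations
#' with analytic gradient and Hessian and step halving. Standard errors come
#' from the inverse observed information. Terms constant within every
#' stratum (the week main effect) are not identifiable and are reported as
#' NA. Coefficients running away on the z-scale (`max |beta| > beta_cap`)
#' indicate separation and raise an error naming the covariate.
#'
#' @param design a [build_design()] result.
#' @param max_iter Newton iteration cap.
#' @param grad_tol convergence threshold on the gradient sup-norm.
#' @param beta_cap separation-detection cap on the z-scale coefficients.
#' @return an `ssf_fit`: `coefficients`, `se`, `ci_lower`, `ci_upper`,
#'   `vcov`, `loglik`, `null_loglik`, `converged`, `iterations`,
#'   `dropped_terms`, `n_strata`.
#' @export
fit_conditional_logit <- function(design, max_iter = 500, grad_tol = 1e-6,
                                  beta_cap = 50) {
  X <- design$X; used <- design$used; stratum <- design$stratum
  tab <- rowsum(used, stratum)
  if (any(tab != 1L)) stop("every stratum must contain exactly one used row")
  drop_col <- stratum_constant_cols(X, stratum)
  Xe <- X[, !drop_col, drop = FALSE]
  idx <- split(seq_len(nrow(Xe)), stratum)
  beta <- rep(0, ncol(Xe))
  cur <- clogit_nll(beta, Xe, used, stratum, idx, want_hessian = TRUE)
  null_nll <- cur$nll
  converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    if (max(abs(cur$grad)) < grad_tol) { converged <- TRUE; break }
    H <- cur$hessian
    step <- tryCatch(solve(H, cur$grad),
                     error = function(e) solve(H + diag(1e-8, ncol(H)), cur$grad))
    lambda <- 1
    repeat {
      beta_new <- beta - lambda * step
      cand <- clogit_nll(beta_new, Xe, used, stratum, idx, want_hessian = TRUE)
      if (is.finite(cand$nll) && cand$nll <= cur$nll + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta_new; cur <- cand
    if (max(abs(beta)) > beta_cap) {
      worst <- colnames(Xe)[which.max(abs(beta))]
      stop("separation detected: coefficient for '", worst,
           "' diverged beyond ", beta_cap, " on the z-scale")
    }
  }
  if (!converged && max(abs(cur$grad)) >= grad_tol)
    stop("conditional logit did not converge after ", max_iter,
         " iterations (gradient sup-norm ", format(max(abs(cur$grad))), ")")
  vc <- solve(cur$hessian)
  terms <- colnames(X)
  coefs <- se <- setNames(rep(NA_real_, length(terms)), terms)
  coefs[colnames(Xe)] <- beta
  se[colnames(Xe)] <- sqrt(diag(vc))
  vcov_full <- matrix(NA_real_, length(terms), length(terms),
                      dimnames = list(terms, terms))
  vcov_full[colnames(Xe), colnames(Xe)] <- vc
  structure(list(
    coefficients = coefs, se = se,
    ci_lower = coefs - 1.96 * se, ci_upper = coefs + 1.96 * se,
    vcov = vcov_full, loglik = -cur$nll, null_loglik = -null_nll,
    converged = converged, iterations = it,
    dropped_terms = terms[drop_col], n_strata = length(idx),
    random_effects = NULL, method = "newton"),
    class = "ssf_fit")
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("ssf_fit (%s): %d strata, logLik %.2f%s\n", x$method, x$n_strata,
              x$loglik, if (x$converged) "" else " [NOT CONVERGED]"))
  est <- data.frame(estimate = x$coefficients, se = x$se,
                    ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  print(round(est, 4))
  if (length(x$dropped_terms))
    cat("dropped (stratum-constant):", paste(x$dropped_terms, collapse = ", "), "\n")
  if (!is.null(x$random_effects))
    cat(sprintf("random slopes: sd(tri) %.3f, sd(dist_ridge) %.3f\n",
                x$random_effects$sd_tri, x$random_effects$sd_dist))
  invisible(x)
}

#' Coefficient table of a step-selection fit
#' @param fit an `ssf_fit`.
#' @return data frame with term, estimate, SE and 95% CI.
#' @export
coef_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(fit$se),
             ci_lower = unname(fit$ci_lower), ci_upper = unname(fit$ci_upper),
             row.names = NULL)
}

#' Fit the mixed conditional logit with individual random slopes
#'
#' Poisson reformulation of the conditional logit: each row is modelled as
#' Poisson with log link, stratum-specific intercepts are random effects
#' with their variance fixed at `1e6` (numerically equivalent to profiling
#' them out as fixed offsets), and individuals get independent Gaussian
#' random slopes on TRI and distance to ridge, integrated by the Laplace
#' approximation (glmmTMB). If the inner optimization fails, the
#' fixed-effects fit is returned with a prominent warning and
#' `method = "fixed_fallback"`.
#'
#' @param strata z-scored stratified dataset (see [annotate_and_transform()]).
#' @param stratum_variance fixed variance of the stratum intercepts.
#' @return an `ssf_fit` with `random_effects` (slope SDs and per-individual
#'   modes).
#' @export
fit_mixed_conditional_logit <- function(strata, stratum_variance = 1e6) {
  design <- build_design(strata)
  n_ind <- length(unique(design$individual))
  if (n_ind < 2)
    stop("random slopes are not identifiable from a single individual; ",
         "use fit_conditional_logit()")
  if (n_ind < 5)
    warning("fewer than 5 individuals: random-slope variances will be poorly identified")
  drop_col <- stratum_constant_cols(design$X, design$stratum)
  dat <- as.data.frame(design$X[, !drop_col, drop = FALSE])
  fe_terms <- names(dat)
  dat$used <- design$used
  dat$stratum_f <- factor(design$stratum)
  dat$individual_f <- factor(design$individual)
  form <- stats::as.formula(paste(
    "used ~ -1 +", paste(fe_terms, collapse = " + "),
    "+ (1 | stratum_f) + (0 + tri | individual_f) + (0 + dist_ridge | individual_f)"))
  fit_try <- tryCatch({
    m <- glmmTMB::glmmTMB(
      form, data = dat, family = stats::poisson(),
      map = list(theta = factor(c(NA, 1, 2))),
      start = list(theta = c(log(sqrt(stratum_variance)), 0, 0)))
    if (!is.null(m$fit$convergence) && m$fit$convergence != 0)
      stop("glmmTMB reported non-convergence")
    m
  }, error = function(e) e, warning = function(w) {
    m <- suppressWarnings(glmmTMB::glmmTMB(
      form, data = dat, family = stats::poisson(),
      map = list(theta = factor(c(NA, 1, 2))),
      start = list(theta = c(log(sqrt(stratum_variance)), 0, 0))))
    m
  })
  if (inherits(fit_try, "error")) {
    warning("mixed-model fit failed (", conditionMessage(fit_try),
            "); falling back to the fixed-effects conditional logit")
    out <- fit_conditional_logit(design)
    out$method <- "fixed_fallback"
    return(out)
  }
  m <- fit_try
  fe <- glmmTMB::fixef(m)$cond
  se_fe <- sqrt(diag(stats::vcov(m)$cond))
  vcs <- glmmTMB::VarCorr(m)$cond
  sd_tri <- attr(vcs[["individual_f"]], "stddev")[["tri"]]
  sd_dist <- attr(vcs[["individual_f.1"]], "stddev")[["dist_ridge"]]
  re <- glmmTMB::ranef(m)$cond$individual_f
  modes <- data.frame(
    individual_id = rownames(re),
    tri = if ("tri" %in% names(re)) re[["tri"]] else NA_real_,
    dist_ridge = if ("dist_ridge" %in% names(re)) re[["dist_ridge"]] else NA_real_)
  terms <- ssf_terms()
  coefs <- se <- setNames(rep(NA_real_, length(terms)), terms)
  coefs[names(fe)] <- fe
  se[names(fe)] <- se_fe[names(fe)]
  structure(list(
    coefficients = coefs, se = se,
    ci_lower = coefs - 1.96 * se, ci_upper = coefs + 1.96 * se,
    vcov = NULL, loglik = as.numeric(stats::logLik(m)), null_loglik = NA_real_,
    converged = TRUE, iterations = NA_integer_,
    dropped_terms = terms[!terms %in% names(fe)], n_strata = nlevels(dat$stratum_f),
    random_effects = list(sd_tri = sd_tri, sd_dist = sd_dist, modes = modes),
    method = "glmmTMB_poisson"),
    class = "ssf_fit")
}

#' Normalized RMSE of a step-selection fit
#'
#' Per-row predicted value = inverse logit of the fixed-effects linear
#' predictor (stratum effects omitted, random effects at the population
#' mean); RMSE against the 0/1 used indicator, normalized by the range of
#' the observed indicator (1), hence in [0, 1]. Lower is better.
#'
#' @param fit an `ssf_fit`.
#' @param strata the z-scored stratified dataset the fit was built from.
#' @return normalized RMSE.
#' @export
normalized_rmse <- function(fit, strata) {
  design <- build_design(strata)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred <- inv_logit(drop(design$X %*% beta[colnames(design$X)]))
  sqrt(mean((design$used - pred)^2)) / diff(range(design$used))
}
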