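# Pre-specified inference: random-intercept linear mixed models for the
# adjustment weight (maximum likelihood, two-tailed Wald tests), random-
# intercept logistic models for the stay/copy indicators (adaptive
# Gauss-Hermite quadrature), and the one-way ANOVA of wave-1 means across
# school years.

# direction x domain factor, reference level = extreme approval prosocial
dirdom_factor <- function(direction, domain) {
  lev <- c("extreme_prosocial", "extreme_risk", "moderate_risk",
           "moderate_prosocial")
  factor(paste(direction, domain, sep = "_"), levels = lev)
}

# assemble the model frame used by both model formulas
lmm_frame <- function(records) {
  check_columns(records, c("S", "block", "age_z", "participant",
                           "round_class"), "records")
  rec <- conform_only(records)
  data.frame(S = rec$S,
             source = as.integer(rec$block == "majority"),
             age_z = rec$age_z,
             dirdom = dirdom_factor(rec$direction, rec$domain),
             participant = rec$participant,
             stringsAsFactors = FALSE)
}

coef_table <- function(est, se) {
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_lo = unname(est - 1.96 * se), ci_hi = unname(est + 1.96 * se),
             p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Random-intercept linear mixed model of the adjustment weight
#'
#' Model 1: `S ~ source + age_z + source:age_z + (1 | participant)`;
#' model 2 adds the four-level direction-by-domain factor (reference:
#' extreme approval of prosocial behaviour). Fitted by maximum likelihood
#' (`lme4::lmer`, REML off). Only conform rounds (0 <= S <= 1) enter the
#' model. Wald 95% CIs (estimate +/- 1.96 SE) and two-tailed normal
#' p-values are reported; a singular fit (participant variance estimated on
#' the zero boundary) is flagged, not an error.
#'
#' @param records scored records carrying `S`, `block`, `age_z`,
#'   `direction`, `domain`, `participant`, `round_class`
#' @param model 1 (source x age) or 2 (adds direction-domain factor)
#' @return list of class `pn_model`: `coefficients` table, `varcomp`
#'   (participant-intercept and residual variance), `n_participants`,
#'   `n_obs`, `singular`, `logLik`, `fit` (the lmerMod object)
#' @export
fit_lmm <- function(records, model = 1) {
  df <- lmm_frame(records)
  if (length(unique(df$participant)) < 2) {
    stop("need at least 2 participants with conform rounds", call. = FALSE)
  }
  fml <- if (model == 1) {
    S ~ source * age_z + (1 | participant)
  } else {
    S ~ source * age_z + dirdom + (1 | participant)
  }
  fit <- lme4::lmer(fml, data = df, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coef_table(est, se),
                 varcomp = data.frame(
                   component = c("participant_intercept", "residual"),
                   variance = c(vc$vcov[vc$grp == "participant"],
                                vc$vcov[vc$grp == "Residual"])),
                 n_participants = length(unique(df$participant)),
                 n_obs = nrow(df),
                 singular = lme4::isSingular(fit),
                 converged = TRUE,
                 logLik = as.numeric(stats::logLik(fit)),
                 model = model,
                 fit = fit),
            class = "pn_model")
}

# --- logistic random-intercept model via adaptive Gauss-Hermite quadrature --

bernoulli_loglik <- function(eta, y) {
  # numerically safe log p(y | eta) for logit link
  -log1p(exp(-(2 * y - 1) * eta))
}

# per-group joint log density h(u) = log p(y | u) + log phi(u; 0, sigma^2)
# mode and curvature via Newton (concave in u, so this is safe)
group_mode <- function(u0, eta0, y, sigma) {
  u <- u0
  for (it in 1:50) {
    mu <- stats::plogis(eta0 + u)
    g <- sum(y - mu) - u / sigma^2
    h <- -sum(mu * (1 - mu)) - 1 / sigma^2
    step <- g / h
    u <- u - step
    if (abs(step) < 1e-10) break
  }
  mu <- stats::plogis(eta0 + u)
  list(mode = u, sd = 1 / sqrt(sum(mu * (1 - mu)) + 1 / sigma^2))
}

# marginal log-likelihood by adaptive GH quadrature (nodes centred and
# scaled at each group's Laplace mode)
logit_rim_loglik <- function(par, X, y, group, gh) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  sigma <- min(max(exp(par[k + 1]), 1e-6), 50)
  eta0 <- drop(X %*% beta)
  total <- 0
  for (g in levels(group)) {
    idx <- group == g
    mo <- group_mode(0, eta0[idx], y[idx], sigma)
    u_k <- mo$mode + sqrt(2) * mo$sd * gh$nodes
    logf <- vapply(u_k, function(u) {
      sum(bernoulli_loglik(eta0[idx] + u, y[idx])) +
        stats::dnorm(u, 0, sigma, log = TRUE)
    }, numeric(1))
    lw <- log(gh$weights) + gh$nodes^2 + logf
    m <- max(lw)
    total <- total + log(sqrt(2) * mo$sd) + m + log(sum(exp(lw - m)))
  }
  total
}

# sigma = 0 degenerate case: plain logistic log-likelihood
logit_loglik <- function(beta, X, y) {
  sum(bernoulli_loglik(drop(X %*% beta), y))
}

#' Random-intercept logistic model for a binary strategy indicator
#'
#' Maximum-likelihood fit of `logit P(y = 1) = X beta + u_participant`,
#' `u ~ N(0, sigma^2)`, with the participant intercept integrated out by
#' adaptive Gauss-Hermite quadrature (default 20 nodes, centred and scaled
#' at each participant's Laplace mode; refitted with 50 nodes if the
#' optimizer does not converge). Standard errors come from the numerical
#' Hessian of the log-likelihood at the optimum. Likely complete separation
#' (fixed effects running away) is flagged in the result.
#'
#' @param records scored records (conform rounds are used)
#' @param response `"stay"` or `"copy"`: the strategy indicator modelled
#' @param model 1 (`source * age_z`) or 2 (`source + direction-domain`)
#' @param nagq number of quadrature nodes
#' @param fix_sigma_zero if TRUE the random intercept is dropped and the
#'   model reduces to ordinary logistic regression (degenerate reference)
#' @return list of class `pn_model` with `coefficients`, `sigma_u`
#'   (random-intercept sd), `logLik`, `n_participants`, `n_obs`, flags
#'   `converged` and `separation`
#' @export
fit_logit_rim <- function(records, response = c("copy", "stay"), model = 1,
                          nagq = 20, fix_sigma_zero = FALSE) {
  response <- match.arg(response)
  df <- lmm_frame(records)
  rec <- conform_only(records)
  df$y <- as.integer(rec$strategy == response)
  X <- if (model == 1) {
    stats::model.matrix(~ source * age_z, df)
  } else {
    stats::model.matrix(~ source + dirdom, df)
  }
  y <- df$y
  group <- factor(df$participant)
  start_glm <- stats::glm.fit(X, y, family = stats::binomial())
  beta0 <- stats::coef(start_glm)
  beta0[!is.finite(beta0)] <- 0   # aliased columns (rank-deficient X)
  if (fix_sigma_zero) {
    opt <- stats::optim(beta0, function(b) -logit_loglik(b, X, y),
                        method = "BFGS", control = list(maxit = 500))
    H <- numDeriv::hessian(function(b) -logit_loglik(b, X, y), opt$par)
    se <- sqrt(diag(solve(H)))
    est <- stats::setNames(opt$par, colnames(X))
    return(structure(list(coefficients = coef_table(est, se),
                          sigma_u = 0, logLik = -opt$value,
                          n_participants = nlevels(group), n_obs = length(y),
                          converged = opt$convergence == 0,
                          separation = any(abs(est) > 10)),
                     class = "pn_model"))
  }
  fit_once <- function(nodes) {
    gh <- statmod::gauss.quad(nodes, kind = "hermite")
    negll <- function(p) {
      v <- -logit_rim_loglik(p, X, y, group, gh)
      if (!is.finite(v)) 1e10 else v   # keep BFGS line searches in range
    }
    opt <- stats::optim(c(beta0, log(0.5)), negll, method = "BFGS",
                        control = list(maxit = 1000))
    list(opt = opt, negll = negll)
  }
  res <- fit_once(nagq)
  if (res$opt$convergence != 0) res <- fit_once(50)
  par <- res$opt$par
  H <- numDeriv::hessian(res$negll, par)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(par),
                                                     length(par)))
  k <- ncol(X)
  se <- sqrt(diag(V))[seq_len(k)]
  est <- stats::setNames(par[seq_len(k)], colnames(X))
  structure(list(coefficients = coef_table(est, se),
                 sigma_u = exp(par[k + 1]),
                 logLik = -res$opt$value,
                 n_participants = nlevels(group),
                 n_obs = length(y),
                 converged = res$opt$convergence == 0,
                 separation = any(abs(est) > 10) || anyNA(se)),
            class = "pn_model")
}

#' One-way ANOVA of participant-level domain means across school years
#'
#' Each participant contributes one observation: their mean wave-1 rating
#' over the domain's items. With three school-year groups and N
#' participants the test has (2, N - 3) degrees of freedom.
#'
#' @param wave1 long wave-1 ratings
#' @param participants participant table with `id` and `school_year`
#' @param domain `"risk"` or `"prosocial"`
#' @return list: `F`, `df1`, `df2`, `MSE`, `p`, `group_means`; `F` is `Inf`
#'   (flagged `degenerate`) when the within-group variance is zero
#' @export
anova_by_year <- function(wave1, participants, domain) {
  check_columns(participants, c("id", "school_year"), "participants")
  w <- wave1[wave1$domain == domain, , drop = FALSE]
  pm <- tapply(w$rating, w$participant, mean)
  df <- data.frame(mean_rating = as.numeric(pm),
                   school_year = factor(participants$school_year[
                     match(names(pm), participants$id)]))
  if (anyNA(df$school_year)) stop("participants missing school_year",
                                  call. = FALSE)
  sizes <- table(df$school_year)
  if (length(sizes) < 2) stop("need at least 2 school-year groups",
                              call. = FALSE)
  if (any(sizes < 2)) stop("each school-year group needs >= 2 participants",
                           call. = FALSE)
  fit <- stats::aov(mean_rating ~ school_year, data = df)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  Fval <- tab[1, "F value"]
  degenerate <- !is.finite(Fval) || mse < 1e-12
  list(F = if (degenerate && mse < 1e-12) Inf else Fval,
       df1 = tab[1, "Df"], df2 = tab["Residuals", "Df"],
       MSE = mse,
       p = if (degenerate) 0 else tab[1, "Pr(>F)"],
       degenerate = degenerate,
       group_means = tapply(df$mean_rating, df$school_year, mean))
}

#' Formatted coefficient table of a fitted model
#'
#' One row per coefficient with the estimate, Wald 95% CI and two-tailed
#' p-value, ready for CSV export.
#'
#' @param result a `pn_model`
#' @param digits rounding applied to the printed columns
#' @return data frame: `term`, `estimate`, `ci_lo`, `ci_hi`, `p`
#' @export
wald_summary <- function(result, digits = 2) {
  ct <- result$coefficients
  if (is.null(ct) || nrow(ct) == 0) {
    return(data.frame(term = character(), estimate = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(), p = numeric()))
  }
  data.frame(term = ct$term,
             estimate = round(ct$estimate, digits),
             ci_lo = round(ct$ci_lo, digits),
             ci_hi = round(ct$ci_hi, digits),
             p = signif(ct$p, 2),
             stringsAsFactors = FALSE)
}

#' @export
print.pn_model <- function(x, ...) {
  cat("Random-intercept model (", x$n_obs, " obs, ", x$n_participants,
      " participants)\n", sep = "")
  print(x$coefficients, digits = 3)
  if (!is.null(x$varcomp)) print(x$varcomp, digits = 3)
  if (!is.null(x$sigma_u)) cat("sigma_u =", signif(x$sigma_u, 3), "\n")
  invisible(x)
}
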