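# Mixed-model inference: the linear random-intercept models, the logistic
# random-intercept model with its quadrature oracle, and the wave-1 ANOVA.

conform_levels <- c("conform", "anticonform", "overshoot", "filler")

test_that("constant responses give zero slopes and a flagged singular fit", {
  rec <- make_records(S = rep(0.4, 80),
                      participant = rep(paste0("p", 1:10), each = 8),
                      block = rep(c("popular", "majority"), 40),
                      age_z = rep(rnorm(10), each = 8))
  fit <- suppressWarnings(fit_lmm(rec, model = 1))  # degenerate: zero variance
  ct <- fit$coefficients
  expect_equal(ct$estimate[ct$term == "(Intercept)"], 0.4, tolerance = 1e-8)
  expect_true(all(abs(ct$estimate[ct$term != "(Intercept)"]) < 1e-8))
})

test_that("the LMM reduces to OLS when the intercept variance hits zero", {
  set.seed(3)
  n <- 12
  df <- data.frame(participant = rep(paste0("p", 1:n),
                                     times = rep(c(3, 5, 7, 4), 3)))
  df$block <- rep(c("popular", "majority"), length.out = nrow(df))
  df$direction <- "extreme"; df$domain <- "risk"
  df$age_z <- rnorm(n)[match(df$participant, paste0("p", 1:n))]
  df$S <- plogis(0.2 * rnorm(nrow(df)))    # no participant effect
  df$round_class <- factor("conform", levels = conform_levels)
  fit <- fit_lmm(df, model = 1)
  expect_true(fit$singular)                # variance estimated on boundary
  ols <- lm(S ~ I(as.integer(block == "majority")) * age_z, df)
  expect_lt(max(abs(fit$coefficients$estimate - coef(ols))), 1e-8)
})

test_that("age standardization is shift-invariant", {
  set.seed(14)
  n <- 20
  age <- runif(n, 12, 19)
  base <- make_records(S = runif(8 * n, 0.2, 0.8),
                       participant = rep(paste0("p", 1:n), each = 8),
                       block = rep(c("popular", "majority"), 4 * n),
                       age_z = rep(as.numeric(scale(age)), each = 8))
  shifted <- base
  shifted$age_z <- rep(as.numeric(scale(age + 7)), each = 8)
  f1 <- fit_lmm(base, 1)$coefficients$estimate
  f2 <- fit_lmm(shifted, 1)$coefficients$estimate
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("model recovery: source effect and CI coverage at study size", {
  # 100 simulated cohorts of 89 participants x 8 trials; generative source
  # effect 0.19, intercept sd 0.12, residual sd 0.25
  set.seed(101)
  beta <- 0.19
  ests <- ses <- numeric(100)
  for (r in 1:100) {
    n <- 89
    u <- rnorm(n, 0, 0.12)
    df <- data.frame(participant = rep(paste0("p", 1:n), each = 8),
                     block = rep(c("popular", "majority"), each = 4,
                                 times = n),
                     direction = "extreme", domain = "risk",
                     age_z = rep(rnorm(n), each = 8))
    df$S <- 0.47 + beta * (df$block == "majority") +
      u[match(df$participant, paste0("p", 1:n))] + rnorm(8 * n, 0, 0.25)
    df$round_class <- factor("conform", levels = conform_levels)
    fit <- fit_lmm(df, 1)
    ct <- fit$coefficients
    ests[r] <- ct$estimate[ct$term == "source"]
    ses[r] <- ct$se[ct$term == "source"]
  }
  expect_lt(abs(mean(ests) - beta), 0.02)
  coverage <- mean(abs(ests - beta) <= 1.96 * ses)
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})

test_that("logistic RIM matches a brute-force integration oracle", {
  set.seed(22)
  n <- 6
  rec <- make_records(S = rep(0.5, 6 * n),
                      participant = rep(paste0("p", 1:n), each = 6),
                      block = rep(c("popular", "majority"), 3 * n),
                      age_z = rep(rnorm(n), each = 6))
  u <- rnorm(n, 0, 0.8)
  eta <- -0.3 + 0.9 * (rec$block == "majority") +
    u[match(rec$participant, paste0("p", 1:n))]
  rec$strategy <- factor(ifelse(runif(6 * n) < plogis(eta), "copy", "stay"),
                         levels = c("stay", "compromise", "copy", "none"))
  fit <- fit_logit_rim(rec, response = "copy", model = 1, nagq = 20)
  # oracle: marginal likelihood by adaptive numerical integration, written
  # independently of the quadrature path
  X <- model.matrix(~ source * age_z,
                    data.frame(source = as.integer(rec$block == "majority"),
                               age_z = rec$age_z))
  beta <- fit$coefficients$estimate
  sigma <- fit$sigma_u
  y <- as.integer(rec$strategy == "copy")
  eta0 <- drop(X %*% beta)
  oracle <- 0
  for (g in paste0("p", 1:n)) {
    idx <- rec$participant == g
    f <- function(uu) {
      vapply(uu, function(v) {
        p <- plogis(eta0[idx] + v)
        prod(ifelse(y[idx] == 1, p, 1 - p)) * dnorm(v, 0, sigma)
      }, numeric(1))
    }
    oracle <- oracle + log(integrate(f, -Inf, Inf, rel.tol = 1e-12)$value)
  }
  expect_lt(abs(fit$logLik - oracle), 1e-6)
})

test_that("with the intercept variance fixed at zero the fit is plain logistic", {
  set.seed(23)
  n <- 10
  rec <- make_records(S = rep(0.5, 8 * n),
                      participant = rep(paste0("p", 1:n), each = 8),
                      block = rep(c("popular", "majority"), 4 * n),
                      age_z = rep(rnorm(n), each = 8))
  rec$strategy <- factor(sample(c("stay", "copy"), 8 * n, replace = TRUE),
                         levels = c("stay", "compromise", "copy", "none"))
  fit0 <- fit_logit_rim(rec, response = "copy", model = 1,
                        fix_sigma_zero = TRUE)
  glm_fit <- glm(I(strategy == "copy") ~ I(as.integer(block == "majority")) *
                   age_z, binomial, rec)
  expect_lt(max(abs(fit0$coefficients$estimate - coef(glm_fit))), 1e-4)
  expect_equal(fit0$sigma_u, 0)
})

test_that("higher majority copy-odds yield a positive source coefficient", {
  # sign consistency over seeded replicates (scaled down for runtime)
  set.seed(31)
  n <- 40
  hits <- 0L
  for (r in 1:20) {
    u <- rnorm(n, 0, 0.5)
    rec <- make_records(S = rep(0.5, 8 * n),
                        participant = rep(paste0("p", 1:n), each = 8),
                        block = rep(c("popular", "majority"), each = 4,
                                    times = n),
                        age_z = rep(rnorm(n), each = 8))
    eta <- -0.5 + 1.0 * (rec$block == "majority") +
      u[match(rec$participant, paste0("p", 1:n))]
    rec$strategy <- factor(ifelse(runif(8 * n) < plogis(eta), "copy", "stay"),
                           levels = c("stay", "compromise", "copy", "none"))
    fit <- fit_logit_rim(rec, response = "copy", model = 1, nagq = 10)
    ct <- fit$coefficients
    hits <- hits + (ct$estimate[ct$term == "source"] > 0)
  }
  expect_gte(hits, 19L)
})

test_that("the school-year ANOVA matches a hand-computed oracle", {
  # groups {1,2,3}, {2,3,4}, {3,4,5}: SSB = 6, MSB = 3, SSW = 6, MSW = 1
  w1 <- data.frame(participant = paste0("p", 1:9), domain = "risk",
                   rating = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
  parts <- data.frame(id = paste0("p", 1:9),
                      school_year = rep(c(1L, 3L, 5L), each = 3))
  a <- anova_by_year(w1, parts, "risk")
  expect_equal(a$F, 3)
  expect_equal(a$MSE, 1)
  expect_equal(c(a$df1, a$df2), c(2, 6))
  expect_equal(a$p, pf(3, 2, 6, lower.tail = FALSE))
})

test_that("ANOVA df are (2, 86) at the study sample size", {
  set.seed(5)
  w1 <- data.frame(participant = rep(paste0("p", 1:89), each = 2),
                   domain = "risk", rating = sample(1:5, 178, replace = TRUE))
  parts <- data.frame(id = paste0("p", 1:89),
                      school_year = rep(c(1L, 3L, 5L), length.out = 89))
  a <- anova_by_year(w1, parts, "risk")
  expect_equal(c(a$df1, a$df2), c(2, 86))
})

test_that("degenerate and underpowered ANOVA inputs are handled", {
  w1 <- data.frame(participant = paste0("p", 1:6), domain = "risk",
                   rating = rep(c(2, 3, 4), each = 2))
  parts <- data.frame(id = paste0("p", 1:6),
                      school_year = rep(c(1L, 3L, 5L), each = 2))
  a <- anova_by_year(w1, parts, "risk")   # zero within-group variance
  expect_true(a$degenerate)
  expect_true(is.infinite(a$F))
  parts2 <- data.frame(id = paste0("p", 1:6),
                       school_year = c(1L, 1L, 1L, 1L, 1L, 5L))
  expect_error(anova_by_year(w1, parts2, "risk"), ">= 2 participants")
})

test_that("wald_summary reproduces printed-CI arithmetic and symmetry", {
  m <- structure(list(coefficients = data.frame(
    term = "source", estimate = 0.1857, se = 0.02806,
    ci_lo = 0.1857 - 1.96 * 0.02806, ci_hi = 0.1857 + 1.96 * 0.02806,
    p = 2 * pnorm(-0.1857 / 0.02806))), class = "pn_model")
  ws <- wald_summary(m)
  expect_equal(ws$estimate, 0.19)
  expect_equal(c(ws$ci_lo, ws$ci_hi), c(0.13, 0.24))
  # two-tailed p symmetric in the sign of the estimate
  m_neg <- m
  m_neg$coefficients$estimate <- -m$coefficients$estimate
  m_neg$coefficients$p <- 2 * pnorm(-abs(-0.1857 / 0.02806))
  expect_equal(wald_summary(m_neg)$p, ws$p)
  empty <- structure(list(coefficients = NULL), class = "pn_model")
  expect_equal(nrow(wald_summary(empty)), 0L)
})
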