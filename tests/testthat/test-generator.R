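# Synthetic cohort generator: structure, determinism, calibration and the
# adjustment-weight mixture.

test_that("generate_classrooms meets the structural contract and is deterministic", {
  cfg <- generator_config(n_classrooms = 5, class_size_range = c(15, 25))
  cls <- generate_classrooms(cfg, seed = 1)
  expect_length(cls, 5)
  parts <- bind_participants(cls)
  expect_gte(nrow(parts), 75)
  expect_lte(nrow(parts), 125)
  for (cl in cls) {
    n <- nrow(cl$participants)
    expect_gte(n, 15); expect_lte(n, 25)
    expect_false(any(cl$nominations$nominator == cl$nominations$nominee))
    expect_true(all(cl$nominations$nominee %in% cl$participants$id))
    expect_equal(nrow(cl$nominations), n)  # one nomination per pupil
  }
  expect_true(all(parts$age >= 12 & parts$age <= 19))
  expect_true(all(parts$school_year %in% c(1L, 3L, 5L)))
  # monotone: older pupils never in a lower school year
  ord <- order(parts$age)
  expect_true(all(diff(parts$school_year[ord]) >= 0))
  expect_equal(generate_classrooms(cfg, seed = 1), cls)
})

test_that("extreme nomination concentration produces a star network", {
  cfg <- generator_config(nomination_concentration = 50)
  cls <- generate_classrooms(cfg, seed = 2)
  for (cl in cls) {
    counts <- table(cl$nominations$nominee)
    # everyone except the star nominates the star (the star picks runner-up)
    expect_gte(max(counts), nrow(cl$participants) - 1L)
  }
})

test_that("class sizes below 6 are rejected", {
  expect_error(generator_config(class_size_range = c(4, 5)), "majority")
})

test_that("wave-1 means are calibrated and degenerate noise collapses to a point", {
  cfg <- generator_config()
  cls <- generate_classrooms(cfg, seed = 7)
  ib <- generate_item_bank(cfg)
  w1 <- generate_wave1(cls, ib, cfg, seed = 7)
  expect_true(all(w1$rating >= 1 & w1$rating <= 11))
  expect_equal(nrow(w1), nrow(bind_participants(cls)) * cfg$n_items)
  pm <- aggregate(rating ~ participant + domain, w1, mean)
  risk <- pm$rating[pm$domain == "risk"]
  pros <- pm$rating[pm$domain == "prosocial"]
  n <- length(risk)
  # means within 3 standard errors of configured values
  expect_lt(abs(mean(risk) - cfg$risk_mean), 3 * cfg$risk_sd / sqrt(n) + 0.1)
  expect_lt(abs(mean(pros) - cfg$prosocial_mean),
            3 * cfg$prosocial_sd / sqrt(n) + 0.1)
  # marginal sds close to configured (age trend inflates risk slightly)
  expect_lt(abs(sd(pros) - cfg$prosocial_sd), 3 * cfg$prosocial_sd / sqrt(2 * n))
  expect_lt(sd(risk), cfg$risk_sd + 3 * cfg$risk_sd / sqrt(2 * n))

  cfg0 <- generator_config(risk_sd = 0, item_effect_sd = 0,
                           item_noise_sd = 0, risk_age_slope = 0)
  w0 <- generate_wave1(cls, ib, cfg0, seed = 1)
  expect_true(all(w0$rating[w0$domain == "risk"] == 3L))  # round(3.13)
})

test_that("risk approval rises with age; prosocial shows no age trend", {
  cfg <- generator_config()
  cls <- generate_classrooms(cfg, seed = 11)
  ib <- generate_item_bank(cfg)
  w1 <- generate_wave1(cls, ib, cfg, seed = 12)
  parts <- bind_participants(cls)
  pm <- aggregate(rating ~ participant + domain, w1, mean)
  pm$age_z <- parts$age_z[match(pm$participant, parts$id)]
  b_risk <- coef(lm(rating ~ age_z, pm[pm$domain == "risk", ]))[2]
  b_pros <- coef(lm(rating ~ age_z, pm[pm$domain == "prosocial", ]))[2]
  expect_gt(b_risk, 0.1)
  se <- cfg$prosocial_sd / sqrt(sum(pm$domain == "prosocial"))
  expect_lt(abs(b_pros), 3.5 * se)
})

test_that("adjustment-weight mixture has point masses and the analytic mean", {
  one_cell <- function(p_stay, p_copy, p_anti = 0, p_over = 0, m = 0.5,
                       prec = 20) {
    update_policy(data.frame(
      source = "majority", direction = "extreme", domain = "risk",
      p_stay = p_stay, p_copy = p_copy, p_anticonform = p_anti,
      p_overshoot = p_over, shape1 = m * prec, shape2 = (1 - m) * prec))
  }
  set.seed(5)
  expect_true(all(sample_adjustment_weight(
    one_cell(1, 0), "majority", "extreme", "risk", n = 100) == 0))
  expect_true(all(sample_adjustment_weight(
    one_cell(0, 1), "majority", "extreme", "risk", n = 100) == 1))
  # mixture mean oracle: 0.15*0 + 0.46*1 + 0.39*0.54 = 0.6706
  pol <- one_cell(0.15, 0.46, m = 0.54)
  s <- sample_adjustment_weight(pol, "majority", "extreme", "risk", n = 10000)
  expect_lt(abs(mean(s) - (0.46 + 0.39 * 0.54)), 0.02)
  expect_error(one_cell(0.7, 0.4), "exceed 1")
  expect_error(sample_adjustment_weight(pol, "popular", "extreme", "risk"),
               "no policy cell")
})

test_that("the update rule hits the stated grid points", {
  expect_equal(apply_update(3, 1, 1), 1)
  expect_equal(apply_update(3, 5, 0.5), 4)
  expect_equal(apply_update(9, 11, 0.5), 10)
})

test_that("round trip: scoring recovers drawn weights (exact / half-grid-step)", {
  set.seed(9)
  for (i in 1:200) {
    P1 <- sample(1:11, 1)
    NI <- sample(setdiff(1:11, P1), 1)
    S <- runif(1)
    P2c <- apply_update(P1, NI, S, integer_grid = FALSE)
    expect_equal(compute_adjustment(P1, P2c, NI), S, tolerance = 1e-12)
    P2i <- apply_update(P1, NI, S)
    expect_lte(abs(compute_adjustment(P1, P2i, NI) - S),
               1 / (2 * abs(NI - P1)) + 1e-12)
  }
})

test_that("simulate_wave2 is seed-deterministic and validates participants", {
  trials <- data.frame(participant = rep(c("p1", "p2"), each = 4),
                       block = "majority",
                       direction = rep(c("extreme", "moderate", "filler",
                                         "extreme"), 2),
                       domain = "risk", P1 = 3L,
                       NI = c(1L, 5L, 3L, 1L), stringsAsFactors = FALSE)
  parts <- data.frame(id = c("p1", "p2"), age_z = c(-1, 1))
  pol <- default_update_policy()
  a <- simulate_wave2(trials, parts, pol, seed = 4)
  b <- simulate_wave2(trials, parts, pol, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$P2 >= 1 & a$P2 <= 11))
  expect_true(all(is.na(a$S_drawn[a$direction == "filler"])))
  bad <- trials; bad$participant[1] <- "ghost"
  expect_error(simulate_wave2(bad, parts, pol, seed = 1), "unknown participant")
})

test_that("mixture limits propagate through the scoring pipeline", {
  cells <- expand.grid(source = c("popular", "majority"),
                       direction = c("extreme", "moderate"),
                       domain = c("risk", "prosocial"),
                       stringsAsFactors = FALSE)
  for (mode in c("stay", "copy")) {
    cells2 <- cbind(cells,
                    p_stay = as.numeric(mode == "stay"),
                    p_copy = as.numeric(mode == "copy"),
                    p_anticonform = 0, p_overshoot = 0,
                    shape1 = 1, shape2 = 1)
    pol <- update_policy(cells2)
    trials <- data.frame(participant = "p1", block = cells$source,
                         direction = cells$direction, domain = cells$domain,
                         P1 = ifelse(cells$domain == "risk", 3L, 9L),
                         NI = ifelse(cells$domain == "risk", 1L, 11L),
                         stringsAsFactors = FALSE)
    parts <- data.frame(id = "p1", age_z = 0)
    sim <- score_trials(simulate_wave2(trials, parts, pol, seed = 2))
    expect_true(all(sim$strategy == mode))
  }
})
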