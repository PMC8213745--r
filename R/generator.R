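# Synthetic cohort generator: classrooms, nomination networks, wave-1 ratings
# and simulated wave-2 responses. Defaults reproduce the structure of a
# five-classroom adolescent sample (N ~ 89, ages 12-19) rating 36 behaviours
# on an 11-point approval scale, half risk-taking and half prosocial.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the target population: 5 classrooms of 15-21 pupils,
#' ages truncated-normal(14.8, 2.1) on \[12, 19\], 36 items (18 risk-taking,
#' 18 prosocial), participant-level risk means around 3.13 (sd 0.97) with a
#' positive age trend (older adolescents less disapproving of risk), and
#' prosocial means around 8.45 (sd 0.98) with no age trend.
#'
#' `item_effect_sd` spreads item "difficulty" around the domain mean
#' (sum-to-zero within domain, so participant-level domain means stay
#' calibrated); without it every item in a domain would share one classroom
#' mode and the wave-2 design could not realise extreme-distance cues.
#' `item_noise_sd` is residual participant-by-item noise.
#'
#' @param n_classrooms number of classrooms
#' @param class_size_range integer c(min, max) pupils per classroom (min >= 6)
#' @param age_mean,age_sd,age_range truncated-normal age distribution (years)
#' @param n_items,n_risk_items item-bank size and its risk-domain count
#' @param risk_mean,risk_sd participant-level mean/sd of risk-item means
#' @param prosocial_mean,prosocial_sd same for prosocial items
#' @param risk_age_slope change in participant risk mean per sd of age
#' @param item_effect_sd sd of item-level offsets (centred within domain)
#' @param item_noise_sd sd of participant-by-item rating noise
#' @param nomination_concentration skew of the latent popularity weights
#'   (weights are `exp(concentration * z)`, z standard normal); larger values
#'   concentrate nominations on fewer pupils
#' @param update_policy an [update_policy()] governing wave-2 responses
#' @param seed optional integer seed recorded in the config
#' @return a list of class `pn_config`
#' @export
generator_config <- function(n_classrooms = 5,
                             class_size_range = c(15L, 21L),
                             age_mean = 14.8, age_sd = 2.1,
                             age_range = c(12, 19),
                             n_items = 36L, n_risk_items = 18L,
                             risk_mean = 3.13, risk_sd = 0.97,
                             prosocial_mean = 8.45, prosocial_sd = 0.98,
                             risk_age_slope = 0.45,
                             item_effect_sd = 1.0,
                             item_noise_sd = 1.1,
                             nomination_concentration = 1.5,
                             update_policy = default_update_policy(),
                             seed = NULL) {
  cfg <- list(n_classrooms = as.integer(n_classrooms),
              class_size_range = as.integer(class_size_range),
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              n_items = as.integer(n_items),
              n_risk_items = as.integer(n_risk_items),
              risk_mean = risk_mean, risk_sd = risk_sd,
              prosocial_mean = prosocial_mean, prosocial_sd = prosocial_sd,
              risk_age_slope = risk_age_slope,
              item_effect_sd = item_effect_sd,
              item_noise_sd = item_noise_sd,
              nomination_concentration = nomination_concentration,
              update_policy = update_policy,
              seed = seed)
  validate_generator_config(cfg)
  structure(cfg, class = "pn_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_classrooms >= 1,
            length(cfg$class_size_range) == 2,
            cfg$class_size_range[1] <= cfg$class_size_range[2],
            cfg$n_risk_items <= cfg$n_items,
            cfg$age_sd > 0, cfg$risk_sd >= 0, cfg$prosocial_sd >= 0,
            cfg$nomination_concentration > 0,
            cfg$item_effect_sd >= 0, cfg$item_noise_sd >= 0)
  if (cfg$class_size_range[1] < 6) {
    stop("class sizes below 6 cannot support a majority norm; increase class_size_range",
         call. = FALSE)
  }
  for (m in c(cfg$risk_mean, cfg$prosocial_mean)) {
    if (m < RATING_MIN || m > RATING_MAX) {
      stop("domain means must lie within the 1-11 rating scale", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Wave-2 response policy: mixture of updating strategies per condition cell
#'
#' A policy holds, for each cell of source (popular/majority) x direction
#' (extreme/moderate) x domain (risk/prosocial), the probabilities of the
#' qualitative responses to a normative cue: *stay* (S = 0), *copy* (S = 1),
#' *anticonformity* (S < 0), *overshoot* (S > 1), with the remaining mass a
#' Beta-distributed *compromise* weight in (0, 1). For majority cells the
#' compromise mean shifts by `age_slope_majority` per sd of age, emulating
#' the declining impact of the majority across adolescence.
#'
#' @param cells data frame with columns `source`, `direction`, `domain`,
#'   `p_stay`, `p_copy`, `p_anticonform`, `p_overshoot`, `shape1`, `shape2`
#' @param age_slope_majority shift in the majority-cell compromise mean per
#'   sd of age (negative: the majority's pull weakens with age)
#' @return a list of class `pn_policy`
#' @export
update_policy <- function(cells, age_slope_majority = 0) {
  check_columns(cells, c("source", "direction", "domain", "p_stay", "p_copy",
                         "p_anticonform", "p_overshoot", "shape1", "shape2"),
                "update policy cells")
  probs <- cells[c("p_stay", "p_copy", "p_anticonform", "p_overshoot")]
  if (any(unlist(probs) < 0) || any(unlist(probs) > 1)) {
    stop("policy probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(rowSums(probs) > 1 + 1e-12)) {
    stop("p_stay + p_copy + p_anticonform + p_overshoot must not exceed 1",
         call. = FALSE)
  }
  if (any(cells$shape1 <= 0 | cells$shape2 <= 0)) {
    stop("compromise Beta shapes must be positive", call. = FALSE)
  }
  structure(list(cells = cells, age_slope_majority = age_slope_majority),
            class = "pn_policy")
}

# Printed condition means the default policy is calibrated to:
# trial-level mean adjustment 0.47 (popular) / 0.67 (majority); direction x
# domain cell means 0.65 / 0.47 / 0.63 / 0.50 for extreme-risk /
# moderate-risk / extreme-prosocial / moderate-prosocial with observation
# counts 179 / 157 / 196 / 160; conform-round strategy shares 28/50/22
# (popular) and 15/39/46 (majority); 7% anticonformity and 5% overshoot
# overall.
PN_SOURCE_MEAN   <- c(popular = 0.47, majority = 0.67)
PN_CELL_MEAN     <- c(extreme.risk = 0.65, moderate.risk = 0.47,
                      extreme.prosocial = 0.63, moderate.prosocial = 0.50)
PN_CELL_N        <- c(extreme.risk = 179, moderate.risk = 157,
                      extreme.prosocial = 196, moderate.prosocial = 160)
PN_STRATEGY_MIX  <- list(popular  = c(stay = 0.28, compromise = 0.50, copy = 0.22),
                         majority = c(stay = 0.15, compromise = 0.39, copy = 0.46))
PN_P_ANTICONFORM <- 0.07
PN_P_OVERSHOOT   <- 0.05

#' Default update policy calibrated to the reported condition means
#'
#' Stay/copy probabilities per source follow the reported strategy mixtures;
#' each cell's compromise-Beta mean is solved so that the cell's expected
#' adjustment equals the source mean plus the direction-by-domain offset
#' around the grand mean. Anticonformity and overshoot occur at their
#' reported overall rates (7% and 5%). The Beta precision (shape1 + shape2)
#' defaults to 20, concentrating compromise weights near the cell mean so
#' that integer-grid rounding rarely relabels a compromise as stay or copy.
#'
#' @param age_slope_majority see [update_policy()]; default -0.07
#' @param precision Beta precision of the compromise distribution
#' @return a `pn_policy`
#' @export
default_update_policy <- function(age_slope_majority = -0.07, precision = 20) {
  grand <- sum(PN_CELL_MEAN * PN_CELL_N) / sum(PN_CELL_N)
  grid <- expand.grid(source = c("popular", "majority"),
                      direction = c("extreme", "moderate"),
                      domain = c("risk", "prosocial"),
                      stringsAsFactors = FALSE)
  conform <- 1 - PN_P_ANTICONFORM - PN_P_OVERSHOOT
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    src <- grid$source[i]
    cell <- paste(grid$direction[i], grid$domain[i], sep = ".")
    mix <- PN_STRATEGY_MIX[[src]]
    target <- PN_SOURCE_MEAN[[src]] + (PN_CELL_MEAN[[cell]] - grand)
    # conditional-on-conform cell mean = 0*stay + 1*copy + m*compromise
    m <- (target - mix[["copy"]]) / mix[["compromise"]]
    m <- min(max(m, 0.02), 0.98)
    data.frame(source = src, direction = grid$direction[i],
               domain = grid$domain[i],
               p_stay = mix[["stay"]] * conform,
               p_copy = mix[["copy"]] * conform,
               p_anticonform = PN_P_ANTICONFORM,
               p_overshoot = PN_P_OVERSHOOT,
               shape1 = m * precision, shape2 = (1 - m) * precision,
               stringsAsFactors = FALSE)
  })
  update_policy(do.call(rbind, rows), age_slope_majority = age_slope_majority)
}

#' Generate the item bank
#'
#' Items get placeholder labels; what matters downstream is the domain split
#' and the per-item offsets that differentiate classroom modes across items.
#'
#' @param config a [generator_config()]
#' @return data frame with columns `item`, `domain`, `label`
#' @export
generate_item_bank <- function(config) {
  n <- config$n_items
  nr <- config$n_risk_items
  domain <- c(rep("risk", nr), rep("prosocial", n - nr))
  data.frame(item = sprintf("item%02d", seq_len(n)),
             domain = domain,
             label = paste0(ifelse(domain == "risk", "risk behaviour ",
                                   "prosocial behaviour "),
                            c(seq_len(nr), seq_len(n - nr))),
             stringsAsFactors = FALSE)
}

#' Generate classrooms with popularity-nomination networks
#'
#' Ages are truncated-normal draws; each pupil nominates exactly one
#' classmate as "most popular", with nominee probability proportional to a
#' latent log-normal popularity weight so in-degree is right-skewed and a
#' clear top-five exists. School year (1/3/5) is assigned by global age
#' tertiles; `age_z` is the cohort-level z-score of age.
#'
#' @param config a [generator_config()]
#' @param seed optional integer; if given, the RNG is seeded
#' @return list of `pn_classroom` objects, each with elements `id`,
#'   `participants` (data frame) and `nominations` (nominator/nominee edges)
#' @export
generate_classrooms <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  size_choices <- seq(config$class_size_range[1], config$class_size_range[2])
  sizes <- if (length(size_choices) == 1) {
    rep(size_choices, config$n_classrooms)
  } else {
    sample(size_choices, config$n_classrooms, replace = TRUE)
  }
  all_parts <- list()
  nomin <- list()
  for (k in seq_len(config$n_classrooms)) {
    n <- sizes[k]
    cid <- sprintf("c%02d", k)
    ids <- sprintf("%s_p%02d", cid, seq_len(n))
    age <- rtruncnorm1(n, config$age_mean, config$age_sd,
                       config$age_range[1], config$age_range[2])
    gender <- sample(c("f", "m"), n, replace = TRUE, prob = c(0.66, 0.34))
    pop_w <- exp(config$nomination_concentration * stats::rnorm(n))
    nominee <- vapply(seq_len(n), function(i) {
      w <- pop_w
      w[i] <- 0                      # no self-nominations
      w <- w / max(w)                # overflow-safe at high concentration
      sample(ids, 1, prob = w)
    }, character(1))
    all_parts[[k]] <- data.frame(id = ids, classroom = cid, age = age,
                                 gender = gender, stringsAsFactors = FALSE)
    nomin[[k]] <- data.frame(nominator = ids, nominee = nominee,
                             stringsAsFactors = FALSE)
  }
  parts <- do.call(rbind, all_parts)
  parts$age_z <- as.numeric(scale(parts$age))
  tert <- stats::quantile(parts$age, c(1 / 3, 2 / 3))
  parts$school_year <- ifelse(parts$age <= tert[1], 1L,
                              ifelse(parts$age <= tert[2], 3L, 5L))
  lapply(seq_len(config$n_classrooms), function(k) {
    cid <- sprintf("c%02d", k)
    structure(list(id = cid,
                   participants = parts[parts$classroom == cid, , drop = FALSE],
                   nominations = nomin[[k]]),
              class = "pn_classroom")
  })
}

#' Bind the participant tables of a list of classrooms
#' @param classrooms list of `pn_classroom`
#' @return one data frame of participants
#' @export
bind_participants <- function(classrooms) {
  do.call(rbind, c(lapply(classrooms, `[[`, "participants"),
                   make.row.names = FALSE))
}

#' Generate wave-1 ratings
#'
#' Participant-level domain means are `domain_mean + slope * age_z + e`,
#' `e ~ N(0, domain_sd)` (slope zero for prosocial items). Item ratings are
#' the participant mean plus a sum-to-zero item offset plus noise, rounded
#' and clipped to the 1-11 grid. Floor/ceiling clipping biases observed
#' domain means slightly towards the scale centre (< 0.1 rating units at the
#' default calibration).
#'
#' @param classrooms from [generate_classrooms()]
#' @param item_bank from [generate_item_bank()]
#' @param config a [generator_config()]
#' @param seed optional RNG seed
#' @return long data frame: `participant`, `classroom`, `item`, `domain`,
#'   `rating` (integer 1-11), complete over participants x items
#' @export
generate_wave1 <- function(classrooms, item_bank, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parts <- bind_participants(classrooms)
  np <- nrow(parts)
  ni <- nrow(item_bank)
  item_eff <- stats::rnorm(ni, 0, config$item_effect_sd)
  for (d in unique(item_bank$domain)) {   # centre offsets within domain
    idx <- item_bank$domain == d
    item_eff[idx] <- item_eff[idx] - mean(item_eff[idx])
  }
  # latent domain locations compensate for floor/ceiling compression so the
  # observed participant-level means match the configured targets
  item_sd <- sqrt(config$item_effect_sd^2 + config$item_noise_sd^2)
  risk_loc <- latent_location(config$risk_mean,
                              sqrt(config$risk_sd^2 + item_sd^2))
  pro_loc <- latent_location(config$prosocial_mean,
                             sqrt(config$prosocial_sd^2 + item_sd^2))
  pmean_risk <- risk_loc + config$risk_age_slope * parts$age_z +
    stats::rnorm(np, 0, config$risk_sd)
  pmean_pro <- pro_loc + stats::rnorm(np, 0, config$prosocial_sd)
  pm <- ifelse(item_bank$domain[col(matrix(0, np, ni))] == "risk",
               pmean_risk[row(matrix(0, np, ni))],
               pmean_pro[row(matrix(0, np, ni))])
  latent <- pm + item_eff[col(matrix(0, np, ni))] +
    stats::rnorm(np * ni, 0, config$item_noise_sd)
  data.frame(participant = rep(parts$id, times = ni),
             classroom = rep(parts$classroom, times = ni),
             item = rep(item_bank$item, each = np),
             domain = rep(item_bank$domain, each = np),
             rating = as.integer(clip_rating(latent)),
             stringsAsFactors = FALSE)
}

#' Draw adjustment weights from a policy cell
#'
#' Returns, per draw: 0 with probability `p_stay`, 1 with `p_copy`, a value
#' in (-0.5, 0) with `p_anticonform`, in (1, 1.5) with `p_overshoot`, and
#' otherwise a Beta compromise weight in (0, 1). For majority-source cells
#' the compromise mean is shifted by `age_slope_majority * age_z` (Beta
#' precision preserved).
#'
#' @param policy a `pn_policy`
#' @param source,direction,domain cell coordinates
#' @param age_z standardized age, recycled to length `n`
#' @param n number of draws
#' @return numeric vector of adjustment weights S
#' @export
sample_adjustment_weight <- function(policy, source, direction, domain,
                                     age_z = 0, n = 1) {
  cells <- policy$cells
  row <- cells[cells$source == source & cells$direction == direction &
                 cells$domain == domain, , drop = FALSE]
  if (nrow(row) != 1) {
    stop(sprintf("no policy cell for (%s, %s, %s)", source, direction, domain),
         call. = FALSE)
  }
  age_z <- rep_len(age_z, n)
  u <- stats::runif(n)
  s <- numeric(n)
  p1 <- row$p_stay
  p2 <- p1 + row$p_copy
  p3 <- p2 + row$p_anticonform
  p4 <- p3 + row$p_overshoot
  s[u < p1] <- 0
  s[u >= p1 & u < p2] <- 1
  anti <- u >= p2 & u < p3
  s[anti] <- -stats::runif(sum(anti), 0, 0.5)
  over <- u >= p3 & u < p4
  s[over] <- 1 + stats::runif(sum(over), 0, 0.5)
  comp <- u >= p4
  if (any(comp)) {
    prec <- row$shape1 + row$shape2
    m <- row$shape1 / prec
    if (source == "majority" && policy$age_slope_majority != 0) {
      m_i <- pmin(pmax(m + policy$age_slope_majority * age_z[comp], 0.02), 0.98)
    } else {
      m_i <- rep(m, sum(comp))
    }
    s[comp] <- stats::rbeta(sum(comp), m_i * prec, (1 - m_i) * prec)
  }
  s
}

#' Apply the weighted-average update rule
#'
#' `P2 = (1 - S) * P1 + S * NI`, optionally rounded and clipped onto the
#' integer rating grid (the behaviour of a discrete 11-point slider).
#'
#' @param P1 initial rating
#' @param NI normative information shown
#' @param S adjustment weight
#' @param integer_grid round/clip onto the 1-11 integer grid?
#' @return the updated rating P2
#' @export
apply_update <- function(P1, NI, S, integer_grid = TRUE) {
  clip_rating((1 - S) * P1 + S * NI, integer_grid = integer_grid)
}

#' Simulate wave-2 responses for a built design
#'
#' Normative trials draw an adjustment weight from the policy cell of the
#' trial and apply [apply_update()]. Filler trials (NI = P1) get symmetric
#' integer jitter P(-1) = P(+1) = 0.4, P(0) = 0.2, emulating baseline rating
#' drift (expected absolute move 0.8).
#'
#' @param trials design data frame from [build_design()] (columns
#'   `participant`, `block`, `direction`, `domain`, `P1`, `NI`)
#' @param participants participant table carrying `id` and `age_z`
#' @param policy a `pn_policy`
#' @param seed optional RNG seed
#' @param integer_grid round responses onto the integer grid?
#' @return `trials` with columns `S_drawn` (NA for fillers) and `P2` added
#' @export
simulate_wave2 <- function(trials, participants, policy, seed = NULL,
                           integer_grid = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  check_columns(trials, c("participant", "block", "direction", "domain",
                          "P1", "NI"), "trials")
  unknown <- setdiff(trials$participant, participants$id)
  if (length(unknown)) {
    stop("trials reference unknown participant(s): ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  age_z <- participants$age_z[match(trials$participant, participants$id)]
  trials$S_drawn <- NA_real_
  trials$P2 <- NA_real_
  is_fill <- trials$direction == "filler"
  if (any(is_fill)) {
    jit <- sample(c(-1L, 0L, 1L), sum(is_fill), replace = TRUE,
                  prob = c(0.4, 0.2, 0.4))
    trials$P2[is_fill] <- clip_rating(trials$P1[is_fill] + jit)
  }
  norm_idx <- which(!is_fill)
  # draw cell by cell so each cell's mixture is sampled in one vectorized call
  key <- interaction(trials$block, trials$direction, trials$domain, drop = TRUE)
  for (cell in levels(key)) {
    idx <- norm_idx[key[norm_idx] == cell]
    if (!length(idx)) next
    parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
    s <- sample_adjustment_weight(policy, parts[1], parts[2], parts[3],
                                  age_z = age_z[idx], n = length(idx))
    trials$S_drawn[idx] <- s
    trials$P2[idx] <- apply_update(trials$P1[idx], trials$NI[idx], s,
                                   integer_grid = integer_grid)
  }
  trials
}
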