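# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small simulated population for structural tests (fast)
small_sim <- function() {
  cached("small_sim", simulate_regnn_data(n = 600, snr = c(5, 1), seed = 42))
}

# medium fit at low noise, used by convergence/consistency tests
medium_sim <- function() {
  cached("medium_sim", simulate_regnn_data(n = 2500, snr = 5, seed = 7))
}

medium_fit <- function() {
  cached("medium_fit", regnn(medium_sim(), snr = 5, epochs = 60, seed = 7))
}

# the full-scale replicate study backing the acceptance checks:
# reference conditions (n = 8000, MLP 35-60-32-1, 100 epochs, batch 50),
# five replicate seeds, full SNR grid
acceptance_study <- function() {
  cached("acceptance_study", {
    run_simulation_study(study_config(seeds = 1:5))
  })
}

# a dataset with a noiseless linear moderation structure:
# o = c0 + b1 x1 + cf xf + (a x1) xf, so M = a * x1 is linear in one input
linear_truth_data <- function(n = 600, a = 1, seed = 5) {
  set.seed(seed)
  tibble::tibble(
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
    xf = rnorm(n)
  ) |>
    dplyr::mutate(y = 1 + 0.5 * x1 - 0.2 * x2 + 0.3 * xf + (a * x1) * xf)
}

# synthetic survey-weighted cohort with the schema of an ageing-cohort
# application (demographics, health conditions, activity levels,
# area-level measures, survey weights); moderation planted on education
# and smoking
synthetic_cohort <- function(n = 1500, seed = 11) {
  set.seed(seed)
  df <- tibble::tibble(
    age = rnorm(n, 65, 10),
    female = rbinom(n, 1, 0.55),
    race_black = rbinom(n, 1, 0.15),
    race_hisp = rbinom(n, 1, 0.12),
    education = pmin(pmax(round(rnorm(n, 13, 3)), 0), 20),
    log_income = rnorm(n, 10.5, 0.9),
    ihs_wealth = rnorm(n, 4, 8),
    bmi = rnorm(n, 28, 6),
    stroke = rbinom(n, 1, 0.08),
    heart = rbinom(n, 1, 0.2),
    lung = rbinom(n, 1, 0.1),
    diabetes = rbinom(n, 1, 0.25),
    hypertension = rbinom(n, 1, 0.55),
    depression = rbinom(n, 1, 0.18),
    smoke_past = rbinom(n, 1, 0.4),
    smoke_current = rbinom(n, 1, 0.15),
    activity = sample(0:4, n, replace = TRUE),
    urban = rbinom(n, 1, 0.7),
    greenspace = runif(n, 0, 100),
    pm25 = rnorm(n, 8, 2),
    weight = exp(rnorm(n, 0, 0.5))
  )
  vuln <- with(df, 0.6 * (13 - education) / 3 + 0.8 * smoke_current +
                 0.4 * smoke_past + 0.4 * female - 0.2 * (greenspace - 50) / 50)
  df$cognition <- with(df, 16 - 0.08 * (age - 65) + 0.25 * (education - 13) +
                         0.5 * log_income - 0.15 * depression * 4 -
                         0.2 * pm25 - 0.8 * vuln * (pm25 - 8) +
                         rnorm(n, 0, 1.2))
  attr(df, "vulnerability") <- vuln
  df
}

cohort_moderators <- function() {
  c("age", "female", "race_black", "race_hisp", "education", "log_income",
    "ihs_wealth", "bmi", "stroke", "heart", "lung", "diabetes",
    "hypertension", "depression", "smoke_past", "smoke_current",
    "activity", "urban", "greenspace")
}
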