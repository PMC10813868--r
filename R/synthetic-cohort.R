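# Synthetic participants: covariate table with the marginal distributions
# (and the configurable age-WMH correlation) of the target cohort.

#' Generate a synthetic cohort
#'
#' Draws `n` participants with age from a truncated normal on the configured
#' interval, sex and CVD history Bernoulli, education and diabetes status
#' from categorical proportions, BMI normal, and relative WMH volume
#' log-normal calibrated to the configured median and quartiles. Age and
#' log10 WMH are correlated at `covariate_params$age_wmh_cor` (WMH burden
#' rises with age); all other covariates are generated mutually independent.
#'
#' The truncated-normal parent parameters for age are solved by moment
#' matching so that the *truncated* distribution has the configured mean and
#' SD (truncation otherwise shrinks the realized SD below its target).
#'
#' Coding conventions (also recorded in the `coding` attribute): sex
#' 0 = male / 1 = female; education ordinal 1 (low) to 3 (high); diabetes
#' status ordinal 0 (no diabetes), 1 (prediabetes), 2 (type 2 diabetes),
#' 3 (other type); CVD history 0/1; `wmh_rel` in % of intracranial volume.
#'
#' @param config a [qc_config()].
#' @return data.frame of `n` rows with columns `participant_id`, `age`,
#'   `sex`, `education`, `bmi`, `diabetes`, `cvd`, `wmh_rel`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "qc_config"))
  cp <- config$covariate_params
  n <- config$n
  if (n < 2) stop("need n >= 2 participants", call. = FALSE)
  with_seed(split_seed(config$seed, 1L), {
    age <- rtruncnorm_calibrated(n, cp$age$mean, cp$age$sd,
                                 cp$age$min, cp$age$max)
    sex <- rbinom(n, 1, cp$sex$p_female)
    education <- sample_categorical(n, cp$education$p, values = 1:3)
    bmi <- rnorm(n, cp$bmi$mean, cp$bmi$sd)
    diabetes <- sample_categorical(n, cp$diabetes$p, values = 0:3)
    cvd <- rbinom(n, 1, cp$cvd$p_yes)
    wmh <- rlognormal_quartiles(n, cp$wmh$median, cp$wmh$q25, cp$wmh$q75,
                                z_partner = age_zscore(age, cp$age),
                                rho = cp$age_wmh_cor)
    out <- data.frame(
      participant_id = sprintf("P%05d", seq_len(n)),
      age = age, sex = sex, education = education, bmi = bmi,
      diabetes = diabetes, cvd = cvd, wmh_rel = wmh,
      stringsAsFactors = FALSE
    )
    attr(out, "coding") <- c(
      sex = "0 = male, 1 = female",
      education = "1 = low, 2 = middle, 3 = high",
      diabetes = "0 = no diabetes, 1 = prediabetes, 2 = type 2, 3 = other",
      cvd = "0 = no, 1 = yes",
      wmh_rel = "% of intracranial volume (log10-transform before modelling)"
    )
    out
  })
}

# Moment-matched truncated normal: find parent (mu, sigma) whose truncation
# to [lo, hi] has the requested mean and sd, then sample by inverse CDF.
rtruncnorm_calibrated <- function(n, target_mean, target_sd, lo, hi) {
  if (target_mean < lo || target_mean > hi) {
    stop("age mean outside the truncation interval", call. = FALSE)
  }
  if (target_sd == 0) return(rep(target_mean, n))
  par <- truncnorm_parent(target_mean, target_sd, lo, hi)
  plo <- pnorm((lo - par$mu) / par$sigma)
  phi <- pnorm((hi - par$mu) / par$sigma)
  u <- runif(n, plo, phi)
  par$mu + par$sigma * qnorm(u)
}

truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (dnorm(a) - dnorm(b)) / z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                    ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = m, sd = sqrt(v))
}

truncnorm_parent <- function(target_mean, target_sd, lo, hi) {
  obj <- function(par) {
    mm <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (mm$mean - target_mean)^2 + (mm$sd - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  mm <- truncnorm_moments(fit$par[1], exp(fit$par[2]), lo, hi)
  if (abs(mm$mean - target_mean) > 0.05 * max(1, abs(target_mean)) ||
      abs(mm$sd - target_sd) > 0.05 * target_sd) {
    stop("requested truncated-normal mean/SD not attainable on [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# theoretical z-score of age under its truncated distribution
age_zscore <- function(age, age_par) {
  if (age_par$sd == 0) return(rep(0, length(age)))
  (age - age_par$mean) / age_par$sd
}

sample_categorical <- function(n, p, values) {
  stop_if_not_prob(p, "category proportions")
  p <- p / sum(p)
  values[1 + findInterval(runif(n), cumsum(p), left.open = TRUE)]
}

# log10-normal with the given median and quartiles; optionally correlated
# with a partner z-score (Gaussian copula on the log scale)
rlognormal_quartiles <- function(n, med, q25, q75, z_partner = NULL,
                                 rho = 0) {
  mu10 <- log10(med)
  sigma10 <- ((log10(q75 / med) + log10(med / q25)) / 2) / qnorm(0.75)
  if (sigma10 == 0) return(rep(med, n))
  eps <- rnorm(n)
  z <- if (!is.null(z_partner) && rho != 0) {
    rho * z_partner + sqrt(1 - rho^2) * eps
  } else {
    eps
  }
  10^(mu10 + sigma10 * z)
}

#' Read / write cohort and quality tables
#'
#' Plain CSV with a header row; column meanings as documented in
#' [generate_cohort()] and [generate_quality()].
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `read_cohort` returns a data.frame.
#' @export
write_cohort <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
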