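#' UCS response profile
#'
#' Generative description of the skin-conductance response to the aversive
#' UCS across the acquisition phase. UCS responses diminish across
#' acquisition; the profile models this as an exponential decay in the
#' reinforced-trial index with additive Gaussian noise, clamped at zero
#' (square-root amplitudes are non-negative by construction).
#'
#' @param initial_amplitude Expected UCS response on the first reinforced
#'   trial (sqrt-microsiemens, >= 0).
#' @param decay_rate Per-reinforced-trial exponential decay rate (>= 0).
#' @param noise_sd Trial-level Gaussian noise sd (sqrt-microsiemens, >= 0).
#' @return A list of class `"ucs_profile"`.
#' @export
ucs_profile <- function(initial_amplitude = 1.2, decay_rate = 0.12,
                        noise_sd = 0.1) {
  stopifnot(initial_amplitude >= 0, decay_rate >= 0, noise_sd >= 0)
  structure(list(initial_amplitude = initial_amplitude,
                 decay_rate = decay_rate, noise_sd = noise_sd),
            class = "ucs_profile")
}

#' Simulate UCS response amplitudes
#'
#' One value per reinforced trial of the conditioning phase, in presentation
#' order: `initial_amplitude * exp(-decay_rate * (j - 1)) + noise` at
#' reinforced-trial index `j`, clamped at 0.
#'
#' @param profile A [ucs_profile()].
#' @param schedule A [build_task_schedule()] schedule.
#' @param seed Integer seed.
#' @return Numeric vector, one amplitude per reinforced trial.
#' @export
simulate_ucs_responses <- function(profile, schedule, seed = 1L) {
  stopifnot(inherits(profile, "ucs_profile"))
  j <- seq_len(sum(schedule$reinforced))
  mu <- profile$initial_amplitude * exp(-profile$decay_rate * (j - 1))
  withr::with_seed(as.integer(seed), {
    pmax(mu + stats::rnorm(length(j), 0, profile$noise_sd), 0)
  })
}

#' Simulate one subject's trial series from a learning model
#'
#' Generative counterpart of [predict_series()] (the generator and the
#' fitter share the same forward model): observed SCR per CS trial equals the
#' model prediction plus Gaussian observation noise, clamped at 0. For models
#' 1-9 in conditioning, UCS amplitudes are drawn from `ucs` (or used as given
#' when `ucs` is numeric) and recorded alongside the series.
#'
#' @param model_id Model identifier (1-14).
#' @param params Named vector of the model's free parameters.
#' @param schedule A [build_task_schedule()] schedule.
#' @param ucs A [ucs_profile()] or a numeric vector of UCS amplitudes (one
#'   per reinforced trial).
#' @param v0 Initial associative strength (see [init_state()]).
#' @param obs_noise_sd Observation noise sd (sqrt-microsiemens).
#' @param seed Integer seed.
#' @param phase `"conditioning"` or `"extinction"`.
#' @param options See [model_options()].
#' @param subject_id Identifier stored in the output.
#' @return A data frame (one row per CS trial of the phase, in presentation
#'   order) with columns `subject_id`, `phase`, `cs`, `trial`, `scr`,
#'   `ucs_scr` (NA except reinforced trials) and `missing`.
#' @export
simulate_subject <- function(model_id, params, schedule, ucs = ucs_profile(),
                             v0 = 0.4, obs_noise_sd = 0.12, seed = 1L,
                             phase = c("conditioning", "extinction"),
                             options = model_options(), subject_id = "s1") {
  phase <- match.arg(phase)
  stopifnot(obs_noise_sd >= 0)
  ph <- phase_rows(schedule, phase)
  need_ucs <- model_id <= 9 && phase == "conditioning"
  withr::with_seed(as.integer(seed), {
    ucs_values <- NULL
    if (phase == "conditioning") {
      if (inherits(ucs, "ucs_profile")) {
        j <- seq_len(sum(ph$reinforced))
        mu <- ucs$initial_amplitude * exp(-ucs$decay_rate * (j - 1))
        ucs_values <- pmax(mu + stats::rnorm(length(j), 0, ucs$noise_sd), 0)
      } else if (is.numeric(ucs)) {
        ucs_values <- ucs
      } else if (need_ucs) {
        stop("`ucs` must be a ucs_profile or a numeric vector", call. = FALSE)
      }
    }
    pred <- predict_series(model_id, params, schedule, phase,
                           v0 = v0, ucs = ucs_values, options = options)
    scr <- if (obs_noise_sd > 0) {
      pmax(pred + stats::rnorm(length(pred), 0, obs_noise_sd), 0)
    } else {
      pred
    }
  })
  out <- data.frame(
    subject_id = subject_id, phase = ph$phase, cs = ph$cs, trial = ph$trial,
    scr = scr, ucs_scr = NA_real_, missing = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(ucs_values) && any(ph$reinforced)) {
    out$ucs_scr[ph$reinforced] <- ucs_values
  }
  out
}

# Subcortical structures (FreeSurfer-style segmentation), typical adult mean
# volumes in mm^3. Used by the cohort generator.
gmv_structure_means <- function() {
  c(amygdala_l = 1700, amygdala_r = 1750,
    hippocampus_l = 4100, hippocampus_r = 4200,
    thalamus_l = 7400, thalamus_r = 7300,
    ventraldc_l = 4100, ventraldc_r = 4200,
    caudate_l = 3600, caudate_r = 3700,
    putamen_l = 5200, putamen_r = 5100,
    pallidum_l = 1800, pallidum_r = 1750,
    accumbens_l = 620, accumbens_r = 600,
    brainstem = 21000)
}

#' Cohort design for the synthetic generator
#'
#' Defines the ground-truth statistical structure of a simulated cohort:
#' sample size, the generating learning model and its parameter
#' distributions, the planted standardized coupling between anxiety severity
#' and the true safety-learning rate, the planted gray-matter-volume (GMV)
#' moderation of that coupling (at one structure), trial-level observation
#' noise and missingness.
#'
#' For the default generating model (model 7, the study-type winner for
#' conditioning) the safety-learning rate is the CS- habituation rate
#' `phi_neg`; for models without habituation it is `alpha_neg`. Extinction
#' data are always generated from model 3 (learning-rate decay), with an
#' optional anxiety coupling on the CS- extinction rate.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param true_model_id Generating conditioning model (1-14).
#' @param param_distribution Named list: each element
#'   `list(mean =, sd =, lower =, upper =)` for one free parameter of the
#'   generating model. Defaults cover model 7.
#' @param anxiety_slope_on_safety_lr Standardized slope coupling anxiety to
#'   the latent (z-scale) true safety-learning rate.
#' @param gmv_moderation_slope Standardized anxiety-by-GMV interaction slope
#'   on the true safety-learning rate, planted at `moderation_structure`.
#' @param moderation_structure Structure carrying the planted moderation.
#' @param anxiety_slope_on_ext_safety Standardized anxiety slope on the true
#'   CS- extinction rate.
#' @param obs_noise_sd Observation noise sd per trial (sqrt-microsiemens).
#' @param missing_rate Per-trial missingness probability, in `[0, 1]`.
#' @param ucs A [ucs_profile()] (scaled per subject by an age-dependent
#'   amplitude factor).
#' @param seed Integer seed; cohorts are reproducible given the design.
#' @return A list of class `"cohort_design"`.
#' @export
cohort_design <- function(n_subjects = 200L, true_model_id = 7L,
                          param_distribution = NULL,
                          anxiety_slope_on_safety_lr = -0.3,
                          gmv_moderation_slope = 0.5,
                          moderation_structure = "accumbens_l",
                          anxiety_slope_on_ext_safety = -0.16,
                          obs_noise_sd = 0.12, missing_rate = 0.02,
                          ucs = ucs_profile(), seed = 1L) {
  stopifnot(n_subjects >= 1, missing_rate >= 0, missing_rate <= 1,
            obs_noise_sd >= 0,
            moderation_structure %in% names(gmv_structure_means()))
  spec <- model_spec(true_model_id)
  if (is.null(param_distribution)) {
    defaults <- list(
      alpha_pos = list(mean = 0.40, sd = 0.20, lower = 0.01, upper = 1),
      alpha_neg = list(mean = 0.30, sd = 0.15, lower = 0.01, upper = 1),
      phi_pos = list(mean = 0.30, sd = 0.20, lower = 0, upper = 2),
      phi_neg = list(mean = 0.35, sd = 0.25, lower = 0, upper = 2),
      gamma_pos = list(mean = 0.5, sd = 0.15, lower = 0, upper = 1),
      gamma_neg = list(mean = 0.5, sd = 0.15, lower = 0, upper = 1),
      kappa_pos = list(mean = 0.4, sd = 0.15, lower = 0.01, upper = 1),
      kappa_neg = list(mean = 0.3, sd = 0.12, lower = 0.01, upper = 1),
      beta0 = list(mean = 0.1, sd = 0.1, lower = -0.5, upper = 0.5),
      beta1 = list(mean = 0.8, sd = 0.3, lower = 0.1, upper = 2),
      beta2 = list(mean = 0.5, sd = 0.2, lower = 0.1, upper = 2)
    )
    param_distribution <- defaults[spec$params[[1]]]
  }
  stopifnot(setequal(names(param_distribution), spec$params[[1]]),
            all(vapply(param_distribution, function(d) d$sd >= 0, logical(1))))
  safety_param <- if ("phi_neg" %in% spec$params[[1]]) "phi_neg" else "alpha_neg"
  structure(list(
    n_subjects = as.integer(n_subjects), true_model_id = as.integer(true_model_id),
    param_distribution = param_distribution, safety_param = safety_param,
    anxiety_slope_on_safety_lr = anxiety_slope_on_safety_lr,
    gmv_moderation_slope = gmv_moderation_slope,
    moderation_structure = moderation_structure,
    anxiety_slope_on_ext_safety = anxiety_slope_on_ext_safety,
    obs_noise_sd = obs_noise_sd, missing_rate = missing_rate,
    ucs = ucs, seed = as.integer(seed)
  ), class = "cohort_design")
}

#' Simulate a synthetic cohort
#'
#' Generates a full cohort with the statistical structure the downstream
#' analyses assume: per-subject covariates (age, sex, anxiety z-score,
#' intracranial volume, subcortical GMV with ICV and sex effects), ground
#' truth learning parameters with the designed anxiety and GMV-moderation
#' couplings, pre-conditioning (habituation) responses, UCS responses
#' diminishing across acquisition, conditioning data from the design's
#' generating model, extinction data from model 3, trial-level observation
#' noise, and missingness. Ground-truth parameters are stored in the subject
#' table (`true_*` columns) for recovery tests. An age-dependent amplitude
#' factor scales each subject's responses (older subjects respond less).
#'
#' @param design A [cohort_design()].
#' @return A list of class `"threat_cohort"` with elements `trials` (one row
#'   per subject x trial; columns as in [simulate_subject()] plus
#'   `order_id`), `subjects` (covariates, GMV, `true_*` ground truth),
#'   `schedules` (counterbalance orders A and B) and `design`.
#' @examples
#' coh <- simulate_cohort(cohort_design(n_subjects = 20, seed = 7))
#' nrow(coh$subjects)
#' @export
simulate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_subjects
  schedules <- list(A = build_task_schedule("A", design$seed),
                    B = build_task_schedule("B", design$seed))
  sm <- gmv_structure_means()
  pd <- design$param_distribution
  b_anx <- design$anxiety_slope_on_safety_lr
  b_mod <- design$gmv_moderation_slope
  b_ext <- design$anxiety_slope_on_ext_safety

  withr::with_seed(design$seed + 1L, {
    age <- stats::runif(n, 8, 50)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    sex_c <- ifelse(sex == "M", 0.5, -0.5)
    anxiety_z <- stats::rnorm(n)
    group <- ifelse(stats::runif(n) < stats::plogis(1.5 * anxiety_z - 0.3),
                    "anxiety", "healthy")
    z_icv <- stats::rnorm(n)
    icv <- 1.45e6 * (1 + 0.09 * sex_c + 0.08 * z_icv)
    # structure GMV: shared ICV and sex loadings + a structure-specific
    # factor. The planted moderation lives on the structure-specific factor
    # of the target structure, i.e. on volume variation conditional on the
    # ICV/sex nuisance -- otherwise the "moderation" would partly be an
    # anxiety-by-ICV interaction shared by every structure.
    eps_g <- matrix(stats::rnorm(n * length(sm)), nrow = n,
                    dimnames = list(NULL, names(sm)))
    load_spec <- sqrt(1 - 0.45^2 - 0.15^2)
    zg <- 0.45 * z_icv + 0.3 * sex_c + load_spec * eps_g
    gmv <- sweep(1 + 0.09 * zg, 2, sm[colnames(zg)], "*")
    colnames(gmv) <- paste0("gmv_", names(sm))

    zg_mod <- eps_g[, design$moderation_structure]

    # ground-truth conditioning parameters
    true_par <- vapply(names(pd), function(p) {
      d <- pd[[p]]
      if (p == design$safety_param) {
        resid <- sqrt(max(0, 1 - b_anx^2))
        z <- b_anx * anxiety_z + b_mod * anxiety_z * zg_mod +
          resid * stats::rnorm(n)
      } else {
        z <- stats::rnorm(n)
      }
      pmin(pmax(d$mean + d$sd * z, d$lower), d$upper)
    }, numeric(n))
    true_par <- matrix(true_par, nrow = n, dimnames = list(NULL, names(pd)))

    # ground-truth extinction parameters (model 3)
    ext_pos <- pmin(pmax(0.35 + 0.12 * stats::rnorm(n), -1), 1)
    z_extneg <- b_ext * anxiety_z + sqrt(max(0, 1 - b_ext^2)) * stats::rnorm(n)
    ext_neg <- pmin(pmax(0.30 + 0.12 * z_extneg, -1), 1)

    amp <- exp(-0.012 * (age - 29)) * exp(stats::rnorm(n, 0, 0.15))
    order_id <- rep(c("A", "B"), length.out = n)

    trials <- vector("list", n)
    for (i in seq_len(n)) {
      sch <- schedules[[order_id[i]]]
      sid <- sprintf("s%03d", i)
      # pre-conditioning: orienting response habituating over presentations
      pre <- phase_rows(sch, "pre")
      pre_scr <- pmax(amp[i] * 0.7 * exp(-0.45 * (pre$trial - 1)) +
                        stats::rnorm(nrow(pre), 0, design$obs_noise_sd * amp[i]), 0)
      v0 <- pre_scr[length(pre_scr)]
      # UCS responses scaled by the subject's amplitude factor
      cond <- phase_rows(sch, "conditioning")
      j <- seq_len(sum(cond$reinforced))
      ucs_mu <- design$ucs$initial_amplitude * amp[i] *
        exp(-design$ucs$decay_rate * (j - 1))
      ucs_values <- pmax(ucs_mu + stats::rnorm(length(j), 0,
                                               design$ucs$noise_sd * amp[i]), 0)
      pred_c <- predict_series(design$true_model_id, true_par[i, ], sch,
                               "conditioning", v0 = v0, ucs = ucs_values)
      scr_c <- pmax(pred_c + stats::rnorm(length(pred_c), 0,
                                          design$obs_noise_sd * amp[i]), 0)
      # extinction starts from end-of-conditioning response level
      v0e <- mean(c(pred_c[cond$cs == "CS+"][sum(cond$cs == "CS+")],
                    pred_c[cond$cs == "CS-"][sum(cond$cs == "CS-")]))
      ext <- phase_rows(sch, "extinction")
      pred_e <- predict_series(3, c(alpha_pos = ext_pos[i], alpha_neg = ext_neg[i]),
                               sch, "extinction", v0 = v0e)
      scr_e <- pmax(pred_e + stats::rnorm(length(pred_e), 0,
                                          design$obs_noise_sd * amp[i]), 0)
      tr <- data.frame(
        subject_id = sid, order_id = order_id[i],
        phase = c(pre$phase, cond$phase, ext$phase),
        cs = c(pre$cs, cond$cs, ext$cs),
        trial = c(pre$trial, cond$trial, ext$trial),
        scr = c(pre_scr, scr_c, scr_e),
        ucs_scr = NA_real_, stringsAsFactors = FALSE
      )
      tr$ucs_scr[tr$phase == "conditioning"][cond$reinforced] <- ucs_values
      tr$missing <- stats::runif(nrow(tr)) < design$missing_rate
      tr$scr[tr$missing] <- NA_real_
      trials[[i]] <- tr
    }
    trials <- do.call(rbind, trials)

    subjects <- data.frame(
      subject_id = sprintf("s%03d", seq_len(n)), order_id = order_id,
      age = age, sex = sex, group = group, anxiety_z = anxiety_z,
      icv = icv, stringsAsFactors = FALSE
    )
    subjects <- cbind(subjects, as.data.frame(gmv))
    tp <- as.data.frame(true_par)
    names(tp) <- paste0("true_", names(tp))
    subjects <- cbind(subjects, tp)
    subjects$true_alpha_pos_ext <- ext_pos
    subjects$true_alpha_neg_ext <- ext_neg
    subjects$true_amp <- amp
  })
  rownames(trials) <- NULL
  structure(list(trials = trials, subjects = subjects,
                 schedules = schedules, design = design),
            class = "threat_cohort")
}

#' @export
print.threat_cohort <- function(x, ...) {
  cat("Synthetic threat-learning cohort: ", nrow(x$subjects), " subjects, ",
      nrow(x$trials), " trial rows (generating model ",
      x$design$true_model_id, ")\n", sep = "")
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` serializes a cohort to `trials.csv`, `subjects.csv` and
#' `schedules.json` in `dir`; `read_cohort()` reconstructs it.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Directory (created if absent).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a list
#'   with `trials`, `subjects` and `schedules`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "threat_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  sch <- lapply(cohort$schedules, function(s) {
    c(list(order_id = attr(s, "order_id")), as.list(as.data.frame(s)))
  })
  jsonlite::write_json(sch, file.path(dir, "schedules.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  raw <- jsonlite::read_json(file.path(dir, "schedules.json"), simplifyVector = TRUE)
  schedules <- lapply(raw, function(s) {
    df <- data.frame(phase = s$phase, cs = s$cs, trial = as.integer(s$trial),
                     reinforced = as.logical(s$reinforced),
                     stringsAsFactors = FALSE)
    attr(df, "order_id") <- s$order_id
    class(df) <- c("task_schedule", "data.frame")
    df
  })
  list(trials = trials, subjects = subjects, schedules = schedules)
}
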