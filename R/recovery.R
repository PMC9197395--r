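#' Default generating-parameter sampler for recovery simulations
#'
#' Uniform over plausible ranges: learning rates (`alpha_*`, `kappa_*`) in
#' `[0.05, 0.9]`, habituation and associability-update rates (`phi_*`,
#' `gamma_*`) in `[0, 1]`, `beta0` in `[-0.5, 0.5]`, `beta1` and `beta2` in
#' `[0.1, 2]`.
#'
#' @param model_id Model identifier.
#' @return A function `f(n)` returning an `n` x `k` matrix of parameter
#'   draws with the model's parameter names as columns.
#' @export
default_param_sampler <- function(model_id) {
  pnames <- model_spec(model_id)$params[[1]]
  function(n) {
    draws <- vapply(pnames, function(p) {
      r <- if (is_lr_param(p)) c(0.05, 0.9)
      else if (grepl("^(phi|gamma)_", p)) c(0, 1)
      else if (p == "beta0") c(-0.5, 0.5)
      else c(0.1, 2)
      stats::runif(n, r[1], r[2])
    }, numeric(n))
    matrix(draws, nrow = n, dimnames = list(NULL, pnames))
  }
}

# Build a fittable series around simulated phase observations: pre-phase
# rows anchor v(0) for conditioning fits.
assemble_series <- function(schedule, phase, scr, ucs_values, v0) {
  ph <- phase_rows(schedule, phase)
  out <- data.frame(subject_id = "sim", phase = ph$phase, cs = ph$cs,
                    trial = ph$trial, scr = scr, ucs_scr = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(ucs_values)) out$ucs_scr[ph$reinforced] <- ucs_values
  if (phase == "conditioning") {
    pre <- phase_rows(schedule, "pre")
    pre_df <- data.frame(subject_id = "sim", phase = pre$phase, cs = pre$cs,
                         trial = pre$trial, scr = v0, ucs_scr = NA_real_,
                         stringsAsFactors = FALSE)
    out <- rbind(pre_df, out)
  }
  out
}

#' Parameter recovery for one model
#'
#' Simulate-from-known, refit, correlate: draws `n_sim` parameter sets from
#' `sampler`, simulates a trial series from each (fresh UCS responses and
#' initial value per simulation, Gaussian observation noise clamped at 0),
#' refits with [fit_subject()], and reports the Pearson correlation between
#' generating and recovered values per parameter. A model is recoverable
#' when every parameter's correlation reaches the 0.20 criterion; an
#' undefined correlation (degenerate sampler or constant recovered values)
#' counts as a failure.
#'
#' @param model_id Model identifier.
#' @param schedule A [build_task_schedule()] schedule.
#' @param phase Fitted phase.
#' @param n_sim Number of simulations (>= 20).
#' @param noise_sd Observation noise sd; if `NULL`, set to `noise_frac`
#'   times the mean noiseless signal range across the drawn parameter sets.
#' @param noise_frac Fraction of the signal range used when `noise_sd` is
#'   `NULL` (default 0.25, "moderate noise").
#' @param seed Integer seed.
#' @param sampler Parameter sampler (default [default_param_sampler()]).
#' @param ucs A [ucs_profile()] for simulated UCS responses.
#' @param v0_range Range of the uniform draw for the generating initial
#'   value.
#' @param control,options Passed to [fit_subject()].
#' @return A list of class `"recovery_report"`: `model_id`, `correlations`
#'   (named, NA = undefined), `recoverable`, `n_sim`, `noise_sd`, `seed`,
#'   and `draws` (data frame of generating and recovered values).
#' @export
parameter_recovery <- function(model_id, schedule,
                               phase = c("conditioning", "extinction"),
                               n_sim = 100L, noise_sd = NULL,
                               noise_frac = 0.25, seed = 1L, sampler = NULL,
                               ucs = ucs_profile(), v0_range = c(0.1, 0.7),
                               control = fit_control(),
                               options = model_options()) {
  phase <- match.arg(phase)
  stopifnot(n_sim >= 20L)
  if (is.null(sampler)) sampler <- default_param_sampler(model_id)
  pnames <- model_spec(model_id)$params[[1]]
  need_ucs <- model_id <= 9 && phase == "conditioning"
  n_reinf <- sum(phase_rows(schedule, "conditioning")$reinforced)

  withr::with_seed(as.integer(seed), {
    gen <- sampler(n_sim)
    stopifnot(identical(colnames(gen), pnames))
    v0s <- stats::runif(n_sim, v0_range[1], v0_range[2])
    ucs_list <- vector("list", n_sim)
    preds <- vector("list", n_sim)
    for (i in seq_len(n_sim)) {
      uv <- NULL
      if (phase == "conditioning") {
        j <- seq_len(n_reinf)
        uv <- pmax(ucs$initial_amplitude * exp(-ucs$decay_rate * (j - 1)) +
                     stats::rnorm(n_reinf, 0, ucs$noise_sd), 0)
      }
      ucs_list[[i]] <- uv
      preds[[i]] <- predict_series(model_id, gen[i, ], schedule, phase,
                                   v0 = v0s[i], ucs = uv, options = options)
    }
    if (is.null(noise_sd)) {
      noise_sd <- noise_frac *
        mean(vapply(preds, function(p) diff(range(p)), numeric(1)))
    }
    rec <- matrix(NA_real_, n_sim, length(pnames),
                  dimnames = list(NULL, pnames))
    for (i in seq_len(n_sim)) {
      scr <- pmax(preds[[i]] + stats::rnorm(length(preds[[i]]), 0, noise_sd), 0)
      ser <- assemble_series(schedule, phase, scr,
                             if (need_ucs) ucs_list[[i]] else NULL, v0s[i])
      fit <- fit_subject(ser, schedule, model_id, phase,
                         control = control, options = options)
      rec[i, ] <- fit$params[pnames]
    }
  })
  cors <- vapply(pnames, function(p) {
    g <- gen[, p]; r <- rec[, p]
    if (stats::sd(g) < 1e-12 || stats::sd(r) < 1e-12) return(NA_real_)
    stats::cor(g, r)
  }, numeric(1))
  draws <- data.frame(gen, rec)
  names(draws) <- c(paste0("gen_", pnames), paste0("rec_", pnames))
  structure(list(
    model_id = model_id, phase = phase, correlations = cors,
    recoverable = all(!is.na(cors) & cors >= 0.20),
    n_sim = n_sim, noise_sd = noise_sd, seed = seed, draws = draws
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery, model ", x$model_id, " (", x$phase, "), ",
      x$n_sim, " simulations at noise sd ", signif(x$noise_sd, 3), ":\n",
      sep = "")
  print(round(x$correlations, 3))
  cat(if (x$recoverable) "recoverable" else "NOT recoverable",
      "at the 0.20 criterion\n")
  invisible(x)
}

#' Model recovery (confusion matrix)
#'
#' For each generating model in `model_subset`, simulates `n_sim_per_model`
#' datasets (parameters from each model's [default_param_sampler()]), fits
#' every model in the subset to each dataset, selects the best model per
#' dataset by BIC, and tallies generating-model by selected-model counts.
#'
#' @param model_subset Models to cross.
#' @param schedule A [build_task_schedule()] schedule.
#' @param phase Fitted phase.
#' @param n_sim_per_model Simulated datasets per generating model.
#' @param noise_sd Observation noise sd (numeric; no automatic scaling here
#'   so every generating model sees identical noise).
#' @param seed Integer seed.
#' @param ucs,v0_range,control,options As in [parameter_recovery()].
#' @return An integer matrix of class `"confusion_matrix"` (rows =
#'   generating model, columns = selected model; rows sum to
#'   `n_sim_per_model`).
#' @export
model_recovery <- function(model_subset, schedule,
                           phase = c("conditioning", "extinction"),
                           n_sim_per_model = 20L, noise_sd = 0.15, seed = 1L,
                           ucs = ucs_profile(), v0_range = c(0.1, 0.7),
                           control = fit_control(), options = model_options()) {
  phase <- match.arg(phase)
  cm <- matrix(0L, length(model_subset), length(model_subset),
               dimnames = list(generating = model_subset,
                               selected = model_subset))
  n_reinf <- sum(phase_rows(schedule, "conditioning")$reinforced)
  withr::with_seed(as.integer(seed), {
    for (gi in seq_along(model_subset)) {
      gm <- model_subset[gi]
      sampler <- default_param_sampler(gm)
      gen <- sampler(n_sim_per_model)
      for (i in seq_len(n_sim_per_model)) {
        v0 <- stats::runif(1, v0_range[1], v0_range[2])
        uv <- NULL
        if (phase == "conditioning") {
          j <- seq_len(n_reinf)
          uv <- pmax(ucs$initial_amplitude * exp(-ucs$decay_rate * (j - 1)) +
                       stats::rnorm(n_reinf, 0, ucs$noise_sd), 0)
        }
        pred <- predict_series(gm, gen[i, ], schedule, phase,
                               v0 = v0, ucs = uv, options = options)
        scr <- pmax(pred + stats::rnorm(length(pred), 0, noise_sd), 0)
        ser <- assemble_series(schedule, phase, scr, uv, v0)
        bics <- vapply(model_subset, function(m) {
          fit_subject(ser, schedule, m, phase,
                      control = control, options = options)$bic
        }, numeric(1))
        sel <- which.min(bics)
        cm[gi, sel] <- cm[gi, sel] + 1L
      }
    }
  })
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}
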