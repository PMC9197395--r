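#' Registry of the fourteen associative-learning model variants
#'
#' The model space couples a base Rescorla-Wagner (RW) rule -- CS+ value
#' updated by prediction errors on reinforced CS+ trials, CS- value updated
#' by the same errors (threat generalization) -- with optional features:
#' learning inertia (prediction errors summed over the `km` most recent
#' update events), Bayesian learning-rate decay (rate divided by the square
#' root of the update-event index), and multiplicative response habituation
#' beyond an onset trial `t0`. Models 9-12 are RW/Pearce-Hall hybrids with
#' adaptive associability; models 10-12 add a linear regression read-out and
#' use binary reinforcement; models 13-14 are Beta-Bernoulli uncertainty
#' models (conditioning only).
#'
#' @return A data frame with one row per model: `model_id`, `name`, feature
#'   flags (`inertia`, `decay`, `habituation`, `hybrid`, `readout`,
#'   `uncertainty`), `k` (number of free parameters), a list-column `params`
#'   of free-parameter names, and `phases` (`"both"` or `"conditioning"`).
#' @examples
#' model_registry()[, c("model_id", "name", "k")]
#' @export
model_registry <- function() {
  rw2 <- c("alpha_pos", "alpha_neg")
  rw4 <- c(rw2, "phi_pos", "phi_neg")
  hy4 <- c("gamma_pos", "gamma_neg", "kappa_pos", "kappa_neg")
  reg <- data.frame(
    model_id = 1:14,
    name = c(
      "RW", "RW+inertia", "RW+decay", "RW+habituation",
      "RW+inertia+decay", "RW+inertia+habituation", "RW+decay+habituation",
      "RW+inertia+decay+habituation", "RW-PH hybrid", "Hybrid(V)",
      "Hybrid(alpha)", "Hybrid(V+alpha)", "Uncertainty",
      "Uncertainty+habituation"
    ),
    inertia = 1:14 %in% c(2, 5, 6, 8),
    decay = 1:14 %in% c(3, 5, 7, 8),
    habituation = 1:14 %in% c(4, 6, 7, 8, 14),
    hybrid = 1:14 %in% 9:12,
    readout = c(rep("none", 9), "V", "alpha", "V+alpha", "z", "z"),
    uncertainty = 1:14 %in% 13:14,
    phases = c(rep("both", 12), "conditioning", "conditioning"),
    stringsAsFactors = FALSE
  )
  reg$params <- list(
    rw2, rw2, rw2, rw4, rw2, rw4, rw4, rw4, hy4,
    c(hy4, "beta0", "beta1"), c(hy4, "beta0", "beta1"),
    c(hy4, "beta0", "beta1", "beta2"),
    c("beta0", "beta1"), c("beta0", "beta1", "phi_pos", "phi_neg")
  )
  reg$k <- lengths(reg$params)
  reg
}

model_spec <- function(model_id) {
  reg <- model_registry()
  if (!is.numeric(model_id) || length(model_id) != 1L ||
      !(model_id %in% reg$model_id)) {
    stop("unknown model_id: ", model_id, call. = FALSE)
  }
  as.list(reg[reg$model_id == model_id, ])
}

check_params <- function(spec, params) {
  wanted <- spec$params[[1]]
  if (is.null(names(params)) || !setequal(names(params), wanted) ||
      anyDuplicated(names(params))) {
    stop(sprintf(
      "model %d expects parameters {%s}, got {%s}",
      spec$model_id, paste(wanted, collapse = ", "),
      paste(names(params), collapse = ", ")
    ), call. = FALSE)
  }
  params[wanted]
}

#' Forward-model options
#'
#' Population-level constants and sensitivity switches shared by the forward
#' model, the fitter, and the synthetic-data generator.
#'
#' @param km Learning-inertia window: prediction errors are summed over the
#'   current and the `km` preceding update events (fixed at 2 population-wide;
#'   `km = 0` reduces inertia models to their base counterparts).
#' @param t0 Habituation onset trial (within-phase, per CS); habituation is
#'   inactive on trials `t <= t0`. Fixed at 2 population-wide.
#' @param h_form Uncertainty-term form for models 13-14: `"literal"` uses
#'   `h = -ln(alpha_B + beta_B)` exactly as printed in the model table;
#'   `"variance"` uses the log of the Beta posterior variance.
#' @param hab_latent If `TRUE`, habituation multiplies the latent value used
#'   in subsequent updates as well as the emitted prediction (sensitivity
#'   switch; the default multiplies the emitted prediction only).
#' @return A list of options for `predict_series()` and `fit_subject()`.
#' @export
model_options <- function(km = 2L, t0 = 2L,
                          h_form = c("literal", "variance"),
                          hab_latent = FALSE) {
  stopifnot(km >= 0, t0 >= 0)
  list(km = as.integer(km), t0 = as.numeric(t0),
       h_form = match.arg(h_form), hab_latent = isTRUE(hab_latent))
}

#' Update-rule primitives
#'
#' Closed-form pieces of the learning models, exposed for testing and reuse:
#' the UCS prediction error, the inertia (accumulated) error, the Bayesian
#' learning-rate decay, the habituation multiplier, the Pearce-Hall
#' associability update, and the Beta-count update of the uncertainty model.
#'
#' @param r Observed UCS response amplitude (sqrt-microsiemens).
#' @param v Current CS+ associative strength.
#' @param delta_history Prediction errors ordered oldest to newest; the last
#'   element is the current trial's error.
#' @param km Inertia window (number of preceding errors included).
#' @param alpha Learning rate (for `decayed_rate`) or current associability
#'   (for `ph_update`).
#' @param t Update-event index (1-based) for `decayed_rate`; within-phase
#'   trial index for `habituation_factor`.
#' @param t0 Habituation onset trial.
#' @param phi Habituation rate (per trial, >= 0 in generative use).
#' @param delta Prediction error.
#' @param gamma Associability update rate.
#' @param a_count,b_count Beta pseudo-counts.
#' @param u Binary outcome (1 if the UCS occurred on the trial, else 0).
#' @name model-primitives
NULL

#' @rdname model-primitives
#' @export
prediction_error <- function(r, v) r - v

#' @rdname model-primitives
#' @export
inertia_error <- function(delta_history, km = 2L) {
  n <- length(delta_history)
  if (n == 0L) return(0)
  sum(delta_history[max(1L, n - km):n])
}

#' @rdname model-primitives
#' @export
decayed_rate <- function(alpha, t) {
  stopifnot(all(t >= 1))
  alpha / sqrt(t)
}

#' @rdname model-primitives
#' @export
habituation_factor <- function(t, t0 = 2L, phi = 0) {
  exp(-phi * pmax(t - t0, 0))
}

#' @rdname model-primitives
#' @export
ph_update <- function(alpha, delta, gamma) {
  gamma * abs(delta) + (1 - gamma) * alpha
}

#' @rdname model-primitives
#' @export
beta_update <- function(a_count, b_count, u) {
  stopifnot(u %in% c(0, 1))
  c(a = a_count + u, b = b_count - u + 1)
}

#' Initialize latent state for a model fit
#'
#' Both CS values start at `v_i`: the last (non-missing) pre-conditioning SCR
#' for conditioning fits, or the first (non-missing) extinction-phase SCR for
#' extinction fits. Pearce-Hall associabilities start at 1 per CS (models
#' 9-12) and the uncertainty models start from a flat Beta(1, 1) prior per CS
#' (models 13-14).
#'
#' @param model_id Model identifier (1-14).
#' @param series A trial series for one subject (see [simulate_subject()]);
#'   must contain the anchor trial for the requested phase.
#' @param schedule A [build_task_schedule()] schedule.
#' @param phase `"conditioning"` or `"extinction"`.
#' @return A list with `v0` (scalar), and, where applicable, `alpha_ph`
#'   (associability per CS) and `beta_counts` (per-CS Beta pseudo-counts).
#' @export
init_state <- function(model_id, series, schedule, phase = c("conditioning", "extinction")) {
  phase <- match.arg(phase)
  spec <- model_spec(model_id)
  if (spec$uncertainty && phase == "extinction") {
    stop("models 13-14 are defined for conditioning only: ",
         "with no UCS the uncertainty model would never update", call. = FALSE)
  }
  anchor_phase <- if (phase == "conditioning") "pre" else "extinction"
  x <- series$scr[series$phase == anchor_phase]
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    stop("no non-missing ", anchor_phase, "-phase SCR available to anchor v(0)",
         call. = FALSE)
  }
  v0 <- if (phase == "conditioning") x[length(x)] else x[1L]
  out <- list(v0 = v0)
  if (spec$hybrid) out$alpha_ph <- c(pos = 1, neg = 1)
  if (spec$uncertainty) {
    out$beta_counts <- list(pos = c(a = 1, b = 1), neg = c(a = 1, b = 1))
  }
  out
}

# Phase context shared by predict_series() and the fit objective:
# integer CS index (1 = CS+, 2 = CS-), within-phase per-CS trial index,
# reinforcement flags, in presentation order.
build_phase_ctx <- function(schedule, phase) {
  ph <- phase_rows(schedule, phase)
  list(
    n = nrow(ph),
    cs = ifelse(ph$cs == "CS+", 1L, 2L),
    tw = as.integer(ph$trial),
    reinf = ph$reinforced,
    phase = phase
  )
}

#' Trial-by-trial model predictions
#'
#' Iterates one of the fourteen learning models over the trials of a phase in
#' presentation order and returns the predicted SCR per CS trial.
#'
#' During conditioning, models 1-9 compute a prediction error
#' `delta = r(t) - v_CS+` only on reinforced CS+ trials, where `r(t)` is the
#' observed UCS response amplitude; both CS values are then updated
#' (`v_CS+ += lr_pos * delta`, `v_CS- += lr_neg * delta`, the latter carrying
#' threat generalization). Models 10-12 compute `delta = b - v_CS+` on every
#' CS+ trial with binary reinforcement `b`, and models 13-14 update per-CS
#' Beta counts on every trial of that CS. Habituation multiplies the emitted
#' prediction only (the latent value is updated unhabituated, unless
#' `options$hab_latent`). During extinction no UCS is delivered; each CS trial
#' generates an omission prediction error `delta = 0 - v_CS` that updates
#' that CS's value with its own learning rate, so responses decay (or grow,
#' for negative rates) through non-reinforcement.
#'
#' @param model_id Model identifier (1-14).
#' @param params Named numeric vector of exactly the model's free parameters
#'   (see [model_registry()]).
#' @param schedule A [build_task_schedule()] schedule.
#' @param phase `"conditioning"` or `"extinction"` (models 13-14:
#'   conditioning only).
#' @param v0 Initial associative strength for both CS (see [init_state()]).
#' @param ucs For models 1-9 in conditioning: numeric vector of UCS response
#'   amplitudes, one per reinforced trial in presentation order. Ignored
#'   otherwise.
#' @param options See [model_options()].
#' @return Numeric vector of predicted SCR, aligned with the phase's rows of
#'   `schedule`.
#' @examples
#' sch <- build_task_schedule("A", 1)
#' p <- predict_series(1, c(alpha_pos = 0.5, alpha_neg = 0.2), sch,
#'                     "conditioning", v0 = 0, ucs = rep(1, 8))
#' @export
predict_series <- function(model_id, params, schedule,
                           phase = c("conditioning", "extinction"),
                           v0, ucs = NULL, options = model_options()) {
  phase <- match.arg(phase)
  spec <- model_spec(model_id)
  if (spec$phases == "conditioning" && phase == "extinction") {
    stop("models 13-14 are defined for conditioning only: ",
         "with no UCS the uncertainty model would never update", call. = FALSE)
  }
  params <- check_params(spec, params)
  ctx <- build_phase_ctx(schedule, phase)
  if (model_id <= 9 && phase == "conditioning") {
    n_reinf <- sum(ctx$reinf)
    if (is.null(ucs) || length(ucs) != n_reinf) {
      stop("models 1-9 need `ucs`: one UCS amplitude per reinforced trial (",
           n_reinf, ")", call. = FALSE)
    }
  }
  predict_core(model_id, params, ctx, v0 = v0, ucs = ucs, opt = options)
}

# Shared forward model. `par` is a named vector already validated against the
# registry. Kept loop-scalar so a single 16-20 trial pass is cheap inside the
# fit objective.
predict_core <- function(model_id, par, ctx, v0, ucs, opt) {
  n <- ctx$n
  cs <- ctx$cs
  tw <- ctx$tw
  reinf <- ctx$reinf
  conditioning <- ctx$phase == "conditioning"
  pred <- numeric(n)

  if (model_id >= 13L) {
    aB <- c(1, 1)
    bB <- c(1, 1)
    b0 <- par[["beta0"]]
    b1 <- par[["beta1"]]
    hab <- model_id == 14L
    phi <- if (hab) c(par[["phi_pos"]], par[["phi_neg"]]) else c(0, 0)
    literal <- opt$h_form == "literal"
    for (i in seq_len(n)) {
      ci <- cs[i]
      s <- aB[ci] + bB[ci]
      h <- if (literal) -log(s) else log(aB[ci] * bB[ci] / (s * s * (s + 1)))
      if (hab) h <- h * exp(-phi[ci] * max(tw[i] - opt$t0, 0))
      pred[i] <- b0 + b1 * (h + aB[ci] / s)
      u <- if (ci == 1L && reinf[i]) 1 else 0
      aB[ci] <- aB[ci] + u
      bB[ci] <- bB[ci] - u + 1
    }
    return(pred)
  }

  hybrid <- model_id >= 9L
  inertia <- model_id %in% c(2L, 5L, 6L, 8L)
  decay <- model_id %in% c(3L, 5L, 7L, 8L)
  hab <- model_id %in% c(4L, 6L, 7L, 8L)
  readout <- if (model_id %in% 10:12) model_id - 9L else 0L  # 1=V, 2=alpha, 3=V+alpha

  v <- c(v0, v0)
  if (hybrid) {
    aph <- c(1, 1)
    kap <- c(par[["kappa_pos"]], par[["kappa_neg"]])
    gam <- c(par[["gamma_pos"]], par[["gamma_neg"]])
  } else {
    alp <- c(par[["alpha_pos"]], par[["alpha_neg"]])
  }
  phi <- if (hab) c(par[["phi_pos"]], par[["phi_neg"]]) else c(0, 0)
  if (readout > 0L) {
    b0 <- par[["beta0"]]
    b1 <- par[["beta1"]]
    b2 <- if (readout == 3L) par[["beta2"]] else 0
  }
  km <- opt$km
  dh <- numeric(0)       # conditioning: shared update-event error history
  dh_cs <- list(numeric(0), numeric(0))  # extinction: per-CS histories
  nup <- 0L
  nup_cs <- c(0L, 0L)
  ridx <- 0L

  for (i in seq_len(n)) {
    ci <- cs[i]
    # emit
    if (readout == 0L) {
      p <- v[ci]
      if (hab) {
        hf <- exp(-phi[ci] * max(tw[i] - opt$t0, 0))
        p <- v[ci] * hf
        if (opt$hab_latent) v[ci] <- p
      }
    } else {
      p <- switch(readout,
                  b0 + b1 * v[ci],
                  b0 + b1 * aph[ci],
                  b0 + b1 * v[ci] + b2 * aph[ci])
    }
    pred[i] <- p
    # update
    if (conditioning) {
      if (ci != 1L) next
      if (readout > 0L) {
        delta <- (if (reinf[i]) 1 else 0) - v[1L]
      } else if (reinf[i]) {
        ridx <- ridx + 1L
        delta <- ucs[ridx] - v[1L]
      } else {
        next
      }
      nup <- nup + 1L
      if (hybrid) {
        v[1L] <- v[1L] + kap[1L] * aph[1L] * delta
        v[2L] <- v[2L] + kap[2L] * aph[2L] * delta
        aph[1L] <- gam[1L] * abs(delta) + (1 - gam[1L]) * aph[1L]
        aph[2L] <- gam[2L] * abs(delta) + (1 - gam[2L]) * aph[2L]
      } else {
        dh[length(dh) + 1L] <- delta
        eff <- if (inertia) sum(dh[max(1L, length(dh) - km):length(dh)]) else delta
        sc <- if (decay) 1 / sqrt(nup) else 1
        v[1L] <- v[1L] + alp[1L] * sc * eff
        v[2L] <- v[2L] + alp[2L] * sc * eff
      }
    } else {
      delta <- -v[ci]
      nup_cs[ci] <- nup_cs[ci] + 1L
      if (hybrid) {
        v[ci] <- v[ci] + kap[ci] * aph[ci] * delta
        aph[ci] <- gam[ci] * abs(delta) + (1 - gam[ci]) * aph[ci]
      } else {
        h <- dh_cs[[ci]]
        h[length(h) + 1L] <- delta
        dh_cs[[ci]] <- h
        eff <- if (inertia) sum(h[max(1L, length(h) - km):length(h)]) else delta
        sc <- if (decay) 1 / sqrt(nup_cs[ci]) else 1
        v[ci] <- v[ci] + alp[ci] * sc * eff
      }
    }
  }
  pred
}
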