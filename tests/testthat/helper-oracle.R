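# Independent brute-force re-iteration of the printed update equations for
# models 1-8, used as the oracle for the package's forward model. Written as
# a direct transcription of the equations (explicit history slicing, per-CS
# bookkeeping), deliberately not sharing code with predict_series().
oracle_predict <- function(model_id, params, schedule, phase, v0,
                           ucs = NULL, km = 2, t0 = 2) {
  has_inertia <- model_id %in% c(2, 5, 6, 8)
  has_decay <- model_id %in% c(3, 5, 7, 8)
  has_hab <- model_id %in% c(4, 6, 7, 8)
  ph <- schedule[schedule$phase == phase, , drop = FALSE]
  vpos <- v0
  vneg <- v0
  hist_shared <- numeric(0)
  hist_pos <- numeric(0)
  hist_neg <- numeric(0)
  n_upd <- 0
  n_upd_pos <- 0
  n_upd_neg <- 0
  u <- 0
  out <- numeric(nrow(ph))
  window_sum <- function(h) sum(rev(h)[seq_len(min(km + 1, length(h)))])
  for (i in seq_len(nrow(ph))) {
    pos <- ph$cs[i] == "CS+"
    tt <- ph$trial[i]
    val <- if (pos) vpos else vneg
    if (has_hab) {
      phi <- if (pos) params[["phi_pos"]] else params[["phi_neg"]]
      val <- val * exp(-phi * max(tt - t0, 0))
    }
    out[i] <- val
    if (phase == "conditioning") {
      if (pos && ph$reinforced[i]) {
        u <- u + 1
        d <- ucs[u] - vpos
        hist_shared <- c(hist_shared, d)
        n_upd <- n_upd + 1
        eff <- if (has_inertia) window_sum(hist_shared) else d
        ap <- params[["alpha_pos"]]
        an <- params[["alpha_neg"]]
        if (has_decay) {
          ap <- ap / sqrt(n_upd)
          an <- an / sqrt(n_upd)
        }
        vpos <- vpos + ap * eff
        vneg <- vneg + an * eff
      }
    } else {
      if (pos) {
        d <- 0 - vpos
        hist_pos <- c(hist_pos, d)
        n_upd_pos <- n_upd_pos + 1
        eff <- if (has_inertia) window_sum(hist_pos) else d
        a <- params[["alpha_pos"]]
        if (has_decay) a <- a / sqrt(n_upd_pos)
        vpos <- vpos + a * eff
      } else {
        d <- 0 - vneg
        hist_neg <- c(hist_neg, d)
        n_upd_neg <- n_upd_neg + 1
        eff <- if (has_inertia) window_sum(hist_neg) else d
        a <- params[["alpha_neg"]]
        if (has_decay) a <- a / sqrt(n_upd_neg)
        vneg <- vneg + a * eff
      }
    }
  }
  out
}

# Random parameter draw for oracle comparisons.
random_rw_params <- function(model_id) {
  p <- c(alpha_pos = runif(1, 0.05, 0.9), alpha_neg = runif(1, 0.05, 0.9))
  if (model_id %in% c(4, 6, 7, 8)) {
    p <- c(p, phi_pos = runif(1, 0, 1), phi_neg = runif(1, 0, 1))
  }
  p
}
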