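#' Bayesian Information Criterion under a Gaussian residual model
#'
#' Computes `BIC = -k * ln(n) + n * ln(variance)`, the form used throughout
#' this pipeline, where `variance` is the mean squared residual (`rss / n`).
#' Note the sign of the complexity term: as written, additional parameters
#' *lower* the criterion by `ln(n)` each. `convention = "standard"` flips it
#' to the conventional `+k * ln(n)` penalty for sensitivity analyses.
#'
#' @param k Number of free parameters.
#' @param n Number of fitted data points.
#' @param variance Mean squared residual (> 0; values at or below zero are
#'   floored at a machine-epsilon scale with a warning).
#' @param convention `"reward"` (default: the complexity-rewarding form above) or `"standard"`.
#' @return The criterion value (lower is better under either convention).
#' @examples
#' compute_bic(2, 20, 1)       # -2 * log(20)
#' compute_bic(4, 20, 0.5)
#' @export
compute_bic <- function(k, n, variance, convention = c("reward", "standard")) {
  convention <- match.arg(convention)
  stopifnot(n >= 1, k >= 0)
  if (variance <= 0) {
    warning("non-positive residual variance floored at machine-epsilon scale")
    variance <- .Machine$double.eps
  }
  pen <- if (convention == "reward") -k * log(n) else k * log(n)
  pen + n * log(variance)
}

#' Fitting control parameters
#'
#' @param restarts Initial values for the learning-rate grid; one
#'   derivative-free simplex (Nelder-Mead) run is started per value, with
#'   every learning-rate-type parameter (`alpha_*`, `kappa_*`; `beta1` for
#'   the uncertainty models, which have no learning rate) set to that value.
#'   Other parameters start at `phi = 0.1`, `gamma = 0.5`, `beta0 = 0`,
#'   `beta1 = 1`, `beta2 = 0`.
#' @param maxit Maximum objective evaluations per restart.
#' @param reltol Relative convergence tolerance on the SSE.
#' @return A list of control settings for [fit_subject()].
#' @export
fit_control <- function(restarts = seq(0.1, 0.8, by = 0.1),
                        maxit = 2000L, reltol = 1e-8) {
  list(restarts = restarts, maxit = as.integer(maxit), reltol = reltol)
}

# Parameter classes used for start values and extinction bounds.
is_lr_param <- function(nm) grepl("^(alpha|kappa)_", nm)

start_vector <- function(param_names, g, model_id) {
  st <- vapply(param_names, function(p) {
    if (is_lr_param(p)) g
    else if (grepl("^phi_", p)) 0.1
    else if (grepl("^gamma_", p)) 0.5
    else if (p == "beta0") 0
    else if (p == "beta1") { if (model_id >= 13) g else 1 }
    else 0  # beta2
  }, numeric(1))
  names(st) <- param_names
  st
}

#' Fit one learning model to one subject's trial series
#'
#' Minimizes the sum of squared differences between model-predicted and
#' observed SCR over the model's free parameters, by Nelder-Mead simplex
#' search restarted from a grid of learning-rate initial values in
#' `[0.1, 0.8]`; the restart with the lowest SSE wins, with ties (SSE within
#' tolerance) broken toward the smallest parameter norm. Conditioning fits
#' are unconstrained. Extinction fits constrain learning-rate parameters to
#' `[-1, +1]` by clipping inside the objective; a parameter whose
#' unconstrained optimum lies outside is returned at the bound with its
#' `pinned_at_bound` flag set. Non-convergence across all restarts is
#' reported in the result, not raised.
#'
#' For models 1-9 in conditioning, the observed UCS response amplitudes
#' (`ucs_scr` on reinforced trials) provide the reinforcement term; the
#' initial value `v(0)` is anchored per [init_state()].
#'
#' @param series One subject's trial data frame (needs the fitted phase and,
#'   for conditioning, the pre-conditioning anchor trials).
#' @param schedule The subject's [build_task_schedule()] schedule.
#' @param model_id Model identifier (1-14).
#' @param phase `"conditioning"` or `"extinction"`.
#' @param control See [fit_control()].
#' @param options See [model_options()].
#' @return A list of class `"fit_result"`: `model_id`, `phase`, `params`
#'   (named, bounds applied), `rss`, `n`, `k`, `variance` (`rss/n`), `bic`,
#'   `predicted`, `observed`, `converged`, `pinned_at_bound` (named
#'   logical), `n_restarts`, `subject_id`, `v0`.
#' @export
fit_subject <- function(series, schedule, model_id,
                        phase = c("conditioning", "extinction"),
                        control = fit_control(), options = model_options()) {
  phase <- match.arg(phase)
  spec <- model_spec(model_id)
  if (spec$phases == "conditioning" && phase == "extinction") {
    stop("models 13-14 are defined for conditioning only: ",
         "with no UCS the uncertainty model would never update", call. = FALSE)
  }
  ctx <- build_phase_ctx(schedule, phase)
  ph <- phase_rows(schedule, phase)
  key <- paste(ph$cs, ph$trial)
  skey <- paste(series$cs, series$trial)[series$phase == phase]
  idx <- match(key, skey)
  if (anyNA(idx)) stop("series does not cover the scheduled ", phase,
                       " trials", call. = FALSE)
  obs <- series$scr[series$phase == phase][idx]
  fit_mask <- !is.na(obs)
  n <- sum(fit_mask)
  if (n < spec$k + 1L) {
    stop("too few non-missing trials (", n, ") to fit model ", model_id,
         call. = FALSE)
  }
  ucs <- NULL
  if (model_id <= 9 && phase == "conditioning") {
    ucs <- series$ucs_scr[series$phase == phase][idx][ctx$reinf]
    if (anyNA(ucs)) stop("missing UCS response amplitudes on reinforced trials",
                         call. = FALSE)
  }
  v0 <- init_state(model_id, series, schedule, phase)$v0
  pnames <- spec$params[[1]]
  clip <- phase == "extinction"
  lr <- is_lr_param(pnames)

  objective <- function(par) {
    names(par) <- pnames
    if (clip) par[lr] <- pmin(pmax(par[lr], -1), 1)
    pred <- predict_core(model_id, par, ctx, v0 = v0, ucs = ucs, opt = options)
    if (!all(is.finite(pred))) return(1e12)
    sum((pred[fit_mask] - obs[fit_mask])^2)
  }

  best <- NULL
  any_conv <- FALSE
  for (g in control$restarts) {
    st <- start_vector(pnames, g, model_id)
    opt <- stats::optim(st, objective, method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    any_conv <- any_conv || opt$convergence == 0L
    cand <- list(par = opt$par, sse = opt$value,
                 converged = opt$convergence == 0L)
    if (is.null(best) || cand$sse < best$sse - 1e-9 ||
        (abs(cand$sse - best$sse) <= 1e-9 &&
         sum(cand$par^2) < sum(best$par^2))) {
      best <- cand
    }
  }
  raw <- best$par
  names(raw) <- pnames
  params <- raw
  pinned <- stats::setNames(rep(FALSE, length(pnames)), pnames)
  if (clip) {
    pinned[lr] <- raw[lr] < -1 | raw[lr] > 1
    params[lr] <- pmin(pmax(raw[lr], -1), 1)
  }
  pred <- predict_core(model_id, params, ctx, v0 = v0, ucs = ucs, opt = options)
  rss <- sum((pred[fit_mask] - obs[fit_mask])^2)
  variance <- rss / n
  structure(list(
    subject_id = series$subject_id[1], model_id = model_id, phase = phase,
    params = params, rss = rss, n = n, k = spec$k, variance = variance,
    bic = compute_bic(spec$k, n, variance),
    predicted = pred, observed = obs, converged = best$converged,
    any_restart_converged = any_conv,
    pinned_at_bound = pinned, n_restarts = length(control$restarts), v0 = v0
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model ", x$model_id, " fit (", x$phase, "): rss = ",
      signif(x$rss, 4), ", BIC = ", signif(x$bic, 5), "\n", sep = "")
  print(signif(x$params, 4))
  invisible(x)
}

#' Fit a set of models to every subject in a cohort
#'
#' @param trials Cohort trial table (cleaned; see [clean_cohort()]).
#' @param schedules Named list of schedules keyed by counterbalance order
#'   (as in [simulate_cohort()]`$schedules`), or a single schedule used for
#'   all subjects.
#' @param model_ids Models to fit.
#' @param phase `"conditioning"` or `"extinction"`.
#' @param control,options Passed to [fit_subject()].
#' @return A data frame with one row per subject x model: `subject_id`,
#'   `model_id`, `phase`, `rss`, `n`, `k`, `bic`, `converged`, `any_pinned`,
#'   and one column per parameter (NA where a model lacks it).
#' @export
fit_cohort <- function(trials, schedules, model_ids,
                       phase = c("conditioning", "extinction"),
                       control = fit_control(), options = model_options()) {
  phase <- match.arg(phase)
  single <- inherits(schedules, "task_schedule")
  ids <- unique(trials$subject_id)
  all_params <- unique(unlist(model_registry()$params[model_ids]))
  rows <- vector("list", length(ids) * length(model_ids))
  r <- 0L
  for (id in ids) {
    s <- trials[trials$subject_id == id, , drop = FALSE]
    sch <- if (single) schedules else schedules[[s$order_id[1]]]
    for (m in model_ids) {
      fit <- fit_subject(s, sch, m, phase, control = control, options = options)
      row <- data.frame(subject_id = id, model_id = m, phase = phase,
                        rss = fit$rss, n = fit$n, k = fit$k, bic = fit$bic,
                        converged = fit$converged,
                        any_pinned = any(fit$pinned_at_bound),
                        stringsAsFactors = FALSE)
      for (p in all_params) row[[p]] <- unname(fit$params[p])
      r <- r + 1L
      rows[[r]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Paired t-test p-value that treats identically-distributed (zero-variance
# difference) pairs as indistinguishable (p = 1) rather than NaN.
paired_p <- function(a, b) {
  d <- a - b
  if (stats::sd(d) < 1e-12 || length(d) < 2L) return(list(t = 0, p = 1))
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Population-level model comparison on BIC
#'
#' Summarizes per-subject BIC values across models: mean and standard error
#' per model, the fraction of subjects best fit by each model, a
#' repeated-measures ANOVA on BIC (model fixed, subject random), and
#' Bonferroni-corrected pairwise paired t-tests. The winning model is the
#' best-scoring (lowest mean BIC) model, except that when a simpler model
#' (fewer free parameters) does not differ significantly from the top model
#' after correction, the simplest such model is preferred.
#'
#' @param fits A [fit_cohort()] data frame (columns `subject_id`,
#'   `model_id`, `bic`).
#' @param model_subset Models to compare (default: all present). Every
#'   subject must have a fit for every compared model.
#' @param alpha Significance level for the tie rule.
#' @return A list of class `"model_comparison"`: `table` (per-model summary),
#'   `anova` (`F`, `df1`, `df2`, `p`), `pairwise` (per-pair `t`, `p`,
#'   `p_adj`), and `winning_model_id`.
#' @export
compare_models <- function(fits, model_subset = NULL, alpha = 0.05) {
  if (is.null(model_subset)) model_subset <- sort(unique(fits$model_id))
  fits <- fits[fits$model_id %in% model_subset, , drop = FALSE]
  ids <- sort(unique(fits$subject_id))
  if (length(model_subset) < 2L || length(ids) < 2L) {
    stop("model comparison needs at least 2 models and 2 subjects", call. = FALSE)
  }
  bic <- matrix(NA_real_, length(ids), length(model_subset),
                dimnames = list(ids, model_subset))
  bic[cbind(match(fits$subject_id, ids),
            match(fits$model_id, model_subset))] <- fits$bic
  if (anyNA(bic)) stop("every subject needs a fit for every compared model",
                       call. = FALSE)
  reg <- model_registry()
  k <- reg$k[match(model_subset, reg$model_id)]
  best <- model_subset[apply(bic, 1, which.min)]
  tab <- data.frame(
    model_id = model_subset, k = k,
    mean_bic = colMeans(bic),
    se_bic = apply(bic, 2, stats::sd) / sqrt(length(ids)),
    best_fraction = as.numeric(table(factor(best, levels = model_subset))) /
      length(ids)
  )
  rownames(tab) <- NULL
  # repeated-measures ANOVA: model fixed, subject random
  long <- data.frame(
    bic = as.vector(bic),
    subject = factor(rep(ids, times = length(model_subset))),
    model = factor(rep(model_subset, each = length(ids)))
  )
  av <- summary(stats::aov(bic ~ model + Error(subject), data = long))
  within <- av[["Error: Within"]][[1]]
  anova_row <- list(F = within["model", "F value"],
                    df1 = within["model", "Df"],
                    df2 = within["Residuals", "Df"],
                    p = within["model", "Pr(>F)"])
  pairs <- utils::combn(seq_along(model_subset), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    pt <- paired_p(bic[, i1], bic[, i2])
    data.frame(model_a = model_subset[i1], model_b = model_subset[i2],
               t = pt$t, p = pt$p)
  }))
  pw$p_adj <- pmin(pw$p * nrow(pw), 1)
  # winner: lowest mean BIC, preferring a simpler statistically-tied model
  top <- tab$model_id[which.min(tab$mean_bic)]
  tied <- vapply(tab$model_id, function(m) {
    if (m == top) return(TRUE)
    row <- pw[(pw$model_a == m & pw$model_b == top) |
                (pw$model_b == m & pw$model_a == top), ]
    row$p_adj >= alpha
  }, logical(1))
  cand <- tab[tied, ]
  cand <- cand[order(cand$k, cand$mean_bic, cand$model_id), ]
  structure(list(table = tab, anova = anova_row, pairwise = pw,
                 winning_model_id = cand$model_id[1]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison across", nrow(x$table), "models; winner: model",
      x$winning_model_id, "\n")
  print(transform(x$table, mean_bic = signif(mean_bic, 5),
                  se_bic = signif(se_bic, 3)))
  cat(sprintf("RM-ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  invisible(x)
}
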