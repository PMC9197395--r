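# Single-pass |z| cut for per-subject parameter estimates entering
# second-level analyses (see param_anxiety_regression for rationale).
param_outlier_mask <- function(x, threshold = 3) {
  if (!is.finite(threshold)) return(rep(FALSE, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  out <- abs(x - mean(x)) / s > threshold
  if (any(out)) {
    message(sum(out), " subject(s) excluded: parameter estimate beyond ",
            threshold, " SD of the group")
  }
  out
}

zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant variable",
                                    call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}

#' Harmonize anxiety severity across age-appropriate instruments
#'
#' Youth (age < 18) anxiety is the mean of child- and parent-report SCARED
#' scores; adult anxiety is the STAI trait score. Each instrument is
#' z-transformed within its own age sample and the z-scores are concatenated
#' into a single severity scale. Subjects missing the instrument matching
#' their age group are dropped (returned as `NA`) with a message.
#'
#' @param age Age in years.
#' @param scared_child,scared_parent SCARED child- and parent-report total
#'   scores (youth).
#' @param stai STAI trait scores (adults).
#' @return Numeric vector of anxiety z-scores aligned with `age` (`NA` for
#'   dropped subjects).
#' @export
combine_anxiety <- function(age, scared_child = NULL, scared_parent = NULL,
                            stai = NULL) {
  n <- length(age)
  if (is.null(scared_child)) scared_child <- rep(NA_real_, n)
  if (is.null(scared_parent)) scared_parent <- rep(NA_real_, n)
  if (is.null(stai)) stai <- rep(NA_real_, n)
  stopifnot(length(scared_child) == n, length(scared_parent) == n,
            length(stai) == n)
  youth <- age < 18
  raw <- ifelse(youth, (scared_child + scared_parent) / 2, stai)
  dropped <- is.na(raw)
  if (any(dropped)) {
    message(sum(dropped), " subject(s) dropped: missing the instrument for",
            " their age group")
  }
  out <- rep(NA_real_, n)
  for (grp in list(youth & !dropped, !youth & !dropped)) {
    if (!any(grp)) next
    if (sum(grp) < 2L) {
      stop("z-transformation undefined: an instrument group has fewer than",
           " 2 subjects", call. = FALSE)
    }
    out[grp] <- zscore(raw[grp])
  }
  out
}

#' Bonferroni-corrected per-test threshold
#'
#' @param n_tests Number of tests in the family (e.g. 4 conditioning
#'   parameters, 2 extinction parameters).
#' @param alpha Family-wise level.
#' @return `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Anxiety association and age moderation for one learning parameter
#'
#' Fits a single regression `parameter ~ anxiety + age + anxiety:age` on
#' z-scored variables (the interaction is the product of z-scores) and flags
#' each term against the family-wise Bonferroni threshold. Additional
#' covariates (e.g. the CS+ habituation rate for specificity analyses) are
#' z-scored and added as adjustment terms.
#'
#' @param param Fitted learning-parameter values, one per subject.
#' @param anxiety_z Anxiety severity z-scores.
#' @param age Age in years.
#' @param covariates Optional data frame of numeric adjustment covariates.
#' @param alpha_family Per-test threshold (0.05/4 = 0.0125 for the four
#'   conditioning parameters; 0.05/2 = 0.025 for extinction).
#' @param param_outlier_sd Before analysis, subjects whose parameter value
#'   lies beyond this many sample SDs of the group (single pass) are
#'   excluded. Unconstrained per-subject least-squares estimates are
#'   heavy-tailed -- a weakly identified parameter can escape to extreme
#'   values -- and a handful of such estimates dominates any standardized
#'   association. The default (3, matching the group-outlier rule used for
#'   raw SCR means) is the same conservative cut; set `Inf` to disable.
#' @return A data frame of class `"association_result"`: `term`, `beta`
#'   (standardized), `se`, `t`, `p`, `significant`, with `n` and
#'   `alpha_family` as attributes. Complete cases only.
#' @export
param_anxiety_regression <- function(param, anxiety_z, age, covariates = NULL,
                                     alpha_family = bonferroni_alpha(4),
                                     param_outlier_sd = 3) {
  d <- data.frame(param = param, anxiety = anxiety_z, age = age)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(param))
    d <- cbind(d, covariates)
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d <- d[!param_outlier_mask(d$param, param_outlier_sd), , drop = FALSE]
  n_terms <- 3L + if (is.null(covariates)) 0L else ncol(covariates)
  if (nrow(d) <= n_terms + 1L) {
    stop("too few complete cases (", nrow(d), ") for ", n_terms,
         " regression terms", call. = FALSE)
  }
  dz <- as.data.frame(lapply(d, zscore))
  dz$anxiety_x_age <- dz$anxiety * dz$age
  rhs <- c("anxiety", "age", "anxiety_x_age",
           if (!is.null(covariates)) names(covariates))
  fit <- stats::lm(stats::reformulate(rhs, response = "param"), data = dz)
  cf <- summary(fit)$coefficients
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  out <- data.frame(
    term = rownames(cf), beta = cf[, 1], se = cf[, 2], t = cf[, 3],
    p = cf[, 4], significant = cf[, 4] < alpha_family,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n") <- nrow(d)
  attr(out, "alpha_family") <- alpha_family
  class(out) <- c("association_result", "data.frame")
  out
}

#' Structure-level GMV moderation with permutation FWE correction
#'
#' For each subcortical structure, fits
#' `parameter ~ anxiety * gmv + sex + icv` on z-scored variables (sex
#' centered) and tests the anxiety-by-GMV interaction. Family-wise error
#' across the structure family is controlled by a Freedman-Lane-style
#' permutation max-statistic null: residuals of the reduced
#' (interaction-free) model are permuted (the same permutation applied to
#' every structure), the full model is refit, and the maximum absolute
#' interaction t-statistic over structures forms the null distribution.
#' Significant interactions are decomposed by the anxiety simple slope at
#' low/high GMV (+/- 1 SD).
#'
#' @param param Fitted learning-parameter values, one per subject.
#' @param anxiety_z Anxiety severity z-scores.
#' @param gmv Data frame or matrix, one column per structure (volumes,
#'   mm^3). Constant columns are skipped with a message.
#' @param sex Subject sex (two-level factor/character or numeric).
#' @param icv Total intracranial volume (nuisance).
#' @param n_perm Number of permutations (>= 1; 10000 by default).
#' @param seed Integer seed for the permutation draw.
#' @param alpha FWE level for the `significant` flag.
#' @param param_outlier_sd Pre-analysis exclusion of extreme parameter
#'   estimates, as in [param_anxiety_regression()].
#' @return A data frame, one row per tested structure: standardized betas
#'   for anxiety, gmv and the interaction, the interaction `t`, parametric
#'   `p`, permutation `p_fwe`, anxiety simple slopes at `gmv = -1` and
#'   `+1` SD, and `significant` (`p_fwe <= alpha`).
#' @export
gmv_moderation <- function(param, anxiety_z, gmv, sex, icv,
                           n_perm = 10000L, seed = 1L, alpha = 0.05,
                           param_outlier_sd = 3) {
  stopifnot(n_perm >= 1L)
  gmv <- as.data.frame(gmv)
  n <- length(param)
  stopifnot(length(anxiety_z) == n, nrow(gmv) == n, length(sex) == n,
            length(icv) == n)
  cc <- stats::complete.cases(param, anxiety_z, gmv, sex, icv)
  cc[cc] <- !param_outlier_mask(param[cc], param_outlier_sd)
  param <- param[cc]; anxiety_z <- anxiety_z[cc]; gmv <- gmv[cc, , drop = FALSE]
  sex <- sex[cc]; icv <- icv[cc]
  n <- sum(cc)
  keep <- vapply(gmv, function(g) stats::sd(g) > 0, logical(1))
  if (any(!keep)) {
    message("skipping constant GMV column(s): ",
            paste(names(gmv)[!keep], collapse = ", "))
    gmv <- gmv[, keep, drop = FALSE]
  }
  structures <- names(gmv)
  y <- zscore(param)
  a <- zscore(anxiety_z)
  icv_z <- zscore(icv)
  sex_c <- if (is.numeric(sex)) sex - mean(sex) else {
    as.numeric(factor(sex)) - mean(as.numeric(factor(sex)))
  }
  p_full <- 6L
  perm_idx <- withr::with_seed(as.integer(seed), {
    matrix(replicate(n_perm, sample.int(n)), nrow = n)
  })
  t_obs <- numeric(length(structures))
  betas <- matrix(NA_real_, length(structures), 3,
                  dimnames = list(structures, c("anxiety", "gmv", "interaction")))
  slopes <- matrix(NA_real_, length(structures), 4,
                   dimnames = list(structures, c("lo", "lo_se", "hi", "hi_se")))
  se_int <- numeric(length(structures))
  t_star <- matrix(NA_real_, length(structures), n_perm)
  for (s in seq_along(structures)) {
    g <- zscore(gmv[[s]])
    X <- cbind(1, a, g, sex_c, icv_z, a * g)
    XtXinv <- solve(crossprod(X))
    bh <- XtXinv %*% crossprod(X, y)
    res <- y - X %*% bh
    sig2 <- sum(res^2) / (n - p_full)
    se6 <- sqrt(sig2 * XtXinv[6, 6])
    t_obs[s] <- bh[6] / se6
    betas[s, ] <- bh[c(2, 3, 6)]
    se_int[s] <- se6
    # simple slopes of anxiety at gmv = -/+ 1 SD
    V <- sig2 * XtXinv
    for (side in 1:2) {
      gv <- c(-1, 1)[side]
      sl <- bh[2] + gv * bh[6]
      sl_se <- sqrt(V[2, 2] + gv^2 * V[6, 6] + 2 * gv * V[2, 6])
      slopes[s, c(2 * side - 1, 2 * side)] <- c(sl, sl_se)
    }
    # Freedman-Lane: permute reduced-model residuals, shared permutations
    Z <- X[, -6, drop = FALSE]
    ZtZinv <- solve(crossprod(Z))
    bz <- ZtZinv %*% crossprod(Z, y)
    fit_r <- Z %*% bz
    res_r <- y - fit_r
    Ystar <- matrix(res_r[perm_idx], nrow = n) + as.vector(fit_r)
    Bstar <- XtXinv %*% crossprod(X, Ystar)
    rss_star <- colSums((Ystar - X %*% Bstar)^2)
    t_star[s, ] <- Bstar[6, ] / sqrt(rss_star / (n - p_full) * XtXinv[6, 6])
  }
  max_t <- apply(abs(t_star), 2, max)
  p_fwe <- vapply(seq_along(structures), function(s) {
    (1 + sum(max_t >= abs(t_obs[s]))) / (n_perm + 1)
  }, numeric(1))
  out <- data.frame(
    structure = structures,
    beta_anxiety = betas[, 1], beta_gmv = betas[, 2],
    beta_interaction = betas[, 3], se_interaction = se_int,
    t_interaction = t_obs,
    p = 2 * stats::pt(-abs(t_obs), df = n - p_full),
    p_fwe = p_fwe,
    slope_low_gmv = slopes[, 1], slope_low_gmv_se = slopes[, 2],
    slope_high_gmv = slopes[, 3], slope_high_gmv_se = slopes[, 4],
    significant = p_fwe <= alpha,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "n_perm") <- n_perm
  out
}

# Flatten a summary.aovlist into a data frame of F tests.
aov_table <- function(av) {
  rows <- list()
  for (stratum in names(av)) {
    tab <- av[[stratum]][[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      rows[[length(rows) + 1L]] <- data.frame(
        term = terms[i], df1 = tab[i, "Df"],
        df2 = tab["Residuals", "Df"],
        ss = tab[i, "Sum Sq"],
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeated-measures ANOVA on raw SCR cell means
#'
#' Computes per-subject mean SCR per phase (conditioning, extinction) by CS
#' (CS+, CS-) cell and fits the 2x2 within-subject ANOVA with anxiety
#' severity and age (centered) as continuous between-subject covariates,
#' via `aov` with an `Error(subject/(phase*cs))` stratum structure. Per-phase
#' CS-effect follow-ups are included. Subjects with an incomplete cell set
#' are dropped with a message.
#'
#' @param trials Cleaned cohort trial table.
#' @param subjects Subject table with `subject_id`, `anxiety_z`, `age`.
#' @return A list of class `"scr_anova"`: `cells` (the cell means), `anova`
#'   (term, df1, df2, ss, F, p), and `followup` (per-phase CS-effect
#'   tables).
#' @export
raw_scr_anova <- function(trials, subjects) {
  tr <- trials[trials$phase %in% c("conditioning", "extinction"), , drop = FALSE]
  cells <- stats::aggregate(scr ~ subject_id + phase + cs, data = tr,
                            FUN = mean, na.rm = TRUE, na.action = NULL)
  cnt <- table(cells$subject_id)
  ok <- tapply(cells$scr, cells$subject_id, function(x) all(is.finite(x)))
  complete <- intersect(names(cnt)[cnt == 4L], names(ok)[ok])
  if (length(complete) < nrow(subjects)) {
    message(nrow(subjects) - length(complete),
            " subject(s) dropped: incomplete phase x CS cell means")
  }
  if (length(complete) < 2L) stop("need at least 2 complete subjects",
                                  call. = FALSE)
  cells <- cells[cells$subject_id %in% complete, , drop = FALSE]
  d <- merge(cells, subjects[, c("subject_id", "anxiety_z", "age")],
             by = "subject_id")
  d$subject <- factor(d$subject_id)
  d$phase <- factor(d$phase, levels = c("conditioning", "extinction"))
  d$cs <- factor(d$cs, levels = c("CS+", "CS-"))
  d$age_c <- d$age - mean(d$age)
  d$anx <- d$anxiety_z
  av <- summary(stats::aov(
    scr ~ (phase * cs) * (anx + age_c) + Error(subject / (phase * cs)),
    data = d
  ))
  main <- aov_table(av)
  followup <- lapply(stats::setNames(levels(d$phase), levels(d$phase)),
                     function(ph) {
    dp <- d[d$phase == ph, , drop = FALSE]
    aov_table(summary(stats::aov(scr ~ cs * (anx + age_c) + Error(subject / cs),
                                 data = dp)))
  })
  structure(list(cells = cells, anova = main, followup = followup),
            class = "scr_anova")
}

#' @export
print.scr_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA on phase x CS SCR cell means\n")
  print(transform(x$anova, ss = signif(ss, 4), F = round(F, 2),
                  p = signif(p, 3)))
  invisible(x)
}
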