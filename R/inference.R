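#' @title Fitted-comparison container
#' @description Every comparison stage returns a `sperm_fit`: the underlying
#' model object plus a uniform tidy contract (term estimates, standard
#' errors, test statistics, degrees of freedom, p-values, optional
#' contrasts, convergence flags and sample sizes). Use [tidy()] /
#' [glance()] to extract tibbles.
#' @name sperm_fit
NULL

new_sperm_fit <- function(stage, model, terms, contrasts = NULL,
                          flags = character(), transform = "identity",
                          n_obs = NA_integer_, n_males = NA_integer_,
                          anova = NULL) {
  structure(
    list(stage = stage, model = model, terms = terms, contrasts = contrasts,
         anova = anova, flags = flags, transform = transform,
         n_obs = n_obs, n_males = n_males),
    class = "sperm_fit"
  )
}

# run a fit, collecting warnings/messages as flags instead of printing them
quiet_fit <- function(expr) {
  flags <- character()
  model <- withCallingHandlers(
    expr,
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      flags <<- c(flags, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  list(model = model, flags = flags)
}

lmer_terms <- function(model) {
  sm <- summary(model)$coefficients
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    df = unname(sm[, "df"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
}

lm_terms <- function(model) {
  sm <- suppressWarnings(summary(model))$coefficients
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    df = model$df.residual,
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
}

glm_terms <- function(model) {
  sm <- summary(model)$coefficients
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    df = Inf,
    statistic = unname(sm[, "z value"]),
    p_value = unname(sm[, "Pr(>|z|)"])
  )
}

group_factor <- function(x) {
  factor(x, levels = c("cold", "warm"))
}

#' Compare deformity proportions between acclimation groups
#'
#' Binomial GLM (logit link) of deformed-cell count out of total counted
#' cells per male on acclimation group, one row per male. The group term is
#' the warm-vs-cold log-odds difference. Complete separation is flagged in
#' the result, not fatal.
#'
#' @param counts Per-male deformity counts with columns `male_id`, `group`
#'   (`"cold"`/`"warm"`), `deformed`, `total_counted`.
#' @return A [sperm_fit].
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   male_id = c("C1", "C2", "W1", "W2"), group = c("cold", "cold", "warm", "warm"),
#'   deformed = c(28, 32, 31, 29), total_counted = rep(100, 4)
#' )
#' tidy(compare_deformity(counts))
compare_deformity <- function(counts) {
  check_columns(counts, c("male_id", "group", "deformed", "total_counted"))
  if (any(counts$total_counted <= 0)) {
    abort("All `total_counted` values must be positive.")
  }
  if (dplyr::n_distinct(counts$group) < 2) {
    abort("Both acclimation groups must be present.")
  }
  dat <- counts %>% mutate(group = group_factor(.data$group))
  fit <- quiet_fit(glm(
    cbind(deformed, total_counted - deformed) ~ group,
    family = binomial(), data = dat
  ))
  flags <- fit$flags
  if (any(grepl("fitted probabilities numerically 0 or 1", flags)) ||
      max(abs(coef(fit$model))) > 15) {
    flags <- unique(c(flags, "separation"))
  }
  new_sperm_fit(
    stage = "deformity", model = fit$model, terms = glm_terms(fit$model),
    flags = flags, transform = "logit",
    n_obs = nrow(dat), n_males = nrow(dat)
  )
}

MORPHOLOGY_MEASURES <- c(
  A_H = "A_H_um2", L_F = "L_F_um", L_T = "L_T_um",
  ratio_LF_LH = "ratio_LF_LH", ratio_LF_AH = "ratio_LF_AH_per_um"
)

#' Compare a morphometric measure between acclimation groups
#'
#' Mixed model of a per-cell morphometric quantity on acclimation group with
#' a per-male random intercept. Absolute sizes (`A_H`, `L_F`, `L_T`) are
#' right-skewed and fitted on the log scale (a linear mixed model for a
#' lognormal response); the two ratio measures are fitted on the identity
#' scale. Degrees of freedom and p-values are Satterthwaite.
#'
#' @param derived Per-cell derived morphometry ([derive_cells()]) with
#'   `male_id` and `group` columns.
#' @param measure One of `"A_H"`, `"L_F"`, `"L_T"`, `"ratio_LF_LH"`,
#'   `"ratio_LF_AH"`.
#' @return A [sperm_fit]; the `groupwarm` term is the warm-vs-cold effect
#'   (log scale for the absolute sizes).
#' @export
compare_morphology <- function(derived,
                               measure = c("ratio_LF_AH", "ratio_LF_LH",
                                           "A_H", "L_F", "L_T")) {
  measure <- match.arg(measure)
  column <- MORPHOLOGY_MEASURES[[measure]]
  check_columns(derived, c("male_id", "group", column))
  per_group <- derived %>%
    dplyr::distinct(.data$male_id, .data$group) %>%
    dplyr::count(.data$group)
  if (nrow(per_group) < 2 || any(per_group$n < 2)) {
    abort("Each acclimation group needs at least 2 males.")
  }
  transform <- if (measure %in% c("A_H", "L_F", "L_T")) "log" else "identity"
  y <- derived[[column]]
  if (transform == "log") {
    if (any(y <= 0)) {
      abort(sprintf("`%s` must be strictly positive for the log-scale fit.", column))
    }
    y <- log(y)
  }
  dat <- tibble(y = y, group = group_factor(derived$group),
                male_id = factor(derived$male_id))
  if (stats::sd(dat$y) < 1e-12) {
    terms <- tibble(
      term = c("(Intercept)", "groupwarm"),
      estimate = c(mean(dat$y), 0),
      std_error = NA_real_, df = NA_real_, statistic = NA_real_,
      p_value = NA_real_
    )
    return(new_sperm_fit(
      stage = paste0("morphology_", measure), model = NULL, terms = terms,
      flags = "degenerate", transform = transform,
      n_obs = nrow(dat), n_males = dplyr::n_distinct(dat$male_id)
    ))
  }
  fit <- tryCatch(
    quiet_fit(lmerTest::lmer(y ~ group + (1 | male_id), data = dat,
                             REML = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # random-effect structure unidentifiable (e.g. zero within-male
    # variance); fall back to OLS, which equals GLS on balanced data
    ols <- quiet_fit(lm(y ~ group, data = dat))
    return(new_sperm_fit(
      stage = paste0("morphology_", measure), model = ols$model,
      terms = lm_terms(ols$model),
      flags = unique(c(ols$flags, "degenerate random-effect structure; OLS fallback")),
      transform = transform,
      n_obs = nrow(dat), n_males = dplyr::n_distinct(dat$male_id)
    ))
  }
  flags <- fit$flags
  if (lme4::isSingular(fit$model, tol = 1e-5)) {
    flags <- unique(c(flags, "boundary (singular) random-effect variance"))
  }
  new_sperm_fit(
    stage = paste0("morphology_", measure), model = fit$model,
    terms = lmer_terms(fit$model), flags = flags, transform = transform,
    n_obs = nrow(dat), n_males = dplyr::n_distinct(dat$male_id)
  )
}

#' Regress sperm swimming speed on a per-male morphology ratio
#'
#' Linear model of per-male average path velocity (VAP) at one activation
#' temperature on a per-male mean morphology ratio, optionally with
#' acclimation group as an additional term. By default the response is
#' modelled on the identity scale at the cold activation temperature and on
#' the log scale at the warm one (where VAP residuals in the emulated study
#' design depart from normality); override with `response_transform`.
#'
#' @param data One row per male, with columns `male_id`, `group`, the ratio
#'   column named by `ratio`, and the VAP column named by `vap_col`.
#' @param ratio Name of the predictor column (a per-male mean ratio, e.g.
#'   `"mean_ratio_LF_AH_per_um"`).
#' @param vap_col Name of the response column (VAP, um/s).
#' @param activation_temp_C Activation temperature the VAP was measured at;
#'   used only to pick the default response transform.
#' @param include_acclimation Add acclimation group as a covariate.
#' @param response_transform `"auto"`, `"identity"` or `"log"`.
#' @return A [sperm_fit]; the ratio term's estimate is the slope.
#' @export
speed_vs_morphology <- function(data, ratio, vap_col,
                                activation_temp_C = 8,
                                include_acclimation = FALSE,
                                response_transform = c("auto", "identity", "log")) {
  response_transform <- match.arg(response_transform)
  check_columns(data, c("male_id", ratio, vap_col))
  if (include_acclimation) {
    check_columns(data, "group")
  }
  n_par <- 2L + as.integer(include_acclimation)
  if (nrow(data) < 3L * n_par) {
    abort(sprintf("Need at least %d males for %d parameters.", 3L * n_par, n_par))
  }
  if (response_transform == "auto") {
    response_transform <- if (activation_temp_C > 10) "log" else "identity"
  }
  y <- data[[vap_col]]
  if (response_transform == "log") {
    if (any(y <= 0)) {
      abort("VAP must be strictly positive for the log-scale fit.")
    }
    y <- log(y)
  }
  dat <- tibble(y = y, ratio = data[[ratio]])
  if (include_acclimation) {
    dat$group <- group_factor(data$group)
  }
  if (stats::sd(dat$ratio) < 1e-12) {
    terms <- tibble(term = c("(Intercept)", "ratio"),
                    estimate = c(mean(dat$y), 0), std_error = NA_real_,
                    df = NA_real_, statistic = NA_real_, p_value = NA_real_)
    return(new_sperm_fit(
      stage = "speed_vs_morphology", model = NULL, terms = terms,
      flags = "degenerate", transform = response_transform,
      n_obs = nrow(dat), n_males = nrow(dat)
    ))
  }
  form <- if (include_acclimation) y ~ ratio + group else y ~ ratio
  fit <- quiet_fit(lm(form, data = dat))
  new_sperm_fit(
    stage = "speed_vs_morphology", model = fit$model,
    terms = lm_terms(fit$model), flags = fit$flags,
    transform = response_transform,
    n_obs = nrow(dat), n_males = nrow(dat)
  )
}

#' Mixed model for theoretical head drag
#'
#' Linear mixed model of per-male mean drag (pN) on acclimation group,
#' activation temperature and their interaction, with a random intercept for
#' male (males are nested within acclimation group, so the per-male
#' intercept realises the nested random-effect structure). Per-term tests
#' use Satterthwaite degrees of freedom; a Type III ANOVA table is stored in
#' `$anova`.
#'
#' @param drag_means Per-male, per-activation-temperature mean drag from
#'   [summarize_drag()], with columns `male_id`, `group`,
#'   `activation_temp_C`, `mean_D_pN`.
#' @return A [sperm_fit].
#' @seealso [activation_contrasts()] for the post-hoc least-squares-means
#'   comparisons.
#' @export
drag_model <- function(drag_means) {
  check_columns(drag_means, c("male_id", "group", "activation_temp_C",
                              "mean_D_pN"))
  design_cells <- drag_means %>%
    dplyr::count(.data$male_id, .data$activation_temp_C)
  full <- tidyr::crossing(male_id = unique(drag_means$male_id),
                          activation_temp_C = unique(drag_means$activation_temp_C))
  if (nrow(design_cells) != nrow(full)) {
    missing <- dplyr::anti_join(full, design_cells,
                                by = c("male_id", "activation_temp_C"))
    abort(sprintf("Male %s has no mean drag at %g degrees C.",
                  missing$male_id[1], missing$activation_temp_C[1]))
  }
  dat <- drag_means %>%
    mutate(
      acclimation = group_factor(.data$group),
      activation = factor(sprintf("%gC", .data$activation_temp_C),
                          levels = sprintf("%gC", sort(unique(.data$activation_temp_C)))),
      male_id = factor(.data$male_id)
    )
  term_names <- c("(Intercept)", "acclimationwarm", "activation13C",
                  "acclimationwarm:activation13C")
  if (stats::sd(dat$mean_D_pN) < 1e-12) {
    terms <- tibble(term = term_names,
                    estimate = c(mean(dat$mean_D_pN), 0, 0, 0),
                    std_error = NA_real_, df = NA_real_,
                    statistic = NA_real_, p_value = NA_real_)
    return(new_sperm_fit(
      stage = "drag", model = NULL, terms = terms, flags = "degenerate",
      n_obs = nrow(dat), n_males = dplyr::n_distinct(dat$male_id)
    ))
  }
  fit <- quiet_fit(lmerTest::lmer(
    mean_D_pN ~ acclimation * activation + (1 | male_id), data = dat,
    REML = TRUE
  ))
  flags <- fit$flags
  if (lme4::isSingular(fit$model, tol = 1e-5)) {
    flags <- unique(c(flags, "boundary (singular) random-effect variance"))
  }
  an <- quiet_fit(anova(fit$model, type = 3))
  an_tbl <- tibble(
    term = rownames(an$model),
    statistic = an$model[["F value"]],
    df_num = an$model[["NumDF"]],
    df_den = an$model[["DenDF"]],
    p_value = an$model[["Pr(>F)"]]
  )
  new_sperm_fit(
    stage = "drag", model = fit$model, terms = lmer_terms(fit$model),
    flags = flags, anova = an_tbl,
    n_obs = nrow(dat), n_males = dplyr::n_distinct(dat$male_id)
  )
}

#' Least-squares-means activation contrasts within acclimation groups
#'
#' Post-hoc pairwise comparisons of activation-temperature least-squares
#' means within each acclimation group, from a fitted [drag_model()]. No
#' multiplicity adjustment is applied (each within-group contrast is a
#' single planned comparison). Degrees of freedom are Satterthwaite by
#' default; for a balanced 8 + 8 males x 2 activation temperatures design
#' the within-group contrast df is 14.
#'
#' @param fit A [sperm_fit] from [drag_model()].
#' @param df_method `"satterthwaite"` or `"kenward-roger"`.
#' @return A tibble: `acclimation`, `contrast`, `estimate`, `std_error`,
#'   `df`, `statistic`, `p_value`.
#' @export
activation_contrasts <- function(fit,
                                 df_method = c("satterthwaite", "kenward-roger")) {
  df_method <- match.arg(df_method)
  if (!inherits(fit, "sperm_fit") || fit$stage != "drag") {
    abort("`fit` must be a sperm_fit from drag_model().")
  }
  if (is.null(fit$model)) {
    # degenerate fit: all means equal, contrasts identically zero
    return(tibble(acclimation = c("cold", "warm"), contrast = "degenerate",
                  estimate = 0, std_error = NA_real_, df = NA_real_,
                  statistic = NA_real_, p_value = NA_real_))
  }
  emm <- emmeans::emmeans(fit$model, ~ activation | acclimation,
                          lmer.df = df_method)
  ctr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  tibble(
    acclimation = as.character(ctr$acclimation),
    contrast = as.character(ctr$contrast),
    estimate = ctr$estimate,
    std_error = ctr$SE,
    df = ctr$df,
    statistic = ctr$t.ratio,
    p_value = ctr$p.value
  )
}

#' @export
print.sperm_fit <- function(x, ...) {
  cat(sprintf("<sperm_fit: %s> n_obs = %d, n_males = %d%s\n",
              x$stage, x$n_obs, x$n_males,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]") else ""))
  print(x$terms)
  invisible(x)
}

#' Tidy a fitted comparison
#'
#' @param x A [sperm_fit].
#' @param ... Unused.
#' @return The per-term tibble: `term`, `estimate`, `std_error`, `df`,
#'   `statistic`, `p_value`.
#' @method tidy sperm_fit
#' @export
tidy.sperm_fit <- function(x, ...) {
  x$terms
}

#' One-row summary of a fitted comparison
#'
#' @param x A [sperm_fit].
#' @param ... Unused.
#' @return A tibble with `stage`, `transform`, `n_obs`, `n_males`,
#'   `degenerate`, `singular`, `n_flags`.
#' @method glance sperm_fit
#' @export
glance.sperm_fit <- function(x, ...) {
  tibble(
    stage = x$stage, transform = x$transform,
    n_obs = x$n_obs, n_males = x$n_males,
    degenerate = "degenerate" %in% x$flags,
    singular = any(grepl("singular", x$flags)),
    n_flags = length(x$flags)
  )
}
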