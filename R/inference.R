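#' Prepare the per-plot model frame
#'
#' Joins a per-plot response onto the design and builds the factors of the
#' fixed-effect structure: `fertilization` (fertilized/unfertilized),
#' `history` (different/same; `different` pools the from-single and
#' from-monoculture sources by default, matching the two-level contrast of
#' the analysis; `pool_history = FALSE` keeps three source levels),
#' `monomix` (monoculture vs mixture) and `nspecies` (2 vs 4, nested within
#' mixtures), plus the random-intercept grouping factors `comb` (species
#' composition), `bed` and `column`. Single plots are excluded.
#'
#' @param design Plot table from [build_design()].
#' @param response Data frame with `plot_id` and one response column.
#' @param response_col Name of the response column in `response`.
#' @param pool_history Pool the two different-history sources (default).
#' @return A model frame with column `y` holding the response.
#' @export
prepare_model_frame <- function(design, response, response_col,
                                pool_history = TRUE) {
  d <- design[design$kind != "single", ]
  d <- merge(d, response, by = "plot_id")   # keeps any extra response columns
  d$y <- d[[response_col]]
  d$fertilization <- factor(ifelse(d$fertilized, "fertilized", "unfertilized"),
                            levels = c("fertilized", "unfertilized"))
  if (pool_history) {
    d$history <- factor(d$history_class, levels = c("different", "same"))
  } else {
    d$history <- factor(ifelse(d$history_class == "same", "same",
                               paste0("different-from-", d$history_source)))
    d$history <- stats::relevel(d$history, ref = levels(d$history)[1])
  }
  d$monomix <- factor(ifelse(d$kind == "monoculture", "monoculture", "mixture"),
                      levels = c("monoculture", "mixture"))
  d$nspecies <- factor(ifelse(d$kind == "mixture", as.character(d$richness),
                              "2"), levels = c("2", "4"))
  d$comb <- factor(d$comp_id)
  d$bed <- factor(d$bed)
  d$column <- factor(d$column)
  d[!is.na(d$y), ]
}

# the nested richness term needs both community kinds; responses defined
# only for mixtures (NE, CE, SE) reduce to the richness contrast alone
.fixed_structure <- function(frame) {
  if (nlevels(droplevels(frame$monomix)) > 1L)
    "fertilization * history * (monomix + monomix:nspecies)"
  else
    "fertilization * history * nspecies"
}

.transform_response <- function(transform) {
  switch(transform,
         none = "y",
         log = "log(y)",
         sqrt = "sqrt(y)",
         stop("unknown transformation: ", transform, call. = FALSE))
}

#' Fit the plot-level mixed model
#'
#' Fits `y ~ fertilization * history * (monomix + monomix:nspecies)` with
#' random intercepts for species composition, bed and column (the crop
#' species number is nested within the monoculture/mixture contrast; its
#' monoculture cell is aliased and dropped automatically). F tests use type
#' III sums of squares with Satterthwaite denominator degrees of freedom;
#' marginal means, percent effect sizes and Tukey-adjusted pairwise
#' contrasts are computed for the history and fertilization margins and
#' back-transformed to the response scale when a transformation is applied.
#' A response with zero variance short-circuits to a null report (all F = 0,
#' effect sizes 0) rather than failing.
#'
#' @param frame Model frame from [prepare_model_frame()].
#' @param transform `"none"`, `"log"` (positive responses) or `"sqrt"`.
#' @param marginal Compute marginal means, effect sizes, Tukey contrasts and
#'   diagnostics (default). Setting `FALSE` returns only the fit and the F
#'   table, which is much faster for repeated-simulation studies that only
#'   need p-values.
#' @return Object of class `coexhist_fit`: list with `model`, `anova`,
#'   `marginal_means` (per factor), `effects_pct`, `contrasts`,
#'   `diagnostics`, `singular` flag and `df_method`.
#' @export
fit_mixed <- function(frame, transform = c("none", "log", "sqrt"),
                      marginal = TRUE) {
  transform <- match.arg(transform)
  if (transform == "log" && any(frame$y <= 0))
    stop("log transformation requires positive responses", call. = FALSE)
  if (transform == "sqrt" && any(frame$y < 0))
    stop("sqrt transformation requires non-negative responses", call. = FALSE)

  if (stats::var(frame$y) == 0) {
    mm <- aggregate(y ~ history, frame, mean)
    return(structure(list(
      model = NULL, anova = NULL,
      marginal_means = list(history = data.frame(history = mm$history,
                                                 emmean = mm$y, SE = 0)),
      effects_pct = c(history = 0, fertilization = 0),
      contrasts = NULL,
      diagnostics = list(note = "constant response"),
      singular = TRUE, df_method = "none",
      note = "constant response: all F = 0, effect sizes 0"),
      class = "coexhist_fit"))
  }

  lhs <- .transform_response(transform)
  fml <- stats::as.formula(paste(
    lhs, "~", .fixed_structure(frame),
    "+ (1 | comb) + (1 | bed) + (1 | column)"))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = frame,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  an <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))

  if (!marginal)
    return(structure(list(model = fit, anova = an, marginal_means = NULL,
                          effects_pct = NULL, contrasts = NULL,
                          diagnostics = NULL,
                          singular = lme4::isSingular(fit),
                          df_method = "Satterthwaite"),
                     class = "coexhist_fit"))

  mm_of <- function(spec) {
    em <- suppressMessages(emmeans::emmeans(fit, spec, type = "response"))
    as.data.frame(em)
  }
  marginal_means <- list(history = mm_of("history"),
                         fertilization = mm_of("fertilization"))
  ctr <- suppressMessages(as.data.frame(
    emmeans::contrast(emmeans::emmeans(fit, ~ history | fertilization),
                      method = "pairwise", adjust = "tukey")))

  resp_col <- function(df) df[[grep("emmean|response", names(df))[1]]]
  eff <- function(df, focal, ref) {
    v <- resp_col(df)
    effect_size_percent(v[df[[1]] == focal], v[df[[1]] == ref])
  }
  effects_pct <- c(
    history = eff(marginal_means$history, "same", "different"),
    fertilization = eff(marginal_means$fertilization, "unfertilized",
                        "fertilized"))

  structure(list(
    model = fit, anova = an, marginal_means = marginal_means,
    effects_pct = effects_pct, contrasts = ctr,
    diagnostics = model_diagnostics(stats::residuals(fit), frame$history),
    singular = lme4::isSingular(fit), df_method = "Satterthwaite"),
    class = "coexhist_fit")
}

#' @export
print.coexhist_fit <- function(x, ...) {
  cat("coexhist mixed-model fit (ddf:", x$df_method, ")\n")
  if (!is.null(x$anova)) print(x$anova)
  cat("\nPercent effect sizes (marginal means):\n")
  print(round(x$effects_pct, 2))
  invisible(x)
}

#' Reference-aware significance test of the coexistence-history effect on RII
#'
#' Every plot in a species x fertilization x history stratum compares its
#' individuals against the *same* estimated single-plant reference mean
#' (four replicates), so reference estimation error is shared across plots
#' of a stratum. A plot-level model that ignores this sharing treats the
#' reference error as treatment signal and is strongly anticonservative for
#' the history term. This test therefore works at the species-RII level
#' (one row per plot x species) and adds random intercepts for species and
#' for the reference stratum `species:fertilization:history`, so the history
#' contrast is tested against the between-stratum variance with
#' Satterthwaite degrees of freedom of the order of the number of reference
#' strata. Use [fit_mixed()] on the plot-level net RII for marginal means
#' and effect sizes; use this test for the history p-value.
#'
#' @param species_rii Species-level RII table from [compute_rii()]
#'   (`plot_id`, `species`, `rii`).
#' @param design Plot table.
#' @param pool_history Pool the two different-history seed sources.
#' @return A `coexhist_fit` with the species-level model and its F table;
#'   `$history_p` carries the history p-value.
#' @export
rii_history_test <- function(species_rii, design, pool_history = TRUE) {
  d <- merge(species_rii, design, by = "plot_id")
  d <- d[d$kind != "single" & !is.na(d$rii), ]
  d$y <- d$rii
  d$fertilization <- factor(ifelse(d$fertilized, "fertilized", "unfertilized"),
                            levels = c("fertilized", "unfertilized"))
  d$history <- if (pool_history)
    factor(d$history_class, levels = c("different", "same"))
  else factor(ifelse(d$history_class == "same", "same",
                     paste0("different-from-", d$history_source)))
  d$monomix <- factor(ifelse(d$kind == "monoculture", "monoculture", "mixture"),
                      levels = c("monoculture", "mixture"))
  d$nspecies <- factor(ifelse(d$kind == "mixture", as.character(d$richness),
                              "2"), levels = c("2", "4"))
  d$comb <- factor(d$comp_id)
  d$bed <- factor(d$bed)
  d$column <- factor(d$column)
  d$species <- factor(d$species)
  d$ref_group <- interaction(d$species, d$fertilization, d$history, drop = TRUE)

  fml <- stats::as.formula(paste(
    "y ~", .fixed_structure(d),
    "+ (1 | comb) + (1 | bed) + (1 | column) + (1 | species) + (1 | ref_group)"))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = d,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  an <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  structure(list(model = fit, anova = an, marginal_means = NULL,
                 effects_pct = NULL, contrasts = NULL,
                 diagnostics = NULL, singular = lme4::isSingular(fit),
                 df_method = "Satterthwaite",
                 history_p = an["history", "Pr(>F)"]),
            class = "coexhist_fit")
}

#' Percent effect size from marginal means
#'
#' `100 * (focal - reference) / |reference|`. The absolute-value denominator
#' makes a less-negative index (e.g. RII moving from -0.50 to -0.23) read as
#' a positive percent increase.
#'
#' @param mm_focal,mm_reference Marginal means.
#' @return Percent effect size.
#' @export
effect_size_percent <- function(mm_focal, mm_reference) {
  if (any(mm_reference == 0))
    stop("undefined effect size: reference marginal mean is zero",
         call. = FALSE)
  100 * (mm_focal - mm_reference) / abs(mm_reference)
}

#' Residual diagnostics
#'
#' Shapiro-Wilk normality test of the residuals and Levene (Brown-Forsythe)
#' test of variance homogeneity across groups.
#'
#' @param residuals Model residuals (at least 3).
#' @param groups Grouping factor for the homogeneity test.
#' @return List with `shapiro` and `levene` components (`statistic`, `p`),
#'   or `NULL` entries when undefined (too few observations, constant
#'   residuals).
#' @export
model_diagnostics <- function(residuals, groups) {
  if (length(residuals) < 3L || stats::sd(residuals) == 0)
    return(list(shapiro = NULL, levene = NULL))
  sub <- if (length(residuals) > 5000) sample(residuals, 5000) else residuals
  sh <- stats::shapiro.test(sub)
  lv <- NULL
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) >= 2L) {
    lt <- car::leveneTest(residuals ~ droplevels(groups))
    lv <- list(statistic = lt[1, "F value"], p = lt[1, "Pr(>F)"])
  }
  list(shapiro = list(statistic = unname(sh$statistic), p = sh$p.value),
       levene = lv)
}

#' Mixed model for weekly canopy light interception
#'
#' Averages the three FPAR readings per plot and week and fits the plot-level
#' fixed structure with an additional random intercept for day of year.
#' With a single measurement week the day term is dropped (with a warning)
#' and the model reduces to [fit_mixed()].
#'
#' @param light Light table (`plot_id`, `day_of_year`, `fpar_pct`).
#' @param design Plot table.
#' @param pool_history See [prepare_model_frame()].
#' @return A `coexhist_fit` object.
#' @export
fpar_model <- function(light, design, pool_history = TRUE) {
  wk <- aggregate(fpar_pct ~ plot_id + day_of_year, light, fpar_plot_week)
  names(wk)[3] <- "fpar"
  # one row per plot x week, with the plot-level factor structure
  frame <- prepare_model_frame(design, wk, "fpar", pool_history)
  frame$doy <- factor(frame$day_of_year)

  if (nlevels(frame$doy) < 2L) {
    warning("single measurement week: dropping day-of-year random term")
    return(fit_mixed(frame))
  }
  fml <- y ~ fertilization * history * (monomix + monomix:nspecies) +
    (1 | comb) + (1 | bed) + (1 | column) + (1 | doy)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = frame,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  an <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  mm <- as.data.frame(suppressMessages(emmeans::emmeans(fit, "history")))
  eff <- effect_size_percent(mm$emmean[mm$history == "same"],
                             mm$emmean[mm$history == "different"])
  structure(list(
    model = fit, anova = an,
    marginal_means = list(history = mm),
    effects_pct = c(history = eff),
    contrasts = NULL,
    diagnostics = model_diagnostics(stats::residuals(fit), frame$history),
    singular = lme4::isSingular(fit), df_method = "Satterthwaite"),
    class = "coexhist_fit")
}
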