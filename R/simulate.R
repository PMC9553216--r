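#' Default simulation parameters
#'
#' Ground-truth parameters for the synthetic experiment. Yield acts
#' multiplicatively: a plant growing in a community realises a fraction `c`
#' of its single-plant yield, and the three treatments relax that competition
#' on the `(1 - c)` scale,
#' `1 - c_eff = (1 - c) * (1 - gamma)^(unfertilized) * (1 - delta)^(same history)`.
#' The defaults place the fertilized, different-history baseline at `c = 0.5`
#' (net RII of -1/3) and solve the two relaxations jointly
#' (`delta = 0.439853`, `gamma = 0.582526`) so that the implied marginal-mean
#' contrasts on net RII are exactly +50% for same vs different history and
#' +64% for unfertilized vs fertilized (see [implied_effects()]). Trait convergence under a common history is
#' emulated by a mean shift (taller plants, lower leaf dry matter content)
#' plus a shrink of trait dispersion.
#'
#' @param ... Named overrides of any default component.
#' @return An object of class `coexhist_params`: a list with the species
#'   trait/yield table and the scalar parameters documented above.
#' @export
default_params <- function(...) {
  species <- data.frame(
    code = c("Av", "Ca", "Co", "Le", "Li", "Tr"),
    base_yield = c(7, 2, 4, 3, 2.5, 6),       # g/plant, single, unfertilized
    harvest_index = c(0.40, 0.30, 0.35, 0.45, 0.35, 0.45),
    height_mean = c(95, 70, 60, 35, 65, 75), height_sd = c(9, 7, 6, 4, 6, 7),
    width_mean = c(22, 18, 25, 20, 15, 18),  width_sd = c(3, 2.5, 3.5, 3, 2, 2.5),
    sla_mean = c(200, 170, 250, 220, 150, 180), sla_sd = c(22, 20, 30, 25, 18, 20),
    ldmc_mean = c(0.28, 0.30, 0.20, 0.25, 0.33, 0.30),
    ldmc_sd = c(0.030, 0.030, 0.020, 0.025, 0.030, 0.030),
    leafdm_mean = c(0.12, 0.06, 0.08, 0.05, 0.07, 0.15),
    leafdm_sd = c(0.02, 0.01, 0.015, 0.01, 0.012, 0.025),
    seed_mass_mean = c(0.035, 0.0011, 0.010, 0.045, 0.006, 0.045),
    seed_mass_sd = c(0.004, 0.0002, 0.0015, 0.005, 0.0008, 0.005),
    stringsAsFactors = FALSE
  )
  p <- list(
    species = species,
    c_intra = 0.5,              # competition multiplier, monocultures
    c_inter = 0.5,              # competition multiplier, mixtures
    delta_history = 0.439853,   # same-history relaxation on (1 - c)
    gamma_unfert = 0.582526,    # unfertilized relaxation on (1 - c)
    fert_mult = 1.5,            # fertilization multiplier on baseline yield
    sigma = 0.2,                # lognormal sdlog of individual yield noise
    n_marked = 3L,              # marked individuals per species per plot
    plot_area = 0.25,           # m2
    height_shift_same = 0.05,   # relative height increase, same history
    ldmc_shift_same = -0.03,    # relative LDMC change, same history
    sd_shrink_same = 0.85,      # trait-dispersion shrink factor, same history
    trait_sd_frac = 1,          # global scaling of trait SDs
    fpar_max = 85,              # asymptotic canopy FPAR, communities (%)
    fpar_max_single = 20,       # asymptotic FPAR, single plants (%)
    fpar_midpoint = 160,        # day of year of half canopy closure
    fpar_rate = 12,             # logistic time constant (days)
    fpar_same_increment = 3,    # FPAR increase under same history (% points)
    fpar_sd = 3,                # reading noise SD (% points)
    fpar_days = seq(135L, 198L, by = 7L)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(over)] <- over
  }
  validate_params(p)
  structure(p, class = "coexhist_params")
}

#' @rdname default_params
#' @param params A parameter list to validate.
#' @export
validate_params <- function(params) {
  stopifnot(params$c_intra > 0, params$c_inter > 0,
            params$delta_history >= 0, params$delta_history <= 1,
            params$gamma_unfert >= 0, params$gamma_unfert <= 1,
            params$sigma >= 0, params$fert_mult > 0,
            all(params$species$ldmc_mean > 0), all(params$species$ldmc_mean < 1),
            all(params$species$base_yield > 0),
            all(params$species[grep("_sd$", names(params$species))] >= 0))
  invisible(params)
}

#' Effective competition multiplier
#'
#' @param c0 Baseline multiplier (fertilized, different history).
#' @param fertilized,same_history Logical treatment indicators.
#' @param gamma,delta Relaxation fractions on the `(1 - c)` scale.
#' @return Effective multiplier, vectorized.
#' @export
effective_competition <- function(c0, fertilized, same_history, gamma, delta) {
  1 - (1 - c0) * ifelse(fertilized, 1, 1 - gamma) *
    ifelse(same_history, 1 - delta, 1)
}

#' Closed-form treatment effects implied by simulation parameters
#'
#' Computes the noiseless net RII of each fertilization x history cell from
#' the multiplicative yield model, `RII = (c_eff - 1)/(c_eff + 1)`, and the
#' percent marginal-mean contrasts they imply: same vs different history
#' (averaged over fertilization) and unfertilized vs fertilized (averaged
#' over history). These are the values the pipeline should recover from
#' simulated data up to Monte-Carlo error.
#'
#' @param params A `coexhist_params` object.
#' @param c0 Baseline competition multiplier (defaults to `params$c_inter`;
#'   with the package defaults `c_intra == c_inter` so the cell table applies
#'   to monocultures and mixtures alike).
#' @return A list with the 2x2 `cells` table of net RII and the percent
#'   contrasts `history_pct` and `fertilization_pct`.
#' @export
implied_effects <- function(params = default_params(), c0 = params$c_inter) {
  grid <- expand.grid(fertilized = c(TRUE, FALSE), same = c(FALSE, TRUE))
  ce <- effective_competition(c0, grid$fertilized, grid$same,
                              params$gamma_unfert, params$delta_history)
  grid$rii <- (ce - 1) / (ce + 1)
  mm <- function(sub) mean(grid$rii[sub])
  hist_pct <- 100 * (mm(grid$same) - mm(!grid$same)) / abs(mm(!grid$same))
  fert_pct <- 100 * (mm(!grid$fertilized) - mm(grid$fertilized)) /
    abs(mm(grid$fertilized))
  list(cells = grid, history_pct = hist_pct, fertilization_pct = fert_pct)
}

.sown_count <- function(density, area) pmax(1L, round(density * area))

#' Simulate the full experiment
#'
#' Generates individual-level yields and traits, plot-level species yields
#' and biomass, and weekly canopy-light (FPAR) readings for every plot of a
#' design, under the multiplicative competition model described in
#' [default_params()]. Per-plant yield is
#' `baseline x fert multiplier x c_eff x lognormal(-sigma^2/2, sigma)` (noise
#' has unit mean); plot-level species yield is the per-plant mean of the
#' marked individuals times the sown count, so plot and individual tables are
#' mutually consistent and the whole dataset is deterministic at `sigma = 0`.
#' Same-history plots get taller, lower-LDMC phenotypes with shrunken trait
#' dispersion; in mixtures the shrink also pulls species trait means towards
#' the community mean (character convergence).
#'
#' @param design Plot table from [build_design()].
#' @param params A `coexhist_params` object.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `coexhist_dataset`: list with `design`,
#'   `plots` (plot x species yields/biomass), `individuals` (marked plants
#'   with raw trait measurements), `light` (plot x day, three FPAR readings)
#'   and `truth` (the parameters used).
#' @export
simulate_experiment <- function(design, params = default_params(), seed = 1L) {
  validate_params(params)
  sp <- params$species
  unknown <- setdiff(unlist(strsplit(design$members, "+", fixed = TRUE)), sp$code)
  if (length(unknown))
    stop("configuration error: design contains species absent from params: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  reg <- species_registry()
  density <- setNames(reg$sowing_density, reg$code)

  .with_seed(seed, {
    ind_list <- vector("list", nrow(design))
    plot_list <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      pl <- design[i, ]
      members <- strsplit(pl$members, "+", fixed = TRUE)[[1]]
      same <- pl$history_class == "same"
      c0 <- switch(pl$kind, single = 1, monoculture = params$c_intra,
                   mixture = params$c_inter)
      c_eff <- if (pl$kind == "single") 1 else
        effective_competition(c0, pl$fertilized, same,
                              params$gamma_unfert, params$delta_history)

      spi <- sp[match(members, sp$code), ]
      n_mark <- if (pl$kind == "single") 1L else params$n_marked
      # substitutive design: each species occupies 1/S of the plot's rows at
      # its own monoculture density
      n_sown <- if (pl$kind == "single") rep(1L, length(members)) else
        .sown_count(density[members] / length(members), params$plot_area)

      # character convergence: shift then shrink species means towards the
      # community mean in same-history plots
      h_mean <- spi$height_mean * (1 + if (same) params$height_shift_same else 0)
      l_mean <- spi$ldmc_mean * (1 + if (same) params$ldmc_shift_same else 0)
      w_mean <- spi$width_mean
      s_mean <- spi$sla_mean
      m_mean <- spi$seed_mass_mean
      d_mean <- spi$leafdm_mean
      if (same && length(members) > 1L) {
        shrink <- function(m) mean(m) + params$sd_shrink_same * (m - mean(m))
        h_mean <- shrink(h_mean); l_mean <- shrink(l_mean)
        w_mean <- shrink(w_mean); s_mean <- shrink(s_mean)
        m_mean <- shrink(m_mean); d_mean <- shrink(d_mean)
      }
      sd_fac <- params$trait_sd_frac * (if (same) params$sd_shrink_same else 1)

      rows <- vector("list", length(members))
      for (k in seq_along(members)) {
        mu <- spi$base_yield[k] * (if (pl$fertilized) params$fert_mult else 1) *
          c_eff
        noise <- stats::rlnorm(n_mark, meanlog = -params$sigma^2 / 2,
                               sdlog = params$sigma)
        yield <- mu * noise
        biomass <- yield / spi$harvest_index[k]
        tr <- function(m, s, lo = -Inf, hi = Inf)
          pmin(hi, pmax(lo, stats::rnorm(n_mark, m, s * sd_fac)))
        ldmc_i <- tr(l_mean[k], spi$ldmc_sd[k], 0.02, 0.98)
        leafdm <- tr(d_mean[k], spi$leafdm_sd[k], 0.005)
        sla_i <- tr(s_mean[k], spi$sla_sd[k], 10)
        rows[[k]] <- data.frame(
          plot_id = pl$plot_id, species = members[k],
          individual = seq_len(n_mark),
          yield_g = yield, biomass_g = biomass,
          height_cm = tr(h_mean[k], spi$height_sd[k], 1),
          width_cm = tr(w_mean[k], spi$width_sd[k], 1),
          leaf_area_cm2 = sla_i * leafdm,
          leaf_sat_mass_g = leafdm / ldmc_i,
          leaf_dry_mass_g = leafdm,
          seed_mass_g = tr(m_mean[k], spi$seed_mass_sd[k], 1e-4),
          stringsAsFactors = FALSE)
      }
      ind <- do.call(rbind, rows)
      ind_list[[i]] <- ind

      agg_y <- tapply(ind$yield_g, ind$species, mean)[members]
      agg_b <- tapply(ind$biomass_g, ind$species, mean)[members]
      plot_list[[i]] <- data.frame(
        plot_id = pl$plot_id, species = members, n_sown = n_sown,
        yield_g = unname(agg_y) * n_sown,
        biomass_g = unname(agg_b) * n_sown, stringsAsFactors = FALSE)
    }
    individuals <- do.call(rbind, ind_list)
    plots <- do.call(rbind, plot_list)

    # canopy light: logistic closure in time, same-history increment
    lg <- expand.grid(plot_id = design$plot_id, day_of_year = params$fpar_days,
                      stringsAsFactors = FALSE)
    lg <- merge(lg, design[, c("plot_id", "kind", "history_class")],
                by = "plot_id", sort = FALSE)
    fmax <- ifelse(lg$kind == "single", params$fpar_max_single,
                   params$fpar_max) +
      ifelse(lg$history_class == "same", params$fpar_same_increment, 0)
    base <- fmax / (1 + exp(-(lg$day_of_year - params$fpar_midpoint) /
                              params$fpar_rate))
    light <- data.frame(
      plot_id = rep(lg$plot_id, each = 3L),
      day_of_year = rep(lg$day_of_year, each = 3L),
      reading = rep(1:3, nrow(lg)),
      fpar_pct = pmin(100, pmax(0, rep(base, each = 3L) +
                                  stats::rnorm(3L * nrow(lg), 0, params$fpar_sd))),
      stringsAsFactors = FALSE)
    light <- light[order(light$plot_id, light$day_of_year, light$reading), ]
    rownames(light) <- NULL
    rownames(individuals) <- NULL
    rownames(plots) <- NULL

    structure(list(design = design, plots = plots, individuals = individuals,
                   light = light, truth = params),
              class = "coexhist_dataset")
  })
}

#' @export
print.coexhist_dataset <- function(x, ...) {
  cat("coexhist synthetic dataset:",
      nrow(x$design), "plots,", nrow(x$individuals), "marked individuals,",
      nrow(x$light), "light readings\n")
  invisible(x)
}
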