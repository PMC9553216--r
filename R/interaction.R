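#' Relative interaction index
#'
#' `RII = (y_comm - y_single) / (y_comm + y_single)`: a symmetric,
#' standardized index of plant-plant interaction intensity comparing the
#' grain yield of an individual in a community with the mean yield of a
#' conspecific single plant grown in isolation under the same fertilization
#' and coexistence-history stratum. Negative values indicate competition,
#' positive values facilitation; the index is bounded in [-1, 1], is
#' antisymmetric under swapping its arguments and invariant to rescaling
#' both yields by the same factor.
#'
#' @param yield_comm Yield in community (g), `>= 0`.
#' @param yield_single Reference single-plant yield (g).
#' @return Dimensionless index in `[-1, 1]`, vectorized; `NA` inputs
#'   propagate.
#' @export
rii <- function(yield_comm, yield_single) {
  if (any(yield_comm < 0 | yield_single < 0, na.rm = TRUE))
    stop("yields must be non-negative", call. = FALSE)
  if (any(yield_comm == 0 & yield_single == 0, na.rm = TRUE))
    stop("undefined RII: both yields are zero", call. = FALSE)
  (yield_comm - yield_single) / (yield_comm + yield_single)
}

#' Community net relative interaction index
#'
#' Abundance-weighted mean of the species-level RIIs of a plot,
#' `RII_net = sum(RII_i * r_i)`. With the experiment's substitutive design the
#' relative abundance is `r_i = 1/S`, in which case the net index is the
#' unweighted mean over species.
#'
#' @param species_rii Species-level RII values.
#' @param weights Relative abundances, summing to 1; defaults to `1/S`.
#' @return The net index, or `NA` if any species RII is missing.
#' @export
rii_net <- function(species_rii, weights = NULL) {
  s <- length(species_rii)
  if (is.null(weights)) weights <- rep(1 / s, s)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  if (anyNA(species_rii)) return(NA_real_)
  sum(species_rii * weights)
}

#' Coexistence-history contrast on reference performance
#'
#' Same index shape as [rii()] but contrasting the performance of a community
#' type under a community-derived seed history against the matching baseline
#' history: for single plants, singles grown from community seed vs singles
#' grown from single-plant seed; for monocultures, monocultures grown from
#' mixture or single seed vs monocultures grown from monoculture seed.
#'
#' @param yield_focal Mean yield under the focal (non-baseline) history (g).
#' @param yield_baseline Mean yield under the baseline history (g).
#' @return Dimensionless contrast in `[-1, 1]`.
#' @export
rii_coexistence <- function(yield_focal, yield_baseline) {
  rii(yield_focal, yield_baseline)
}

#' Single-plant reference yields
#'
#' Averages the grain yield of isolated single plants per species x
#' fertilization x stratum, the denominator of the individual-level RII. The
#' default stratum is the same/different history class matched to the focal
#' plot; stratification by the raw seed source is available as an option.
#'
#' @param individuals Individual table (needs `plot_id`, `species`,
#'   `yield_g`).
#' @param design Plot table; only `kind == "single"` plots contribute.
#' @param stratify `"history_class"` (default) or `"history_source"`.
#' @return Data frame `species`, `fertilized`, stratum column,
#'   `reference_yield_g`, `n_reps`. Strata absent from the data are simply
#'   absent (downstream joins yield `NA`, never zero).
#' @export
build_single_reference <- function(individuals, design,
                                   stratify = c("history_class", "history_source")) {
  stratify <- match.arg(stratify)
  d <- merge(individuals, design, by = "plot_id")
  d <- d[d$kind == "single" & !is.na(d$yield_g), ]
  if (!nrow(d)) {
    out <- data.frame(species = character(), fertilized = logical(),
                      stratum = character(), reference_yield_g = numeric(),
                      n_reps = integer(), stringsAsFactors = FALSE)
    names(out)[3] <- stratify
    return(out)
  }
  agg <- aggregate(d$yield_g,
                   by = list(species = d$species, fertilized = d$fertilized,
                             stratum = d[[stratify]]),
                   FUN = function(x) c(mean = mean(x), n = length(x)))
  out <- data.frame(agg[1:3], reference_yield_g = agg$x[, "mean"],
                    n_reps = as.integer(agg$x[, "n"]))
  names(out)[3] <- stratify
  out[order(out$species, out$fertilized, out[[3]]), , drop = FALSE]
}

#' Individual, species and plot-level RII for a dataset
#'
#' The metrics stage of the pipeline: builds the single-plant reference,
#' computes RII for every marked individual of every community plot against
#' the reference of its species x fertilization x history stratum, averages
#' individuals within species (default; pooling all individuals before
#' averaging is available and coincides with the default when plots are
#' balanced), and forms the plot-level net RII with `r_i = 1/S` weights.
#' Plots whose reference stratum is missing get `NA` with a reason, never an
#' implicit zero.
#'
#' @param dataset A `coexhist_dataset`, or a list with `design`,
#'   `individuals`.
#' @param stratify Reference stratification, see [build_single_reference()].
#' @param average `"species_first"` (default) or `"pooled"`.
#' @return List with `reference`, `individual_rii`, `species_rii` and
#'   `plot_rii` data frames; `plot_rii` has `plot_id`, `rii_net`,
#'   `n_species`, `reason` (NA when complete).
#' @export
compute_rii <- function(dataset, stratify = "history_class",
                        average = c("species_first", "pooled")) {
  average <- match.arg(average)
  design <- dataset$design
  ref <- build_single_reference(dataset$individuals, design, stratify)

  comm <- merge(dataset$individuals,
                design[, c("plot_id", "kind", "fertilized", "history_class",
                           "history_source")],
                by = "plot_id")
  comm <- comm[comm$kind != "single", ]
  comm <- merge(comm, ref, by = c("species", "fertilized", stratify),
                all.x = TRUE, sort = FALSE)
  comm$rii <- ifelse(is.na(comm$reference_yield_g), NA_real_,
                     (comm$yield_g - comm$reference_yield_g) /
                       (comm$yield_g + comm$reference_yield_g))

  sp_fun <- function(x) mean(x)
  species_rii <- aggregate(rii ~ plot_id + species, data = comm, FUN = sp_fun,
                           na.action = stats::na.pass)

  if (average == "species_first") {
    per_plot <- split(species_rii$rii, species_rii$plot_id)
  } else {
    per_plot <- split(comm$rii, comm$plot_id)
  }
  plot_rii <- data.frame(
    plot_id = names(per_plot),
    rii_net = vapply(per_plot, function(v) if (anyNA(v)) NA_real_ else mean(v),
                     0.0),
    n_species = vapply(split(species_rii$species, species_rii$plot_id),
                       length, 0L)[names(per_plot)],
    stringsAsFactors = FALSE)
  plot_rii$reason <- ifelse(is.na(plot_rii$rii_net), "missing-reference",
                            NA_character_)
  rownames(plot_rii) <- NULL
  list(reference = ref,
       individual_rii = comm[, c("plot_id", "species", "individual",
                                 "yield_g", "reference_yield_g", "rii")],
       species_rii = species_rii,
       plot_rii = plot_rii)
}

#' Coexistence-history contrasts for singles and monocultures
#'
#' Computes [rii_coexistence()] per species x fertilization: for singles,
#' each community-derived seed history (from monocultures or from the pooled
#' mixture lot) against the single-seed baseline; for monocultures, each
#' non-monoculture seed history against the monoculture-seed baseline.
#' Single-plant yields come from the individuals table, monoculture yields
#' from plot totals.
#'
#' @param dataset A `coexhist_dataset`-like list.
#' @return Data frame with `community` (`single`/`monoculture`), `species`,
#'   `fertilized`, `focal_source`, focal and baseline mean yields, and
#'   `rii_coexistence`.
#' @export
rii_coexistence_table <- function(dataset) {
  design <- dataset$design
  rows <- list()

  contrast <- function(df, community) {
    base_src <- if (community == "single") "single" else "monoculture"
    out <- list()
    for (spc in unique(df$species)) for (f in unique(df$fertilized)) {
      sub <- df[df$species == spc & df$fertilized == f, ]
      base <- mean(sub$y[sub$history_source == base_src])
      for (src in setdiff(unique(sub$history_source), base_src)) {
        foc <- mean(sub$y[sub$history_source == src])
        if (!is.finite(base) || !is.finite(foc)) next
        out[[length(out) + 1L]] <- data.frame(
          community = community, species = spc, fertilized = f,
          focal_source = src, focal_yield_g = foc, baseline_yield_g = base,
          rii_coexistence = rii_coexistence(foc, base),
          stringsAsFactors = FALSE)
      }
    }
    out
  }

  si <- merge(dataset$individuals, design, by = "plot_id")
  si <- si[si$kind == "single", ]
  si$y <- si$yield_g
  rows <- c(rows, contrast(si, "single"))

  mo <- merge(dataset$plots, design, by = "plot_id")
  mo <- mo[mo$kind == "monoculture", ]
  mo$y <- mo$yield_g
  rows <- c(rows, contrast(mo, "monoculture"))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
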