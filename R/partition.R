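#' Expected mixture yield from monocrop references
#'
#' `Y_E = sum(r_i * M_i)`: the yield a mixture would produce if every species
#' performed as in its monoculture, weighted by its proportion in the
#' mixture.
#'
#' @param monocrop_means Per-species monoculture plot yields `M_i` (g).
#' @param proportions Species proportions `r_i`, summing to 1; defaults to
#'   `1/N`.
#' @return Expected yield (g); `NA` if any `M_i` is missing.
#' @export
expected_yield <- function(monocrop_means, proportions = NULL) {
  n <- length(monocrop_means)
  if (is.null(proportions)) proportions <- rep(1 / n, n)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1", call. = FALSE)
  if (anyNA(monocrop_means)) return(NA_real_)
  if (any(monocrop_means <= 0))
    stop("invalid reference: monocrop means must be positive", call. = FALSE)
  sum(proportions * monocrop_means)
}

#' Additive partition of the net biodiversity effect
#'
#' Loreau-Hector partition of overyielding: with `dRY_i = Yo_i/M_i - r_i`,
#' `NE = Yo - Y_E = CE + SE` where `CE = N * mean(dRY) * mean(M)` is the
#' complementarity effect and `SE = N * cov_pop(dRY, M)` the selection
#' effect, using the population covariance (1/N denominator) so the identity
#' is exact. The partition is invariant to the ordering of species.
#'
#' @param observed_yields Observed per-species mixture yields `Yo_i` (g).
#' @param monocrop_means Monoculture reference yields `M_i` (g), `> 0`.
#' @param proportions Species proportions `r_i`; defaults to `1/N`
#'   (substitutive design).
#' @return List with `Yo`, `YE`, `NE`, `CE`, `SE`, and the per-species
#'   vectors `dRY` and `M`.
#' @export
partition_effects <- function(observed_yields, monocrop_means,
                              proportions = NULL) {
  n <- length(observed_yields)
  if (n < 2L) stop("partition requires at least two species", call. = FALSE)
  if (length(monocrop_means) != n)
    stop("observed and monocrop vectors differ in length", call. = FALSE)
  if (anyNA(monocrop_means))
    return(list(Yo = sum(observed_yields), YE = NA_real_, NE = NA_real_,
                CE = NA_real_, SE = NA_real_, dRY = rep(NA_real_, n),
                M = monocrop_means))
  if (any(monocrop_means <= 0))
    stop("invalid reference: monocrop means must be positive", call. = FALSE)
  if (is.null(proportions)) proportions <- rep(1 / n, n)

  dRY <- observed_yields / monocrop_means - proportions
  covp <- mean((dRY - mean(dRY)) * (monocrop_means - mean(monocrop_means)))
  CE <- n * mean(dRY) * mean(monocrop_means)
  SE <- n * covp
  Yo <- sum(observed_yields)
  YE <- expected_yield(monocrop_means, proportions)
  list(Yo = Yo, YE = YE, NE = Yo - YE, CE = CE, SE = SE, dRY = dRY,
       M = monocrop_means)
}

#' Monocrop reference yields
#'
#' Averages monoculture plot yields per species x fertilization x stratum,
#' the `M_i` references of the biodiversity-effect partition. As with the
#' RII reference, the stratum defaults to the same/different history class
#' so a mixture is compared with monocultures sharing its coexistence
#' history.
#'
#' @param plots Plot-level yield table (`plot_id`, `species`, `yield_g`).
#' @param design Plot table; only monoculture plots contribute.
#' @param stratify `"history_class"` (default) or `"history_source"`.
#' @return Data frame `species`, `fertilized`, stratum, `monocrop_yield_g`,
#'   `n_reps`; empty strata are absent (joins give `NA`).
#' @export
build_monocrop_reference <- function(plots, design,
                                     stratify = c("history_class", "history_source")) {
  stratify <- match.arg(stratify)
  d <- merge(plots, design, by = "plot_id")
  d <- d[d$kind == "monoculture" & !is.na(d$yield_g), ]
  if (!nrow(d)) {
    out <- data.frame(species = character(), fertilized = logical(),
                      stratum = character(), monocrop_yield_g = numeric(),
                      n_reps = integer(), stringsAsFactors = FALSE)
    names(out)[3] <- stratify
    return(out)
  }
  agg <- aggregate(d$yield_g,
                   by = list(species = d$species, fertilized = d$fertilized,
                             stratum = d[[stratify]]),
                   FUN = function(x) c(mean = mean(x), n = length(x)))
  out <- data.frame(agg[1:3], monocrop_yield_g = agg$x[, "mean"],
                    n_reps = as.integer(agg$x[, "n"]))
  names(out)[3] <- stratify
  out[order(out$species, out$fertilized, out[[3]]), , drop = FALSE]
}

#' Total plot grain yield
#'
#' Sum of the per-species seed mass of a plot.
#'
#' @param species_yields Per-species plot yields (g), `>= 0`.
#' @return Total yield (g).
#' @export
total_yield <- function(species_yields) {
  if (any(species_yields < 0, na.rm = TRUE))
    stop("yields must be non-negative", call. = FALSE)
  sum(species_yields)
}

#' Net biodiversity effect partition for every mixture plot
#'
#' The partition stage of the pipeline: builds the monocrop reference, then
#' for each mixture plot joins each species' `M_i` from the stratum matching
#' the plot's fertilization and history class and applies
#' [partition_effects()] with `r_i = 1/N`. Plots with missing monocrop
#' strata yield `NA` components with a reason.
#'
#' @param dataset A `coexhist_dataset`-like list with `design` and `plots`.
#' @param stratify Reference stratification, see
#'   [build_monocrop_reference()].
#' @return List with `reference` and `partition` (one row per mixture plot:
#'   `plot_id`, `Yo`, `YE`, `NE`, `CE`, `SE`, `n_species`, `reason`).
#' @export
compute_partition <- function(dataset, stratify = "history_class") {
  design <- dataset$design
  ref <- build_monocrop_reference(dataset$plots, design, stratify)
  mix <- design[design$kind == "mixture", ]
  py <- dataset$plots

  rows <- vector("list", nrow(mix))
  for (i in seq_len(nrow(mix))) {
    pl <- mix[i, ]
    members <- strsplit(pl$members, "+", fixed = TRUE)[[1]]
    yo <- py$yield_g[match(paste(pl$plot_id, members),
                           paste(py$plot_id, py$species))]
    key <- paste(members, pl$fertilized, pl[[stratify]])
    m <- ref$monocrop_yield_g[match(key, paste(ref$species, ref$fertilized,
                                               ref[[stratify]]))]
    res <- partition_effects(yo, m)
    rows[[i]] <- data.frame(
      plot_id = pl$plot_id, Yo = res$Yo, YE = res$YE, NE = res$NE,
      CE = res$CE, SE = res$SE, n_species = length(members),
      reason = if (anyNA(m)) "missing-monocrop-reference" else NA_character_,
      stringsAsFactors = FALSE)
  }
  part <- do.call(rbind, rows)
  rownames(part) <- NULL
  list(reference = ref, partition = part)
}
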