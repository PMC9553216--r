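#' Leaf dry matter content
#'
#' Ratio of leaf dry mass to water-saturated leaf mass, in g/g; lies in
#' (0, 1] for physically valid measurements.
#'
#' @param dry_mass,saturated_mass Leaf masses (g).
#' @return LDMC (g/g), vectorized.
#' @export
ldmc <- function(dry_mass, saturated_mass) {
  if (any(saturated_mass <= 0, na.rm = TRUE))
    stop("invalid measurement: saturated mass must be positive", call. = FALSE)
  if (any(dry_mass > saturated_mass + 1e-12, na.rm = TRUE))
    stop("invalid measurement: dry mass exceeds saturated mass", call. = FALSE)
  dry_mass / saturated_mass
}

#' Specific leaf area
#'
#' Ratio of one-sided leaf area (cm2) to leaf dry mass (g).
#'
#' @param leaf_area Leaf area (cm2).
#' @param dry_mass Leaf dry mass (g), `> 0`.
#' @return SLA (cm2/g), vectorized.
#' @export
sla <- function(leaf_area, dry_mass) {
  if (any(dry_mass <= 0, na.rm = TRUE))
    stop("invalid measurement: dry mass must be positive", call. = FALSE)
  leaf_area / dry_mass
}

#' Community-weighted mean
#'
#' Average of species trait values weighted by species relative biomass;
#' bounded by the minimum and maximum species mean.
#'
#' @param trait_means Species-level trait means.
#' @param weights Non-negative weights (biomass fractions); normalized to
#'   sum to 1.
#' @return The weighted mean, or `NA` if total weight is zero.
#' @export
cwm <- function(trait_means, weights) {
  if (any(weights < 0, na.rm = TRUE))
    stop("weights must be non-negative", call. = FALSE)
  tot <- sum(weights)
  if (!isTRUE(tot > 0)) return(NA_real_)
  sum(trait_means * weights / tot)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean;
#' scale-invariant.
#'
#' @param values Numeric vector; needs at least 2 finite values.
#' @return CV (dimensionless); `NA` for fewer than 2 values or a zero mean.
#' @export
cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  stats::sd(values) / m
}

#' Weekly plot-level canopy light interception
#'
#' Arithmetic mean of the three FPAR readings taken per plot and week,
#' each calibrated against the ambient sensor and expressed in percent.
#'
#' @param readings FPAR readings (%), all in `[0, 100]`.
#' @return Mean FPAR (%).
#' @export
fpar_plot_week <- function(readings) {
  if (any(readings < 0 | readings > 100, na.rm = TRUE))
    stop("FPAR readings must lie in [0, 100]", call. = FALSE)
  mean(readings)
}

#' Exact convex-hull volume of a point set
#'
#' Computes the d-dimensional volume of the convex hull of `n` points by
#' recursive supporting-hyperplane enumeration: every d-subset spanning a
#' hyperplane with all remaining points on one side is a (piece of a) hull
#' facet; facet (d-1)-volumes are computed recursively in an orthonormal
#' in-plane basis and assembled into pyramids over the centroid. Exact for
#' the small per-plot point sets of this analysis (coplanar facet points are
#' handled by merging hyperplanes, so boxes and grids work, not only points
#' in general position).
#'
#' @param points Numeric matrix, rows = points, columns = dimensions.
#' @param tol Tolerance for sidedness/coplanarity tests.
#' @return Hull volume; `0` when the points are affinely degenerate in the
#'   ambient dimension.
#' @export
convhull_volume <- function(points, tol = 1e-9) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (n < d + 1L) return(0)
  if (d == 1L) return(diff(range(points)))

  ctr <- colMeans(points)
  cen <- sweep(points, 2L, ctr)
  scale <- max(abs(cen), 1)
  if (qr(cen, tol = tol)$rank < d) return(0)

  hp_normals <- list(); hp_offsets <- numeric(0)
  combs <- utils::combn(n, d)
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    A <- points[idx, , drop = FALSE]
    B <- sweep(A[-1L, , drop = FALSE], 2L, A[1L, ])
    sv <- svd(B, nu = 0, nv = d)
    if (sv$d[d - 1L] <= tol * scale) next       # degenerate subset
    nrm <- sv$v[, d]
    off <- sum(nrm * A[1L, ])
    side <- points %*% nrm - off
    if (!(all(side <= tol * scale) || all(side >= -tol * scale))) next
    # canonical orientation, then dedupe
    s <- sign(nrm[which(abs(nrm) > 1e-12)[1L]])
    nrm <- nrm * s; off <- off * s
    dup <- FALSE
    for (k in seq_along(hp_normals)) {
      if (max(abs(hp_normals[[k]] - nrm)) < 1e-7 &&
          abs(hp_offsets[k] - off) < 1e-7 * scale) { dup <- TRUE; break }
    }
    if (!dup) {
      hp_normals[[length(hp_normals) + 1L]] <- nrm
      hp_offsets <- c(hp_offsets, off)
    }
  }

  vol <- 0
  for (k in seq_along(hp_normals)) {
    nrm <- hp_normals[[k]]; off <- hp_offsets[k]
    on_plane <- abs(points %*% nrm - off) <= 10 * tol * scale
    S <- points[on_plane, , drop = FALSE]
    # orthonormal in-plane basis from the normal's complement
    basis <- svd(diag(d) - tcrossprod(nrm))$u[, seq_len(d - 1L), drop = FALSE]
    coords <- sweep(S, 2L, S[1L, ]) %*% basis
    fv <- if (d - 1L == 1L) diff(range(coords)) else convhull_volume(coords, tol)
    h <- abs(sum(ctr * nrm) - off)
    vol <- vol + fv * h / d
  }
  vol
}

#' Functional richness of a plot
#'
#' Convex-hull volume occupied by the marked individuals of a plot in
#' standardized trait space. Traits are expected to be standardized (zero
#' mean, unit variance) across the whole dataset before calling. When the
#' plot has too few individuals to span the ambient trait space (fewer than
#' d + 1 points, or affine rank below d), the points are projected onto
#' their leading principal axes, the hull volume is computed in that reduced
#' space, and the reduced dimension is reported; configurations that remain
#' degenerate (fewer than 2 effective dimensions' worth of spread, or < 3
#' points) yield `NA`.
#'
#' @param trait_matrix Numeric matrix, individuals x traits.
#' @param tol Degeneracy tolerance.
#' @return List with `volume`, `dim` (dimension actually used) and
#'   `degenerate` flag.
#' @export
fric <- function(trait_matrix, tol = 1e-9) {
  m <- as.matrix(trait_matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); d <- ncol(m)
  if (n < 3L)
    return(list(volume = NA_real_, dim = NA_integer_, degenerate = TRUE))
  cen <- sweep(m, 2L, colMeans(m))
  rank <- qr(cen, tol = 1e-8)$rank
  target <- min(n - 1L, rank, d)
  if (target < 1L)
    return(list(volume = NA_real_, dim = NA_integer_, degenerate = TRUE))
  if (target < d) {
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    m <- pc$x[, seq_len(target), drop = FALSE]
    d <- target
  }
  if (n < d + 1L)
    return(list(volume = NA_real_, dim = d, degenerate = TRUE))
  v <- convhull_volume(m, tol)
  list(volume = v, dim = d, degenerate = FALSE)
}

#' Derive leaf traits on the individuals table
#'
#' Adds `sla_cm2_g` (leaf area / dry mass) and `ldmc_g_g` (dry mass /
#' saturated mass) columns computed from the raw leaf measurements.
#'
#' @param individuals Individuals table with `leaf_area_cm2`,
#'   `leaf_dry_mass_g`, `leaf_sat_mass_g`.
#' @return The table with the two derived columns appended.
#' @export
derive_traits <- function(individuals) {
  individuals$sla_cm2_g <- sla(individuals$leaf_area_cm2,
                               individuals$leaf_dry_mass_g)
  individuals$ldmc_g_g <- ldmc(individuals$leaf_dry_mass_g,
                               individuals$leaf_sat_mass_g)
  individuals
}

.default_traits <- c("height_cm", "width_cm", "sla_cm2_g", "ldmc_g_g",
                     "seed_mass_g")

#' Species- and community-level trait summaries
#'
#' The trait stage of the pipeline. Per species x plot: trait means and CVs
#' over the marked individuals. Per plot: community-weighted means (weights =
#' per-species share of plot aboveground biomass), the community-level CV
#' pooling all marked individuals of the plot, and functional richness as
#' the convex-hull volume in trait space standardized (zero mean, unit
#' variance) across all individuals of the dataset.
#'
#' @param dataset A `coexhist_dataset`-like list (`design`, `individuals`,
#'   `plots`).
#' @param traits Trait columns entering the summaries and the FRic hull.
#' @return List with `species_traits` (plot x species means and CVs),
#'   `plot_traits` (CWM and CV per trait, plus `fric`, `fric_dim`) — both
#'   restricted to community plots.
#' @export
trait_summaries <- function(dataset, traits = .default_traits) {
  ind <- derive_traits(dataset$individuals)
  design <- dataset$design
  ind <- merge(ind, design[, c("plot_id", "kind")], by = "plot_id")
  comm <- ind[ind$kind != "single", ]

  sp_rows <- list()
  for (tr in traits) {
    agg <- aggregate(comm[[tr]], by = list(plot_id = comm$plot_id,
                                           species = comm$species),
                     FUN = function(x) c(mean(x), cv(x)))
    sp_rows[[tr]] <- data.frame(agg[1:2], trait = tr,
                                mean = agg$x[, 1], cv = agg$x[, 2],
                                stringsAsFactors = FALSE)
  }
  species_traits <- do.call(rbind, sp_rows)
  rownames(species_traits) <- NULL

  # biomass weights from plot-level per-species biomass
  w <- dataset$plots[, c("plot_id", "species", "biomass_g")]

  std <- scale(as.matrix(ind[, traits]))   # dataset-wide standardization
  plot_ids <- unique(comm$plot_id)
  pt <- vector("list", length(plot_ids))
  for (i in seq_along(plot_ids)) {
    pid <- plot_ids[i]
    sub <- comm[comm$plot_id == pid, ]
    row <- list(plot_id = pid)
    for (tr in traits) {
      spm <- tapply(sub[[tr]], sub$species, mean)
      wt <- w$biomass_g[w$plot_id == pid][
        match(names(spm), w$species[w$plot_id == pid])]
      row[[paste0("cwm_", tr)]] <- cwm(as.numeric(spm), as.numeric(wt))
      row[[paste0("cv_", tr)]] <- cv(sub[[tr]])
    }
    fr <- fric(std[ind$plot_id == pid & ind$kind != "single", , drop = FALSE])
    row$fric <- fr$volume
    row$fric_dim <- fr$dim
    pt[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  plot_traits <- do.call(rbind, pt)
  rownames(plot_traits) <- NULL
  list(species_traits = species_traits, plot_traits = plot_traits)
}
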