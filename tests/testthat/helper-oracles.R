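# Independent oracles and small fixtures shared across the suite.

# Exhaustive-enumeration oracle for admissible pair/quad counts given a
# group assignment (named character vector code -> group).
oracle_pair_count <- function(groups) {
  codes <- names(groups)
  cnt <- 0L
  for (i in seq_along(codes)) for (j in seq_along(codes)) {
    if (i < j && groups[i] != groups[j]) cnt <- cnt + 1L
  }
  cnt
}

oracle_quad_count <- function(groups) {
  all_groups <- c("monocot", "superasterid", "legume", "superrosid_nonlegume")
  sizes <- vapply(all_groups, function(g) sum(groups == g), 0L)
  prod(sizes)
}

# 2-D convex hull area by base-R chull ordering + shoelace formula —
# independent of the package's facet-enumeration algorithm.
oracle_hull_area_2d <- function(pts) {
  h <- grDevices::chull(pts)
  p <- pts[h, , drop = FALSE]
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  unname(abs(s) / 2)
}

# Brute-force population covariance.
oracle_cov_pop <- function(x, y) mean(x * y) - mean(x) * mean(y)

# A species table whose registry invariants hold, for randomized design
# property tests.
random_group_assignment <- function() {
  groups <- c("monocot", "superasterid", "legume", "superrosid_nonlegume")
  setNames(sample(groups, 6, replace = TRUE), c("A", "B", "C", "D", "E", "F"))
}

species_table_from_groups <- function(groups) {
  data.frame(code = names(groups), name = names(groups),
             phylo_group = unname(groups),
             sowing_density = 160, stringsAsFactors = FALSE)
}

# Small deterministic dataset used by several module tests.
small_dataset <- function(sigma = 0, delta = 0, gamma = 0,
                          c_intra = 0.5, c_inter = 0.5, seed = 42, ...) {
  des <- build_design(seed = 1)
  p <- default_params(sigma = sigma, delta_history = delta,
                      gamma_unfert = gamma, c_intra = c_intra,
                      c_inter = c_inter, ...)
  simulate_experiment(des, p, seed = seed)
}
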