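#' Species registry for the crop-diversity experiment
#'
#' Six annual seed crops spanning four phylogenetic groups: two monocots
#' (wheat, oat), one superasterid (coriander), one legume (lentil) and two
#' non-legume superrosids (flax, camelina). Sowing densities follow current
#' cultivation practice and are given per square metre of monoculture; in
#' mixtures each species keeps its monoculture density within its own rows.
#'
#' @return A data frame with one row per species and columns `code`, `name`,
#'   `phylo_group` and `sowing_density` (seeds per m2).
#' @examples
#' species_registry()
#' @export
species_registry <- function() {
  data.frame(
    code = c("Av", "Ca", "Co", "Le", "Li", "Tr"),
    name = c("oat", "camelina", "coriander", "lentil", "flax", "wheat"),
    phylo_group = c("monocot", "superrosid_nonlegume", "superasterid",
                    "legume", "superrosid_nonlegume", "monocot"),
    sowing_density = c(400, 592, 240, 160, 592, 400),
    stringsAsFactors = FALSE
  )
}

.phylo_groups <- c("monocot", "superasterid", "legume", "superrosid_nonlegume")

.check_species_table <- function(species) {
  needed <- c("code", "phylo_group", "sowing_density")
  if (!all(needed %in% names(species)))
    stop("invalid design: species table needs columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (anyDuplicated(species$code))
    stop("invalid design: duplicated species codes", call. = FALSE)
  bad <- setdiff(unique(species$phylo_group), .phylo_groups)
  if (length(bad))
    stop("invalid design: unknown phylogenetic group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(species)
}

comp_members <- function(comp_id) strsplit(comp_id, "+", fixed = TRUE)

#' Enumerate admissible community compositions
#'
#' Builds the complete composition set of the experiment: one single and one
#' monoculture per species, every 2-species combination whose members belong
#' to two distinct phylogenetic groups, and every 4-species combination with
#' exactly one species per phylogenetic group. With the registry's group
#' sizes (2, 1, 1, 2) this yields 13 pairs and 4 quads.
#'
#' @param species Species table as returned by [species_registry()].
#' @return A data frame with columns `comp_id` (species codes joined by
#'   `"+"`, sorted), `kind` (`single`, `monoculture` or `mixture`),
#'   `richness` and `members` (the `"+"`-joined code string). Ordering is
#'   deterministic: by kind, then richness, then code.
#' @export
enumerate_compositions <- function(species = species_registry()) {
  .check_species_table(species)
  codes <- sort(species$code)
  grp <- setNames(species$phylo_group, species$code)

  singles <- data.frame(comp_id = paste0("S:", codes), kind = "single",
                        richness = 1L, members = codes,
                        stringsAsFactors = FALSE)
  monos <- data.frame(comp_id = paste0("M:", codes), kind = "monoculture",
                      richness = 1L, members = codes,
                      stringsAsFactors = FALSE)

  pairs <- utils::combn(codes, 2L, simplify = FALSE)
  pairs <- Filter(function(p) grp[p[1]] != grp[p[2]], pairs)

  quads <- list()
  if (all(lengths(split(codes, grp[codes])[.phylo_groups]) > 0L)) {
    by_grp <- lapply(.phylo_groups, function(g) codes[grp[codes] == g])
    quads <- apply(expand.grid(by_grp, stringsAsFactors = FALSE), 1L,
                   function(q) sort(unname(unlist(q))), simplify = FALSE)
  }

  mix_df <- function(sets) {
    if (!length(sets))
      return(data.frame(comp_id = character(), kind = character(),
                        richness = integer(), members = character(),
                        stringsAsFactors = FALSE))
    mem <- vapply(sets, paste, "", collapse = "+")
    mem <- sort(mem)
    data.frame(comp_id = mem, kind = "mixture",
               richness = lengths(strsplit(mem, "+", fixed = TRUE)),
               members = mem, stringsAsFactors = FALSE)
  }
  out <- rbind(singles, monos, mix_df(pairs), mix_df(quads))
  out <- out[order(match(out$kind, c("single", "monoculture", "mixture")),
                   out$richness, out$comp_id), ]
  rownames(out) <- NULL
  out
}

#' Classify the coexistence history of a plot
#'
#' A plot has the *same* coexistence history when its plants grow in the same
#' community type their seeds were collected from: monocultures sown from
#' monoculture seed, singles from single-plant seed, and mixtures from seed of
#' the identical species combination. Everything else (monocultures from
#' singles or from the pooled 4-species-mixture seed lot, mixtures from
#' singles or monocultures, and mixture seed of a different composition) is
#' classified *different*.
#'
#' @param kind Community kind of the focal plot: `single`, `monoculture` or
#'   `mixture`.
#' @param source_kind Community kind the seeds were harvested from.
#' @param composition,source_composition `"+"`-joined member strings; only
#'   consulted for mixture-from-mixture, where they must be identical for a
#'   `same` classification. Seed-pool tokens such as `"pooled-4mix"` never
#'   match a composition.
#' @return `"same"` or `"different"` (vectorized).
#' @export
classify_history <- function(kind, source_kind, composition = NA_character_,
                             source_composition = NA_character_) {
  kinds <- c("single", "monoculture", "mixture")
  if (!all(kind %in% kinds) || !all(source_kind %in% kinds))
    stop("kind and source_kind must be one of: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  same <- kind == source_kind
  need_comp <- same & kind == "mixture"
  same[need_comp] <- !is.na(composition[need_comp]) &
    !is.na(source_composition[need_comp]) &
    composition[need_comp] == source_composition[need_comp]
  ifelse(same, "same", "different")
}

#' Build the full plot table of the experiment
#'
#' Expands the composition set over fertilization levels, coexistence-history
#' seed sources and replicates, derives the same/different history class, and
#' assigns plots to beds and within-bed columns by seeded randomization.
#' Community plots (monocultures and mixtures) and single plants are placed
#' in separate beds, and beds are never shared between fertilization levels,
#' mirroring bed-level fertilizer application. With the default replication
#' (2 community replicates, 4 single replicates, 2 fertilization levels,
#' 3 seed sources) the design holds 276 community plots, of which 204 are
#' mixtures.
#'
#' @param compositions Composition table from [enumerate_compositions()].
#' @param n_rep_community,n_rep_single Replicates per composition x
#'   fertilization x seed source cell.
#' @param fert_levels Logical vector of fertilization levels.
#' @param history_sources Seed-source community kinds.
#' @param bed_capacity Plots per bed.
#' @param seed Integer seed for the bed/column randomization.
#' @return A data frame of plots with columns `plot_id`, `comp_id`, `kind`,
#'   `richness`, `members`, `fertilized`, `history_source`,
#'   `source_composition`, `history_class`, `replicate`, `bed`, `column`.
#' @export
build_design <- function(compositions = enumerate_compositions(),
                         n_rep_community = 2L, n_rep_single = 4L,
                         fert_levels = c(TRUE, FALSE),
                         history_sources = c("single", "monoculture", "mixture"),
                         bed_capacity = 28L, seed = 1L) {
  if (n_rep_community < 1L || n_rep_single < 1L)
    stop("replicate counts must be positive", call. = FALSE)

  one_cell <- function(i) {
    comp <- compositions[i, ]
    nrep <- if (comp$kind == "single") n_rep_single else n_rep_community
    grid <- expand.grid(fertilized = fert_levels, history_source = history_sources,
                        replicate = seq_len(nrep), stringsAsFactors = FALSE)
    grid$comp_id <- comp$comp_id
    grid$kind <- comp$kind
    grid$richness <- comp$richness
    grid$members <- comp$members
    grid
  }
  des <- do.call(rbind, lapply(seq_len(nrow(compositions)), one_cell))

  # seed provenance: same-kind sources carry the concrete composition;
  # monocultures/singles sown "from mixture" use the pooled 4-species lot
  des$source_composition <- ifelse(
    des$history_source == des$kind, des$members,
    ifelse(des$history_source == "mixture", "pooled-4mix",
           ifelse(des$history_source == "monoculture", "own-monocultures",
                  "own-singles")))
  des$history_class <- classify_history(des$kind, des$history_source,
                                        des$members, des$source_composition)

  des <- des[order(des$kind != "single", des$comp_id, des$fertilized,
                   des$history_source, des$replicate), ]
  des$plot_id <- sprintf("P%03d", seq_len(nrow(des)))

  # bed assignment: shuffle within (single vs community) x fertilization,
  # then fill beds of bed_capacity; column = position within bed
  rng <- .with_seed(seed, {
    des$bed <- NA_character_
    des$column <- NA_character_
    bed_no <- 0L
    for (single in c(FALSE, TRUE)) for (fert in unique(des$fertilized)) {
      idx <- which((des$kind == "single") == single & des$fertilized == fert)
      idx <- sample(idx)
      nbed <- ceiling(length(idx) / bed_capacity)
      beds <- rep(seq_len(nbed), each = bed_capacity)[seq_along(idx)]
      des$bed[idx] <- sprintf("B%02d", bed_no + beds)
      des$column[idx] <- sprintf("C%02d", stats::ave(beds, beds, FUN = seq_along))
      bed_no <- bed_no + nbed
    }
    des
  })
  des <- rng
  cols <- c("plot_id", "comp_id", "kind", "richness", "members", "fertilized",
            "history_source", "source_composition", "history_class",
            "replicate", "bed", "column")
  des <- des[, cols]
  rownames(des) <- NULL
  des
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  force(seed)   # before saving state: seed may itself be drawn from the RNG
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
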