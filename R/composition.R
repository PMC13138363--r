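MARKERS <- c("insulin", "glucagon", "somatostatin", "pdx1", "brn4")

#' Define a marker profile
#'
#' A profile is a required-positive set and a required-negative set over the
#' five endocrine markers (insulin, glucagon, somatostatin, PDX1, BRN4);
#' markers in neither set are unconstrained. E.g. beta cells are
#' insulin+glucagon- and alpha cells insulin-glucagon+.
#'
#' @param positive character vector of markers required positive.
#' @param negative character vector of markers required negative.
#' @param name optional display name.
#' @return object of class `marker_profile`.
#' @export
marker_profile <- function(positive = character(0), negative = character(0),
                           name = NULL) {
  positive <- match.arg(positive, MARKERS, several.ok = TRUE)
  if (length(negative)) negative <- match.arg(negative, MARKERS, several.ok = TRUE)
  if (length(intersect(positive, negative)))
    stopf("positive and negative marker sets must be disjoint")
  if (is.null(name)) {
    pos <- if (length(positive)) paste0(positive, "+") else character(0)
    neg <- if (length(negative)) paste0(negative, "-") else character(0)
    name <- paste0(c(pos, neg), collapse = "")
  }
  structure(list(positive = positive, negative = negative, name = name),
            class = "marker_profile")
}

#' Standard endocrine marker profiles
#'
#' The profiles tabulated in composition studies: any-positive profiles for
#' each marker, beta (insulin+glucagon-), alpha (insulin-glucagon+),
#' bihormonal insulin+glucagon+, and the PDX1/BRN4 plasticity profiles.
#'
#' @return named list of [marker_profile()] objects.
#' @export
standard_profiles <- function() {
  list(
    insulin_pos   = marker_profile("insulin"),
    beta          = marker_profile("insulin", "glucagon", name = "insulin+glucagon-"),
    ins_glu_dpos  = marker_profile(c("insulin", "glucagon")),
    glucagon_pos  = marker_profile("glucagon"),
    alpha         = marker_profile("glucagon", "insulin", name = "insulin-glucagon+"),
    glu_brn4      = marker_profile(c("glucagon", "brn4"), c("insulin", "pdx1")),
    pdx1_pos      = marker_profile("pdx1"),
    brn4_pos      = marker_profile("brn4"),
    pdx1_brn4     = marker_profile(c("pdx1", "brn4")),
    somatostatin_pos = marker_profile("somatostatin"))
}

validate_cell_table <- function(cells) {
  need <- c("cell_id", "islet_id", "dapi_positive", MARKERS)
  miss <- setdiff(need, names(cells))
  if (length(miss)) stopf("cell table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(cells$cell_id)) stopf("cell_id must be unique")
  for (m in c("dapi_positive", MARKERS)) {
    if (any(is.na(cells[[m]]))) stopf("marker flag '%s' contains NA", m)
  }
  invisible(cells)
}

#' Islet positivity rule
#'
#' An islet is positive iff it contains at least three insulin-positive cells
#' or at least three glucagon-positive cells (among DAPI-positive cells).
#' Only positive islets enter composition summaries.
#'
#' @param cells cell table rows of one islet.
#' @param min_cells required positive-cell count (default 3).
#' @return logical flag.
#' @export
islet_positivity <- function(cells, min_cells = 3L) {
  validate_cell_table(cells)
  if (!nrow(cells)) stopf("islet has no cells")
  d <- cells$dapi_positive
  sum(d & cells$insulin) >= min_cells || sum(d & cells$glucagon) >= min_cells
}

#' Proportion of profile-matching cells in one islet
#'
#' Count of DAPI-positive cells matching the profile divided by the total
#' number of DAPI-positive nuclei in the islet.
#'
#' @param cells cell table rows of one islet (>= 1 DAPI-positive cell).
#' @param profile a [marker_profile()].
#' @return fraction in [0, 1].
#' @export
profile_proportion <- function(cells, profile) {
  validate_cell_table(cells)
  d <- cells[cells$dapi_positive, , drop = FALSE]
  if (!nrow(d))
    stopf("islet has no DAPI-positive cells; proportion undefined")
  m <- rep(TRUE, nrow(d))
  for (mk in profile$positive) m <- m & d[[mk]]
  for (mk in profile$negative) m <- m & !d[[mk]]
  sum(m) / nrow(d)
}

#' Summarize islet composition across islets and groups
#'
#' Applies the islet positivity rule (non-positive islets and islets without
#' DAPI-positive nuclei are excluded, with reasons recorded), computes the
#' per-islet proportion of each profile, and aggregates to a table of
#' mean, SD and islet count per profile and group. Aggregation is pooled
#' across islets by default; `aggregate = "per_animal"` averages per animal
#' first (requires an `animal_id` column).
#'
#' @param cells cell table (columns `cell_id`, `islet_id`, `dapi_positive`,
#'   the five markers; optionally `group`, `animal_id`).
#' @param profiles named list of [marker_profile()]s
#'   (default [standard_profiles()]).
#' @param group optional grouping column name (default `"group"` when present).
#' @param aggregate "pooled" or "per_animal".
#' @param min_cells positivity-rule threshold.
#' @return data.frame (profile x group: mean, sd, n_islets) with attributes
#'   `per_islet` (per-islet proportions) and `excluded` (islet, reason).
#' @export
summarize_composition <- function(cells, profiles = standard_profiles(),
                                  group = if ("group" %in% names(cells)) "group" else NULL,
                                  aggregate = c("pooled", "per_animal"),
                                  min_cells = 3L) {
  aggregate <- match.arg(aggregate)
  validate_cell_table(cells)
  if (aggregate == "per_animal" && !"animal_id" %in% names(cells))
    stopf("per-animal aggregation requires an 'animal_id' column")
  islets <- split(cells, cells$islet_id)
  excluded <- data.frame(islet_id = character(0), reason = character(0))
  keep <- list()
  for (nm in names(islets)) {
    isl <- islets[[nm]]
    if (!sum(isl$dapi_positive)) {
      excluded <- rbind(excluded, data.frame(islet_id = nm, reason = "no DAPI-positive nuclei"))
    } else if (!islet_positivity(isl, min_cells)) {
      excluded <- rbind(excluded, data.frame(islet_id = nm, reason = "failed positivity rule"))
    } else keep[[nm]] <- isl
  }
  per_islet <- do.call(rbind, lapply(names(keep), function(nm) {
    isl <- keep[[nm]]
    props <- vapply(profiles, function(p) profile_proportion(isl, p), numeric(1))
    data.frame(islet_id = nm,
               group = if (!is.null(group)) as.character(isl[[group]][1]) else "all",
               animal_id = if ("animal_id" %in% names(isl)) as.character(isl$animal_id[1]) else NA_character_,
               profile = names(profiles), proportion = unname(props),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_islet)) per_islet <- data.frame(
    islet_id = character(0), group = character(0), animal_id = character(0),
    profile = character(0), proportion = numeric(0))
  agg_unit <- if (aggregate == "per_animal") {
    stats::aggregate(proportion ~ profile + group + animal_id,
                     data = per_islet, FUN = mean)
  } else per_islet
  out <- do.call(rbind, lapply(split(agg_unit, agg_unit[c("profile", "group")], drop = TRUE),
    function(d) data.frame(profile = d$profile[1], group = d$group[1],
                           mean = mean(d$proportion), sd = stats::sd(d$proportion),
                           n = nrow(d), stringsAsFactors = FALSE)))
  if (!is.null(out)) {
    out <- out[order(match(out$profile, names(profiles)), out$group), ]
    rownames(out) <- NULL
    # n is islet count in pooled mode, animal count in per-animal mode
    names(out)[names(out) == "n"] <-
      if (aggregate == "per_animal") "n_animals" else "n_islets"
  }
  attr(out, "per_islet") <- per_islet
  attr(out, "excluded") <- excluded
  out
}

#' Fold change between two group means
#'
#' @param mean_a numerator group mean.
#' @param mean_b denominator group mean.
#' @return `mean_a / mean_b`, or `NA` (with attribute `undefined = TRUE`)
#'   when `mean_b` is 0.
#' @export
group_fold_change <- function(mean_a, mean_b) {
  if (!is_number(mean_a) || !is_number(mean_b))
    stopf("means must be single finite numbers")
  if (mean_b == 0) return(structure(NA_real_, undefined = TRUE))
  mean_a / mean_b
}

#' Simulate a per-cell marker-call table
#'
#' Generative stand-in for thresholded multiplexed-IHC marker calls: each cell
#' draws an endocrine type from `type_probs`, then marker flags independently
#' from the type's emission probabilities in `marker_probs`. The implied true
#' profile proportions are computable in closed form with
#' [expected_profile_proportion()], which makes estimator convergence
#' testable.
#'
#' @param n_islets number of islets.
#' @param cells_per_islet mean cells per islet (Poisson, minimum 1).
#' @param type_probs named probabilities over cell types (rows of
#'   `marker_probs`).
#' @param marker_probs matrix type x marker of P(marker positive | type).
#' @param dapi_prob probability a cell is DAPI-positive.
#' @param group optional group label column value.
#' @param animal_ids optional vector of animal ids islets are assigned to
#'   (round-robin).
#' @param seed integer seed.
#' @return cell table data.frame.
#' @export
simulate_cell_table <- function(n_islets = 100L, cells_per_islet = 120,
                                type_probs = c(beta = 0.50, alpha = 0.20,
                                               bihormonal = 0.05, delta = 0.07,
                                               other = 0.18),
                                marker_probs = default_marker_probs(),
                                dapi_prob = 1,
                                group = NULL, animal_ids = NULL, seed = 1L) {
  stopifnot(all(rownames(marker_probs) == names(type_probs)),
            all(colnames(marker_probs) == MARKERS))
  with_local_seed(seed, {
    rows <- lapply(seq_len(n_islets), function(i) {
      n <- max(1L, stats::rpois(1, cells_per_islet))
      ty <- sample(names(type_probs), n, replace = TRUE,
                   prob = type_probs / sum(type_probs))
      flags <- vapply(MARKERS, function(mk) {
        stats::runif(n) < marker_probs[ty, mk]
      }, logical(n))
      if (n == 1L) flags <- matrix(flags, nrow = 1L, dimnames = list(NULL, MARKERS))
      d <- data.frame(islet_id = sprintf("islet_%04d", i),
                      dapi_positive = stats::runif(n) < dapi_prob)
      cbind(d, as.data.frame(flags))
    })
    cells <- do.call(rbind, rows)
    cells <- cbind(cell_id = seq_len(nrow(cells)), cells)
    if (!is.null(group)) cells$group <- group
    if (!is.null(animal_ids)) {
      map <- rep_len(animal_ids, n_islets)
      cells$animal_id <- map[match(cells$islet_id, sprintf("islet_%04d", seq_len(n_islets)))]
    }
    cells
  })
}

#' Default marker emission probabilities per cell type
#' @return matrix (type x marker).
#' @export
default_marker_probs <- function() {
  m <- rbind(
    beta       = c(insulin = 0.97, glucagon = 0.03, somatostatin = 0.01, pdx1 = 0.90, brn4 = 0.02),
    alpha      = c(insulin = 0.03, glucagon = 0.96, somatostatin = 0.01, pdx1 = 0.10, brn4 = 0.12),
    bihormonal = c(insulin = 0.95, glucagon = 0.95, somatostatin = 0.02, pdx1 = 0.70, brn4 = 0.30),
    delta      = c(insulin = 0.02, glucagon = 0.02, somatostatin = 0.95, pdx1 = 0.20, brn4 = 0.05),
    other      = c(insulin = 0.02, glucagon = 0.02, somatostatin = 0.02, pdx1 = 0.30, brn4 = 0.05))
  m
}

#' Closed-form profile proportion implied by the simulation model
#'
#' Marginal probability that a cell matches the profile, under the cell-type
#' mixture and conditionally independent marker emissions of
#' [simulate_cell_table()].
#'
#' @inheritParams simulate_cell_table
#' @param profile a [marker_profile()].
#' @return probability in [0, 1].
#' @export
expected_profile_proportion <- function(profile,
                                        type_probs = c(beta = 0.50, alpha = 0.20,
                                                       bihormonal = 0.05, delta = 0.07,
                                                       other = 0.18),
                                        marker_probs = default_marker_probs()) {
  p <- type_probs / sum(type_probs)
  sum(vapply(names(p), function(ty) {
    pr <- 1
    for (mk in profile$positive) pr <- pr * marker_probs[ty, mk]
    for (mk in profile$negative) pr <- pr * (1 - marker_probs[ty, mk])
    p[[ty]] * pr
  }, numeric(1)))
}

#' Write a composition summary as a composition-table CSV
#' @param summary data.frame from [summarize_composition()].
#' @param path output CSV path.
#' @export
write_composition_table <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
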