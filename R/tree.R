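# Vessel trees: branches + bifurcation topology + anatomical labels.

#' Construct a vessel tree
#'
#' @param branches Named list of [centerline()] tibbles (names are branch
#'   ids, e.g. "LM", "LAD", "LCx", "diagonal").
#' @param bifurcations Tibble with columns `parent`, `child_main`,
#'   `child_side` (branch ids); each branch may parent at most one
#'   bifurcation, at its distal end. `child_side = NA` marks a degenerate
#'   (continuation-only) junction, as left behind by trimming.
#' @param inlet Branch id of the root.
#' @return A list of class `vessel_tree`.
#' @export
vessel_tree <- function(branches, bifurcations, inlet) {
  if (is.null(names(branches)) || any(names(branches) == "")) {
    abort("`branches` must be a named list.")
  }
  ids <- names(branches)
  if (!inlet %in% ids) abort("`inlet` is not a branch id.")
  bif <- as_tibble(bifurcations)
  kids <- stats::na.omit(c(bif$child_main, bif$child_side))
  if (!all(c(bif$parent, kids) %in% ids)) {
    abort("bifurcation references a missing branch.")
  }
  if (any(is.na(bif$child_main))) abort("`child_main` cannot be NA.")
  if (anyDuplicated(kids) || inlet %in% kids) {
    abort("topology is not a rooted tree (a branch has two parents or the inlet has one).")
  }
  if (anyDuplicated(bif$parent)) {
    abort("a branch parents more than one bifurcation.")
  }
  reach <- inlet
  repeat {
    here <- bif$parent %in% reach
    nxt <- setdiff(stats::na.omit(c(bif$child_main[here], bif$child_side[here])),
                   reach)
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  if (!setequal(reach, ids)) abort("tree has branches unreachable from the inlet.")
  structure(list(branches = branches, bifurcations = bif, inlet = inlet),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d branches, %d junctions, inlet=%s\n",
              length(x$branches), nrow(x$bifurcations), x$inlet))
  invisible(x)
}

#' Branch ids that terminate the tree (outlets)
#' @param tree A [vessel_tree()].
#' @return Character vector of outlet branch ids.
#' @export
tree_outlets <- function(tree) {
  setdiff(names(tree$branches), tree$bifurcations$parent)
}

#' Trim distal branches below a diameter threshold
#'
#' Each branch is truncated at the first arc-length position where the lumen
#' diameter drops below `min_diameter` (mirroring the resolution-driven
#' trimming of reconstructed coronary trees at 2 mm). Branches trimmed at
#' their origin are removed together with all their descendants; a junction
#' that loses its side child degenerates to a continuation.
#'
#' @param tree A [vessel_tree()] whose branches carry radii.
#' @param min_diameter Diameter threshold (m); default 2 mm.
#' @return A trimmed `vessel_tree`.
#' @export
trim_small_branches <- function(tree, min_diameter = 2e-3) {
  keep <- list()
  removed <- character()
  for (id in names(tree$branches)) {
    br <- tree$branches[[id]]
    if (is.null(br[["radius"]])) abort("all branches need radii for trimming.")
    below <- which(2 * br$radius < min_diameter)
    if (!length(below)) {
      keep[[id]] <- br
    } else if (below[1] <= 2L) {
      removed <- c(removed, id)
    } else {
      keep[[id]] <- br[seq_len(below[1] - 1L), , drop = FALSE]
    }
  }
  if (tree$inlet %in% removed) {
    abort("inlet branch is entirely below the diameter threshold.")
  }
  # cascade removal down the tree
  repeat {
    here <- tree$bifurcations$parent %in% removed
    orphan <- setdiff(
      stats::na.omit(c(tree$bifurcations$child_main[here],
                       tree$bifurcations$child_side[here])),
      removed)
    orphan <- intersect(orphan, names(keep))
    if (!length(orphan)) break
    removed <- c(removed, orphan)
    keep[orphan] <- NULL
  }
  bif <- tree$bifurcations |>
    filter(!.data$parent %in% removed) |>
    mutate(
      # promote the side child when the main one is gone
      promote = .data$child_main %in% removed & !.data$child_side %in% removed &
        !is.na(.data$child_side),
      child_main = ifelse(.data$promote, .data$child_side, .data$child_main),
      child_side = ifelse(.data$promote | .data$child_side %in% removed,
                          NA_character_, .data$child_side)
    ) |>
    filter(!.data$child_main %in% removed) |>
    select(-"promote")
  vessel_tree(keep, bif, tree$inlet)
}
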