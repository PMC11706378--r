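# Hierarchical composite scores: equal-weight aggregation, component
# removal with re-averaging, cutoff percentiles and treatment assignment.

#' Default composite-score hierarchy
#'
#' A synthetic tree with the shape of the GHSI 2021 index: 96 sub-indicators
#' feeding 37 indicators, grouped into 6 categories, aggregated into an
#' overall score.  Category sizes are 6, 6, 7, 6, 7 and 5 indicators;
#' sub-indicators are distributed deterministically (three per indicator
#' for the first 22 indicators, two for the rest).  Node ids follow the
#' index's dotted convention: category `"1"`, indicator `"1.3"`,
#' sub-indicator `"1.3.2"`.  Indicator `"1.6"` plays the role of the
#' vaccination-coverage indicator that [recompute_equal_weight()] removes
#' by default.
#'
#' @return A data frame with columns `node_id`, `parent_id`, `level`.
#' @export
default_hierarchy <- function() {
  cat_sizes <- c(6L, 6L, 7L, 6L, 7L, 5L)
  nodes <- data.frame(node_id = "overall", parent_id = NA_character_,
                      level = "overall", stringsAsFactors = FALSE)
  ind_ids <- character(0)
  for (c_i in seq_along(cat_sizes)) {
    cid <- as.character(c_i)
    nodes <- rbind(nodes, data.frame(node_id = cid, parent_id = "overall",
                                     level = "category"))
    ids <- paste(cid, seq_len(cat_sizes[c_i]), sep = ".")
    nodes <- rbind(nodes, data.frame(node_id = ids, parent_id = cid,
                                     level = "indicator"))
    ind_ids <- c(ind_ids, ids)
  }
  n_sub <- rep(2L, length(ind_ids))
  n_sub[seq_len(96L - 2L * length(ind_ids))] <- 3L
  for (k in seq_along(ind_ids)) {
    ids <- paste(ind_ids[k], seq_len(n_sub[k]), sep = ".")
    nodes <- rbind(nodes, data.frame(node_id = ids, parent_id = ind_ids[k],
                                     level = "sub-indicator"))
  }
  rownames(nodes) <- NULL
  nodes
}

validate_structure <- function(structure) {
  need <- c("node_id", "parent_id", "level")
  assert_that(all(need %in% names(structure)),
              "hierarchy structure needs columns node_id, parent_id, level",
              "ghsdid_specification")
  assert_that(!anyDuplicated(structure$node_id),
              "duplicate node ids in hierarchy", "ghsdid_specification")
  root <- structure$node_id[is.na(structure$parent_id)]
  assert_that(length(root) == 1,
              "hierarchy must have exactly one root node",
              "ghsdid_specification")
  parents <- structure$parent_id[!is.na(structure$parent_id)]
  assert_that(all(parents %in% structure$node_id),
              "every child must reference an existing parent",
              "ghsdid_specification")
  invisible(root)
}

# Children of each node, in structure order.
children_map <- function(structure) {
  split(structure$node_id[!is.na(structure$parent_id)],
        factor(structure$parent_id[!is.na(structure$parent_id)],
               levels = structure$node_id))
}

# Node ids ordered so that all children precede their parent.
bottom_up_order <- function(structure) {
  depth <- setNames(rep(NA_integer_, nrow(structure)), structure$node_id)
  root <- structure$node_id[is.na(structure$parent_id)]
  depth[root] <- 0L
  repeat {
    todo <- is.na(depth)
    if (!any(todo)) break
    parent_depth <- depth[structure$parent_id[todo]]
    if (all(is.na(parent_depth))) {
      ghs_error("hierarchy contains a cycle or unreachable nodes",
                "ghsdid_specification")
    }
    depth[structure$node_id[todo]] <- parent_depth + 1L
  }
  structure$node_id[order(depth, decreasing = TRUE)]
}

#' Aggregate leaf scores bottom-up with equal weights
#'
#' Every internal node's value is the unweighted mean of its children's
#' values, computed from the leaves upward.
#'
#' @param structure Hierarchy definition (see [default_hierarchy()]).
#' @param leaf_values Numeric matrix, rows = countries (rownames = ISO3),
#'   columns = leaf node ids.
#' @return A full value matrix with one column per node in the hierarchy.
#' @export
aggregate_scores <- function(structure, leaf_values) {
  validate_structure(structure)
  ch <- children_map(structure)
  leaves <- structure$node_id[lengths(ch)[structure$node_id] == 0]
  assert_that(all(leaves %in% colnames(leaf_values)),
              "leaf_values must contain a column for every leaf node",
              "ghsdid_specification")
  vals <- matrix(NA_real_, nrow(leaf_values), nrow(structure),
                 dimnames = list(rownames(leaf_values), structure$node_id))
  vals[, leaves] <- leaf_values[, leaves]
  for (id in bottom_up_order(structure)) {
    kids <- ch[[id]]
    if (length(kids) > 0) {
      vals[, id] <- rowMeans(vals[, kids, drop = FALSE])
    }
  }
  vals
}

#' Construct a score hierarchy object
#'
#' @param structure Hierarchy definition data frame (`node_id`,
#'   `parent_id`, `level`).
#' @param values Either a full value matrix (countries x all nodes), whose
#'   internal consistency (each parent equal to the mean of its children
#'   within 1e-8) is verified, or a matrix of leaf values only, which is
#'   aggregated bottom-up.
#' @return An object of class `score_hierarchy`.
#' @export
score_hierarchy <- function(structure, values) {
  root <- validate_structure(structure)
  assert_that(is.matrix(values) && !is.null(rownames(values)),
              "values must be a matrix with country rownames")
  if (!all(structure$node_id %in% colnames(values))) {
    values <- aggregate_scores(structure, values)
  } else {
    values <- values[, structure$node_id, drop = FALSE]
    full <- aggregate_scores(
      structure, values[, setdiff(colnames(values),
                                  names(which(lengths(children_map(structure)) > 0))),
                        drop = FALSE])
    if (max(abs(full - values)) > 1e-8) {
      ghs_error("internal node values are not the equal-weight mean of their children",
                "ghsdid_specification")
    }
    values <- full
  }
  rng <- range(values)
  assert_that(rng[1] >= -1e-9 && rng[2] <= 100 + 1e-9,
              "score values must lie in [0, 100]")
  structure(list(structure = structure, values = values, root = root),
            class = "score_hierarchy")
}

#' @export
print.score_hierarchy <- function(x, ...) {
  lv <- table(x$structure$level)
  cat(sprintf("<score_hierarchy> %d countries, %d nodes (%s)\n",
              nrow(x$values), nrow(x$structure),
              paste(names(lv), lv, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Extract one node's per-country scores
#'
#' @param hierarchy A `score_hierarchy`.
#' @param node Node id (default the root, i.e. the overall score).
#' @return Named numeric vector of scores, names = ISO3 codes.
#' @export
score_values <- function(hierarchy, node = NULL) {
  stopifnot(inherits(hierarchy, "score_hierarchy"))
  node <- node %||% hierarchy$root
  assert_that(node %in% hierarchy$structure$node_id,
              paste("unknown node id:", node), "ghsdid_lookup")
  hierarchy$values[, node]
}

#' Long-format view of a score hierarchy
#'
#' @param x A `score_hierarchy`.
#' @param ... Unused.
#' @return Data frame with columns `iso3`, `node_id`, `value`.
#' @export
as.data.frame.score_hierarchy <- function(x, ...) {
  data.frame(iso3 = rep(rownames(x$values), ncol(x$values)),
             node_id = rep(colnames(x$values), each = nrow(x$values)),
             value = as.vector(x$values),
             stringsAsFactors = FALSE)
}

#' Remove a component and re-average the hierarchy with equal weights
#'
#' Deletes the given node (and its entire subtree) and recomputes every
#' ancestor's value bottom-up as the unweighted mean of its remaining
#' children.  All non-ancestor nodes are left untouched.  This is how a
#' composite score is purged of a component that would otherwise leak the
#' outcome into the exposure (e.g. removing the vaccination-coverage
#' indicator before using the overall score to assign treatment groups on
#' immunization outcomes).
#'
#' @param hierarchy A `score_hierarchy`.
#' @param removed_node Node id to remove; must not be the root, and its
#'   parent must keep at least one child.
#' @return A new `score_hierarchy` without the removed subtree.
#' @export
recompute_equal_weight <- function(hierarchy, removed_node) {
  stopifnot(inherits(hierarchy, "score_hierarchy"))
  st <- hierarchy$structure
  assert_that(removed_node %in% st$node_id,
              paste("unknown node id:", removed_node), "ghsdid_lookup")
  assert_that(removed_node != hierarchy$root,
              "cannot remove the root of the hierarchy", "ghsdid_degeneracy")
  parent <- st$parent_id[st$node_id == removed_node]
  siblings <- st$node_id[!is.na(st$parent_id) & st$parent_id == parent]
  if (length(siblings) < 2) {
    ghs_error(sprintf("cannot remove %s: it is the only child of %s",
                      removed_node, parent),
              "ghsdid_degeneracy")
  }
  # subtree of the removed node
  drop_ids <- removed_node
  repeat {
    more <- st$node_id[!is.na(st$parent_id) & st$parent_id %in% drop_ids &
                         !(st$node_id %in% drop_ids)]
    if (length(more) == 0) break
    drop_ids <- c(drop_ids, more)
  }
  new_st <- st[!(st$node_id %in% drop_ids), , drop = FALSE]
  rownames(new_st) <- NULL
  vals <- hierarchy$values[, new_st$node_id, drop = FALSE]
  ch <- children_map(new_st)
  # recompute the ancestor chain bottom-up
  a <- parent
  while (!is.na(a)) {
    vals[, a] <- rowMeans(vals[, ch[[a]], drop = FALSE])
    a <- new_st$parent_id[new_st$node_id == a]
  }
  structure(list(structure = new_st, values = vals, root = hierarchy$root),
            class = "score_hierarchy")
}

#' Fraction of countries scoring below a cutoff
#'
#' Reports where a cutoff sits in the score distribution, using the
#' convention "fraction of countries strictly below the cutoff".
#'
#' @param scores Named numeric vector of per-country scores.
#' @param cutoff Threshold on the score scale.
#' @return List with `fraction` (raw) and `percentile` (rounded to two
#'   decimals, the reporting convention).
#' @export
percentile_of_cutoff <- function(scores, cutoff) {
  assert_that(length(scores) >= 1 && !anyNA(scores),
              "scores must be a non-empty numeric vector without NAs")
  frac <- mean(scores < cutoff)
  list(fraction = frac, percentile = round(frac, 2))
}

#' Assign treatment by score cutoff
#'
#' Countries with `score >= cutoff` form the treated group (ties at the
#' cutoff are treated); the rest are controls.  Post-pandemic years default
#' to 2020-2022.
#'
#' @param scores Named numeric vector of per-country scores.
#' @param cutoff Threshold; treated = scores at or above it.
#' @param post_years Years defining the post period.
#' @param score_id Optional label for the score variable used.
#' @return An object of class `treatment_assignment` with `treated` and
#'   `control` ISO3 vectors.  A partition with zero treated or zero control
#'   countries raises a `ghsdid_degenerate` error (the cutoff sweep treats
#'   this as a failed gate, not a crash).
#' @export
assign_treatment <- function(scores, cutoff, post_years = 2020:2022,
                             score_id = "overall") {
  assert_that(length(scores) >= 1 && !is.null(names(scores)),
              "scores must be a named numeric vector")
  treated <- names(scores)[scores >= cutoff]
  control <- names(scores)[scores < cutoff]
  if (length(treated) == 0 || length(control) == 0) {
    ghs_error(sprintf(
      "degenerate assignment at cutoff %s: %d treated, %d control",
      format(cutoff), length(treated), length(control)),
      "ghsdid_degenerate")
  }
  structure(list(score_id = score_id, cutoff = cutoff,
                 treated = treated, control = control,
                 post_years = as.integer(post_years),
                 n_treated = length(treated),
                 n_control = length(control)),
            class = "treatment_assignment")
}

#' @export
print.treatment_assignment <- function(x, ...) {
  cat(sprintf("<treatment_assignment> %s >= %s: %d treated, %d control; post %s\n",
              x$score_id, format(x$cutoff), x$n_treated, x$n_control,
              paste(range(x$post_years), collapse = "-")))
  invisible(x)
}
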