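#' Build a clonal lineage tree from the germline root
#'
#' Grows a rooted lineage tree in the style of grow-from-root
#' minimum-spanning reconstruction: starting from the germline FR1-FR4
#' sequence, the unplaced clone with the smallest nucleotide edit
#' distance to any current tree node is attached next; when that
#' distance exceeds one, inferred intermediate nodes are inserted along
#' one minimum-edit path so that every edge in the final tree has edit
#' distance exactly one. Ties are broken deterministically: smaller edit
#' distance first, then larger clone UMI count, then lexicographic
#' sequence order; among equidistant attachment nodes the earliest-added
#' node wins.
#'
#' @param clones Clone tibble from [define_clones()].
#' @param germline A [germline_reference()]; its full sequence is the
#'   root.
#' @return An object of class `lineage_tree`: list with `nodes` (tibble
#'   `node_id`, `seq`, `type` root/observed/inferred, `clone_id`,
#'   `level`), `edges` (tibble `parent`, `child`, `dist`, all 1), and
#'   `total_cost` (sum of attachment edit distances).
#' @export
build_lineage_tree <- function(clones, germline) {
  stopifnot(nrow(clones) >= 1L)
  nodes <- tibble::tibble(
    node_id = "root", seq = germline$nt_seq, type = "root",
    clone_id = NA_character_, level = 0L
  )
  edges <- tibble::tibble(parent = character(), child = character(),
                          dist = integer())
  unplaced <- clones[order(-clones$total_umi, clones$defining_seq), ]
  total_cost <- 0L
  n_inferred <- 0L
  while (nrow(unplaced) > 0L) {
    d <- utils::adist(unplaced$defining_seq, nodes$seq)
    best_per_clone <- apply(d, 1L, min)
    # clone order already encodes UMI/lexicographic tie-breaks
    ci <- which.min(best_per_clone)
    ni <- which(d[ci, ] == best_per_clone[ci])[1]
    clone <- unplaced[ci, ]
    unplaced <- unplaced[-ci, ]
    attach_dist <- best_per_clone[ci]
    total_cost <- total_cost + attach_dist
    parent <- nodes$node_id[ni]
    parent_level <- nodes$level[ni]
    path <- edit_path(nodes$seq[ni], clone$defining_seq)
    stopifnot(length(path) == attach_dist)
    if (attach_dist == 0L) {
      # identical to an existing node (e.g. unmutated clone = root):
      # represent as a zero-distance child to keep every clone a node
      node_id <- clone$clone_id
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        node_id = node_id, seq = clone$defining_seq, type = "observed",
        clone_id = clone$clone_id, level = parent_level
      ))
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        parent = parent, child = node_id, dist = 0L
      ))
      next
    }
    for (k in seq_along(path)) {
      last <- k == length(path)
      node_id <- if (last) {
        clone$clone_id
      } else {
        n_inferred <- n_inferred + 1L
        sprintf("I%04d", n_inferred)
      }
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        node_id = node_id, seq = path[k],
        type = if (last) "observed" else "inferred",
        clone_id = if (last) clone$clone_id else NA_character_,
        level = parent_level + k
      ))
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        parent = parent, child = node_id, dist = 1L
      ))
      parent <- node_id
    }
  }
  structure(list(nodes = nodes, edges = edges, total_cost = total_cost),
            class = "lineage_tree")
}

# sequence states along one minimum-edit path from `from` to `to`,
# applying alignment-column edits left to right; excludes `from`,
# includes `to`; length equals the Levenshtein distance
edit_path <- function(from, to) {
  if (identical(from, to)) return(character(0))
  unit <- matrix(-1, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                           c("A", "C", "G", "T", "N")))
  diag(unit) <- 0
  pa <- Biostrings::pairwiseAlignment(
    pattern = to, subject = from, type = "global",
    substitutionMatrix = unit, gapOpening = 0, gapExtension = 1
  )
  a <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]  # from
  b <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]  # to
  # current sequence as a list of columns; apply one edit at a time
  cur <- a
  out <- character(0)
  for (i in seq_along(a)) {
    if (a[i] != b[i]) {
      cur[i] <- b[i]  # substitution, insertion (a="-"), or deletion (b="-")
      out <- c(out, paste(cur[cur != "-"], collapse = ""))
    }
  }
  out
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf(
    "<lineage_tree> %d observed clone(s), %d inferred node(s), max level %d, total cost %d\n",
    sum(x$nodes$type == "observed"), sum(x$nodes$type == "inferred"),
    max(x$nodes$level), x$total_cost
  ))
  invisible(x)
}

#' @rdname tidy-maturr
#' @export
tidy.lineage_tree <- function(x, ...) {
  lv <- x$nodes$level[match(x$edges$child, x$nodes$node_id)]
  dplyr::mutate(x$edges, child_level = lv)
}

#' @rdname tidy-maturr
#' @export
glance.lineage_tree <- function(x, ...) {
  tibble::tibble(
    n_observed = sum(x$nodes$type == "observed"),
    n_inferred = sum(x$nodes$type == "inferred"),
    max_level = max(x$nodes$level),
    total_cost = x$total_cost
  )
}

#' Per-level clone counts split by compartment membership
#'
#' Counts observed clones at each tree level (level 0 = germline) and
#' splits them into clones shared between the two compartments versus
#' clones private to each. Inferred intermediates are not counted.
#'
#' @param tree A `lineage_tree`.
#' @param clones The clone tibble the tree was built from.
#' @return A tibble `level`, `category` (`"shared"` or
#'   `"<compartment>-only"`), `n`.
#' @export
tree_level_histogram <- function(tree, clones) {
  obs <- tree$nodes[tree$nodes$type == "observed", ]
  comp <- clones$compartments[match(obs$clone_id, clones$clone_id)]
  category <- ifelse(grepl(",", comp), "shared", paste0(comp, "-only"))
  tibble::tibble(level = obs$level, category = category) |>
    dplyr::count(.data$level, .data$category, name = "n")
}

#' Export a lineage tree as a Newick string
#'
#' Inferred intermediates carry their `I....` labels; all branch lengths
#' equal the stored edge distances.
#'
#' @param tree A `lineage_tree`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(tree, path = NULL) {
  children <- split(tree$edges$child, tree$edges$parent)
  dist <- stats::setNames(tree$edges$dist, tree$edges$child)
  rec <- function(id) {
    kids <- children[[id]]
    label <- id
    body <- if (is.null(kids)) {
      label
    } else {
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
             ")", label)
    }
    if (id == "root") body else paste0(body, ":", dist[[id]])
  }
  nwk <- paste0(rec("root"), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
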