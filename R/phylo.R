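#' Read a binary character matrix
#'
#' TSV with species in the first column and one binary character per
#' remaining column; states are 0, 1 or `?` (missing).
#'
#' @param path TSV file.
#' @return Matrix of 0/1/`NA` with species row names.
#' @export
read_character_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m[m == "?"] <- NA
  if (!all(m %in% c("0", "1", NA)))
    stop("character states must be 0, 1 or ?")
  storage.mode(m) <- "integer"
  m
}

#' @noRd
#' Named leaf states aligned to tree tips; NA for unscored leaves.
align_states <- function(tree, states) {
  if (is.null(names(states))) stop("states must be named by species")
  extra <- setdiff(names(states), tree$tip.label)
  if (length(extra))
    stop("species not in tree: ", paste(extra, collapse = ", "))
  out <- setNames(rep(NA_integer_, length(tree$tip.label)), tree$tip.label)
  out[names(states)] <- as.integer(states)
  out
}

new_reconstruction <- function(method, min_changes, node_states, events,
                               non_unique) {
  structure(list(method = method, min_changes = min_changes,
                 node_states = node_states, events = events,
                 non_unique = non_unique),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(x$method, "reconstruction:", x$min_changes, "change(s)",
      if (x$non_unique) "(placement not unique)", "\n")
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Fitch (minimum-change) parsimony for one binary character
#'
#' Computes the exact minimum number of 0/1 state changes on a rooted
#' tree (polytomies allowed) by dynamic programming over per-node state
#' costs, and materializes one most-parsimonious reconstruction with
#' root preference for state 0 on ties. Leaves with missing data
#' contribute both states at zero cost (the standard Fitch treatment)
#' and never generate events. When alternative assignments exist the
#' reconstruction is flagged `non_unique` (the change *count* is always
#' unambiguous).
#'
#' @param tree a rooted `ape::phylo` tree (node labels optional).
#' @param states named vector of 0/1/`NA` leaf states; at least 2
#'   non-missing.
#' @return A `reconstruction` object: `min_changes`, `node_states`
#'   (leaves then internal nodes, ape numbering), `events` (data frame
#'   `node`, `label`, `type`), `non_unique`.
#' @export
fitch_parsimony <- function(tree, states) {
  leaf <- align_states(tree, states)
  if (sum(!is.na(leaf)) < 2L)
    stop("need at least 2 scored leaves (got ", sum(!is.na(leaf)), ")")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  cost <- matrix(0, ntip + nnode, 2L)
  cost[seq_len(ntip), ] <- t(vapply(leaf, function(s) {
    if (is.na(s)) c(0, 0) else if (s == 0L) c(0, Inf) else c(Inf, 0)
  }, c(0, 0)))
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    cost[p, ] <- cost[p, ] + pmin(cost[ch, ], rev(cost[ch, ]) + 1)
  }
  root <- ntip + 1L
  min_changes <- min(cost[root, ])
  non_unique <- FALSE
  state <- integer(ntip + nnode)
  state[root] <- if (cost[root, 1L] <= cost[root, 2L]) 0L else 1L
  if (cost[root, 1L] == cost[root, 2L]) non_unique <- TRUE
  events <- list()
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label) && length(tree$node.label) == nnode)
                tree$node.label else paste0("node", seq_len(nnode) + ntip))
  for (k in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    ps <- state[p]
    v <- cost[ch, ] + c(ps != 0L, ps != 1L)
    if (v[1L] == v[2L]) {
      state[ch] <- ps          # tie: keep parent state (no spurious change)
      # a tie at an unscored leaf is filled-in data, not a real ambiguity
      if (!(ch <= ntip && is.na(leaf[ch]))) non_unique <- TRUE
    } else state[ch] <- which.min(v) - 1L
    if (state[ch] != ps)
      events[[length(events) + 1L]] <- data.frame(
        node = ch, label = labels[ch],
        type = if (state[ch] == 1L) "gain" else "loss",
        stringsAsFactors = FALSE)
  }
  events <- if (length(events))
    do.call(rbind, c(events, list(make.row.names = FALSE)))
  else data.frame(node = integer(), label = character(), type = character())
  stopifnot(nrow(events) == min_changes)  # MPR consistency
  new_reconstruction("fitch", as.integer(min_changes),
                     setNames(state, labels), events, non_unique)
}

#' Dollo parsimony (single gain, unlimited losses)
#'
#' Places the unique gain on the stem of the smallest clade containing
#' all state-1 leaves, then counts one loss per maximal subtree of that
#' clade whose scored leaves are all 0. Leaves with missing data are
#' ignored (they join the surrounding state and never anchor a loss).
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param states named vector of 0/1/`NA` leaf states; at least one 1.
#' @return A `reconstruction` object with `min_changes = 1 + losses` and
#'   an event list (`gain` on the clade stem, one `loss` per maximal
#'   all-0 subtree).
#' @export
dollo_parsimony <- function(tree, states) {
  leaf <- align_states(tree, states)
  ones <- which(leaf == 1L)
  if (!length(ones)) stop("Dollo parsimony requires at least one leaf in state 1")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label) && length(tree$node.label) == nnode)
                tree$node.label else paste0("node", seq_len(nnode) + ntip))
  gain_node <- if (length(ones) == 1L) ones else ape::getMRCA(tree, ones)
  # per-node scored-leaf and state-1 counts (postorder accumulation)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  n_scored <- c(as.integer(!is.na(leaf)), rep(0L, nnode))
  n_one <- c(as.integer(!is.na(leaf) & leaf == 1L), rep(0L, nnode))
  for (k in seq_len(nrow(edge))) {
    n_scored[edge[k, 1L]] <- n_scored[edge[k, 1L]] + n_scored[edge[k, 2L]]
    n_one[edge[k, 1L]] <- n_one[edge[k, 1L]] + n_one[edge[k, 2L]]
  }
  children <- split(edge[, 2L], edge[, 1L])
  state <- integer(ntip + nnode)  # default 0 outside the gain clade
  losses <- list()
  recurse <- function(v) {
    if (n_scored[v] > 0L && n_one[v] == 0L) {  # maximal all-0 subtree
      losses[[length(losses) + 1L]] <<- data.frame(
        node = v, label = labels[v], type = "loss", stringsAsFactors = FALSE)
      return(invisible())
    }
    state[v] <<- 1L
    for (ch in children[[as.character(v)]]) recurse(ch)
  }
  recurse(gain_node)
  events <- rbind(
    data.frame(node = gain_node, label = labels[gain_node], type = "gain",
               stringsAsFactors = FALSE),
    if (length(losses)) do.call(rbind, c(losses, list(make.row.names = FALSE))))
  new_reconstruction("dollo", nrow(events), setNames(state, labels),
                     events, non_unique = FALSE)
}

#' Species retaining the hybrid intermediate state
#'
#' Flags species that possess a Hairless adaptor *and* both ancestral
#' co-repressor recruitment motifs in Su(H) itself (CtBP and Gro), i.e.
#' both the novel indirect and the ancestral direct recruitment
#' mechanisms.
#'
#' @param matrix binary character matrix (species x characters) with
#'   columns `Hairless`, `SuH_CtBP`, `SuH_Gro` (additional columns
#'   ignored).
#' @return Character vector of flagged species (empty for an empty
#'   matrix).
#' @export
hybrid_species <- function(matrix) {
  required <- c("Hairless", "SuH_CtBP", "SuH_Gro")
  if (nrow(matrix) == 0L) return(character())
  missing_cols <- setdiff(required, colnames(matrix))
  if (length(missing_cols))
    stop("character matrix lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  keep <- rowSums(matrix[, required, drop = FALSE] == 1L) == 3L
  rownames(matrix)[!is.na(keep) & keep]
}

#' Annotated-tree rendering of a reconstruction
#'
#' Newick string with node comments carrying the reconstructed state,
#' plus gain/loss marks, for plain-text figure-style reports.
#'
#' @param tree `ape::phylo`.
#' @param rec a `reconstruction`.
#' @return A single newick string with `[state=..]` comments.
#' @export
annotate_tree <- function(tree, rec) {
  ntip <- length(tree$tip.label)
  ev <- setNames(rep("", length(rec$node_states)), NULL)
  if (nrow(rec$events)) ev[rec$events$node] <- paste0(",", rec$events$type)
  t2 <- tree
  t2$tip.label <- paste0(tree$tip.label, "[state=",
                         rec$node_states[seq_len(ntip)],
                         ev[seq_len(ntip)], "]")
  t2$node.label <- paste0("[state=", rec$node_states[-seq_len(ntip)],
                          ev[-seq_len(ntip)], "]")
  ape::write.tree(t2)
}
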