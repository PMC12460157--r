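# Gene-family presence/absence evolution on a species tree.

#' Simulate gene-family gain and loss along a rooted tree
#'
#' Each of `n_root_families` families originates at the root; additional
#' families originate on internal or terminal branches, with the number of
#' gains per branch drawn Poisson(`gain_rate`). Losses are events per
#' branch as well: each branch draws Poisson(`loss_rate`) loss events, each
#' removing one family (chosen uniformly among those still present at the
#' parent node); once lost a family stays absent in the whole subtree
#' (single origination, no regain). Families absent from every leaf are
#' dropped from the emitted matrix but retained in the truth record.
#'
#' @param tree A rooted `phylo` tree (see [ape::read.tree]); internal nodes
#'   are auto-labelled `Node1..` when unlabelled.
#' @param n_root_families Families present at the root.
#' @param gain_rate Expected gain events per branch (Poisson mean).
#' @param loss_rate Expected loss events per branch (Poisson mean).
#' @param seed Integer seed.
#' @return List with `matrix` (wide tibble: `family_id` plus one 0/1 column
#'   per species), `tree` (with node labels filled in) and `truth` (events
#'   tibble: `family_id`, `branch`, `kind`; branches are named by their child
#'   node label, with the synthetic pre-root branch called `"root"`).
#' @export
simulate_family_evolution <- function(tree, n_root_families = 100,
                                      gain_rate = 0.5, loss_rate = 0.5,
                                      seed = 1L) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (ape::Ntip(tree) < 2) stop("tree needs at least 2 leaves")
  stopifnot(gain_rate >= 0, loss_rate >= 0)
  tree <- label_tree_nodes(tree)

  withr::with_seed(substream_seed(seed, "family_evolution"), {
    tree <- stats::reorder(tree, "cladewise") # edges in preorder
    nl <- node_labels(tree)
    root <- ape::Ntip(tree) + 1L
    edges <- tree$edge # parent, child (internal node numbering)

    fam_origin <- rep(root, n_root_families)
    origin_branch <- rep("root", n_root_families)
    n_gained <- rpois(nrow(edges), gain_rate)
    for (e in seq_len(nrow(edges))) {
      if (n_gained[e] > 0) {
        fam_origin <- c(fam_origin, rep(edges[e, 2], n_gained[e]))
        origin_branch <- c(origin_branch, rep(nl[edges[e, 2]], n_gained[e]))
      }
    }
    n_fam <- length(fam_origin)
    fam_ids <- sprintf("fam%04d", seq_len(n_fam))

    preord <- seq_len(nrow(edges)) # cladewise: parents precede children
    n_nodes <- max(edges)
    present <- matrix(FALSE, n_nodes, n_fam)
    present[root, ] <- fam_origin == root
    events <- vector("list", 2 * n_fam)
    ev_n <- 0
    for (e in preord) {
      par <- edges[e, 1]; child <- edges[e, 2]
      state <- present[par, ]
      state[fam_origin == child] <- TRUE
      at_risk <- which(present[par, ])
      n_loss <- min(rpois(1, loss_rate), length(at_risk))
      lost <- if (n_loss > 0) {
        at_risk[sample.int(length(at_risk), n_loss)]
      } else integer(0)
      state[lost] <- FALSE
      present[child, ] <- state
      if (length(lost) > 0) {
        ev_n <- ev_n + 1
        events[[ev_n]] <- tibble::tibble(family_id = fam_ids[lost],
                                         branch = nl[child], kind = "loss")
      }
    }
    gains <- tibble::tibble(family_id = fam_ids, branch = origin_branch,
                            kind = "gain")
    events <- dplyr::bind_rows(gains, dplyr::bind_rows(events[seq_len(ev_n)]))

    leaf_mat <- t(present[seq_len(ape::Ntip(tree)), , drop = FALSE]) * 1L
    colnames(leaf_mat) <- tree$tip.label
    keep <- rowSums(leaf_mat) > 0
    pam <- tibble::as_tibble(leaf_mat[keep, , drop = FALSE]) |>
      dplyr::mutate(family_id = fam_ids[keep], .before = 1)

    list(
      matrix = pam,
      tree = tree,
      truth = sim_truth(
        "family_evolution",
        list(n_root_families = n_root_families, gain_rate = gain_rate,
             loss_rate = loss_rate, seed = seed,
             emitted_families = fam_ids[keep]),
        dplyr::arrange(events, .data$family_id)
      )
    )
  })
}

# Fill in internal node labels (Node1..) when absent; tip labels must exist.
label_tree_nodes <- function(tree) {
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    tree <- ape::makeNodeLabel(tree, prefix = "Node")
  }
  if (anyDuplicated(c(tree$tip.label, tree$node.label)) > 0) {
    stop("tree labels must be unique")
  }
  tree
}

# Label of every node (tips then internals), indexed by ape node number.
node_labels <- function(tree) {
  c(tree$tip.label, tree$node.label)
}
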