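# Gene-family gains and losses by Dollo parsimony, lineage-specific family
# identification, and hypergeometric phylostratum enrichment.

#' Infer per-branch family gains and losses (Dollo parsimony)
#'
#' Each family originates exactly once, at the last common ancestor of the
#' leaves where it is present (families present in a single leaf gain on
#' that terminal branch; families spanning the root gain on a synthetic
#' pre-root branch named `"root"`). Losses are then placed minimally: within
#' the gain subtree, a loss is assigned to every branch leading to a maximal
#' subtree containing no present leaf. Per-branch totals are summed across
#' families; total gains equal the number of families.
#'
#' @param tree Rooted `phylo` tree; leaves must match the matrix species.
#' @param pam Presence/absence tibble: `family_id` plus one 0/1 column per
#'   species (no all-zero rows).
#' @return Event tibble: `branch` (child-node label, `"root"` for the
#'   pre-root branch), `gains`, `losses`.
#' @export
dollo_events <- function(tree, pam) {
  tree <- label_tree_nodes(tree)
  species <- setdiff(names(pam), "family_id")
  if (!setequal(species, tree$tip.label)) {
    stop("matrix species must match tree leaves")
  }
  mat <- as.matrix(pam[tree$tip.label]) > 0
  if (any(rowSums(mat) == 0)) stop("all-absent families are not allowed")

  tree <- stats::reorder(tree, "postorder")
  edges <- tree$edge
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nl <- node_labels(tree)
  n_nodes <- max(edges)
  children <- split(edges[, 2], edges[, 1])

  branch_names <- c("root", nl[edges[, 2]])
  gains <- setNames(numeric(length(branch_names)), branch_names)
  losses <- gains

  for (f in seq_len(nrow(mat))) {
    present_tips <- which(mat[f, ])
    # occupied[v]: subtree of v contains a present leaf (postorder fill)
    occupied <- logical(n_nodes)
    occupied[present_tips] <- TRUE
    for (e in seq_len(nrow(edges))) {
      if (occupied[edges[e, 2]]) occupied[edges[e, 1]] <- TRUE
    }
    # gain node: deepest occupied node whose subtree holds all present tips;
    # walk down from the root while exactly one child is occupied
    g <- root
    repeat {
      occ_children <- children[[as.character(g)]]
      occ_children <- occ_children[occupied[occ_children]]
      if (length(occ_children) == 1) g <- occ_children else break
    }
    gains[if (g == root) "root" else nl[g]] <-
      gains[if (g == root) "root" else nl[g]] + 1
    # losses: edges inside the gain subtree from occupied parent to
    # unoccupied child
    stack <- g
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (ch in children[[as.character(v)]]) {
        if (occupied[ch]) {
          stack <- c(stack, ch)
        } else {
          losses[nl[ch]] <- losses[nl[ch]] + 1
        }
      }
    }
  }
  tibble::tibble(branch = branch_names, gains = unname(gains),
                 losses = unname(losses))
}

#' Identify lineage-specific gene families
#'
#' Families present in at least `min_focal` of the focal species and in no
#' non-focal species.
#'
#' @param pam Presence/absence tibble (`family_id` + species columns).
#' @param focal Character vector of focal species (subset of the columns).
#' @param min_focal Minimum focal species a family must occupy.
#' @return Character vector of family ids.
#' @export
lineage_specific_families <- function(pam, focal, min_focal = 2) {
  species <- setdiff(names(pam), "family_id")
  if (!all(focal %in% species)) stop("focal species absent from matrix")
  outgroup <- setdiff(species, focal)
  in_focal <- rowSums(as.matrix(pam[focal]) > 0)
  in_out <- if (length(outgroup) > 0) {
    rowSums(as.matrix(pam[outgroup]) > 0)
  } else rep(0, nrow(pam))
  pam$family_id[in_focal >= min_focal & in_out == 0]
}

#' Hypergeometric phylostratum enrichment of marker sets
#'
#' For every (cluster, stratum) cell: the upper-tail hypergeometric
#' probability of drawing at least the observed overlap of cluster markers
#' with stratum genes from the universe, BH-corrected across the full
#' cluster x stratum grid. Empty clusters are skipped with a warning.
#'
#' @param markers Tibble `cluster`, `gene_id` (marker sets; genes must lie
#'   in the universe).
#' @param ages Tibble `gene_id`, `stratum` covering the universe; strata are
#'   reported in their order of appearance (oldest first by convention).
#' @param universe Character vector of all genes.
#' @return Enrichment tibble: `cluster`, `stratum`, `overlap`,
#'   `cluster_size`, `stratum_size`, `universe_size`, `p`, `q`.
#' @export
phylostratum_enrichment <- function(markers, ages, universe) {
  if (!all(markers$gene_id %in% universe)) {
    stop("marker genes must be a subset of the universe")
  }
  if (!all(universe %in% ages$gene_id)) {
    stop("ages must cover the universe")
  }
  ages <- dplyr::filter(ages, .data$gene_id %in% universe)
  strata <- unique(ages$stratum)
  clusters <- unique(markers$cluster)
  empty <- setdiff(clusters, markers$cluster[!is.na(markers$gene_id)])
  sizes <- table(factor(ages$stratum, strata))
  N <- length(universe)
  stratum_genes <- split(ages$gene_id, factor(ages$stratum, strata))

  res <- purrr::map_dfr(clusters, function(cl) {
    mk <- unique(markers$gene_id[markers$cluster == cl])
    if (length(mk) == 0) {
      warning("skipping empty cluster: ", cl)
      return(NULL)
    }
    purrr::map_dfr(strata, function(st) {
      ov <- length(intersect(mk, stratum_genes[[st]]))
      m <- as.integer(sizes[[st]])
      tibble::tibble(
        cluster = cl, stratum = st, overlap = ov,
        cluster_size = length(mk), stratum_size = m, universe_size = N,
        p = phyper(ov - 1, m, N - m, length(mk), lower.tail = FALSE)
      )
    })
  })
  res$q <- p.adjust(res$p, method = "BH")
  res
}
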