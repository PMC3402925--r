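# Lineage-aware breakpoint selection
# ----------------------------------
# A multi-species BPR table labels every region with the evolutionary branch
# on which the rearrangement happened.  Only breakpoints on branches lying on
# the path between two species since their most recent common ancestor
# differentiate that pair; all others are shared by both species or by
# neither.  The phylogeny-to-label mapping is pure configuration (a small
# newick tree), never hard-coded, because label vocabularies differ across
# BPR tables.

#' Branch labels on the path between two species
#'
#' Given a rooted phylogeny in which every edge carries a label -- encoded in
#' newick by labelling each node with the label of the edge *above* it (tip
#' names label the terminal edges, internal-node labels the internal edges)
#' -- returns the labels of the edges on the unique path between two leaves.
#' These are exactly the branches whose breakpoints differentiate the pair.
#'
#' @param phylogeny An [ape::phylo] tree, or a path to a newick file, or a
#'   newick string (must contain `"("` and `";"`).
#' @param species_a,species_b Tip names.
#' @return Character vector of branch labels on the path (empty if
#'   `species_a == species_b`).
#' @examples
#' tr <- ape::read.tree(text = "((human,chimp)human-chimp,macaque)root;")
#' branches_on_path(tr, "human", "macaque")
#' @export
branches_on_path <- function(phylogeny, species_a, species_b) {
  tree <- as_phylo_tree(phylogeny)
  tips <- tree$tip.label
  for (sp in c(species_a, species_b)) {
    if (!sp %in% tips) {
      stop("species '", sp, "' not found in the phylogeny", call. = FALSE)
    }
  }
  ia <- match(species_a, tips)
  ib <- match(species_b, tips)
  if (ia == ib) return(character())
  nodes <- ape::nodepath(tree, ia, ib)
  mrca <- ape::getMRCA(tree, c(ia, ib))
  # each non-MRCA node on the path contributes the edge from it to its parent;
  # that edge's label is the node's own label (tip name or node label)
  on_path <- setdiff(nodes, mrca)
  labs <- vapply(on_path, function(nd) node_edge_label(tree, nd), character(1))
  labs <- labs[nzchar(labs)]
  unique(labs)
}

as_phylo_tree <- function(phylogeny) {
  if (inherits(phylogeny, "phylo")) return(phylogeny)
  if (is.character(phylogeny) && length(phylogeny) == 1L) {
    if (grepl("\\(", phylogeny) && grepl(";", phylogeny)) {
      return(ape::read.tree(text = phylogeny))
    }
    return(ape::read.tree(phylogeny))
  }
  stop("phylogeny must be a phylo object, a newick string, or a file path",
       call. = FALSE)
}

node_edge_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) {
    tree$tip.label[node]
  } else {
    lab <- tree$node.label[node - n_tip]
    if (is.null(lab) || is.na(lab)) "" else lab
  }
}

#' Select breakpoints on chosen evolutionary branches
#'
#' Retains exactly the BPR records whose branch label is in `branch_labels`,
#' preserving order and coordinates.  Labels are matched case-insensitively
#' after trimming.  A per-label summary of retained and discarded counts is
#' attached as the `"summary"` attribute.
#'
#' @param bprs BPR `data.frame` from [read_bpr_table()].
#' @param branch_labels Character vector of branch labels to retain, e.g. the
#'   output of [branches_on_path()].
#' @return The retained sublist of `bprs`, with attribute `"summary"`: a
#'   `data.frame` of `branch`, `n`, `retained`.
#' @export
select_breakpoints <- function(bprs, branch_labels) {
  if (length(branch_labels) == 0L) {
    stop("branch_labels must be non-empty", call. = FALSE)
  }
  want <- tolower(trimws(branch_labels))
  have <- tolower(trimws(bprs$branch))
  missing_labels <- setdiff(want, unique(have))
  if (length(missing_labels) > 0L) {
    warning("branch label(s) never observed in the BPR table: ",
            paste(missing_labels, collapse = ", "))
  }
  keep <- have %in% want
  out <- bprs[keep, , drop = FALSE]
  rownames(out) <- NULL
  tab <- table(bprs$branch, factor(keep, levels = c(FALSE, TRUE)))
  summary <- data.frame(branch = rownames(tab),
                        n = as.integer(rowSums(tab)),
                        retained = as.integer(tab[, "TRUE"]),
                        stringsAsFactors = FALSE)
  attr(out, "summary") <- summary
  out
}
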