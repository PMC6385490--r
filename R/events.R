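# Branch placement of intron-loss and translocation events by parsimony
# under irreversibility, and the co-timing report that asks whether intron
# losses and translocation gains map to the same branches -- the signature
# of promoter-carrying retrocopy.

#' Irreversible-loss parsimony for intron counts
#'
#' Intron counts can only decrease toward the tips.  Each internal node is
#' assigned the maximum of its children's values, which yields the unique
#' latest-loss (closest-to-tips) reconstruction; a loss event of magnitude
#' `parent - child` is emitted on every branch where the value drops.  Tips
#' with `NA` counts (no intact copy) contribute no constraint.
#'
#' @param tree Rooted `phylo` tree.
#' @param tip_counts Named integer vector of intron counts at (a subset of)
#'   tips.
#' @param ancestral_count Intron count at the root.
#' @return Tibble of events: `branch_id`, `kind = "intron_loss"`,
#'   `magnitude`.  A drop already implied above the root is reported on
#'   branch `"(root)"`.
#' @export
irreversible_loss_parsimony <- function(tree, tip_counts, ancestral_count) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(names(tip_counts), tree$tip.label)
  if (length(unknown)) stop("unknown tips: ", paste(unknown, collapse = ", "))
  if (any(!is.na(tip_counts) & tip_counts > ancestral_count)) {
    stop("tip intron count exceeds the ancestral count")
  }
  ntip <- ape::Ntip(tree)
  val <- rep(NA_real_, ntip + tree$Nnode)
  val[match(names(tip_counts), tree$tip.label)] <- as.numeric(tip_counts)
  post <- function(node) {
    if (node <= ntip) return(val[node])
    kids <- tree_children(tree, node)
    vs <- vapply(kids, post, numeric(1))
    v <- if (all(is.na(vs))) NA_real_ else max(vs, na.rm = TRUE)
    val[node] <<- v
    v
  }
  root <- tree_root(tree)
  post(root)
  out <- list()
  if (!is.na(val[root]) && val[root] < ancestral_count) {
    out[[1]] <- tibble(branch_id = "(root)", kind = "intron_loss",
                       magnitude = as.integer(ancestral_count - val[root]))
  }
  walk <- function(node, pv) {
    for (child in tree_children(tree, node)) {
      cv <- val[child]
      eff <- if (is.na(cv)) pv else cv
      if (!is.na(cv) && cv < pv) {
        out[[length(out) + 1]] <<- tibble(
          branch_id = clade_id(tree, child), kind = "intron_loss",
          magnitude = as.integer(pv - cv))
      }
      if (child > ntip) walk(child, eff)
    }
  }
  walk(root, min(ancestral_count, if (is.na(val[root])) ancestral_count
                 else val[root]))
  if (length(out) == 0) {
    return(tibble(branch_id = character(0), kind = character(0),
                  magnitude = integer(0)))
  }
  dplyr::bind_rows(out)
}

#' Dollo parsimony for slot presence
#'
#' A syntenic slot is gained once -- on the branch above the most recent
#' common ancestor of all species carrying the gene or its vestige -- and
#' may only be lost afterwards.  Losses are placed on the minimal branch
#' set explaining absence inside the gain clade.  With graded states,
#' vestiges count as presence for gain dating, and each minimal branch on
#' which functionality (a full-length copy) was lost is annotated as
#' `pseudogenization` when at least one descendant retains a vestige, and
#' `copy_loss` when every descendant lost even the vestige.
#'
#' @param tree Rooted `phylo` tree.
#' @param states Named vector over tips: `"full"`/`"vestige"`/`"absent"`,
#'   or logical/0-1 presence (then treated as full/absent).
#' @return List with `gain` (branch id; `"(root)"` when presence spans the
#'   root) and `losses` (tibble `branch_id`, `kind`).
#' @export
dollo_presence_parsimony <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  if (is.logical(states) || is.numeric(states)) {
    states <- setNames(ifelse(as.numeric(states) > 0, "full", "absent"),
                       names(states))
  }
  states <- states[names(states) %in% tree$tip.label]
  full_states <- setNames(rep("absent", ape::Ntip(tree)), tree$tip.label)
  full_states[names(states)] <- unname(states)
  present <- names(full_states)[full_states != "absent"]
  if (length(present) == 0) stop("all-zero presence column")
  ntip <- ape::Ntip(tree)
  gain_node <- if (length(present) == 1) {
    match(present, tree$tip.label)
  } else {
    ape::getMRCA(tree, present)
  }
  gain <- clade_id(tree, gain_node)
  # minimal branches inside the gain clade on which the full-length copy
  # was lost
  losses <- list()
  tip_state <- function(node) full_states[tree$tip.label[node]]
  all_nonfull <- function(node) {
    tips <- clade_tips(tree, node)
    all(full_states[tree$tip.label[tips]] != "full")
  }
  descend <- function(node) {
    for (child in tree_children(tree, node)) {
      if (all_nonfull(child)) {
        tips <- clade_tips(tree, child)
        st <- full_states[tree$tip.label[tips]]
        kind <- if (all(st == "absent")) "copy_loss" else "pseudogenization"
        losses[[length(losses) + 1]] <<- tibble(
          branch_id = clade_id(tree, child), kind = kind)
      } else if (child > ntip) {
        descend(child)
      }
    }
  }
  if (gain_node > ntip && !all_nonfull(gain_node)) descend(gain_node)
  losses <- if (length(losses)) dplyr::bind_rows(losses) else
    tibble(branch_id = character(0), kind = character(0))
  list(gain = gain, losses = losses)
}

#' Report branches carrying both intron loss and translocation
#'
#' The retrocopy mechanism predicts that the branch on which a copy lost
#' introns is the branch on which it appeared at a new syntenic slot.  This
#' intersects the two placements at branch level; the overall verdict is
#' `"co-timed"` when every intron-loss branch also carries a translocation
#' gain.
#'
#' @param intron_events Tibble from [irreversible_loss_parsimony()].
#' @param translocation_events Tibble with `branch_id` of inferred gains.
#' @return Tibble (`branch_id`, `intron_loss`, `translocation`, `co_timed`)
#'   with the overall verdict in attribute `"verdict"`.
#' @export
cotiming_report <- function(intron_events, translocation_events) {
  ib <- unique(intron_events$branch_id)
  tb <- unique(translocation_events$branch_id)
  branches <- union(ib, tb)
  out <- tibble(branch_id = branches,
                intron_loss = branches %in% ib,
                translocation = branches %in% tb) |>
    dplyr::mutate(co_timed = .data$intron_loss & .data$translocation)
  verdict <- if (length(ib) > 0 && all(ib %in% tb)) "co-timed"
             else "not co-timed"
  attr(out, "verdict") <- verdict
  out
}
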