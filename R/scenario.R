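# Randomised planted-event scenarios used to validate end-to-end recovery.
# Each scenario draws a small random tree and a set of events constrained to
# be identifiable: a "witness" lineage always retains the ancestral gene
# untouched (without an outgroup that preserves the ancestral intron count
# and locus, no parsimony method could date the events); branches carrying
# independent intron signals are clade-disjoint; erasures never remove a
# whole root-child subtree's record of the parent locus.

#' Draw a random identifiable scenario
#'
#' Generates a rooted random tree of `n_leaves` species and a planted event
#' set: one retrocopy translocation on an internal branch (with 0-8 introns
#' removed and a random promoter carry flag), optionally a second
#' translocation and an in-place intron loss on clade-disjoint branches,
#' optionally a pseudogenization of the parent copy on a terminal branch
#' and an erasure of the parent copy on a non-root-child terminal branch.
#' Destinations are drawn without replacement from three anchor
#' neighborhoods on distinct chromosomes.
#'
#' @param seed Scenario seed (also the simulation seed).
#' @param rate Per-branch substitution rate.
#' @param n_leaves Number of species.
#' @return List with `tree`, `params`, `events`.
#' @export
random_scenario <- function(seed, rate = 0, n_leaves = 5) {
  set.seed(seed)
  tree <- ape::rtree(n_leaves, br = NULL)
  tree$tip.label <- paste0("sp", seq_len(n_leaves))
  binfo <- branch_ids(tree)
  ntip <- ape::Ntip(tree)
  tips_of <- lapply(binfo$node, function(n)
    tree$tip.label[clade_tips(tree, n)])
  names(tips_of) <- binfo$branch_id
  internal <- binfo$branch_id[binfo$node > ntip]
  terminal <- binfo$branch_id[binfo$node <= ntip]
  root_children <- vapply(tree_children(tree, tree_root(tree)),
                          function(n) clade_id(tree, n), character(1))

  witness <- sample(tree$tip.label, 1)  # untouched outgroup lineage
  used <- witness                       # tips claimed by disjoint signals
  decayed <- character(0)

  pick_disjoint <- function(cands) {
    cands <- sample(cands)
    for (b in cands) {
      if (!any(tips_of[[b]] %in% used)) return(b)
    }
    NULL
  }

  ev <- list()
  dests <- sample(list(c("chr2", "d2"), c("chr3", "e2"), c("chr4", "f2")))

  b1 <- pick_disjoint(internal)
  if (is.null(b1)) b1 <- pick_disjoint(terminal)
  ev[[1]] <- tibble(branch = b1, kind = "translocation_gain",
                    source = "copy0", new_copy = "copy1",
                    introns_removed = sample(0:8, 1),
                    dest_chrom = dests[[1]][1], dest_after = dests[[1]][2],
                    dest_strand = sample(c("+", "-"), 1),
                    carry_promoter = sample(c(TRUE, FALSE), 1))
  used <- c(used, tips_of[[b1]])

  if (runif(1) < 0.4) {
    b2 <- pick_disjoint(setdiff(internal, b1))
    if (!is.null(b2)) {
      ev[[length(ev) + 1]] <- tibble(
        branch = b2, kind = "translocation_gain", source = "copy0",
        new_copy = "copy2", introns_removed = sample(0:8, 1),
        dest_chrom = dests[[2]][1], dest_after = dests[[2]][2],
        dest_strand = sample(c("+", "-"), 1),
        carry_promoter = sample(c(TRUE, FALSE), 1))
      used <- c(used, tips_of[[b2]])
    }
  }

  if (runif(1) < 0.3) {
    b3 <- pick_disjoint(binfo$branch_id)
    if (!is.null(b3)) {
      ev[[length(ev) + 1]] <- tibble(
        branch = b3, kind = "intron_loss", target = "copy0",
        n = sample(1:8, 1))
      used <- c(used, tips_of[[b3]])
    }
  }

  # at most one decay of the parent copy: a second decay hitting the
  # sibling lineage would merge both into one stem event under minimal
  # placement, which no inference could split again
  decay_kind <- sample(c("none", "pseudogenization", "copy_loss"), 1,
                       prob = c(0.3, 0.4, 0.3))
  if (decay_kind == "pseudogenization") {
    cands <- setdiff(terminal, witness)
    if (length(cands)) {
      ev[[length(ev) + 1]] <- tibble(
        branch = sample(cands, 1), kind = "pseudogenization",
        target = "copy0", stage = sample(c("fragment", "short"), 1))
    }
  } else if (decay_kind == "copy_loss") {
    cands <- setdiff(terminal, c(root_children, witness))
    if (length(cands)) {
      ev[[length(ev) + 1]] <- tibble(branch = sample(cands, 1),
                                     kind = "copy_loss", target = "copy0")
    }
  }

  events <- dplyr::bind_rows(ev)
  events <- prune_unidentifiable(tree, events)
  list(tree = tree, params = sim_params(seed = seed, rate = rate),
       events = events)
}

# Intron counts at the tips implied by a planted event set (the count of
# the best-preserved intact copy; NA when no intact copy survives).
implied_tip_counts <- function(tree, events) {
  events <- normalize_events(events)
  ntip <- ape::Ntip(tree)
  counts <- setNames(rep(NA_real_, ntip), tree$tip.label)
  for (tip in seq_len(ntip)) {
    # root-to-tip branch path
    path <- character(0)
    node <- tip
    while (node != tree_root(tree)) {
      path <- c(clade_id(tree, node), path)
      node <- tree$edge[tree$edge[, 2] == node, 1]
    }
    copy0 <- 8; copy0_alive <- TRUE
    daughters <- numeric(0)
    for (b in path) {
      ev <- events[events$branch == b, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        e <- ev[i, ]
        if (e$kind == "intron_loss") copy0 <- copy0 - e$n
        if (e$kind == "translocation_gain") {
          daughters <- c(daughters, copy0 - e$introns_removed)
        }
        if (e$kind %in% c("pseudogenization", "copy_loss")) {
          copy0_alive <- FALSE
        }
      }
    }
    alive <- c(if (copy0_alive) copy0, daughters)
    counts[tip] <- if (length(alive)) min(alive) else NA_real_
  }
  counts
}

# Drop optional intron-affecting events until the planted intron events are
# exactly what count-level parsimony reconstructs (scenarios are sampled
# from identifiable histories).
prune_unidentifiable <- function(tree, events) {
  planted_introns <- function(ev) {
    ev <- normalize_events(ev)
    rows <- dplyr::bind_rows(
      ev |> dplyr::filter(.data$kind == "intron_loss") |>
        dplyr::transmute(branch_id = .data$branch,
                         magnitude = as.integer(.data$n)),
      ev |> dplyr::filter(.data$kind == "translocation_gain",
                          .data$introns_removed > 0) |>
        dplyr::transmute(branch_id = .data$branch,
                         magnitude = as.integer(.data$introns_removed)))
    dplyr::arrange(rows, .data$branch_id, .data$magnitude)
  }
  repeat {
    counts <- implied_tip_counts(tree, events)
    inferred <- irreversible_loss_parsimony(tree, counts[!is.na(counts)], 8)
    inf <- dplyr::arrange(inferred[c("branch_id", "magnitude")],
                          .data$branch_id, .data$magnitude)
    if (identical(as.data.frame(planted_introns(events)),
                  as.data.frame(inf))) {
      return(events)
    }
    # drop a standalone intron loss first, then strip introns_removed from
    # the later translocation
    il <- which(events$kind == "intron_loss")
    if (length(il)) {
      events <- events[-il[length(il)], , drop = FALSE]
      next
    }
    tg <- which(events$kind == "translocation_gain" &
                  events$introns_removed > 0)
    if (length(tg) == 0) return(events)  # nothing left to relax
    events$introns_removed[tg[length(tg)]] <- 0L
  }
}

#' Simulate and analyse one scenario
#'
#' @param seed,rate,n_leaves Passed to [random_scenario()].
#' @return The `he_run` (with `$scorecard` against the planted log).
#' @export
run_scenario <- function(seed, rate = 0, n_leaves = 5) {
  sc <- random_scenario(seed, rate = rate, n_leaves = n_leaves)
  sim <- simulate_clade(sc$tree, sc$params, events = sc$events)
  run_pipeline(sim)
}

#' Aggregate recovery over a batch of scenarios
#'
#' @param seeds Scenario seeds.
#' @param rate Substitution rate for all scenarios.
#' @param n_leaves Species per scenario.
#' @return Tibble with one row per scenario (`seed`, `planted`,
#'   `recovered`, `spurious`, `carry_total`, `carry_correct`); aggregate
#'   rates in attributes `recovery_rate` and `carryover_accuracy`.
#' @export
recovery_batch <- function(seeds, rate = 0, n_leaves = 5) {
  rows <- lapply(seeds, function(s) {
    run <- run_scenario(s, rate = rate, n_leaves = n_leaves)
    sc <- run$scorecard
    tibble(seed = s,
           planted = nrow(sc$detail),
           recovered = sum(sc$detail$recovered),
           spurious = sc$n_spurious,
           carry_total = if (is.null(sc$carryover)) 0L
                         else nrow(sc$carryover),
           carry_correct = if (is.null(sc$carryover)) 0L
                           else sum(sc$carryover$correct))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "recovery_rate") <- sum(out$recovered) / sum(out$planted)
  attr(out, "carryover_accuracy") <-
    if (sum(out$carry_total) > 0) sum(out$carry_correct) / sum(out$carry_total)
    else NA_real_
  out
}
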