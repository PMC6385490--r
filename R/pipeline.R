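# Orchestration: clone -> synteny -> events -> promoter over a set of
# annotated genomes and a species tree, with optional scoring against a
# planted ground-truth event log.

#' Run the full inference pipeline
#'
#' Locates every copy of the focal family in each genome
#' ([cross_species_clone()]), extracts flanking-gene contexts and matches
#' them into syntenic slots, builds the presence matrix, places intron-loss
#' events ([irreversible_loss_parsimony()] on the per-species minimum
#' intron count over intact copies) and translocation gains / decay events
#' ([dollo_presence_parsimony()] per slot; the slot whose gain sits closest
#' to the root is the parent slot and is not a translocation), reports
#' branch co-timing, and classifies promoter carry-over of every
#' daughter-slot locus against the reference promoter.
#'
#' @param genomes Named list of [annotated_genome()], or a
#'   [simulate_clade()] result (then `tree`, `family` and `event_log`
#'   default to the simulation's).
#' @param tree Rooted `phylo` species tree covering the genome species.
#' @param family List with `exons` (seed exon sequences, 5' to 3') and
#'   optionally `promoter` (reference upstream window ending at the TSS).
#' @param window Upstream window (bp).
#' @param k,min_anchors Synteny parameters (see [extract_context()],
#'   [match_slots()]).
#' @param min_intron,max_mismatch_rate Splice-mapping parameters.
#' @param event_log Optional ground-truth log for scoring.
#' @return An object of class `he_run`.
#' @export
run_pipeline <- function(genomes, tree = NULL, family = NULL, window = 200,
                         k = 3, min_anchors = 2, min_intron = 40,
                         max_mismatch_rate = 0.05, event_log = NULL) {
  if (inherits(genomes, "clade_sim")) {
    sim <- genomes
    genomes <- sim$genomes
    if (is.null(tree)) tree <- sim$tree
    if (is.null(family)) family <- sim$family
    if (is.null(event_log)) event_log <- sim$event_log
  }
  if (length(genomes) == 0) stop("no input genomes")
  stopifnot(inherits(tree, "phylo"), !is.null(family$exons))
  missing_sp <- setdiff(names(genomes), tree$tip.label)
  if (length(missing_sp)) {
    stop("species absent from tree: ", paste(missing_sp, collapse = ", "))
  }

  # -- clone every focal locus ------------------------------------------
  loci <- dplyr::bind_rows(lapply(genomes, function(g)
    cross_species_clone(family$exons, g, min_intron = min_intron,
                        max_mismatch_rate = max_mismatch_rate)))

  # -- synteny contexts and slots ---------------------------------------
  if (nrow(loci) == 0) stop("no focal loci found in any genome")
  ctx <- dplyr::bind_rows(lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    cx <- extract_context(genomes[[l$species_id]], l$chromosome, l$start,
                          l$end, strand = l$strand, k = k, state = l$state)
    cx$intron_count <- l$intron_count
    cx$coverage <- l$coverage
    cx$model <- l$model
    cx
  }))
  ctx <- match_slots(ctx, min_anchors = min_anchors)
  pm <- build_presence_matrix(ctx, species = names(genomes))

  # -- intron-loss parsimony --------------------------------------------
  counts <- ctx |>
    dplyr::filter(.data$state == "full") |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(introns = min(.data$intron_count), .groups = "drop")
  tip_counts <- setNames(counts$introns, counts$species_id)
  ancestral <- length(family$exons) - 1L
  intron_ev <- irreversible_loss_parsimony(tree, tip_counts, ancestral)

  # -- per-slot Dollo placement -----------------------------------------
  depths <- node_depths(tree)
  blk <- branch_lookup(tree)
  slot_info <- lapply(sort(unique(pm$slot)), function(s) {
    rows <- pm[pm$slot == s, ]
    states <- setNames(rows$state, rows$species_id)
    dp <- dollo_presence_parsimony(tree, states)
    depth <- if (dp$gain == "(root)") 0L else depths[blk[[dp$gain]]]
    list(slot = s, gain = dp$gain, depth = depth, losses = dp$losses,
         n_present = sum(states != "absent"))
  })
  gain_tbl <- dplyr::bind_rows(lapply(slot_info, function(x)
    tibble(slot = x$slot, gain_branch = x$gain, gain_depth = x$depth,
           n_present = x$n_present)))
  parent_slot <- gain_tbl |>
    dplyr::arrange(.data$gain_depth, dplyr::desc(.data$n_present),
                   .data$slot) |>
    dplyr::slice(1) |>
    dplyr::pull("slot")
  transloc_ev <- gain_tbl |>
    dplyr::filter(.data$slot != parent_slot) |>
    dplyr::transmute(branch_id = .data$gain_branch,
                     kind = "translocation_gain", magnitude = NA_integer_,
                     slot = .data$slot)
  decay_ev <- dplyr::bind_rows(lapply(slot_info, function(x) {
    if (nrow(x$losses) == 0) return(NULL)
    dplyr::mutate(x$losses, magnitude = NA_integer_, slot = x$slot)
  }))
  if (is.null(decay_ev) || nrow(decay_ev) == 0) {
    decay_ev <- tibble(branch_id = character(0), kind = character(0),
                       magnitude = integer(0), slot = character(0))
  }
  events <- dplyr::bind_rows(
    dplyr::mutate(intron_ev, slot = NA_character_), transloc_ev, decay_ev)

  # -- co-timing ---------------------------------------------------------
  cotiming <- cotiming_report(intron_ev, transloc_ev)

  # -- promoter carry-over ----------------------------------------------
  ref_report <- if (!is.null(family$promoter)) {
    promoter_report(family$promoter, species_id = "reference",
                    slot = parent_slot)
  } else NULL
  reports <- list()
  carry_rows <- list()
  for (i in seq_len(nrow(ctx))) {
    if (ctx$state[i] != "full" || is.null(ctx$model[[i]])) next
    sp <- ctx$species_id[i]
    up <- extract_upstream(genomes[[sp]], ctx$model[[i]], window = window)
    rep <- promoter_report(up, species_id = sp, slot = ctx$slot[i])
    reports[[paste(sp, ctx$slot[i], sep = "/")]] <- rep
    if (!is.null(ref_report) && ctx$slot[i] != parent_slot) {
      cc <- classify_carryover(ref_report, rep)
      carry_rows[[length(carry_rows) + 1]] <- tibble(
        species_id = sp, slot = ctx$slot[i], carryover = cc$carryover,
        evidence = list(cc$evidence))
    }
  }
  carryover <- if (length(carry_rows)) dplyr::bind_rows(carry_rows) else
    tibble(species_id = character(0), slot = character(0),
           carryover = logical(0), evidence = list())
  utree <- NULL
  with_tata <- Filter(function(r) !is.na(r$tata_offset), reports)
  if (length(with_tata) >= 3) {
    utree <- tryCatch(
      upstream_tree(setNames(vapply(with_tata, function(r) r$upstream_seq,
                                    character(1)), names(with_tata))),
      warning = function(w) suppressWarnings(
        upstream_tree(setNames(vapply(with_tata, function(r) r$upstream_seq,
                                      character(1)), names(with_tata)))),
      error = function(e) NULL)
  }

  run <- structure(list(
    loci = loci, contexts = ctx, presence = pm, tip_introns = tip_counts,
    ancestral_introns = ancestral, events = events, gains = gain_tbl,
    parent_slot = parent_slot, cotiming = cotiming, carryover = carryover,
    promoter_reports = reports, upstream_tree = utree, tree = tree,
    settings = list(window = window, k = k, min_anchors = min_anchors,
                    min_intron = min_intron,
                    max_mismatch_rate = max_mismatch_rate)),
    class = "he_run")
  if (!is.null(event_log)) {
    run$scorecard <- score_against_truth(run, event_log)
  }
  run
}

#' @export
print.he_run <- function(x, ...) {
  cat("<he_run> ", length(unique(x$presence$species_id)), " species, ",
      nrow(x$loci), " loci, ", length(unique(x$presence$slot)),
      " slots (parent: ", x$parent_slot, ")\n", sep = "")
  cat("events:\n")
  print(as_tibble(x$events))
  cat("co-timing verdict:", attr(x$cotiming, "verdict"), "\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object An `he_run`.
#' @param ... Unused.
#' @export
tidy.he_run <- function(x, ...) as_tibble(x$events)

#' @rdname run_pipeline
#' @export
glance.he_run <- function(x, ...) {
  tibble(
    n_species = length(unique(x$presence$species_id)),
    n_loci = nrow(x$loci),
    n_slots = length(unique(x$presence$slot)),
    n_daughter_slots = count_daughter_slots(x$presence, x$parent_slot),
    n_intron_loss = sum(x$events$kind == "intron_loss"),
    n_translocations = sum(x$events$kind == "translocation_gain"),
    n_cotimed = sum(x$cotiming$co_timed),
    verdict = attr(x$cotiming, "verdict"),
    carryover_rate = if (nrow(x$carryover)) mean(x$carryover$carryover)
                     else NA_real_)
}

#' @rdname run_pipeline
#' @export
autoplot.he_run <- function(object, ...) autoplot(object$presence, ...)

#' Score inferred events against a planted ground truth
#'
#' Branch-exact matching of inferred events to the simulator's event log:
#' an `intron_loss` matches on branch and magnitude, other kinds on branch
#' alone.  Also grades promoter carry-over calls against the planted
#' carry flags of each translocation.
#'
#' @param run An `he_run`.
#' @param event_log Ground-truth log from [simulate_clade()].
#' @return List of class `he_scorecard`: `by_kind` tibble (planted,
#'   recovered, spurious), `recovery_rate`, `spurious`, `carryover`
#'   (per planted translocation) and `carryover_accuracy`.
#' @export
score_against_truth <- function(run, event_log) {
  planted <- as_tibble(event_log)
  inferred <- as_tibble(run$events)
  match_one <- function(kind, branch, magnitude) {
    hit <- inferred$kind == kind & inferred$branch_id == branch
    if (kind == "intron_loss") {
      hit <- hit & !is.na(inferred$magnitude) &
        inferred$magnitude == magnitude
    }
    any(hit)
  }
  planted$recovered <- vapply(seq_len(nrow(planted)), function(i)
    match_one(planted$kind[i], planted$branch[i], planted$magnitude[i]),
    logical(1))
  spurious <- vapply(seq_len(nrow(inferred)), function(i) {
    hit <- planted$kind == inferred$kind[i] &
      planted$branch == inferred$branch_id[i]
    if (inferred$kind[i] == "intron_loss") {
      hit <- hit & !is.na(planted$magnitude) &
        planted$magnitude == inferred$magnitude[i]
    }
    !any(hit)
  }, logical(1))
  by_kind <- planted |>
    dplyr::group_by(kind = .data$kind) |>
    dplyr::summarise(planted = dplyr::n(),
                     recovered = sum(.data$recovered), .groups = "drop") |>
    dplyr::left_join(
      inferred[spurious, ] |>
        dplyr::count(kind = .data$kind, name = "spurious"),
      by = "kind") |>
    dplyr::mutate(spurious = dplyr::coalesce(.data$spurious, 0L))
  # carry-over grading: match each planted translocation's branch to an
  # inferred daughter slot, then compare the carry flag with the call
  tr <- planted[planted$kind == "translocation_gain", , drop = FALSE]
  carry <- NULL
  if (nrow(tr) > 0 && !all(is.na(tr$carry_promoter))) {
    gains <- inferred[inferred$kind == "translocation_gain", , drop = FALSE]
    carry <- dplyr::bind_rows(lapply(seq_len(nrow(tr)), function(i) {
      slot <- gains$slot[gains$branch_id == tr$branch[i]]
      call <- if (length(slot) == 0) NA else {
        calls <- run$carryover$carryover[run$carryover$slot %in% slot]
        if (length(calls) == 0) NA else mean(calls) >= 0.5
      }
      tibble(branch = tr$branch[i], planted_carry = tr$carry_promoter[i],
             called_carry = call,
             correct = !is.na(call) & call == tr$carry_promoter[i])
    }))
  }
  structure(list(
    by_kind = by_kind,
    detail = planted,
    recovery_rate = if (nrow(planted)) mean(planted$recovered) else NA_real_,
    n_spurious = sum(spurious),
    carryover = carry,
    carryover_accuracy = if (!is.null(carry) && nrow(carry))
      mean(carry$correct) else NA_real_), class = "he_scorecard")
}

#' @export
print.he_scorecard <- function(x, ...) {
  cat("<he_scorecard> recovery ", round(100 * x$recovery_rate, 1), "%, ",
      x$n_spurious, " spurious\n", sep = "")
  print(x$by_kind)
  if (!is.null(x$carryover)) {
    cat("carry-over accuracy:", round(100 * x$carryover_accuracy, 1), "%\n")
  }
  invisible(x)
}

#' Write a run's outputs to disk
#'
#' Emits the presence matrix and event table as TSV, per-context records as
#' JSON lines and the upstream tree (when built) as Newick.
#'
#' @param run An `he_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(run$events),
                     file.path(dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pm <- tidyr::pivot_wider(
    as_tibble(run$presence)[c("species_id", "slot", "state")],
    names_from = "slot", values_from = "state")
  utils::write.table(as.data.frame(pm), file.path(dir, "presence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "contexts.jsonl"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(run$contexts))) {
    cx <- run$contexts[i, ]
    rec <- list(species_id = cx$species_id, chromosome = cx$chromosome,
                start = cx$start, end = cx$end, strand = cx$strand,
                state = cx$state, slot = cx$slot,
                upstream = cx$upstream[[1]], downstream = cx$downstream[[1]],
                host_insertion = cx$host_insertion[[1]])
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                             na = "null")), con)
  }
  if (!is.null(run$upstream_tree)) {
    ape::write.tree(run$upstream_tree, file.path(dir, "upstream_tree.nwk"))
  }
  invisible(dir)
}
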