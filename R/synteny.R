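# Ordered flanking-gene contexts around focal loci, matching of contexts
# across species into syntenic slots, and the species-by-slot
# presence/vestige matrix that event inference works from.
#
# "Upstream"/"downstream" neighbors are taken in genomic coordinate order
# (left/right of the locus) so that slot identity never depends on the
# orientation of the focal gene itself.

SENTINEL <- "(end)"

#' Extract the flanking-gene context of a locus
#'
#' Collects up to `k` annotated neighbor genes on each side of the locus
#' (nearest first), padding with the sentinel symbol `"(end)"` at
#' chromosome ends.  Genes whose exons overlap the locus are excluded (they
#' are the locus itself); a gene whose span contains the locus without
#' exonic overlap is reported as `host_insertion` with the 1-based intron
#' ordinal in the host's transcription direction and the relative
#' orientation of the locus.
#'
#' @param genome An [annotated_genome()].
#' @param chromosome,start,end Locus interval (0-based half-open).
#' @param strand Strand of the locus occupant (may be `NA`).
#' @param k Neighbors per side.
#' @param state Occupant state to record (`"full"`, `"fragment"`, ...).
#' @return One-row tibble with list columns `upstream`, `downstream`
#'   (tibbles of `symbol`, `strand`) and `host_insertion`.
#' @export
extract_context <- function(genome, chromosome, start, end, strand = NA,
                            k = 3, state = "full") {
  g <- genome$genes[genome$genes$chromosome == chromosome, , drop = FALSE]
  spans <- t(vapply(g$exons, gene_span, numeric(2)))
  exon_overlap <- vapply(g$exons, function(ex)
    any(ex[, "start"] < end & ex[, "end"] > start), logical(1))
  contains <- spans[, 1] <= start & spans[, 2] >= end & !exon_overlap
  host <- NULL
  if (any(contains)) {
    i <- which(contains)[1]
    ex <- g$exons[[i]]
    # intron ordinal: introns counted 1-based in transcription direction
    n_before <- sum(ex[, "end"] <= start)   # forward gap index
    ordinal <- if (g$strand[i] == "+") n_before
               else nrow(ex) - n_before
    host <- list(host_symbol = g$symbol[i],
                 intron_ordinal = as.integer(ordinal),
                 orientation = if (is.na(strand)) NA_character_
                               else if (strand == g$strand[i]) "same"
                               else "opposite")
  }
  keep <- !exon_overlap & !contains
  g <- g[keep, , drop = FALSE]
  spans <- spans[keep, , drop = FALSE]
  mids <- (spans[, 1] + spans[, 2]) / 2
  left <- order(mids[mids < (start + end) / 2], decreasing = TRUE)
  left_idx <- which(mids < (start + end) / 2)[left]
  right_idx <- which(mids >= (start + end) / 2)[
    order(mids[mids >= (start + end) / 2])]
  side_tbl <- function(idx) {
    sym <- g$symbol[idx][seq_len(min(k, length(idx)))]
    str <- g$strand[idx][seq_len(min(k, length(idx)))]
    pad <- k - length(sym)
    tibble(symbol = c(sym, rep(SENTINEL, pad)),
           strand = c(str, rep(NA_character_, pad)))
  }
  tibble(species_id = genome$species_id, chromosome = chromosome,
         start = start, end = end, strand = strand, state = state,
         upstream = list(side_tbl(left_idx)),
         downstream = list(side_tbl(right_idx)),
         host_insertion = list(host))
}

context_anchors <- function(ctx_row) {
  up <- ctx_row$upstream[[1]]
  dn <- ctx_row$downstream[[1]]
  a <- c(rev(up$symbol), dn$symbol)
  a[a != SENTINEL]
}

# Two anchor lists are slot-compatible when they share >= min_anchors
# symbols and those shared symbols appear in the same relative order.
anchors_compatible <- function(a, b, min_anchors = 2) {
  common <- intersect(a, b)
  if (length(common) < min_anchors) return(FALSE)
  identical(a[a %in% common], b[b %in% common])
}

#' Assign synteny contexts to slots
#'
#' Contexts sharing at least `min_anchors` flanking-gene symbols in a
#' consistent relative order are merged (union-find closure) into one slot.
#' Slot ids are deterministic: the lexicographically smallest anchor symbol
#' of the slot's contexts, prefixed with `"slot:"`.
#'
#' @param contexts Tibble of rows from [extract_context()].
#' @param min_anchors Minimum shared ordered anchors.
#' @return `contexts` with a `slot` column; slot metadata in attribute
#'   `"slots"` (tibble of `slot`, `anchors`).
#' @export
match_slots <- function(contexts, min_anchors = 2) {
  stopifnot(nrow(contexts) >= 1)
  n <- nrow(contexts)
  anchors <- lapply(seq_len(n), function(i) context_anchors(contexts[i, ]))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (anchors_compatible(anchors[[i]], anchors[[j]], min_anchors)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  slot_of_comp <- vapply(unique(comp), function(cc) {
    syms <- sort(unique(unlist(anchors[comp == cc])))
    if (length(syms) == 0) syms <- "unanchored"
    paste0("slot:", syms[1])
  }, character(1))
  names(slot_of_comp) <- as.character(unique(comp))
  # disambiguate clashes between distinct components
  if (anyDuplicated(slot_of_comp)) {
    for (s in unique(slot_of_comp[duplicated(slot_of_comp)])) {
      ix <- which(slot_of_comp == s)
      slot_of_comp[ix] <- paste0(s, ".", seq_along(ix))
    }
  }
  contexts$slot <- unname(slot_of_comp[as.character(comp)])
  meta <- dplyr::bind_rows(lapply(unique(comp), function(cc) {
    tibble(slot = unname(slot_of_comp[as.character(cc)]),
           anchors = list(sort(unique(unlist(anchors[comp == cc])))))
  }))
  attr(contexts, "slots") <- meta
  contexts
}

#' Build the species-by-slot presence matrix
#'
#' Maps occupant states to cell values: `full` where a gene model backs the
#' locus, `vestige` for fragment/short-fragment occupants, `absent`
#' elsewhere (including species with no context for a slot).  Conflicting
#' duplicate cells raise an error.
#'
#' @param contexts Output of [match_slots()].
#' @param species All species to include as rows (defaults to those seen).
#' @return Long tibble (`species_id`, `slot`, `state`) of class
#'   `presence_matrix`; detailed states kept in `detail`.
#' @export
build_presence_matrix <- function(contexts, species = NULL) {
  stopifnot("slot" %in% names(contexts))
  if (is.null(species)) species <- unique(contexts$species_id)
  cells <- contexts |>
    dplyr::mutate(cell = dplyr::case_when(
      .data$state == "full" ~ "full",
      .data$state %in% c("fragment", "short_fragment") ~ "vestige",
      TRUE ~ "absent")) |>
    dplyr::select("species_id", "slot", "cell", detail = "state")
  dup <- cells |>
    dplyr::distinct(.data$species_id, .data$slot, .data$cell) |>
    dplyr::count(.data$species_id, .data$slot) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("conflicting duplicate presence cells for ",
         paste(dup$species_id, dup$slot, sep = "/", collapse = ", "))
  }
  cells <- cells |>
    dplyr::distinct(.data$species_id, .data$slot, .keep_all = TRUE)
  grid <- tidyr::expand_grid(species_id = species,
                             slot = sort(unique(cells$slot)))
  pm <- grid |>
    dplyr::left_join(cells, by = c("species_id", "slot")) |>
    dplyr::mutate(state = dplyr::coalesce(.data$cell, "absent"),
                  detail = dplyr::coalesce(.data$detail, "absent")) |>
    dplyr::select("species_id", "slot", "state", "detail")
  attr(pm, "slots") <- attr(contexts, "slots")
  class(pm) <- c("presence_matrix", class(pm))
  pm
}

#' Count daughter synteny slots
#'
#' The number of distinct non-parent slots holding at least one full-length
#' occupant, optionally restricted to a subset of species (e.g. one
#' subclade).
#'
#' @param pm A [build_presence_matrix()] result.
#' @param parent_slot Slot id of the ancestral (parent) locus.
#' @param species Optional subset of species rows to consider.
#' @return Integer count.
#' @export
count_daughter_slots <- function(pm, parent_slot, species = NULL) {
  if (!parent_slot %in% pm$slot) stop("unknown parent slot: ", parent_slot)
  x <- pm
  if (!is.null(species)) x <- x[x$species_id %in% species, , drop = FALSE]
  length(unique(x$slot[x$state == "full" & x$slot != parent_slot]))
}

#' @export
print.presence_matrix <- function(x, ...) {
  w <- tidyr::pivot_wider(as_tibble(x)[c("species_id", "slot", "state")],
                          names_from = "slot", values_from = "state")
  print(w, ...)
  invisible(x)
}

#' @rdname build_presence_matrix
#' @param object,x A `presence_matrix`.
#' @param ... Unused.
#' @export
tidy.presence_matrix <- function(x, ...) as_tibble(x)

#' @rdname build_presence_matrix
#' @export
autoplot.presence_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$slot, y = .data$species_id,
                               fill = .data$state)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(full = "#c23b22",
                                          vestige = "grey70",
                                          absent = "white")) +
    ggplot2::labs(x = "syntenic slot", y = NULL, fill = "occupant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
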