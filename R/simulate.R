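# Forward simulator of a miniature clade.  Genomes are lists of sequence
# elements (spacers, single- or multi-exon neighbor genes, and focal-gene
# copies with promoter, exons and GT..AG introns) evolving along a rooted
# species tree under uniform per-site substitution, with planted events:
# retrocopy translocation (precise excision of the 3'-most introns, with or
# without the ~200 bp promoter block), in-place intron loss, graded
# pseudogenization of a copy, and complete erasure.  Functional elements keep
# their splice dinucleotides and promoter motifs fixed (purifying selection);
# decayed copies drift freely.

#' Simulation parameters
#'
#' @param seed Integer seed controlling every random choice.
#' @param rate Per-branch, per-site substitution probability.
#' @param n_neighbors Neighbor genes per flank of the ancestral focal locus.
#' @param spacer_len Length of intergenic spacers (nt).
#' @param neighbor_len Length of single-exon neighbor genes (nt).
#' @param events Optional planted-event table (see [simulate_clade()]).
#' @return A `sim_params` list.
#' @export
sim_params <- function(seed = 1L, rate = 0.01, n_neighbors = 3,
                       spacer_len = 200, neighbor_len = 300, events = NULL) {
  stopifnot(rate >= 0, rate <= 1, n_neighbors >= 1)
  structure(list(seed = as.integer(seed), rate = rate,
                 n_neighbors = n_neighbors, spacer_len = spacer_len,
                 neighbor_len = neighbor_len, events = events),
            class = "sim_params")
}

# ---- ancestral focal gene -------------------------------------------------

ACTIVE_SITE_1 <- "HEILHLLGFYHEQSRSDR"   # instance of HExxHxxGFxHExxRxDR
ACTIVE_SITE_2 <- "SIMHY"                # instance of SxMHY

# Build the ancestral nine-exon gene: protein with the two active-site
# consensus motifs and exactly six cysteines, CDS split into nine exons by
# eight GT..AG introns, and a 200 bp promoter carrying a TATA box (offset
# -31) plus klf (CWCCC, -150) and foxa3 (TGTTTRCWYW, -120) binding sites
# inside the -192..-91 subregion.  Consumes the session RNG.
.make_gene <- function() {
  filler <- setdiff(AA_LETTERS, c("C", "H", "M"))
  f <- function(n) sample(filler, n, replace = TRUE)
  prot <- c("M", f(40), "C", f(15), strsplit(ACTIVE_SITE_1, "")[[1]],
            f(12), "C", f(10), "C", f(8), strsplit(ACTIVE_SITE_2, "")[[1]],
            f(20), "C", f(12), "C", f(25), "C", f(87))
  protein <- paste(prot, collapse = "")
  gc_tab <- Biostrings::GENETIC_CODE
  codons_by_aa <- split(names(gc_tab), unname(gc_tab))
  cds <- paste(vapply(prot, function(a) {
    cs <- codons_by_aa[[a]]
    cs[sample.int(length(cs), 1)]
  }, character(1)), collapse = "")
  cds <- paste0(cds, "TAA")
  widths <- c(120, 90, 60, 81, 90, 120, 75, 84, 60)
  stopifnot(sum(widths) == nchar(cds))
  ends <- cumsum(widths)
  starts <- c(1, head(ends, -1) + 1)
  exon_seqs <- Map(function(s, e) substr(cds, s, e), starts, ends)
  intron_seqs <- lapply(seq_len(8), function(i)
    paste0("GT", random_dna(sample(56:86, 1)), "AG"))
  promoter <- random_dna(200)
  substring(promoter, 170, 176) <- "TATAAAA"    # offset -31 from TSS
  substring(promoter, 51, 55) <- "CACCC"        # klf site, offset -150
  substring(promoter, 81, 90) <- "TGTTTACTTA"   # foxa3 site, offset -120
  # the planted TATA must be the unique match in the -50..-20 search window
  promoter <- scrub_motif(promoter, "TATAWAW", keep = 170L,
                          window = c(151L, 181L))
  list(protein = protein, cds = cds,
       exon_seqs = unname(exon_seqs), intron_seqs = intron_seqs,
       promoter = promoter,
       motifs = list(tata = c(170L, 7L), klf = c(51L, 5L), foxa = c(81L, 10L)))
}

#' Construct the ancestral focal gene
#'
#' Nine exons, eight GT..AG introns, a CDS that translates without internal
#' stops into a protein carrying one `HExxHxxGFxHExxRxDR` and one `SxMHY`
#' active-site motif and exactly six cysteines, and a 200 bp promoter block
#' with a TATA box and klf/foxa3 binding sites inside the -192..-91
#' subregion.
#'
#' @param params A [sim_params()] object (only `seed` is used here).
#' @return List with `protein`, `cds`, `exon_seqs`, `intron_seqs`,
#'   `promoter` and promoter-relative `motifs` positions.
#' @export
make_ancestral_gene <- function(params = sim_params()) {
  set.seed(params$seed)
  .make_gene()
}

# ---- genome elements ------------------------------------------------------

el_spacer <- function(len) list(type = "spacer", seq = random_dna(len))

el_gene <- function(symbol, strand, len = 300, n_exons = 1,
                    exon_len = 45, intron_len = 70) {
  if (n_exons == 1) {
    seq <- random_dna(len)
    exons <- cbind(start = 0, end = len)
  } else {
    parts <- character(0)
    exs <- integer(n_exons); exe <- integer(n_exons); pos <- 0
    for (i in seq_len(n_exons)) {
      exs[i] <- pos
      parts <- c(parts, random_dna(exon_len)); pos <- pos + exon_len
      exe[i] <- pos
      if (i < n_exons) {
        parts <- c(parts, paste0("GT", random_dna(intron_len - 4), "AG"))
        pos <- pos + intron_len
      }
    }
    seq <- paste(parts, collapse = "")
    exons <- cbind(start = exs, end = exe)
  }
  list(type = "gene", symbol = symbol, strand = strand, seq = seq,
       exons = exons, nested = NULL)
}

el_focal <- function(copy_id, strand, gene, has_promoter = TRUE) {
  list(type = "focal", copy_id = copy_id, strand = strand,
       has_promoter = has_promoter, promoter = gene$promoter,
       motifs = gene$motifs, exon_seqs = gene$exon_seqs,
       intron_seqs = gene$intron_seqs, decay = "none", seq = NULL)
}

# Chromosome-forward rendering of a focal element.
render_focal <- function(el) {
  if (el$decay != "none") {
    return(list(seq = el$seq, exons = NULL))
  }
  sense <- if (el$has_promoter) el$promoter else ""
  pos <- nchar(sense)
  k <- length(el$exon_seqs)
  exs <- integer(k); exe <- integer(k)
  for (i in seq_len(k)) {
    exs[i] <- pos
    sense <- paste0(sense, el$exon_seqs[[i]])
    pos <- pos + nchar(el$exon_seqs[[i]])
    exe[i] <- pos
    if (i < k) {
      sense <- paste0(sense, el$intron_seqs[[i]])
      pos <- pos + nchar(el$intron_seqs[[i]])
    }
  }
  L <- nchar(sense)
  if (el$strand == "+") {
    list(seq = sense, exons = cbind(start = exs, end = exe))
  } else {
    list(seq = revcomp(sense),
         exons = cbind(start = L - rev(exe), end = L - rev(exs)))
  }
}

focal_len <- function(el) nchar(render_focal(el)$seq)

# ---- mutation -------------------------------------------------------------

mutate_focal <- function(el, rate) {
  if (el$decay != "none") {
    el$seq <- mutate_seq(el$seq, rate)
    return(el)
  }
  if (el$has_promoter) {
    prot <- unlist(lapply(el$motifs, function(m) seq(m[1], m[1] + m[2] - 1)))
    el$promoter <- mutate_seq(el$promoter, rate, protect = prot)
  }
  el$exon_seqs <- lapply(el$exon_seqs, mutate_seq, rate = rate)
  el$intron_seqs <- lapply(el$intron_seqs, function(s)
    mutate_seq(s, rate, protect = c(1, 2, nchar(s) - 1, nchar(s))))
  el
}

mutate_element <- function(el, rate) {
  if (rate <= 0) return(el)
  if (el$type == "focal") return(mutate_focal(el, rate))
  if (el$type == "gene" && !is.null(el$nested)) {
    off <- el$nested$offset; len <- el$nested$len
    el$seq <- mutate_seq(el$seq, rate, protect = seq(off + 1, off + len))
    el$nested$el <- mutate_focal(el$nested$el, rate)
    nseq <- render_focal(el$nested$el)$seq
    stopifnot(nchar(nseq) == len)
    substr(el$seq, off + 1, off + len) <- nseq
    return(el)
  }
  el$seq <- mutate_seq(el$seq, rate)
  el
}

mutate_state <- function(state, rate) {
  if (rate <= 0) return(state)
  state$chromosomes <- lapply(state$chromosomes, function(els)
    lapply(els, mutate_element, rate = rate))
  state
}

# ---- event application ----------------------------------------------------

find_copy <- function(state, copy_id) {
  for (chrom in names(state$chromosomes)) {
    els <- state$chromosomes[[chrom]]
    for (i in seq_along(els)) {
      el <- els[[i]]
      if (el$type == "focal" && el$copy_id == copy_id) {
        return(list(chrom = chrom, idx = i, nested = FALSE))
      }
      if (el$type == "gene" && !is.null(el$nested) &&
          el$nested$el$copy_id == copy_id) {
        return(list(chrom = chrom, idx = i, nested = TRUE))
      }
    }
  }
  stop("focal copy not found in genome: ", copy_id)
}

get_copy <- function(state, loc) {
  el <- state$chromosomes[[loc$chrom]][[loc$idx]]
  if (loc$nested) el$nested$el else el
}

set_copy <- function(state, loc, new_el) {
  if (!loc$nested) {
    state$chromosomes[[loc$chrom]][[loc$idx]] <- new_el
    return(state)
  }
  host <- state$chromosomes[[loc$chrom]][[loc$idx]]
  off <- host$nested$offset; old_len <- host$nested$len
  nseq <- render_focal(new_el)$seq
  delta <- nchar(nseq) - old_len
  host$seq <- paste0(substr(host$seq, 1, off), nseq,
                     substr(host$seq, off + old_len + 1, nchar(host$seq)))
  shift <- host$exons[, "start"] >= off + old_len
  host$exons[shift, ] <- host$exons[shift, , drop = FALSE] + delta
  host$nested <- list(offset = off, len = nchar(nseq), el = new_el)
  state$chromosomes[[loc$chrom]][[loc$idx]] <- host
  state
}

strip_introns <- function(el, n) {
  k <- length(el$intron_seqs)
  n <- as.integer(n)
  stopifnot(n >= 0, n <= k)
  if (n == 0) return(el)
  keep <- k - n
  merged <- paste(unlist(el$exon_seqs[(keep + 1):(k + 1)]), collapse = "")
  el$exon_seqs <- c(el$exon_seqs[seq_len(keep)], list(merged))
  el$intron_seqs <- el$intron_seqs[seq_len(keep)]
  el
}

drop_nt <- function(s, pos) {
  paste0(substr(s, 1, pos - 1), substr(s, pos + 1, nchar(s)))
}

decay_element <- function(el, stage) {
  base <- if (el$decay == "none") paste(unlist(el$exon_seqs), collapse = "")
          else el$seq
  frac <- if (stage == "fragment") runif(1, 0.4, 0.6) else runif(1, 0.1, 0.2)
  flen <- max(30, floor(frac * nchar(base)))
  flen <- min(flen, nchar(base))
  s0 <- sample.int(nchar(base) - flen + 1, 1)
  frag <- substr(base, s0, s0 + flen - 1)
  nshift <- if (stage == "fragment") 2 else 1
  for (j in seq_len(nshift)) {
    frag <- drop_nt(frag, max(2, floor(j * nchar(frag) / 3)))
  }
  el$decay <- stage
  el$seq <- frag
  el$has_promoter <- FALSE
  el$exon_seqs <- NULL
  el$intron_seqs <- NULL
  el
}

erase_element <- function(el) {
  len <- if (el$decay == "none") focal_len(el) else nchar(el$seq)
  el$decay <- "erased"
  el$seq <- random_dna(len)
  el$has_promoter <- FALSE
  el$exon_seqs <- NULL
  el$intron_seqs <- NULL
  el
}

# Insert a retrocopy of `source` (3'-most `k` introns excised, promoter iff
# `carry`) either between two intergenic neighbors (after gene `dest_after`
# on `dest_chrom`) or inside intron `dest_intron` of host gene `dest_host`.
apply_translocation <- function(state, ev) {
  loc <- find_copy(state, ev$source)
  src <- get_copy(state, loc)
  stopifnot(src$decay == "none")
  newel <- src
  newel$copy_id <- ev$new_copy
  newel$has_promoter <- isTRUE(ev$carry_promoter)
  newel <- strip_introns(newel, ev$introns_removed)
  if (!is.na(ev$dest_host)) {
    # intragenic insertion
    chrom <- NULL; idx <- NULL
    for (cn in names(state$chromosomes)) {
      els <- state$chromosomes[[cn]]
      hit <- which(vapply(els, function(e)
        e$type == "gene" && e$symbol == ev$dest_host, logical(1)))
      if (length(hit)) { chrom <- cn; idx <- hit[1]; break }
    }
    if (is.null(chrom)) stop("destination host gene not found: ", ev$dest_host)
    host <- state$chromosomes[[chrom]][[idx]]
    K <- nrow(host$exons)
    j <- as.integer(ev$dest_intron)
    stopifnot(j >= 1, j <= K - 1)
    fwd_gap <- if (host$strand == "+") j else K - j
    gap <- c(host$exons[fwd_gap, "end"], host$exons[fwd_gap + 1, "start"])
    point <- floor(mean(gap))
    newel$strand <- if (identical(ev$dest_orientation, "opposite")) {
      if (host$strand == "+") "-" else "+"
    } else host$strand
    nseq <- render_focal(newel)$seq
    host$seq <- paste0(substr(host$seq, 1, point), nseq,
                       substr(host$seq, point + 1, nchar(host$seq)))
    shift <- host$exons[, "start"] >= point
    host$exons[shift, ] <- host$exons[shift, , drop = FALSE] + nchar(nseq)
    host$nested <- list(offset = point, len = nchar(nseq), el = newel)
    state$chromosomes[[chrom]][[idx]] <- host
  } else {
    els <- state$chromosomes[[ev$dest_chrom]]
    if (is.null(els)) stop("destination chromosome not found: ", ev$dest_chrom)
    idx <- which(vapply(els, function(e)
      e$type == "gene" && identical(e$symbol, ev$dest_after), logical(1)))
    if (!length(idx)) stop("destination anchor gene not found: ", ev$dest_after)
    newel$strand <- if (!is.na(ev$dest_strand)) ev$dest_strand else "+"
    ins <- list(el_spacer(120), newel, el_spacer(120))
    state$chromosomes[[ev$dest_chrom]] <-
      append(els, ins, after = idx[1])
  }
  state
}

# ---- state construction and rendering -------------------------------------

build_ancestral_state <- function(gene, params) {
  nb <- params$n_neighbors
  sp <- function() el_spacer(params$spacer_len)
  chr1 <- list(sp())
  strands <- c("+", "-")
  for (i in rev(seq_len(nb))) {
    chr1 <- c(chr1, list(el_gene(paste0("nL", i), strands[1 + i %% 2],
                                 params$neighbor_len), sp()))
  }
  chr1 <- c(chr1, list(el_focal("copy0", "+", gene), sp()))
  for (i in seq_len(nb)) {
    chr1 <- c(chr1, list(el_gene(paste0("nR", i), strands[1 + (i + 1) %% 2],
                                 params$neighbor_len), sp()))
  }
  # destination chromosomes with disjoint anchor sets, so distinct planted
  # destinations never share flanking symbols and cannot collapse into one
  # syntenic slot
  dest_chrom <- function(prefix) {
    els <- list(sp())
    for (i in seq_len(4)) {
      els <- c(els, list(el_gene(paste0(prefix, i), strands[1 + i %% 2],
                                 params$neighbor_len), sp()))
    }
    els
  }
  list(chromosomes = list(chr1 = chr1, chr2 = dest_chrom("d"),
                          chr3 = dest_chrom("e"), chr4 = dest_chrom("f")))
}

render_state <- function(state, species_id) {
  chroms <- character(0)
  genes <- list()
  truth <- list()
  for (chrom in names(state$chromosomes)) {
    off <- 0
    pieces <- character(0)
    for (el in state$chromosomes[[chrom]]) {
      if (el$type == "spacer") {
        pieces <- c(pieces, el$seq)
        off <- off + nchar(el$seq)
      } else if (el$type == "gene") {
        genes[[length(genes) + 1]] <- tibble(
          gene_id = paste0(chrom, ":", el$symbol), symbol = el$symbol,
          chromosome = chrom, strand = el$strand,
          exons = list(el$exons + off), focal = FALSE)
        if (!is.null(el$nested)) {
          ne <- el$nested$el
          n_off <- off + el$nested$offset
          if (ne$decay == "none") {
            r <- render_focal(ne)
            genes[[length(genes) + 1]] <- tibble(
              gene_id = paste0(chrom, ":", ne$copy_id), symbol = ne$copy_id,
              chromosome = chrom, strand = ne$strand,
              exons = list(r$exons + n_off), focal = TRUE)
          }
          truth[[length(truth) + 1]] <- tibble(
            species_id = species_id, copy_id = ne$copy_id,
            chromosome = chrom, start = n_off, end = n_off + el$nested$len,
            strand = ne$strand, decay = ne$decay,
            n_introns = if (ne$decay == "none") length(ne$intron_seqs)
                        else NA_integer_,
            has_promoter = isTRUE(ne$has_promoter), host = el$symbol)
        }
        pieces <- c(pieces, el$seq)
        off <- off + nchar(el$seq)
      } else {  # focal
        r <- render_focal(el)
        if (el$decay == "none") {
          genes[[length(genes) + 1]] <- tibble(
            gene_id = paste0(chrom, ":", el$copy_id), symbol = el$copy_id,
            chromosome = chrom, strand = el$strand,
            exons = list(r$exons + off), focal = TRUE)
        }
        truth[[length(truth) + 1]] <- tibble(
          species_id = species_id, copy_id = el$copy_id,
          chromosome = chrom, start = off, end = off + nchar(r$seq),
          strand = el$strand, decay = el$decay,
          n_introns = if (el$decay == "none") length(el$intron_seqs)
                      else NA_integer_,
          has_promoter = isTRUE(el$has_promoter), host = NA_character_)
        pieces <- c(pieces, r$seq)
        off <- off + nchar(r$seq)
      }
    }
    chroms[chrom] <- paste(pieces, collapse = "")
  }
  list(genome = annotated_genome(species_id, chroms, dplyr::bind_rows(genes)),
       truth = dplyr::bind_rows(truth))
}

# ---- the simulator --------------------------------------------------------

EVENT_COLS <- c("branch", "kind", "n", "introns_removed", "source",
                "new_copy", "target", "dest_chrom", "dest_after",
                "dest_host", "dest_intron", "dest_orientation",
                "dest_strand", "carry_promoter", "stage")

normalize_events <- function(events) {
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble(branch = character(0), kind = character(0))
  }
  events <- as_tibble(events)
  for (cn in EVENT_COLS) {
    if (!cn %in% names(events)) {
      events[[cn]] <- if (cn == "carry_promoter") NA else NA
    }
  }
  bad <- setdiff(events$kind, c("intron_loss", "translocation_gain",
                                "pseudogenization", "copy_loss"))
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  events
}

#' Simulate a clade with planted retrocopy events
#'
#' Evolves the ancestral genome along `tree` (preorder), applying uniform
#' substitutions on every branch and the planted events assigned to each
#' branch.  Event kinds: `intron_loss` (in-place excision of the 3'-most `n`
#' introns of copy `target`), `translocation_gain` (retrocopy of `source`
#' with `introns_removed` introns excised, inserted after anchor gene
#' `dest_after` on `dest_chrom` -- or inside intron `dest_intron` of host
#' gene `dest_host` with `dest_orientation` -- carrying the promoter iff
#' `carry_promoter`; the copy is named `new_copy`), `pseudogenization`
#' (decay of `target` to `stage` `"fragment"` or `"short"`), and `copy_loss`
#' (erasure of `target`).  A `translocation_gain` with `introns_removed > 0`
#' is logged as an `intron_loss` plus a `translocation_gain` on the same
#' branch, which is the retrocopy signature the inference side looks for.
#'
#' @param tree Rooted `phylo` species tree with >= 2 leaves.
#' @param params A [sim_params()] object.
#' @param events Planted-event tibble (columns as above; `branch` uses the
#'   ids of [branch_ids()]).  Defaults to `params$events`.
#' @param layout Optional replacement for the default ancestral genome
#'   builder: a `function(gene, params)` returning the element state.
#' @return List with `genomes` (named list of [annotated_genome()]),
#'   `event_log` (ground truth, root-to-tip order), `truth` (per-species
#'   focal-copy table), `family` (seed exons/cds/promoter/protein of the
#'   ancestral gene), `tree` and `params`.
#' @export
simulate_clade <- function(tree, params = sim_params(), events = NULL,
                           layout = NULL) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 2)
  if (is.null(events)) events <- params$events
  events <- normalize_events(events)
  valid <- branch_ids(tree)$branch_id
  bad <- setdiff(events$branch, valid)
  if (length(bad)) {
    stop("event references branch(es) absent from tree: ",
         paste(bad, collapse = ", "))
  }
  set.seed(params$seed)
  gene <- .make_gene()
  builder <- if (is.null(layout)) build_ancestral_state else layout
  state0 <- builder(gene, params)

  env <- new.env()
  env$genomes <- list()
  env$truth <- list()
  env$log <- list()

  apply_branch <- function(state, bid) {
    state <- mutate_state(state, params$rate)
    ev <- events[events$branch == bid, , drop = FALSE]
    if (nrow(ev)) {
      prio <- c(intron_loss = 1, translocation_gain = 2,
                pseudogenization = 3, copy_loss = 4)
      ev <- ev[order(prio[ev$kind]), , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        e <- ev[i, ]
        if (e$kind == "intron_loss") {
          loc <- find_copy(state, e$target)
          el <- strip_introns(get_copy(state, loc), e$n)
          state <- set_copy(state, loc, el)
          env$log[[length(env$log) + 1]] <- tibble(
            branch = bid, kind = "intron_loss", magnitude = as.integer(e$n),
            copy_id = e$target, carry_promoter = NA)
        } else if (e$kind == "translocation_gain") {
          if (!is.na(e$introns_removed) && e$introns_removed > 0) {
            env$log[[length(env$log) + 1]] <- tibble(
              branch = bid, kind = "intron_loss",
              magnitude = as.integer(e$introns_removed),
              copy_id = e$new_copy, carry_promoter = NA)
          }
          state <- apply_translocation(state, e)
          env$log[[length(env$log) + 1]] <- tibble(
            branch = bid, kind = "translocation_gain", magnitude = NA_integer_,
            copy_id = e$new_copy, carry_promoter = isTRUE(e$carry_promoter))
        } else if (e$kind == "pseudogenization") {
          loc <- find_copy(state, e$target)
          el <- decay_element(get_copy(state, loc), e$stage)
          state <- set_copy(state, loc, el)
          env$log[[length(env$log) + 1]] <- tibble(
            branch = bid, kind = "pseudogenization", magnitude = NA_integer_,
            copy_id = e$target, carry_promoter = NA)
        } else if (e$kind == "copy_loss") {
          loc <- find_copy(state, e$target)
          el <- erase_element(get_copy(state, loc))
          state <- set_copy(state, loc, el)
          env$log[[length(env$log) + 1]] <- tibble(
            branch = bid, kind = "copy_loss", magnitude = NA_integer_,
            copy_id = e$target, carry_promoter = NA)
        }
      }
    }
    state
  }

  walk <- function(node, state) {
    for (child in tree_children(tree, node)) {
      bid <- clade_id(tree, child)
      st <- apply_branch(state, bid)
      if (child <= ape::Ntip(tree)) {
        r <- render_state(st, tree$tip.label[child])
        env$genomes[[tree$tip.label[child]]] <- r$genome
        env$truth[[length(env$truth) + 1]] <- r$truth
      } else {
        walk(child, st)
      }
    }
  }
  walk(tree_root(tree), state0)

  log <- if (length(env$log)) dplyr::bind_rows(env$log) else
    tibble(branch = character(0), kind = character(0),
           magnitude = integer(0), copy_id = character(0),
           carry_promoter = logical(0))
  structure(list(
    genomes = env$genomes[tree$tip.label],
    event_log = log,
    truth = dplyr::bind_rows(env$truth),
    family = list(exons = unlist(gene$exon_seqs), cds = gene$cds,
                  promoter = gene$promoter, protein = gene$protein),
    tree = tree, params = params), class = "clade_sim")
}

#' @export
print.clade_sim <- function(x, ...) {
  cat("<clade_sim> ", length(x$genomes), " genomes, ",
      nrow(x$event_log), " planted event record(s)\n", sep = "")
  invisible(x)
}

#' Write a simulated clade to disk
#'
#' One FASTA + GFF3 pair per species, the tree as Newick and the
#' ground-truth event log as TSV.
#'
#' @param sim A [simulate_clade()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_clade <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]
    write_fasta(g$chromosomes, file.path(dir, paste0(sp, ".fa")))
    write_gff3(g, file.path(dir, paste0(sp, ".gff3")))
  }
  ape::write.tree(sim$tree, file.path(dir, "species_tree.nwk"))
  utils::write.table(sim$event_log, file.path(dir, "event_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(c(setNames(sim$family$exons,
                         paste0("exon", seq_along(sim$family$exons))),
                promoter = sim$family$promoter),
              file.path(dir, "family_seed.fa"))
  invisible(dir)
}
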