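# In-silico cloning: determine exon-intron structure by splice-aware mapping
# of a CDS onto genomic sequence under the GT-AG rule, scan protein
# diagnostics of the focal protease family, and grade locus occupants from
# full gene down to erased vestige.

#' Construct a gene model
#'
#' @param gene_id Identifier.
#' @param chromosome Chromosome name (or `NA` for region-relative models).
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (`start`, `end`) of 0-based half-open
#'   genomic exon intervals, sorted by start.
#' @param cds Spliced coding sequence (gene sense).
#' @param host_insertion Optional list `(host_symbol, intron_ordinal,
#'   orientation)` for copies inserted inside another gene's intron.
#' @param mismatches Mismatch count against the seed used for inference.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds,
                       host_insertion = NULL, mismatches = 0L) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 exons = exons, cds = toupper(cds),
                 intron_count = nrow(exons) - 1L,
                 host_insertion = host_insertion,
                 mismatches = as.integer(mismatches)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, ": ", nrow(x$exons), " exon(s), ",
      x$intron_count, " intron(s), strand ", x$strand, "\n", sep = "")
  invisible(x)
}

#' @rdname gene_model
#' @param x A `gene_model`.
#' @param ... Unused.
#' @export
tidy.gene_model <- function(x, ...) {
  tibble(gene_id = x$gene_id, chromosome = x$chromosome, strand = x$strand,
         exon = seq_len(nrow(x$exons)),
         start = x$exons[, "start"], end = x$exons[, "end"])
}

#' Infer exon-intron structure under the GT-AG rule
#'
#' Aligns a coding sequence onto a genomic region as a chain of ungapped
#' exon segments separated by GT..AG introns of length at least `min_intron`.
#' The chain with the fewest introns (then fewest mismatches) is returned;
#' ties are broken by the leftmost donor.  If the best GT-AG chain leaves
#' more than `max_mismatch_rate` of CDS positions unmatched the function
#' raises `"unmappable"` -- or `"splice violation"` when dropping the GT-AG
#' requirement would rescue the chain.
#'
#' @param cds Coding sequence (gene sense), length >= 30.
#' @param genomic_region Genomic sequence containing the gene (plus strand).
#' @param strand Strand of the gene on `genomic_region`.
#' @param min_intron Minimum intron length (nt).
#' @param max_mismatch_rate Tolerated fraction of mismatched CDS positions.
#' @param gene_id Identifier for the resulting model.
#' @return A [gene_model()] with exon coordinates on the plus strand of
#'   `genomic_region` and `cds` equal to the spliced genomic sequence.
#' @export
infer_gene_structure <- function(cds, genomic_region, strand = "+",
                                 min_intron = 40, max_mismatch_rate = 0.05,
                                 gene_id = "inferred") {
  cds <- toupper(cds); genomic_region <- toupper(genomic_region)
  if (nchar(cds) < 30) stop("CDS shorter than 30 nt")
  m <- nchar(genomic_region)
  sense <- if (strand == "-") revcomp(genomic_region) else genomic_region
  res <- .splice_chain_cpp(cds, sense, as.integer(min_intron), TRUE)
  budget <- max_mismatch_rate * nchar(cds)
  if (!isTRUE(res$ok) || res$mismatches > budget) {
    relaxed <- .splice_chain_cpp(cds, sense, as.integer(min_intron), FALSE)
    if (isTRUE(relaxed$ok) && relaxed$mismatches <= budget &&
        relaxed$introns > 0) {
      stop("splice violation: best chain requires a non-GT-AG gap")
    }
    stop("unmappable: no GT-AG chain covering the CDS within the mismatch tolerance")
  }
  ex <- cbind(start = res$exon_start, end = res$exon_end)
  if (strand == "-") {
    ex <- cbind(start = m - ex[, "end"], end = m - ex[, "start"])
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  }
  spliced <- splice_exons(genomic_region, ex, strand)
  gene_model(gene_id, NA_character_, strand, ex, spliced,
             mismatches = res$mismatches)
}

#' Splice exon intervals out of a chromosome sequence
#'
#' Concatenates the exon slices of a plus-strand sequence and
#' reverse-complements the result for minus-strand genes, yielding the
#' gene-sense spliced sequence.
#'
#' @param chrom_seq Chromosome (plus-strand) sequence.
#' @param exons Two-column matrix (`start`, `end`), 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @return The spliced sequence.
#' @export
splice_exons <- function(chrom_seq, exons, strand) {
  parts <- vapply(seq_len(nrow(exons)), function(i)
    substr(chrom_seq, exons[i, "start"] + 1, exons[i, "end"]), character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Scan protease diagnostics in a protein
#'
#' Counts non-overlapping occurrences of the two active-site consensus
#' motifs of the hatching-enzyme (astacin) family, `HExxHxxGFxHExxRxDR` and
#' `SxMHY` (`x` = any residue), plus the total number of cysteines.
#'
#' @param protein Amino-acid string (20-letter alphabet; may be empty).
#' @return List with `active_site_hits` (count), `positions` (tibble of
#'   motif, 1-based position) and `cysteine_count`.
#' @export
scan_protein_diagnostics <- function(protein) {
  protein <- toupper(protein)
  if (nchar(protein) > 0 &&
      grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "]"), protein)) {
    stop("illegal residue in protein")
  }
  motifs <- c(active_site = "HEXXHXXGFXHEXXRXDR", smhy = "SXMHY")
  pos <- lapply(motifs, function(p) {
    hits <- match_iupac(p, protein, type = "protein")
    # greedy non-overlapping selection
    keep <- integer(0); last_end <- 0
    for (h in hits) {
      if (h > last_end) { keep <- c(keep, h); last_end <- h + nchar(p) - 1 }
    }
    keep
  })
  positions <- dplyr::bind_rows(lapply(names(pos), function(nm)
    if (length(pos[[nm]])) tibble(motif = nm, position = pos[[nm]])))
  if (is.null(positions) || nrow(positions) == 0) {
    positions <- tibble(motif = character(0), position = integer(0))
  }
  list(active_site_hits = sum(lengths(pos)),
       positions = positions,
       cysteine_count = lengths(regmatches(protein,
                                           gregexpr("C", protein)))[[1]])
}

vestige_sub_matrix <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-3, 5, 5, dimnames = list(b, b))
  diag(m) <- 2
  m["N", ] <- -6; m[, "N"] <- -6
  m
}

local_align <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = vestige_sub_matrix(),
    gapOpening = 5, gapExtension = 2)
}

#' Grade a locus occupant against a reference CDS
#'
#' Local alignment of the reference coding sequence against the locus
#' sequence yields a coverage (fraction of reference positions matched) and
#' a disruption count (frameshifting indels plus premature in-frame stops).
#' These are thresholded into the four vestige grades: `full` (coverage >=
#' 0.9, no disruption), `fragment` (0.2-0.9, or full coverage with
#' disruptions), `short_fragment` (0.05-0.2) and `absent` (< 0.05).
#'
#' An intact copy that still carries GT..AG introns is recognized by a
#' splice-aware pass first, so introns are never miscounted as
#' frameshifts.
#'
#' @param locus_sequence Genomic sequence at the locus (either strand; both
#'   are tried).
#' @param reference_cds Reference coding sequence.
#' @param min_intron,max_mismatch_rate Passed to the splice-aware pass.
#' @return List with `state`, `coverage`, `disruption`, `strand`.
#' @export
classify_vestige <- function(locus_sequence, reference_cds, min_intron = 40,
                             max_mismatch_rate = 0.05) {
  stopifnot(nchar(reference_cds) > 0)
  locus_sequence <- toupper(locus_sequence)
  reference_cds <- toupper(reference_cds)
  if (nchar(reference_cds) >= 30 &&
      nchar(locus_sequence) >= nchar(reference_cds)) {
    for (strand in c("+", "-")) {
      m <- tryCatch(
        infer_gene_structure(reference_cds, locus_sequence, strand,
                             min_intron = min_intron,
                             max_mismatch_rate = max_mismatch_rate),
        error = function(e) NULL)
      if (!is.null(m)) {
        return(list(state = "full",
                    coverage = 1 - m$mismatches / nchar(reference_cds),
                    disruption = 0L, strand = strand))
      }
    }
  }
  best <- NULL
  for (strand in c("+", "-")) {
    subj <- if (strand == "-") revcomp(locus_sequence) else locus_sequence
    aln <- local_align(reference_cds, subj)
    if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best$aln)) {
      best <- list(aln = aln, strand = strand)
    }
  }
  aln <- best$aln
  cov <- Biostrings::nmatch(aln) / nchar(reference_cds)
  disruption <- count_disruptions(aln)
  state <- if (cov >= 0.9 && disruption == 0) "full"
           else if (cov >= 0.2) "fragment"
           else if (cov >= 0.05) "short_fragment"
           else "absent"
  list(state = state, coverage = cov, disruption = disruption,
       strand = best$strand)
}

# Frameshifting indels (gap runs with length not divisible by 3) plus
# premature stop codons read in the reference frame.
count_disruptions <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gaps <- 0
  r <- rle(ifelse(p == "-", "ins", ifelse(s == "-", "del", "m")))
  gaps <- sum(r$lengths[r$values != "m"] %% 3 != 0)
  # premature stops: assemble subject bases at reference codon slots
  ref_pos <- Biostrings::start(Biostrings::pattern(aln)) - 1  # 0-based
  ref_len <- nchar(as.character(Biostrings::unaligned(Biostrings::pattern(aln))))
  codon_chars <- list()
  rp <- ref_pos
  for (i in seq_along(p)) {
    if (p[i] != "-") {
      if (s[i] != "-") {
        ci <- rp %/% 3
        codon_chars[[as.character(ci)]] <-
          c(codon_chars[[as.character(ci)]], s[i])
      }
      rp <- rp + 1
    }
  }
  n_codons <- ref_len %/% 3
  stops <- 0
  for (nm in names(codon_chars)) {
    ci <- as.integer(nm)
    if (ci >= n_codons - 1) next  # terminal codon may legitimately be a stop
    cc <- codon_chars[[nm]]
    if (length(cc) == 3 && paste(cc, collapse = "") %in% c("TAA", "TAG", "TGA"))
      stops <- stops + 1
  }
  gaps + stops
}

#' Locate and clone all copies of a gene family in a genome
#'
#' Scans every chromosome (both strands) for loci matching the seed exons'
#' concatenated coding sequence, assembles a [gene_model()] where a GT-AG
#' splice chain covers the CDS, and otherwise grades the locus as a vestige
#' with [classify_vestige()].  Loci below 5% reference coverage are not
#' reported (absence is the default state).
#'
#' @param seed_exons Character vector of exon sequences (gene sense) of a
#'   related species' gene, 5' to 3'.
#' @param genome An [annotated_genome()].
#' @param min_intron,max_mismatch_rate Passed to [infer_gene_structure()].
#' @param min_coverage Minimum reference coverage for a locus to be reported.
#' @param max_hits_per_chrom Search depth per chromosome.
#' @return Tibble of loci: `species_id`, `chromosome`, `start`, `end`,
#'   `strand`, `state`, `coverage`, `disruption`, `intron_count`, `model`
#'   (list column of [gene_model()] or `NULL`).
#' @export
cross_species_clone <- function(seed_exons, genome, min_intron = 40,
                                max_mismatch_rate = 0.05, min_coverage = 0.05,
                                max_hits_per_chrom = 8) {
  stopifnot(length(seed_exons) >= 1)
  cds <- toupper(paste(seed_exons, collapse = ""))
  pad <- nchar(cds) + 8 * 200 + 200
  out <- list()
  for (chrom in names(genome$chromosomes)) {
    cur <- genome$chromosomes[[chrom]]
    L <- nchar(cur)
    orig <- cur
    for (round in seq_len(max_hits_per_chrom)) {
      aln_p <- local_align(cds, cur)
      aln_m <- local_align(cds, revcomp(cur))
      use_minus <- Biostrings::score(aln_m) > Biostrings::score(aln_p)
      aln <- if (use_minus) aln_m else aln_p
      if (Biostrings::nmatch(aln) < min_coverage * nchar(cds)) break
      s1 <- Biostrings::start(Biostrings::subject(aln))
      e1 <- Biostrings::end(Biostrings::subject(aln))
      if (use_minus) {                # map to plus-strand 0-based interval
        hit <- c(L - e1, L - s1 + 1)
      } else {
        hit <- c(s1 - 1, e1)
      }
      w0 <- max(0, hit[1] - pad); w1 <- min(L, hit[2] + pad)
      win_plus <- substr(orig, w0 + 1, w1)
      sense_win <- if (use_minus) revcomp(win_plus) else win_plus
      strand <- if (use_minus) "-" else "+"
      model <- tryCatch(
        infer_gene_structure(cds, win_plus, strand = strand,
                             min_intron = min_intron,
                             max_mismatch_rate = max_mismatch_rate),
        error = function(e) NULL)
      if (!is.null(model)) {
        ex <- model$exons
        ex[, "start"] <- ex[, "start"] + w0
        ex[, "end"] <- ex[, "end"] + w0
        model$exons <- ex
        model$chromosome <- chrom
        model$gene_id <- sprintf("%s.%s.%d", genome$species_id, chrom,
                                 length(out) + 1)
        span <- gene_span(ex)
        out[[length(out) + 1]] <- tibble(
          species_id = genome$species_id, chromosome = chrom,
          start = span[1], end = span[2], strand = strand, state = "full",
          coverage = 1 - model$mismatches / nchar(cds),
          disruption = 0L, intron_count = model$intron_count,
          model = list(model))
        mask <- c(max(0, span[1] - 100), min(L, span[2] + 100))
      } else {
        vest <- classify_vestige(win_plus, cds)
        if (vest$coverage >= min_coverage && vest$state != "full") {
          out[[length(out) + 1]] <- tibble(
            species_id = genome$species_id, chromosome = chrom,
            start = hit[1], end = hit[2], strand = vest$strand,
            state = vest$state, coverage = vest$coverage,
            disruption = vest$disruption, intron_count = NA_integer_,
            model = list(NULL))
        }
        mask <- c(max(0, hit[1] - 100), min(L, hit[2] + 100))
      }
      substr(cur, mask[1] + 1, mask[2]) <-
        strrep("N", mask[2] - mask[1])
    }
  }
  if (length(out) == 0) {
    return(tibble(species_id = character(0), chromosome = character(0),
                  start = numeric(0), end = numeric(0), strand = character(0),
                  state = character(0), coverage = numeric(0),
                  disruption = integer(0), intron_count = integer(0),
                  model = list()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chromosome, .data$start)
}
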