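# Promoter carry-over analysis: upstream windows, TATA box location,
# klf3/17 (CWCCC) and foxa3 (TGTTTRCWYW) motif scanning, conserved-block
# detection across species, carry-over classification and a neighbor-joining
# tree of the regions upstream of the TATA box.
#
# Offsets are negative coordinates relative to the transcription start site
# (modeled as the first base of exon 1): the base immediately 5' of the TSS
# has offset -1.

KLF_PATTERN <- "CWCCC"          # CACCC or CTCCC
FOXA3_PATTERN <- "TGTTTRCWYW"   # TGTTT(A/G)C(T/A)(T/C)(A/T)
TATA_PATTERN <- "TATAWAW"

#' Extract the upstream window of a gene
#'
#' The `window` bases immediately 5' of the TSS in the gene's sense,
#' truncated (and flagged via the `"truncated"` attribute) at chromosome
#' ends.
#'
#' @param genome An [annotated_genome()].
#' @param gene A [gene_model()] with absolute coordinates.
#' @param window Window size in bp (> 0).
#' @return Upstream sequence (gene sense), with attribute `truncated`.
#' @export
extract_upstream <- function(genome, gene, window = 200) {
  if (window <= 0) stop("window must be positive")
  chrom <- genome$chromosomes[[gene$chromosome]]
  if (is.null(chrom)) stop("unknown chromosome: ", gene$chromosome)
  L <- nchar(chrom)
  if (gene$strand == "+") {
    tss <- min(gene$exons[, "start"])
    s0 <- max(0, tss - window)
    seq <- substr(chrom, s0 + 1, tss)
    truncated <- tss - window < 0
  } else {
    tss <- max(gene$exons[, "end"])
    e1 <- min(L, tss + window)
    seq <- revcomp(substr(chrom, tss + 1, e1))
    truncated <- tss + window > L
  }
  attr(seq, "truncated") <- truncated
  seq
}

# 1-based string position -> TSS-relative offset
pos_to_offset <- function(pos, len) as.integer(pos - len - 1L)

#' Locate the TATA box in an upstream window
#'
#' Scans for `TATAWAW` and returns the offset of the 3'-most match whose
#' start falls inside the search window.
#'
#' @param upstream_seq Upstream sequence ending at the TSS.
#' @param search_window Offsets (inclusive) within which the match must
#'   start; default -50..-20.
#' @return Integer offset, or `NA` if absent.
#' @export
find_tata <- function(upstream_seq, search_window = c(-50, -20)) {
  L <- nchar(upstream_seq)
  hits <- match_iupac(TATA_PATTERN, upstream_seq)
  off <- pos_to_offset(hits, L)
  off <- off[off >= search_window[1] & off <= search_window[2]]
  if (length(off) == 0) NA_integer_ else max(off)
}

#' Scan transcription-factor binding motifs
#'
#' All sense-strand matches of the klf3/17 site (`CWCCC`) and the foxa3
#' site (`TGTTTRCWYW`).
#'
#' @param upstream_seq Upstream sequence ending at the TSS.
#' @return Tibble with `site` (`"klf"`/`"foxa3"`), `offset`, `match`.
#' @export
scan_tf_sites <- function(upstream_seq) {
  L <- nchar(upstream_seq)
  one <- function(site, pattern) {
    hits <- match_iupac(pattern, upstream_seq)
    if (length(hits) == 0) return(NULL)
    tibble(site = site, offset = pos_to_offset(hits, L),
           match = vapply(hits, function(i)
             substr(upstream_seq, i, i + nchar(pattern) - 1), character(1)))
  }
  out <- dplyr::bind_rows(one("klf", KLF_PATTERN),
                          one("foxa3", FOXA3_PATTERN))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(site = character(0), offset = integer(0),
                  match = character(0))
  }
  out
}

#' Longest conserved block across upstream windows
#'
#' Finds the longest window (aligned at the TSS end) whose pairwise
#' identity is at least `min_identity` for every sequence pair.  Sequences
#' are truncated to the shortest at the 5' end; the simulator introduces no
#' promoter indels, so columns are directly comparable.
#'
#' @param upstream_seqs List/vector of >= 2 upstream sequences.
#' @param min_identity Minimum pairwise identity inside the block.
#' @param min_length Minimum block length (bp).
#' @return List `(start_offset, end_offset)` (half-open, TSS-relative), or
#'   `NULL` when no block qualifies.
#' @export
conserved_block <- function(upstream_seqs, min_identity = 0.7,
                            min_length = 100) {
  seqs <- toupper(unlist(upstream_seqs))
  stopifnot(length(seqs) >= 2)
  L <- min(nchar(seqs))
  if (L < min_length) return(NULL)
  seqs <- substr(seqs, nchar(seqs) - L + 1, nchar(seqs))  # keep TSS end
  mats <- t(vapply(seqs, function(s) strsplit(s, "")[[1]], character(L)))
  pairs <- utils::combn(length(seqs), 2)
  match_cum <- vapply(seq_len(ncol(pairs)), function(p) {
    eq <- mats[pairs[1, p], ] == mats[pairs[2, p], ]
    cumsum(eq)
  }, numeric(L))
  match_cum <- rbind(0, match_cum)  # (L+1) x npairs
  for (len in seq(L, min_length)) {
    starts <- seq_len(L - len + 1)
    counts <- match_cum[starts + len, , drop = FALSE] -
      match_cum[starts, , drop = FALSE]
    ok <- rowSums(counts >= min_identity * len) == ncol(pairs)
    if (any(ok)) {
      s <- starts[which(ok)[1]]
      return(list(start_offset = pos_to_offset(s, L),
                  end_offset = pos_to_offset(s + len, L)))
    }
  }
  NULL
}

#' Promoter report for one locus
#'
#' @param upstream_seq Upstream window (gene sense, ending at the TSS).
#' @param species_id,slot Labels carried through to the report.
#' @return A `promoter_report` list: `upstream_seq`, `tata_offset`, `hits`
#'   (motif tibble), `species_id`, `slot`.
#' @export
promoter_report <- function(upstream_seq, species_id = NA_character_,
                            slot = NA_character_) {
  structure(list(species_id = species_id, slot = slot,
                 upstream_seq = as.character(upstream_seq),
                 tata_offset = find_tata(upstream_seq),
                 hits = scan_tf_sites(upstream_seq),
                 truncated = isTRUE(attr(upstream_seq, "truncated"))),
            class = "promoter_report")
}

#' @export
print.promoter_report <- function(x, ...) {
  cat("<promoter_report> ", x$species_id, "/", x$slot,
      ": TATA at ", x$tata_offset, ", ", nrow(x$hits), " motif hit(s)\n",
      sep = "")
  invisible(x)
}

#' @rdname promoter_report
#' @param object A `promoter_report`.
#' @param ... Unused.
#' @export
autoplot.promoter_report <- function(object, ...) {
  feats <- object$hits |>
    dplyr::transmute(feature = .data$site, start = .data$offset,
                     end = .data$offset + nchar(.data$match))
  if (!is.na(object$tata_offset)) {
    feats <- dplyr::bind_rows(feats, tibble(
      feature = "TATA", start = object$tata_offset,
      end = object$tata_offset + nchar(TATA_PATTERN)))
  }
  ggplot2::ggplot(feats) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$feature,
                                       yend = .data$feature),
                          linewidth = 4) +
    ggplot2::xlim(-nchar(object$upstream_seq), 0) +
    ggplot2::labs(x = "offset from TSS (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Classify promoter carry-over at a daughter locus
#'
#' A translocated copy carried its promoter when its upstream window shares
#' a conserved block with the reference (parent-slot or cross-species)
#' promoter and that block contains a TATA box plus at least one klf and
#' one foxa3 site inside the indispensable `-192..-91` subregion.
#'
#' @param parent_report Reference [promoter_report()].
#' @param daughter_report Daughter-locus [promoter_report()].
#' @param region Indispensable subregion (offsets, half-open upper bound).
#' @param min_identity,min_length Passed to [conserved_block()].
#' @return List `carryover` (logical) and `evidence` (tibble of checks).
#' @export
classify_carryover <- function(parent_report, daughter_report,
                               region = c(-192, -91), min_identity = 0.7,
                               min_length = 100) {
  block <- conserved_block(list(parent_report$upstream_seq,
                                daughter_report$upstream_seq),
                           min_identity = min_identity,
                           min_length = min_length)
  in_region <- function(off) off >= region[1] & off < region[2]
  in_block <- function(off) {
    if (is.null(block)) return(FALSE)
    off >= block$start_offset && off < block$end_offset
  }
  hits <- daughter_report$hits
  klf <- hits$offset[hits$site == "klf"]
  fox <- hits$offset[hits$site == "foxa3"]
  klf_ok <- any(in_region(klf) & vapply(klf, in_block, logical(1)))
  fox_ok <- any(in_region(fox) & vapply(fox, in_block, logical(1)))
  tata_ok <- !is.na(daughter_report$tata_offset) &&
    in_block(daughter_report$tata_offset)
  evidence <- tibble(
    check = c("conserved_block", "tata_in_block", "klf_in_region",
              "foxa3_in_region"),
    ok = c(!is.null(block), tata_ok, isTRUE(klf_ok), isTRUE(fox_ok)),
    detail = c(
      if (is.null(block)) "no conserved block vs reference"
      else sprintf("block %d..%d", block$start_offset, block$end_offset),
      if (tata_ok) sprintf("TATA at %d", daughter_report$tata_offset)
      else "TATA missing or outside block",
      if (isTRUE(klf_ok)) paste("klf at",
                                paste(klf[in_region(klf)], collapse = ","))
      else "missing klf site",
      if (isTRUE(fox_ok)) paste("foxa3 at",
                                paste(fox[in_region(fox)], collapse = ","))
      else "missing foxa3 site"))
  list(carryover = !is.null(block) && tata_ok && isTRUE(klf_ok) &&
         isTRUE(fox_ok),
       evidence = evidence)
}

#' Neighbor-joining tree of upstream regions
#'
#' Extracts the 100 bp immediately 5' of each TATA box, computes
#' Jukes-Cantor distances and builds a neighbor-joining tree.  Sequences
#' without a TATA box are excluded with a warning; at least three usable
#' sequences are required.
#'
#' @param upstream_seqs Named list/vector of upstream windows.
#' @param tata_offsets Named integer offsets from [find_tata()] (computed
#'   when missing).
#' @param region_len Region length 5' of the TATA box (bp).
#' @return A `phylo` tree with attributes `method` and `distances`.
#' @export
upstream_tree <- function(upstream_seqs, tata_offsets = NULL,
                          region_len = 100) {
  seqs <- unlist(upstream_seqs)
  if (is.null(names(seqs))) stop("upstream sequences must be named")
  if (is.null(tata_offsets)) {
    tata_offsets <- vapply(seqs, find_tata, integer(1))
  }
  tata_offsets <- tata_offsets[names(seqs)]
  usable <- !is.na(tata_offsets)
  if (any(!usable)) {
    warning("excluding sequence(s) without a TATA box: ",
            paste(names(seqs)[!usable], collapse = ", "))
  }
  seqs <- seqs[usable]; tata_offsets <- tata_offsets[usable]
  if (length(seqs) < 3) stop("need at least 3 sequences with a TATA box")
  regions <- vapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[i])
    it <- L + 1L + tata_offsets[i]           # string index of TATA start
    substr(seqs[i], max(1, it - region_len), it - 1)
  }, character(1))
  names(regions) <- names(seqs)
  w <- max(nchar(regions))
  regions <- vapply(regions, function(s)
    paste0(strrep("N", w - nchar(s)), s), character(1))
  mat <- do.call(rbind, strsplit(tolower(regions), ""))
  rownames(mat) <- names(regions)
  d <- ape::dist.dna(ape::as.DNAbin(mat), model = "JC69",
                     pairwise.deletion = TRUE)
  tr <- if (length(regions) == 3) {
    dm <- as.matrix(d)
    nm <- rownames(dm)
    v <- c((dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2,
           (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2,
           (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2)
    ape::read.tree(text = sprintf("(%s:%f,%s:%f,%s:%f);",
                                  nm[1], max(v[1], 0), nm[2], max(v[2], 0),
                                  nm[3], max(v[3], 0)))
  } else {
    ape::nj(d)
  }
  attr(tr, "method") <- "NJ + JC69"
  attr(tr, "distances") <- d
  tr
}
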