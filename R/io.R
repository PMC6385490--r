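# Readers/writers for FASTA, GFF3 and Newick, the annotated-genome container
# and stable branch identifiers on rooted species trees.
#
# Conventions: genomic coordinates are 0-based half-open internally; GFF3 I/O
# converts to/from the format's 1-based closed convention.  Genome sequences
# are uppercased on read and restricted to A/C/G/T/N.

#' Read a FASTA file
#'
#' @param path Path to a (possibly line-wrapped) FASTA file.
#' @param alphabet `"dna"` rejects records containing symbols outside
#'   A/C/G/T/N after uppercasing; `"any"` skips the check.
#' @return Named character vector of uppercased sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna", "any")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  if (alphabet == "dna" && any(grepl("[^ACGTN]", seqs))) {
    stop("non-ACGTN symbols in FASTA records: ",
         paste(nm[grepl("[^ACGTN]", seqs)], collapse = ", "))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct an annotated genome
#'
#' Bundles the chromosome sequences of one species with its ordered gene
#' records.  Exon intervals are 0-based half-open; invariants (sorted
#' non-overlapping exons inside the chromosome) are checked.
#'
#' @param species_id Species label.
#' @param chromosomes Named character vector of chromosome sequences.
#' @param genes Tibble with columns `gene_id`, `symbol`, `chromosome`,
#'   `strand` (`"+"`/`"-"`), `exons` (list of two-column matrices
#'   `start`,`end`, 0-based half-open) and optionally `focal` (logical,
#'   marks planted copies of the focal family).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(species_id, chromosomes, genes) {
  genes <- as_tibble(genes)
  if (!"focal" %in% names(genes)) genes$focal <- FALSE
  need <- c("gene_id", "symbol", "chromosome", "strand", "exons")
  if (!all(need %in% names(genes))) {
    stop("genes must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    ex <- matrix(as.numeric(ex), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    chr <- genes$chromosome[i]
    if (!chr %in% names(chromosomes)) {
      stop("gene ", genes$gene_id[i], " on unknown chromosome ", chr)
    }
    if (any(ex[, "end"] <= ex[, "start"])) {
      stop("gene ", genes$gene_id[i], " has an exon with end <= start")
    }
    if (is.unsorted(ex[, "start"], strictly = TRUE) && nrow(ex) > 1) {
      ex <- ex[order(ex[, "start"]), , drop = FALSE]
    }
    if (nrow(ex) > 1 && any(ex[-1, "start"] < ex[-nrow(ex), "end"])) {
      stop("gene ", genes$gene_id[i], " has overlapping exons")
    }
    if (min(ex[, "start"]) < 0 || max(ex[, "end"]) > nchar(chromosomes[[chr]])) {
      stop("gene ", genes$gene_id[i], " extends beyond chromosome ", chr)
    }
    genes$exons[[i]] <- ex
  }
  genes <- genes[order(genes$chromosome, vapply(genes$exons, function(e)
    min(e[, "start"]), numeric(1))), ]
  structure(list(species_id = species_id,
                 chromosomes = chromosomes,
                 genes = genes),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$species_id, ": ",
      length(x$chromosomes), " chromosome(s), ",
      nrow(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

gene_span <- function(exons) c(min(exons[, "start"]), max(exons[, "end"]))

#' Read gene annotations from GFF3
#'
#' Parses `gene` and `exon` features (linked by `ID`/`Parent` attributes) and
#' converts GFF3 1-based closed coordinates to internal 0-based half-open.
#'
#' @param path GFF3 file.
#' @param chromosomes Named character vector of chromosome sequences the
#'   annotation refers to.
#' @param species_id Species label for the resulting genome.
#' @return An [annotated_genome()].
#' @export
read_gff3 <- function(path, chromosomes, species_id = "genome") {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (any(df$end < df$start)) stop("GFF3 feature with end < start")
  genes <- df[df$type == "gene", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in ", path)
  recs <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exons[vapply(exons$Parent, function(p) g$ID %in% p, logical(1)), ,
                drop = FALSE]
    if (nrow(ex) == 0) {  # single-exon gene annotated without exon children
      ex <- g
    }
    if (!all(as.character(ex$seqnames) == as.character(g$seqnames))) {
      stop("exon of ", g$ID, " on a different chromosome than its gene")
    }
    m <- cbind(start = ex$start - 1, end = ex$end)
    m <- m[order(m[, "start"]), , drop = FALSE]
    if (m[1, "start"] < g$start - 1 || m[nrow(m), "end"] > g$end) {
      stop("exon outside parent gene span for ", g$ID)
    }
    foc <- if ("focal" %in% names(g)) isTRUE(g$focal == "true" | g$focal == TRUE) else FALSE
    tibble(gene_id = as.character(g$ID),
           symbol = if (!is.null(g$Name) && !is.na(g$Name)) as.character(g$Name)
                    else as.character(g$ID),
           chromosome = as.character(g$seqnames),
           strand = as.character(g$strand),
           exons = list(m), focal = foc)
  })
  annotated_genome(species_id, chromosomes, dplyr::bind_rows(recs))
}

#' Write gene annotations to GFF3
#'
#' @param genome An [annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  rows <- list()
  for (i in seq_len(nrow(g))) {
    ex <- g$exons[[i]]
    sp <- gene_span(ex)
    rows[[length(rows) + 1]] <- data.frame(
      seqnames = g$chromosome[i], start = sp[1] + 1, end = sp[2],
      strand = g$strand[i], type = "gene", ID = g$gene_id[i],
      Name = g$symbol[i], Parent = NA_character_,
      focal = tolower(as.character(isTRUE(g$focal[i]))),
      stringsAsFactors = FALSE)
    for (j in seq_len(nrow(ex))) {
      rows[[length(rows) + 1]] <- data.frame(
        seqnames = g$chromosome[i], start = ex[j, "start"] + 1,
        end = ex[j, "end"], strand = g$strand[i], type = "exon",
        ID = paste0(g$gene_id[i], ".exon", j), Name = NA_character_,
        Parent = g$gene_id[i], focal = NA_character_)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Name <- df$Name
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$focal <- df$focal
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a rooted species tree from Newick
#'
#' Duplicate leaf labels are rejected.  A multifurcating root is accepted but
#' flagged via the `"multifurcating_root"` attribute.
#'
#' @param path Newick file, or a Newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  root <- ape::Ntip(tr) + 1L
  nchild <- sum(tr$edge[, 1] == root)
  if (nchild < 2) stop("root must have at least two children")
  attr(tr, "multifurcating_root") <- nchild > 2
  tr
}

#' Stable branch identifiers
#'
#' Every branch of a rooted tree is named after the clade below it: the tip
#' label for terminal branches, the sorted tip labels joined by `"|"` for
#' internal branches.  These ids are invariant under reserialization.
#'
#' @param tree A `phylo` object.
#' @return Tibble with columns `node` (child node number) and `branch_id`.
#' @export
branch_ids <- function(tree) {
  nodes <- tree$edge[, 2]
  tibble(node = nodes,
         branch_id = vapply(nodes, function(n) clade_id(tree, n), character(1)))
}

# Branch id of the branch subtending `node`; `"(root)"` for the root itself.
clade_id <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node == ntip + 1L) return("(root)")
  if (node <= ntip) return(tree$tip.label[node])
  tips <- sort(tree$tip.label[clade_tips(tree, node)])
  paste(tips, collapse = "|")
}

# Branch id for the stem of the clade containing exactly `tips`.
stem_branch <- function(tree, tips) {
  tips <- sort(tips)
  if (length(tips) == 1) return(tips)
  paste(tips, collapse = "|")
}

clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, tree = tree))
}

tree_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

tree_root <- function(tree) ape::Ntip(tree) + 1L

# Map branch_id -> child node for a tree.
branch_lookup <- function(tree) {
  b <- branch_ids(tree)
  setNames(b$node, b$branch_id)
}

node_depths <- function(tree) {
  root <- tree_root(tree)
  depth <- integer(max(tree$edge))
  ord <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # preorder: parents always come before children in ape's edge matrix after
  # reorder
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(tr$edge))) {
    depth[tr$edge[i, 2]] <- depth[tr$edge[i, 1]] + 1L
  }
  depth
}
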