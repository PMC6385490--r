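# A deterministic miniature teleost-like clade whose planted history mirrors
# the qualitative findings on the clade I hatching-enzyme genes: an ancestral
# nine-exon gene between tgfb2l and kcnk4 (tail-to-tail), a retrocopy with
# three introns lost inserted into the 14th intron of an aox5-like host in
# opposite orientation on the otophysi-like stem, a fully intron-less
# retrocopy near glo1/slco3a1/mctp2b on the euteleostei-like stem, four
# further daughter insertions in four euteleost subclades, and graded decay
# of the euteleost parent-locus copy down to complete erasure in the
# cichlid-like species.  All retrocopies carry the 200 bp promoter block.

FIXTURE_NEWICK <- paste0(
  "((arowana,eel),((herring,(zebrafish,(cavefish,catfish))),",
  "(salmon,(tonguesole,((medaka,(tilapia,cichlid)),",
  "((croaker,(seabass,stickleback)),(takifugu,tetraodon)))))));")

fixture_layout <- function(gene, params) {
  sp <- function() el_spacer(params$spacer_len)
  g <- function(symbol, strand, ...) el_gene(symbol, strand, ...)
  chr <- function(...) {
    els <- list(...)
    out <- list(sp())
    for (e in els) out <- c(out, list(e, sp()))
    out
  }
  list(chromosomes = list(
    # ancestral (teleost parent) locus: tgfb2l(+) / focal / kcnk4(-)
    chr1 = list(sp(), g("adam15", "+"), sp(), g("paqr6", "-"), sp(),
                g("tgfb2l", "+"), sp(), el_focal("copy0", "+", gene), sp(),
                g("kcnk4", "-"), sp(), g("slc25a44", "+"), sp(),
                g("pmf1", "-"), sp()),
    # otophysi destination: aox5-like host with 16 exons / 15 introns
    chr2 = chr(g("rnf141", "+"), g("slc17a6", "-"),
               g("aox5", "+", n_exons = 16), g("pik3c2a", "+"),
               g("nucb2", "-")),
    # euteleost parent slot: glo1 - slco3a1 - [dest] - mctp2b
    chr3 = chr(g("edar", "-"), g("glo1", "+"), g("slco3a1", "+"),
               g("mctp2b", "+"), g("ube3d", "+")),
    # four daughter slots
    chr4 = chr(g("lrrk1", "-"), g("anxa2a", "+"), g("roraa", "-"),
               g("otud7a", "+")),
    chr5 = chr(g("fntb", "+"), g("glrx5", "+"), g("prkrip1", "+"),
               g("serpina1l", "-")),
    chr6 = chr(g("helz", "-"), g("adgra1a", "+"), g("acbd4", "-"),
               g("llgl2", "+")),
    chr7 = chr(g("rbm39", "-"), g("fer1l4", "+"), g("cpne1", "+"),
               g("nfs1", "-"))
  ))
}

fixture_events <- function(tree) {
  oto <- stem_branch(tree, c("zebrafish", "cavefish", "catfish"))
  eut <- stem_branch(tree, c("salmon", "tonguesole", "medaka", "tilapia",
                             "cichlid", "croaker", "seabass", "stickleback",
                             "takifugu", "tetraodon"))
  tc <- stem_branch(tree, c("tilapia", "cichlid"))
  css <- stem_branch(tree, c("croaker", "seabass", "stickleback"))
  ss <- stem_branch(tree, c("seabass", "stickleback"))
  tt <- stem_branch(tree, c("takifugu", "tetraodon"))
  dplyr::bind_rows(
    # retrocopy with 3 introns lost into the 14th intron of aox5, opposite
    # orientation; the teleost parent copy is obliterated in otophysi
    tibble(branch = oto, kind = "translocation_gain", source = "copy0",
           new_copy = "copy_oto", introns_removed = 3L, dest_host = "aox5",
           dest_intron = 14L, dest_orientation = "opposite",
           carry_promoter = TRUE),
    tibble(branch = oto, kind = "copy_loss", target = "copy0"),
    # fully spliced retrocopy into the glo1/slco3a1/mctp2b region
    tibble(branch = eut, kind = "translocation_gain", source = "copy0",
           new_copy = "copy_eut", introns_removed = 8L, dest_chrom = "chr3",
           dest_after = "slco3a1", dest_strand = "+", carry_promoter = TRUE),
    tibble(branch = eut, kind = "copy_loss", target = "copy0"),
    # four independent daughter translocations of the intron-less gene
    tibble(branch = "salmon", kind = "translocation_gain",
           source = "copy_eut", new_copy = "copy_sal", introns_removed = 0L,
           dest_chrom = "chr4", dest_after = "anxa2a", dest_strand = "+",
           carry_promoter = TRUE),
    tibble(branch = tc, kind = "translocation_gain", source = "copy_eut",
           new_copy = "copy_tc", introns_removed = 0L, dest_chrom = "chr5",
           dest_after = "glrx5", dest_strand = "-", carry_promoter = TRUE),
    tibble(branch = css, kind = "translocation_gain", source = "copy_eut",
           new_copy = "copy_css", introns_removed = 0L, dest_chrom = "chr6",
           dest_after = "adgra1a", dest_strand = "+", carry_promoter = TRUE),
    tibble(branch = tt, kind = "translocation_gain", source = "copy_eut",
           new_copy = "copy_tt", introns_removed = 0L, dest_chrom = "chr7",
           dest_after = "fer1l4", dest_strand = "+", carry_promoter = TRUE),
    # graded decay of the euteleost parent-locus copy
    tibble(branch = "tilapia", kind = "pseudogenization",
           target = "copy_eut", stage = "short"),
    tibble(branch = "cichlid", kind = "copy_loss", target = "copy_eut"),
    tibble(branch = ss, kind = "pseudogenization", target = "copy_eut",
           stage = "fragment"),
    tibble(branch = tt, kind = "pseudogenization", target = "copy_eut",
           stage = "fragment"))
}

#' The teleost-history fixture clade
#'
#' A deterministic 16-species clade whose planted event history reproduces,
#' in miniature, the qualitative retrocopy history inferred for teleost
#' clade I hatching-enzyme genes: basal species keep the nine-exon gene
#' between `tgfb2l` and `kcnk4` (tail-to-tail); the otophysi-like subclade
#' carries a five-intron copy inside the 14th intron of an `aox5`-like host
#' in opposite orientation; the euteleost-like subclade carries an
#' intron-less copy near `glo1`/`slco3a1`/`mctp2b`; four further daughter
#' insertions arise independently in four euteleost subclades; and the
#' euteleost parent-locus copy decays to fragment, short fragment or nothing
#' along the planted lineages.
#'
#' @param seed Simulation seed.
#' @param rate Per-branch substitution rate (kept low: these are
#'   strongly conserved loci).
#' @return A [simulate_clade()] result; `$event_log` is the ground truth.
#' @export
fixture_clade <- function(seed = 20L, rate = 0.002) {
  tree <- read_newick(FIXTURE_NEWICK)
  params <- sim_params(seed = seed, rate = rate)
  simulate_clade(tree, params, events = fixture_events(tree),
                 layout = fixture_layout)
}

#' Euteleost-like species of the fixture clade
#' @return Character vector of tip labels.
#' @export
fixture_euteleosts <- function() {
  c("salmon", "tonguesole", "medaka", "tilapia", "cichlid", "croaker",
    "seabass", "stickleback", "takifugu", "tetraodon")
}
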