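# Upstream windows, TATA/motif scanning, conserved blocks, carry-over and
# the upstream-region tree.

test_that("extract_upstream handles strand, coordinates and truncation", {
  chrom <- paste(rep(c("A", "C", "G", "T"), length.out = 1000),
                 collapse = "")
  g <- annotated_genome("sp", c(chr = chrom), tibble::tibble(
    gene_id = "g", symbol = "g", chromosome = "chr", strand = "+",
    exons = list(cbind(start = 500, end = 700))))
  m <- gene_model("g", "chr", "+", cbind(start = 500, end = 700),
                  substr(chrom, 501, 700))
  up <- extract_upstream(g, m, window = 192)
  expect_equal(nchar(up), 192)
  expect_identical(as.character(up), substr(chrom, 309, 500))
  expect_false(attr(up, "truncated"))

  # minus strand: reverse complement of the slice 3' of the gene
  toy <- c(chr = "AACCGGTTAACCGGTTAACC")
  gm <- gene_model("g", "chr", "-", cbind(start = 2, end = 10), "x")
  gn <- annotated_genome("sp", toy, tibble::tibble(
    gene_id = "g", symbol = "g", chromosome = "chr", strand = "-",
    exons = list(cbind(start = 2, end = 10))))
  up2 <- extract_upstream(gn, gm, window = 5)
  # bases 11..15 of the plus strand are "CCGGT"; hand reverse complement:
  # complement GGCCA, reversed -> "ACCGG"
  expect_identical(as.character(up2), "ACCGG")

  # truncation at the chromosome start
  gm3 <- gene_model("g", "chr", "+", cbind(start = 10, end = 18), "x")
  up3 <- extract_upstream(gn, gm3, window = 200)
  expect_equal(nchar(up3), 10)
  expect_true(attr(up3, "truncated"))
  expect_error(extract_upstream(gn, gm3, window = 0), "positive")
})

test_that("find_tata returns the 3'-most in-window match", {
  pad <- function(n) strrep("C", n)
  # plant at offset -31 (200-bp window): string index 170
  s <- paste0(pad(169), "TATAAAA", pad(24))
  expect_equal(find_tata(s), -31)
  expect_true(is.na(find_tata(strrep("C", 200))))
  # matches at -45 and -28: the 3'-most wins
  s2 <- paste0(pad(155), "TATAAAT", pad(10), "TATATAA", pad(21))
  expect_equal(nchar(s2), 200)
  expect_equal(find_tata(s2), -28)
  # a match outside the -50..-20 search window is ignored
  s3 <- paste0(pad(100), "TATAAAA", pad(93))
  expect_true(is.na(find_tata(s3)))
})

test_that("scan_tf_sites equals the expanded-literal oracle", {
  s <- paste0(strrep("G", 40), "CACCC", strrep("G", 20), "CTCCC",
              strrep("G", 20), "TGTTTGCATT", strrep("G", 30))
  hits <- scan_tf_sites(s)
  expect_equal(sum(hits$site == "klf"), 2)
  expect_equal(sum(hits$site == "foxa3"), 1)
  expect_identical(hits$match[hits$site == "foxa3"], "TGTTTGCATT")
  # no foxa3 hit without G/T-rich symbols
  set.seed(3)
  ac <- paste(sample(c("A", "C"), 100, replace = TRUE), collapse = "")
  expect_equal(sum(scan_tf_sites(ac)$site == "foxa3"), 0)
  # property: offsets match the oracle on random sequences
  for (rep in 1:5) {
    r <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    h <- scan_tf_sites(r)
    expect_identical(sort(h$offset[h$site == "klf"]),
                     sort(oracle_match_iupac("CWCCC", r) - nchar(r) - 1L))
    expect_identical(sort(h$offset[h$site == "foxa3"]),
                     sort(oracle_match_iupac("TGTTTRCWYW", r) -
                            nchar(r) - 1L))
  }
})

test_that("conserved_block finds shared windows and rejects noise", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  blk <- conserved_block(list(s, s, s))
  expect_equal(blk$start_offset, -200)
  expect_equal(blk$end_offset, 0)
  # unrelated random sequences: expected identity ~0.25, no block
  r1 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  r2 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  expect_null(conserved_block(list(r1, r2)))
  # simulated clade at low rate: the planted 200 bp block is found and
  # covers TATA plus both motif classes
  sim <- simulate_clade(read_newick("((A,B),C);"),
                        sim_params(seed = 6, rate = 0.005))
  ups <- lapply(sim$genomes, function(g) {
    loci <- cross_species_clone(sim$family$exons, g)
    extract_upstream(g, loci$model[[1]], 200)
  })
  blk2 <- conserved_block(ups)
  expect_gte(blk2$end_offset - blk2$start_offset, 150)
  rep <- promoter_report(ups[[1]])
  expect_gte(rep$tata_offset, blk2$start_offset)
  expect_true(any(rep$hits$offset[rep$hits$site == "klf"] >=
                    blk2$start_offset))
  expect_true(any(rep$hits$offset[rep$hits$site == "foxa3"] >=
                    blk2$start_offset))
})

test_that("carry-over classification follows the planted promoter flag", {
  ref <- promoter_report(get_gene()$promoter, "reference", "parent")
  tree <- read_newick("((A,B),C);")
  for (carry in c(TRUE, FALSE)) {
    ev <- tibble::tibble(branch = "A|B", kind = "translocation_gain",
                         source = "copy0", new_copy = "copy1",
                         introns_removed = 8L, dest_chrom = "chr2",
                         dest_after = "d2", carry_promoter = carry)
    sim <- simulate_clade(tree, sim_params(seed = 14, rate = 0),
                          events = ev)
    g <- sim$genomes$A
    loci <- cross_species_clone(sim$family$exons, g)
    daughter <- loci[loci$intron_count == 0, ]
    up <- extract_upstream(g, daughter$model[[1]], 200)
    repd <- promoter_report(up, "A", "daughter")
    refp <- promoter_report(sim$family$promoter, "reference", "parent")
    cc <- classify_carryover(refp, repd)
    expect_identical(cc$carryover, carry, info = paste("carry", carry))
    if (!carry) {
      expect_false(all(cc$evidence$ok))
    }
  }
})

test_that("a daughter lacking the foxa3 site is rejected with evidence", {
  gene <- get_gene()
  ref <- promoter_report(gene$promoter, "reference", "parent")
  # deletion-construct analog: same promoter with the foxa3 site scrubbed
  del <- retrotrace:::scrub_motif(gene$promoter, "TGTTTRCWYW")
  repd <- promoter_report(del, "sp", "daughter")
  cc <- classify_carryover(ref, repd)
  expect_false(cc$carryover)
  ev <- cc$evidence
  expect_true(ev$ok[ev$check == "conserved_block"])
  expect_false(ev$ok[ev$check == "foxa3_in_region"])
  expect_match(ev$detail[ev$check == "foxa3_in_region"], "missing foxa3")
})

test_that("upstream_tree builds an NJ tree over TATA-anchored regions", {
  g <- get_gene()
  p <- g$promoter
  seqs <- c(a = p, b = p, c = p)
  tr <- upstream_tree(seqs)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  expect_true(all(as.matrix(attr(tr, "distances")) == 0))

  # known 4-taxon divergence pattern: NJ recovers the generating topology
  mut <- function(s, idx) {
    ch <- strsplit(s, "")[[1]]
    for (i in idx) ch[i] <- chartr("ACGT", "GTAC", ch[i])
    paste(ch, collapse = "")
  }
  # distinct substitutions in the 100 bp upstream of the TATA (indices
  # 70..169 in the 200 bp window); a/b share none, c/d share a clade set
  s4 <- c(a = p, b = mut(p, 75:78), c = mut(p, 120:133),
          d = mut(p, c(120:133, 145:150)))
  tr4 <- upstream_tree(s4)
  truth <- read_newick("((a,b),(c,d));")
  expect_equal(ape::dist.topo(ape::unroot(tr4), ape::unroot(truth)), 0,
               ignore_attr = TRUE)

  # sequences without TATA are excluded with a warning
  seqs5 <- c(s4, e = strrep("C", 200))
  expect_warning(tr5 <- upstream_tree(seqs5), "without a TATA")
  expect_setequal(tr5$tip.label, c("a", "b", "c", "d"))
  expect_error(suppressWarnings(upstream_tree(
    c(x = strrep("C", 200), y = strrep("C", 200), z = strrep("C", 200)))),
    "at least 3")
})

test_that("carry-over recovery is perfect over simulator scenarios at rate 0", {
  b <- recovery_batch(c(51, 52, 53), rate = 0)
  expect_equal(attr(b, "carryover_accuracy"), 1)
})
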