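# Flanking-gene contexts, slot matching and the presence matrix.

toy_genome <- function() {
  chrom <- c(chr = strrep("A", 5000))
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    symbol = c("w", "x", "y", "z", "q"),
    chromosome = "chr", strand = c("+", "-", "+", "-", "+"),
    exons = list(cbind(0, 200), cbind(400, 600), cbind(800, 1000),
                 cbind(1600, 1800), cbind(2000, 2200)))
  annotated_genome("toy", chrom, genes)
}

test_that("extract_context orders neighbors by distance and pads at ends", {
  g <- toy_genome()
  ctx <- extract_context(g, "chr", 1200, 1400, strand = "+", k = 3)
  expect_identical(ctx$upstream[[1]]$symbol, c("y", "x", "w"))
  expect_identical(ctx$downstream[[1]]$symbol, c("z", "q", "(end)"))
  # locus one gene from the chromosome start
  ctx2 <- extract_context(g, "chr", 250, 300, k = 3)
  expect_identical(ctx2$upstream[[1]]$symbol, c("w", "(end)", "(end)"))
})

test_that("fixture contexts reproduce the diagnostic neighborhoods", {
  run <- get_fixture_run()
  h <- run$contexts[run$contexts$species_id == "herring", ]
  expect_identical(h$upstream[[1]]$symbol[1], "tgfb2l")
  expect_identical(h$upstream[[1]]$strand[1], "+")
  expect_identical(h$downstream[[1]]$symbol[1], "kcnk4")
  expect_identical(h$downstream[[1]]$strand[1], "-")
  # tail-to-tail: the left neighbor points right, the right neighbor left
  z <- run$contexts[run$contexts$species_id == "zebrafish", ]
  hi <- z$host_insertion[[1]]
  expect_identical(hi$host_symbol, "aox5")
  expect_equal(hi$intron_ordinal, 14L)
  expect_identical(hi$orientation, "opposite")
})

test_that("host intron ordinal round-trips for intragenic insertions", {
  for (ordn in c(3L, 14L)) {
    tree <- read_newick("(A,B);")
    ev <- tibble::tibble(branch = "A", kind = "translocation_gain",
                         source = "copy0", new_copy = "copy1",
                         introns_removed = 8L, dest_host = "h16",
                         dest_intron = ordn, dest_orientation = "opposite",
                         carry_promoter = TRUE)
    layout <- function(gene, params) {
      st <- retrotrace:::build_ancestral_state(gene, params)
      st$chromosomes$chr5 <- list(
        retrotrace:::el_spacer(200),
        retrotrace:::el_gene("u1", "+", 300), retrotrace:::el_spacer(200),
        retrotrace:::el_gene("h16", "-", n_exons = 16),
        retrotrace:::el_spacer(200),
        retrotrace:::el_gene("u2", "+", 300), retrotrace:::el_spacer(200))
      st
    }
    sim <- simulate_clade(tree, sim_params(seed = 13, rate = 0),
                          events = ev, layout = layout)
    loci <- cross_species_clone(sim$family$exons, sim$genomes$A)
    l <- loci[loci$chromosome == "chr5", ]
    expect_equal(nrow(l), 1)
    ctx <- extract_context(sim$genomes$A, "chr5", l$start, l$end,
                           strand = l$strand)
    hi <- ctx$host_insertion[[1]]
    expect_identical(hi$host_symbol, "h16")
    expect_equal(hi$intron_ordinal, ordn)
    expect_identical(hi$orientation, "opposite")
  }
})

ctx_from_anchors <- function(species, up, dn, up_strand = NULL,
                             dn_strand = NULL) {
  k <- 3
  pad <- function(x) c(x, rep("(end)", k - length(x)))
  tibble::tibble(
    species_id = species, chromosome = "chr", start = 0, end = 1,
    strand = "+", state = "full",
    upstream = list(tibble::tibble(symbol = pad(up),
                                   strand = rep("+", k))),
    downstream = list(tibble::tibble(symbol = pad(dn),
                                     strand = rep("+", k))),
    host_insertion = list(NULL))
}

test_that("slot matching follows shared ordered anchors", {
  # all three flanked by glo1/slco3a1/mctp2b -> one slot
  a <- ctx_from_anchors("salmon", c("slco3a1", "glo1"), "mctp2b")
  b <- ctx_from_anchors("croaker", c("slco3a1", "glo1"), "mctp2b")
  c3 <- ctx_from_anchors("medaka", c("slco3a1", "glo1"), "mctp2b")
  m <- match_slots(dplyr::bind_rows(a, b, c3))
  expect_length(unique(m$slot), 1)

  # 2 of 3 anchors in the same order -> same slot; only 1 -> different
  d <- ctx_from_anchors("sp4", c("slco3a1"), "mctp2b")
  e <- ctx_from_anchors("sp5", c("slco3a1"), "other")
  m2 <- match_slots(dplyr::bind_rows(a, d, e))
  expect_identical(m2$slot[1], m2$slot[2])
  expect_false(m2$slot[3] == m2$slot[1])

  # order reversal is not tolerated
  f <- ctx_from_anchors("sp6", c("glo1", "slco3a1"), "mctp2b")
  g2 <- ctx_from_anchors("sp7", "mctp2b", c("slco3a1", "glo1"))
  m3 <- match_slots(dplyr::bind_rows(a, g2))
  expect_length(unique(m3$slot), 2)

  # reflexivity and permutation invariance
  set.seed(2)
  rows <- dplyr::bind_rows(a, b, c3, d, e)
  m4 <- match_slots(rows)
  perm <- sample(nrow(rows))
  m5 <- match_slots(rows[perm, ])
  expect_identical(m4$slot[perm], m5$slot)
  # sentinels never count as anchors
  s1 <- ctx_from_anchors("s1", "(end)", "(end)")
  s2 <- ctx_from_anchors("s2", "(end)", "(end)")
  m6 <- match_slots(dplyr::bind_rows(s1, s2))
  expect_length(unique(m6$slot), 2)
})

test_that("presence matrix maps occupant grades and completes absences", {
  a <- ctx_from_anchors("sp1", c("x2", "x1"), c("x3"))
  b <- ctx_from_anchors("sp2", c("x2", "x1"), c("x3"))
  b$state <- "fragment"
  c3 <- ctx_from_anchors("sp3", c("x2", "x1"), c("x3"))
  c3$state <- "short_fragment"
  m <- match_slots(dplyr::bind_rows(a, b, c3))
  pm <- build_presence_matrix(m, species = c("sp1", "sp2", "sp3", "sp4"))
  states <- setNames(pm$state, pm$species_id)
  expect_identical(states[["sp1"]], "full")
  expect_identical(states[["sp2"]], "vestige")
  expect_identical(states[["sp3"]], "vestige")
  expect_identical(states[["sp4"]], "absent")
  # order invariance
  pm2 <- build_presence_matrix(m[c(3, 1, 2), ],
                               species = c("sp1", "sp2", "sp3", "sp4"))
  expect_identical(dplyr::arrange(tibble::as_tibble(pm), species_id),
                   dplyr::arrange(tibble::as_tibble(pm2), species_id))
  # conflicting duplicate cells raise
  dup <- dplyr::bind_rows(a, dplyr::mutate(b, species_id = "sp1"))
  m3 <- match_slots(dup)
  expect_error(build_presence_matrix(m3), "conflicting duplicate")
})

test_that("the fixture presence matrix shows the graded parent-slot decay", {
  run <- get_fixture_run()
  pm <- run$presence
  p1 <- attr(pm, "slots")
  eut_parent <- pm$slot[pm$species_id == "medaka" & pm$state == "full"]
  expect_length(eut_parent, 1)
  cell <- function(sp) pm$state[pm$species_id == sp & pm$slot == eut_parent]
  for (sp in c("salmon", "croaker", "tonguesole", "medaka")) {
    expect_identical(cell(sp), "full")
  }
  for (sp in c("seabass", "stickleback", "tilapia")) {
    expect_identical(cell(sp), "vestige")
  }
  expect_identical(cell("cichlid"), "absent")
  # tilapia's remnant is shorter than the other parent-slot vestiges
  cov <- function(sp) {
    ctx <- run$contexts
    ctx$coverage[ctx$species_id == sp & ctx$slot == eut_parent]
  }
  expect_lt(cov("tilapia"), cov("seabass"))
  expect_lt(cov("tilapia"), cov("stickleback"))
})

test_that("daughter slot counting matches the fixture and the ground truth", {
  run <- get_fixture_run()
  eut_parent <- run$presence$slot[run$presence$species_id == "medaka" &
                                    run$presence$state == "full"]
  expect_equal(count_daughter_slots(run$presence, eut_parent,
                                    species = fixture_euteleosts()), 4)
  # degenerate: a matrix with only the parent slot
  a <- ctx_from_anchors("sp1", c("x2", "x1"), "x3")
  pm <- build_presence_matrix(match_slots(a))
  expect_equal(count_daughter_slots(pm, pm$slot[1]), 0)
  expect_error(count_daughter_slots(pm, "slot:nope"), "unknown parent")
})

test_that("slots recovered equal slots planted at rate 0", {
  for (seed in c(101, 202)) {
    run <- run_scenario(seed, rate = 0)
    sim_gains <- sum(run$scorecard$detail$kind == "translocation_gain")
    expect_equal(nrow(run$gains) - 1L, sim_gains)  # minus the parent slot
  }
})
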