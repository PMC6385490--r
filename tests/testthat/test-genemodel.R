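# Splice-aware structure inference, protein diagnostics and vestige grading.

test_that("a contiguous CDS maps as a single exon", {
  set.seed(1)
  cds <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  region <- paste0(strrep("T", 37), cds, strrep("A", 53))
  m <- infer_gene_structure(cds, region)
  expect_equal(nrow(m$exons), 1)
  expect_equal(m$intron_count, 0)
  expect_identical(m$cds, cds)
})

test_that("the simulator's ancestral gene maps back to 9 exons / 8 introns", {
  g <- get_gene()
  body <- gene_body(g)
  m <- infer_gene_structure(g$cds, body)
  expect_equal(nrow(m$exons), 9)
  expect_equal(m$intron_count, 8)
  expect_identical(m$cds, g$cds)
  # every inferred intron is GT..AG
  for (i in seq_len(nrow(m$exons) - 1)) {
    intr <- substr(body, m$exons[i, "end"] + 1, m$exons[i + 1, "start"])
    expect_identical(substr(intr, 1, 2), "GT")
    expect_identical(substr(intr, nchar(intr) - 1, nchar(intr)), "AG")
  }
  # minus strand gives mirrored coordinates and the same spliced CDS
  m2 <- infer_gene_structure(g$cds, revcomp(body), strand = "-")
  expect_identical(m2$cds, g$cds)
  expect_equal(nchar(body) - m2$exons[nrow(m2$exons), "end"],
               m$exons[1, "start"], ignore_attr = TRUE)
})

test_that("splice inference is fewest-introns optimal vs the chain enumerator", {
  set.seed(33)
  for (rep in 1:6) {
    n_int <- sample(1:3, 1)
    widths <- sample(40:70, n_int + 1, replace = TRUE)
    cds <- paste(sample(c("A", "C", "G", "T"), sum(widths), replace = TRUE),
                 collapse = "")
    ends <- cumsum(widths); starts <- c(1, head(ends, -1) + 1)
    parts <- character(0)
    for (i in seq_along(starts)) {
      parts <- c(parts, substr(cds, starts[i], ends[i]))
      if (i <= n_int) {
        parts <- c(parts, paste0("GT", paste(
          sample(c("A", "C", "G", "T"), sample(40:60, 1), replace = TRUE),
          collapse = ""), "AG"))
      }
    }
    region <- paste0(strrep("C", 20), paste(parts, collapse = ""),
                     strrep("G", 20))
    chains <- oracle_enum_chains(cds, region, min_intron = 40)
    expect_gt(length(chains), 0)
    best <- min(vapply(chains, `[[`, numeric(1), "introns"))
    m <- infer_gene_structure(cds, region, min_intron = 40)
    expect_equal(m$intron_count, best)
    expect_equal(m$mismatches, 0)
    # leftmost-donor tie-break: the returned chain is lexicographically
    # smallest among optimal exact chains
    opt <- Filter(function(ch) ch$introns == best, chains)
    donor_key <- function(ex) paste(ex[-nrow(ex), 2], collapse = ",")
    expect_equal(donor_key(m$exons),
                 sort(vapply(opt, function(ch) donor_key(ch$exons),
                             character(1)))[1])
  }
})

test_that("alternative equal-cost donors 4 nt apart resolve to the leftmost", {
  # the intron begins GTAG and exon2 also begins GTAG, so the donor can
  # slide 4 nt right (exon1 absorbing the intron's first four bases) and
  # still leave a valid zero-mismatch GT..AG chain
  set.seed(12)
  exon1 <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                 collapse = "")
  exon2 <- paste0("GTAG", paste(sample(c("A", "C", "G", "T"), 36,
                                       replace = TRUE), collapse = ""))
  intron <- paste0("GTAG", "GT", strrep("C", 44), "AG")
  cds <- paste0(exon1, exon2)
  region <- paste0(exon1, intron, exon2)
  chains <- oracle_enum_chains(cds, region, min_intron = 40)
  best <- min(vapply(chains, `[[`, numeric(1), "introns"))
  opt <- Filter(function(ch) ch$introns == best, chains)
  donors <- sort(vapply(opt, function(ch) ch$exons[1, 2], numeric(1)))
  expect_gte(length(opt), 2)           # genuinely ambiguous
  expect_equal(diff(donors)[1], 4)
  m <- infer_gene_structure(cds, region, min_intron = 40)
  expect_equal(m$intron_count, best)
  expect_equal(m$exons[1, "end"], donors[1], ignore_attr = TRUE)
})

test_that("unmappable and splice-violation inputs raise distinct errors", {
  set.seed(4)
  cds <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
  junk <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
  expect_error(infer_gene_structure(cds, junk), "unmappable")
  # a real intron whose splice sites are not GT..AG
  half1 <- substr(cds, 1, 70); half2 <- substr(cds, 71, 150)
  bad_intron <- paste0("CC", strrep("T", 50), "CC")
  region <- paste0(half1, bad_intron, half2)
  expect_error(infer_gene_structure(cds, region), "splice violation")
  expect_error(infer_gene_structure("ACGTACGT", "ACGTACGT"), "shorter")
})

test_that("protein diagnostics count motifs and cysteines", {
  p <- paste0("MAAA", "HEAAHAAGFAHEAARADR", "GGG", "SAMHY", "CCAC")
  d <- scan_protein_diagnostics(p)
  expect_equal(d$active_site_hits, 2)
  expect_equal(d$cysteine_count, 3)
  expect_equal(nrow(d$positions), 2)
  empty <- scan_protein_diagnostics("")
  expect_equal(empty$active_site_hits, 0)
  expect_equal(empty$cysteine_count, 0)
  expect_error(scan_protein_diagnostics("MA1A"), "illegal residue")
})

test_that("classify_vestige grades exact, fragmented and random loci", {
  g <- get_gene()
  cds <- g$cds
  expect_identical(classify_vestige(cds, cds)$state, "full")
  # contiguous 50% with 2 frameshifts: coverage tracks the construction
  frag <- substr(cds, 101, 100 + round(nchar(cds) * 0.5))
  frag <- paste0(substr(frag, 1, 130), substr(frag, 132, 260),
                 substr(frag, 262, nchar(frag)))
  v <- classify_vestige(frag, cds)
  expect_identical(v$state, "fragment")
  expect_gt(v$coverage, 0.4)
  expect_lt(v$coverage, 0.6)
  expect_gte(v$disruption, 1)
  set.seed(8)
  rand <- paste(sample(c("A", "C", "G", "T"), nchar(cds), replace = TRUE),
                collapse = "")
  expect_identical(classify_vestige(rand, cds)$state, "absent")
  # reverse-complemented occupant is still recognized
  expect_identical(classify_vestige(revcomp(cds), cds)$state, "full")
})

test_that("vestige grade decreases monotonically with planted decay stage", {
  g <- get_gene()
  rank <- c(full = 3, fragment = 2, short_fragment = 1, absent = 0)
  for (seed in 1:4) {
    tree <- read_newick("((A,B),(C,(D,E)));")
    ev <- dplyr::bind_rows(
      tibble::tibble(branch = "C", kind = "pseudogenization",
                     target = "copy0", stage = "fragment"),
      tibble::tibble(branch = "D", kind = "pseudogenization",
                     target = "copy0", stage = "short"),
      tibble::tibble(branch = "E", kind = "copy_loss", target = "copy0"))
    sim <- simulate_clade(tree, sim_params(seed = seed, rate = 0),
                          events = ev)
    grade <- function(sp) {
      t <- sim$truth[sim$truth$species_id == sp &
                       sim$truth$copy_id == "copy0", ]
      s <- substr(sim$genomes[[sp]]$chromosomes[[t$chromosome]],
                  t$start + 1, t$end)
      rank[classify_vestige(s, sim$family$cds)$state]
    }
    expect_true(grade("A") > grade("C"), info = paste("seed", seed))
    expect_true(grade("C") > grade("D"), info = paste("seed", seed))
    expect_true(grade("D") >= grade("E"), info = paste("seed", seed))
  }
})

test_that("cross_species_clone recovers planted copies of all grades", {
  tree <- read_newick("((A,B),(C,D));")
  ev <- dplyr::bind_rows(
    tibble::tibble(branch = "C|D", kind = "translocation_gain",
                   source = "copy0", new_copy = "copy1",
                   introns_removed = 8L, dest_chrom = "chr3",
                   dest_after = "e2", carry_promoter = FALSE),
    tibble::tibble(branch = "D", kind = "copy_loss", target = "copy0"))
  sim <- simulate_clade(tree, sim_params(seed = 21, rate = 0), events = ev)
  # unmutated ortholog: the model matches the planted structure exactly
  lociA <- cross_species_clone(sim$family$exons, sim$genomes$A)
  expect_equal(nrow(lociA), 1)
  expect_equal(lociA$intron_count, 8L)
  truthA <- sim$truth[sim$truth$species_id == "A", ]
  mA <- lociA$model[[1]]
  expect_equal(min(mA$exons[, "start"]), truthA$start + 200)  # promoter
  expect_identical(mA$cds, sim$family$cds)
  # intron-less retrocopy: single exon, near-identical CDS
  lociC <- cross_species_clone(sim$family$exons, sim$genomes$C)
  rc <- lociC[lociC$intron_count == 0 & !is.na(lociC$intron_count), ]
  expect_equal(nrow(rc), 1)
  expect_gte(rc$coverage, 0.95)
  expect_equal(nrow(rc$model[[1]]$exons), 1)
  # erased locus yields no hit there: D has only the retrocopy
  lociD <- cross_species_clone(sim$family$exons, sim$genomes$D)
  expect_equal(nrow(lociD), 1)
  expect_equal(lociD$intron_count, 0L)
})

test_that("structure inference round-trips every simulator gene at rate 0", {
  tree <- read_newick("((A,B),(C,D));")
  ev <- tibble::tibble(branch = "C|D", kind = "translocation_gain",
                       source = "copy0", new_copy = "copy1",
                       introns_removed = 4L, dest_chrom = "chr2",
                       dest_after = "d2", dest_strand = "-",
                       carry_promoter = TRUE)
  sim <- simulate_clade(tree, sim_params(seed = 31, rate = 0), events = ev)
  for (sp in c("A", "C")) {
    loci <- cross_species_clone(sim$family$exons, sim$genomes[[sp]])
    tr <- sim$truth[sim$truth$species_id == sp, ]
    for (i in seq_len(nrow(loci))) {
      m <- loci$model[[i]]
      t <- tr[tr$chromosome == loci$chromosome[i], ]
      # exon span sits inside the planted element and splices to the CDS
      expect_gte(min(m$exons[, "start"]), t$start)
      expect_lte(max(m$exons[, "end"]), t$end)
      expect_identical(
        splice_exons(sim$genomes[[sp]]$chromosomes[[m$chromosome]],
                     m$exons, m$strand), m$cds)
    }
  }
})
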