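# Independent brute-force oracles used to validate the implementation.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Expand a degenerate pattern into every literal string and search each
# literally; union of match positions.
oracle_match_iupac <- function(pattern, subject) {
  sets <- lapply(strsplit(toupper(pattern), "")[[1]], function(s) IUPAC_SETS[[s]])
  literals <- Reduce(function(acc, s) {
    unlist(lapply(acc, function(a) paste0(a, s)))
  }, sets, accumulate = FALSE, init = "")
  subject <- toupper(subject)
  hits <- integer(0)
  for (lit in literals) {
    start <- 1
    repeat {
      i <- regexpr(lit, substr(subject, start, nchar(subject)), fixed = TRUE)
      if (i == -1) break
      hits <- c(hits, start + i - 1)
      start <- start + i
    }
  }
  sort(unique(as.integer(hits)))
}

# Enumerate every exact-match GT..AG splice chain of `cds` in `region`
# (zero mismatches).  Returns a list of chains; each chain is a list with
# `exons` (two-column matrix, 0-based half-open) and `introns` (count).
oracle_enum_chains <- function(cds, region, min_intron = 40,
                               max_chains = 10000) {
  n <- nchar(cds); m <- nchar(region)
  cdsv <- strsplit(cds, "")[[1]]
  regv <- strsplit(region, "")[[1]]
  donors <- which(regv[-m] == "G" & regv[-1] == "T")            # 1-based
  acceptors <- which(regv[-m] == "A" & regv[-1] == "G") + 2     # pos after AG
  chains <- list()
  rec <- function(c0, g0, exon_start, exons) {
    # c0: cds chars consumed; g0: next 1-based genome pos
    if (length(chains) >= max_chains) return()
    if (c0 == n) {
      chains[[length(chains) + 1]] <<- list(
        exons = rbind(exons, c(exon_start - 1, g0 - 1)),
        introns = nrow(exons))
      return()
    }
    # option 1: extend the exon
    if (g0 <= m && regv[g0] == cdsv[c0 + 1]) {
      rec(c0 + 1, g0 + 1, exon_start, exons)
    }
    # option 2: open an intron (not before the first or after the last base)
    if (c0 >= 1 && c0 <= n - 1 && g0 > exon_start && (g0 %in% donors)) {
      for (a in acceptors[acceptors >= g0 + min_intron]) {
        if (a <= m && regv[a] == cdsv[c0 + 1]) {
          rec(c0 + 1, a + 1, a,
              rbind(exons, c(exon_start - 1, g0 - 1)))
        }
      }
    }
  }
  for (g0 in seq_len(m - n + 1)) {
    if (regv[g0] == cdsv[1]) {
      rec(1, g0 + 1, g0, matrix(numeric(0), ncol = 2))
    }
  }
  chains
}

# Minimum total loss magnitude over all monotone (child <= parent) internal
# labelings.  The root is free (<= ancestral); any drop from the ancestral
# count to the root label is charged once, on the (unobserved) root stem --
# the same accounting as the "(root)" events of the implementation.
oracle_min_loss_total <- function(tree, tip_counts, ancestral,
                                  values = 0:8) {
  ntip <- ape::Ntip(tree)
  internal <- setdiff(seq_len(ntip + tree$Nnode), seq_len(ntip))
  tipval <- rep(NA_real_, ntip + tree$Nnode)
  tipval[match(names(tip_counts), tree$tip.label)] <- tip_counts
  root <- ntip + 1L
  grid <- do.call(expand.grid, rep(list(values), length(internal)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- tipval
    lab[internal] <- as.numeric(grid[r, ])
    if (lab[root] > ancestral) next
    ok <- TRUE
    total <- ancestral - lab[root]
    for (e in seq_len(nrow(tree$edge))) {
      p <- lab[tree$edge[e, 1]]; c <- lab[tree$edge[e, 2]]
      if (is.na(c)) next
      if (c > p) { ok <- FALSE; break }
      total <- total + (p - c)
    }
    if (ok && total < best) best <- total
  }
  best
}
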