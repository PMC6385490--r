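# Shared sequence utilities: reverse complement, translation, IUPAC matching,
# seeded random sequence generation.  All coordinates in this package are
# 0-based half-open unless a function's documentation says otherwise.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case preserved as
#'   upper case).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("acgtn", "ACGTN", s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a coding sequence
#'
#' Translates `cds` with the standard genetic code.  A single terminal stop
#' codon is dropped; internal stop codons raise an error unless
#' `allow_stops = TRUE`, in which case they appear as `*`.
#'
#' @param cds A single DNA string whose length is a multiple of 3.
#' @param allow_stops Keep internal stops as `*` instead of erroring.
#' @return The amino-acid string.
#' @export
translate_cds <- function(cds, allow_stops = FALSE) {
  stopifnot(length(cds) == 1)
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length is not a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  if (substring(aa, nchar(aa)) == "*") aa <- substring(aa, 1, nchar(aa) - 1)
  if (!allow_stops && grepl("*", aa, fixed = TRUE)) {
    stop("internal stop codon in CDS")
  }
  aa
}

iupac_regex <- function(pattern, type) {
  syms <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (type == "dna") {
    cls <- vapply(syms, function(s) {
      set <- IUPAC_DNA[[s]]
      if (is.null(set)) stop("illegal IUPAC code: ", s)
      if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
    }, character(1))
  } else {
    cls <- vapply(syms, function(s) {
      if (s == "X") return(".")
      if (!s %in% AA_LETTERS) stop("illegal amino-acid code: ", s)
      s
    }, character(1))
  }
  paste(cls, collapse = "")
}

#' Match a degenerate IUPAC pattern against a sequence
#'
#' Finds all (possibly overlapping) occurrences of a degenerate nucleotide
#' pattern (IUPAC codes) or an amino-acid pattern in which `x` is a wildcard.
#' Matching is case-insensitive and on the given strand only.
#'
#' @param pattern Pattern string over IUPAC nucleotide codes (`type = "dna"`)
#'   or amino acids plus `x` (`type = "protein"`).
#' @param subject Subject sequence (single string).
#' @param type `"dna"` or `"protein"`.
#' @return Integer vector of 1-based match start positions (possibly empty).
#' @examples
#' match_iupac("CWCCC", "GCACCCG")       # 2
#' match_iupac("TGTTTRCWYW", "TGTTTACTTA")
#' @export
match_iupac <- function(pattern, subject, type = c("dna", "protein")) {
  type <- match.arg(type)
  stopifnot(length(pattern) == 1, length(subject) == 1)
  rx <- iupac_regex(pattern, type)
  m <- gregexpr(paste0("(?=", rx, ")"), toupper(subject), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Uniform random DNA of length n (uses the session RNG).
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Replace positions hit by uniform substitution at `rate` per site, never
# touching 1-based positions listed in `protect`.  Substituted bases are drawn
# uniformly from the three alternatives.
mutate_seq <- function(seq, rate, protect = integer(0)) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0) return(seq)
  hit <- which(runif(n) < rate)
  hit <- setdiff(hit, protect)
  if (length(hit) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hit) {
    alt <- DNA_BASES[DNA_BASES != chars[i]]
    chars[i] <- alt[sample.int(3, 1)]
  }
  paste(chars, collapse = "")
}

# Destroy accidental matches of a degenerate pattern, keeping any match that
# starts at a 1-based position in `keep`.  Used by the simulator so that a
# planted motif instance is the only one inside a scanned window.
scrub_motif <- function(seq, pattern, keep = integer(0), window = NULL) {
  repeat {
    hits <- match_iupac(pattern, seq)
    if (!is.null(window)) hits <- hits[hits >= window[1] & hits <= window[2]]
    hits <- setdiff(hits, keep)
    if (length(hits) == 0) return(seq)
    i <- hits[1]
    ch <- substring(seq, i, i)
    repl <- if (ch == "C") "G" else "C"
    substring(seq, i, i) <- repl
  }
}
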