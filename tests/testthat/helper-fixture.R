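# Shared fixtures, computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

get_fixture <- function() cached("fixture", fixture_clade())

get_fixture_run <- function() cached("fixture_run", run_pipeline(get_fixture()))

get_gene <- function() cached("gene", make_ancestral_gene(sim_params(seed = 7)))

# genomic body of the ancestral gene (exons interleaved with introns)
gene_body <- function(gene) {
  paste(mapply(function(e, i) paste0(e, i), gene$exon_seqs,
               c(gene$intron_seqs, list(""))), collapse = "")
}

fixture_tree <- function() read_newick(retrotrace:::FIXTURE_NEWICK)
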