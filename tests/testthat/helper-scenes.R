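# Shared synthetic fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# one small chromosome, a handful of genes: fast unit-test scene
scene_small <- function() fixture("scene_small", function()
  make_genome(genome_spec(n_chroms = 1, chrom_length = 5e5, n_genes = 6,
                          gene_length_range = c(4000, 12000), seed = 101)))

tracks_small <- function() fixture("tracks_small", function()
  make_tracks(scene_small(), seed = 101, timing_period = 2.5e5))

catalog_small <- function() fixture("catalog_small", function()
  make_catalog(scene_small(), tracks_small(),
               mutagenesis_spec(n_samples = 2, n_sbs = 500,
                                dbs_fraction = 0.02, id_fraction = 0.02,
                                seed = 101)))

# default-size scene shared by asymmetry tests
scene_default <- function() fixture("scene_default", function()
  make_genome(genome_spec(seed = 202)))

tracks_default <- function() fixture("tracks_default", function()
  make_tracks(scene_default(), seed = 202))

# naive per-record SBS96 re-classifier used as an independent oracle
naive_sbs96 <- function(catalog, genome) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  vapply(seq_len(nrow(catalog)), function(i) {
    if (nchar(catalog$ref[i]) != 1 || nchar(catalog$alt[i]) != 1)
      return(NA_character_)
    seq <- genome[[catalog$chrom[i]]]
    p <- catalog$pos[i]
    if (p < 2 || p > nchar(seq) - 1) return(NA_character_)
    tri <- substr(seq, p - 1, p + 1)
    if (grepl("[^ACGT]", tri)) return(NA_character_)
    ref <- catalog$ref[i]; alt <- catalog$alt[i]
    if (ref %in% c("A", "G")) {
      tri <- rc(tri); ref <- comp[[ref]]; alt <- comp[[alt]]
    }
    paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3))
  }, character(1))
}
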