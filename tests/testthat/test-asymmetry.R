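# Strand asymmetry. Oracles: hand-placed mutations in hand-placed genes
# (labels and counts enumerable by hand), the generator's latent truth
# labels, and exact density arithmetic on tiny grids.

# four genes on one chromosome; g3/g4 overlap on opposite strands
.hand_genes <- function() {
  gene_models(rep("c1", 4), c(101, 401, 601, 650), c(200, 500, 700, 750),
              c("+", "-", "+", "-"), paste0("g", 1:4), c(0.05, 5, 0.5, 0.5))
}

.hand_annotated <- function() {
  df <- data.frame(sample_id = "s", chrom = "c1",
                   pos = c(150, 160, 450, 470, 455, 300, 660, 900),
                   ref = c("C", "G", "C", "T", "A", "C", "C", "CC"),
                   alt = c("T", "A", "A", "G", "C", "G", "T", "AA"))
  annotate_strand(mutation_catalog(df), .hand_genes())
}

test_that("annotate_strand labels hand-placed mutations correctly", {
  ann <- .hand_annotated()
  expect_identical(ann$strand_label[1], "untranscribed")  # pyr C on + gene
  expect_identical(ann$strand_label[2], "transcribed")    # purine G on + gene
  expect_identical(ann$strand_label[3], "transcribed")    # pyr C on - gene
  expect_identical(ann$strand_label[4], "transcribed")    # pyr T on - gene
  expect_identical(ann$strand_label[5], "untranscribed")  # purine A on - gene
  expect_identical(ann$strand_label[6], "intergenic")
  expect_identical(ann$strand_label[7], "excluded")       # genes on both strands
  expect_true(is.na(ann$strand_label[8]))                 # DBS -> NA
  # pyrimidine-centric classes
  expect_identical(ann$sbs_class[1:5], c("C>T", "C>T", "C>A", "T>G", "T>G"))
  expect_identical(ann$gene_idx[1:6], c(1L, 1L, 2L, 2L, 2L, NA))
})

test_that("trb_by_class counts and tests match hand tallies", {
  tb <- trb_by_class(.hand_annotated())
  expect_identical(tb$class, c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  ct <- tb[tb$class == "C>T", ]
  expect_equal(ct$n_transcribed, 1)
  expect_equal(ct$n_untranscribed, 1)
  expect_equal(ct$ratio, 1)
  expect_equal(ct$p, poisson_pair_test(1, 1))
  ca <- tb[tb$class == "C>A", ]
  expect_equal(ca$n_transcribed, 1)
  expect_equal(ca$n_untranscribed, 0)
  expect_true(is.na(ca$ratio))
  expect_equal(ca$p, 1)                      # 1 vs 0: two-sided p = 1
  cg <- tb[tb$class == "C>G", ]
  expect_true(is.na(cg$ratio) && is.na(cg$p))
  # opportunity lengths change the tested expectation
  tb2 <- trb_by_class(.hand_annotated(), opportunity = c(3, 1))
  expect_equal(tb2$p[tb2$class == "C>T"], poisson_pair_test(1, 1, 3))
})

test_that("trb_by_expression bins genes and normalizes by bin length", {
  te <- trb_by_expression(.hand_annotated(), .hand_genes())
  expect_identical(te$bin, c("0-0.1", "0.1-1", "1-10", "10-20000"))
  b1 <- te[te$bin == "0-0.1", ]              # g1 only: 1 trans, 1 untrans
  expect_equal(b1$n_genes, 1)
  expect_equal(b1$length_mb, 100 / 1e6)
  expect_equal(b1$n_transcribed, 1)
  expect_equal(b1$n_untranscribed, 1)
  expect_equal(b1$density_transcribed, 1 / (100 / 1e6))
  expect_equal(b1$ratio, 1)
  b3 <- te[te$bin == "1-10", ]               # g2: 2 trans, 1 untrans
  expect_equal(b3$n_transcribed, 2)
  expect_equal(b3$n_untranscribed, 1)
  expect_equal(b3$ratio, 2)
  expect_equal(b3$p, poisson_pair_test(2, 1))
  b2 <- te[te$bin == "0.1-1", ]              # g3+g4 carry only excluded muts
  expect_equal(b2$n_genes, 2)
  expect_equal(b2$n_transcribed + b2$n_untranscribed, 0)
  b4 <- te[te$bin == "10-20000", ]           # empty bin -> NA row
  expect_equal(b4$n_genes, 0)
  expect_true(is.na(b4$ratio))
  expect_error(expression_bins(c(1, 1)), "increasing")
})

test_that("tss_profiles places strand-resolved counts in the right offsets", {
  genes <- gene_models("c1", 5001, 15000, "+", "gA", 1)
  df <- data.frame(sample_id = "s", chrom = "c1",
                   pos = c(5500, 5600, 4500, 1500, 20000),
                   ref = c("C", "G", "A", "C", "C"),
                   alt = c("T", "T", "C", "A", "T"))
  ann <- annotate_strand(mutation_catalog(df), genes)
  pr <- tss_profiles(ann, genes, flank = 4000, bin = 1000)
  expect_setequal(pr$offset, c(-4:-1, 1:4))
  expect_true(all(pr$length == 1000))
  expect_identical(unique(pr$side[pr$offset > 0]), "genic")
  expect_identical(unique(pr$side[pr$offset < 0]), "intergenic")
  cell <- function(off, cat) pr$count[pr$offset == off & pr$category == cat]
  # + gene: template strand is "-"; C (purine on -) -> purine_template
  expect_equal(cell(1, "purine_template"), 1)   # pos 5500, ref C
  expect_equal(cell(1, "purine_coding"), 1)     # pos 5600, ref G
  expect_equal(cell(-1, "purine_coding"), 1)    # pos 4500, ref A
  expect_equal(cell(-4, "purine_template"), 1)  # pos 1500, ref C
  expect_equal(sum(pr$count), 4)                # pos 20000 outside all bins
  expect_equal(pr$density, pr$count / pr$length)

  # mirrored geometry for a - gene (TSS at the right end)
  genesm <- gene_models("c1", 5001, 15000, "-", "gB", 1)
  dfm <- data.frame(sample_id = "s", chrom = "c1", pos = c(14500, 15500),
                    ref = c("C", "G"), alt = c("T", "T"))
  prm <- tss_profiles(annotate_strand(mutation_catalog(dfm), genesm),
                      genesm, flank = 4000, bin = 1000)
  cellm <- function(off, cat) prm$count[prm$offset == off & prm$category == cat]
  # - gene: template strand is "+"; ref C (purine -) -> coding; G -> template
  expect_equal(cellm(1, "purine_coding"), 1)    # 14001..15000 genic bin
  expect_equal(cellm(-1, "purine_template"), 1) # 15001..16000 upstream bin
})

test_that("build_timing_consensus averages, filters by sd, and bins", {
  grid <- GenomicRanges::GRanges("c1", IRanges::IRanges(seq(1, 3001, 1000),
                                                        width = 1000))
  a <- grid; a$score <- c(20, 50, 80, 100)
  b <- grid; b$score <- c(24, 50, 120, 100)
  cons <- build_timing_consensus(list(a, b))
  # window 3 dropped (sd 28 > 15); window 4 dropped (mean 100 out of range)
  expect_equal(length(cons), 2)
  expect_equal(cons$score, c(22, 50))
  expect_identical(as.character(cons$bin), c("[10,25]", "(40,55]"))
  bad <- GenomicRanges::GRanges("c1", IRanges::IRanges(seq(2, 3002, 1000),
                                                       width = 1000))
  bad$score <- 1:4
  expect_error(build_timing_consensus(list(a, bad)), "common grid")
  expect_error(build_timing_consensus(list(a)), ">= 2 tracks")
})

test_that("density_by_timing normalizes counts by genic/intergenic territory", {
  grid <- GenomicRanges::GRanges("c1", IRanges::IRanges(seq(1, 9001, 1000),
                                                        width = 1000))
  a <- grid; a$score <- 20
  cons <- build_timing_consensus(list(a, a))
  genes <- gene_models("c1", 2001, 4000, "+", "g", 1)
  df <- data.frame(sample_id = "s", chrom = "c1", pos = c(2500, 3000, 8000),
                   ref = c("G", "C", "C"), alt = c("A", "T", "A"))
  ann <- annotate_strand(mutation_catalog(df), genes)
  dd <- density_by_timing(ann, cons, genes)
  row <- function(cat) dd[dd$bin == "[10,25]" & dd$category == cat, ]
  expect_equal(row("transcribed")$count, 1)
  expect_equal(row("transcribed")$length, 2000)
  expect_equal(row("transcribed")$density, 1 / (2000 / 1e6))
  expect_equal(row("untranscribed")$count, 1)
  expect_equal(row("intergenic")$count, 1)
  expect_equal(row("intergenic")$length, 8000)
  expect_equal(row("intergenic")$density, 1 / (8000 / 1e6))
  # bins with no consensus territory report NA densities
  empty <- dd[dd$bin != "[10,25]", ]
  expect_true(all(is.na(empty$density)))
  expect_true(all(empty$count == 0))
})

test_that("fork_direction_bins filters discordance and bins on [-1, 1]", {
  grid <- GenomicRanges::GRanges("c1", IRanges::IRanges(seq(1, 2001, 1000),
                                                        width = 1000))
  a <- grid; a$score <- c(-0.8, 0.1, 0.6)
  b <- grid; b$score <- c(-0.6, 0.6, 0.7)
  fb <- fork_direction_bins(list(a, b))
  expect_equal(length(fb), 2)                # middle window discordant (0.5)
  expect_equal(fb$score, c(-0.7, 0.65))
  expect_identical(as.character(fb$bin), c("[-1,-0.5]", "(0.5,1]"))
  # single-track path keeps everything
  fb1 <- fork_direction_bins(list(a))
  expect_equal(length(fb1), 3)
})

test_that("replication_strand_bias tallies pyrimidine/purine references", {
  grid <- GenomicRanges::GRanges("c1", IRanges::IRanges(seq(1, 2001, 1000),
                                                        width = 1000))
  a <- grid; a$score <- c(-0.8, 0.1, 0.6)
  b <- grid; b$score <- c(-0.6, 0.6, 0.7)
  fb <- fork_direction_bins(list(a, b))
  df <- data.frame(sample_id = "s", chrom = "c1",
                   pos = c(100, 200, 300, 2100),
                   ref = c("C", "A", "G", "T"),
                   alt = c("T", "G", "T", "C"))
  rb <- replication_strand_bias(mutation_catalog(df), fb)
  all1 <- rb[rb$bin == "[-1,-0.5]" & rb$class == "all", ]
  expect_equal(all1$n_pyr, 1)
  expect_equal(all1$n_pur, 2)
  expect_equal(all1$ratio, 0.5)
  expect_equal(all1$p, poisson_pair_test(1, 2))
  all2 <- rb[rb$bin == "(0.5,1]" & rb$class == "all", ]
  expect_equal(all2$n_pyr, 1)
  expect_equal(all2$n_pur, 0)
  expect_true(is.na(all2$ratio))
  ct1 <- rb[rb$bin == "[-1,-0.5]" & rb$class == "C>T", ]
  expect_equal(ct1$n_pyr, 1)                 # C>T on the reference strand
  expect_equal(ct1$n_pur, 0)                 # G>T is C>A, not C>T
})

test_that("mark_quantile_density: exact densities on a 10-window grid", {
  grid <- GenomicRanges::GRanges("c1", IRanges::IRanges(seq(1, 9001, 1000),
                                                        width = 1000))
  mark <- grid; mark$score <- 1:10
  alig <- grid; alig$score <- 1
  genes <- gene_models("c1", 20001, 20100, "+", "far", 1)   # nothing overlaps
  df <- data.frame(sample_id = "s", chrom = "c1", pos = c(400, 500, 9500),
                   ref = "C", alt = "T")
  ann <- annotate_strand(mutation_catalog(df), genes)
  md <- mark_quantile_density(ann, mark, alig, categories = "intergenic")
  expect_equal(nrow(md), 5)
  expect_true(all(md$length == 2000))        # 10 windows into 5 equal groups
  expect_equal(md$count, c(2, 0, 0, 0, 1))   # scores sort windows in order
  overall <- 3 / 10000
  expect_equal(md$relative_density, (md$count / 2000) / overall)
  # length-weighted mean relative density is exactly 1
  expect_equal(sum(md$length * md$relative_density) / sum(md$length), 1)
  # alignability gap removes its window
  alig2 <- alig; alig2$score[3] <- 0
  md2 <- mark_quantile_density(ann, mark, alig2, categories = "intergenic")
  expect_equal(sum(md2$length), 9000)
  # degenerate marks warn
  mark3 <- grid; mark3$score <- 7
  expect_warning(mark_quantile_density(ann, mark3, alig,
                                       categories = "intergenic"),
                 "degenerate")
})

test_that("chromatin_state_density normalizes to a weighted mean of 1", {
  states <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 1001),
                                                          c(1000, 4000)))
  states$name <- c("X", "Y")
  df <- data.frame(sample_id = "s", chrom = "c1",
                   pos = c(100, 500, 900, 2000),
                   ref = "C", alt = "T")
  cd <- chromatin_state_density(mutation_catalog(df), states)
  # overall = 4/4000; X: (3/1000)/overall = 3; Y: (1/3000)/overall = 1/3
  expect_equal(cd$relative_density[cd$state == "X"], 3)
  expect_equal(cd$relative_density[cd$state == "Y"], 1 / 3)
  expect_equal(sum(cd$length * cd$relative_density) / sum(cd$length), 1)
})

test_that("simulated TRB catalog: labels match latent truth, ratio near 2", {
  scene <- scene_small()
  tracks <- tracks_small()
  ctl <- make_catalog(scene, tracks,
                      mutagenesis_spec(n_samples = 1, n_sbs = 4000,
                                       trb_factor = 2, seed = 7))
  ann <- annotate_strand(ctl, scene$genes)
  # annotation agrees with the generator's latent strand truth everywhere
  gen <- ann[ann$mut_class == "SBS" & !is.na(ann$xsim_template) &
               ann$strand_label %in% c("transcribed", "untranscribed"), ]
  expect_gt(nrow(gen), 100)
  expect_true(all((gen$strand_label == "untranscribed") == gen$xsim_template))
  itg <- ann[ann$strand_label %in% "intergenic", ]
  expect_true(all(!itg$xsim_template, na.rm = TRUE))
  # aggregate transcribed/untranscribed ratio estimates the repair fold (2)
  tb <- trb_by_class(ann)
  ratio <- sum(tb$n_transcribed) / sum(tb$n_untranscribed)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
  # strand-resolved signature refit runs and returns per-group fractions
  sw <- suppressWarnings(
    strandwise_signature_contrast(ann, scene$genes, example_signatures(),
                                  scene$genome, min_mutations = 20))
  expect_equal(nrow(sw), 8)                  # 2 strands x 2 activities x K=2
  agg <- tapply(sw$fraction, paste(sw$strand, sw$activity), sum)
  expect_true(all(is.na(agg) | abs(agg - 1) < 1e-8))
})

test_that("simulated replication bias: lagging boost shows the right sign", {
  scene <- scene_small()
  tracks <- tracks_small()
  ctl <- make_catalog(scene, tracks,
                      mutagenesis_spec(n_samples = 1, n_sbs = 4000,
                                       replication_factor = 2, seed = 8))
  # truth: accepted lesions are lagging-enriched at 2:1
  lag <- mean(ctl$xsim_lagging[!is.na(ctl$xsim_lagging)])
  expect_gt(lag, 0.55)
  expect_lt(lag, 0.8)
  fb <- fork_direction_bins(tracks$fork)
  rb <- replication_strand_bias(ctl, fb)
  allr <- rb[rb$class == "all", ]
  lo <- allr$ratio[allr$bin == "[-1,-0.5]"]
  hi <- allr$ratio[allr$bin == "(0.5,1]"]
  # purine lesions pile onto the lagging strand: pyr/pur ratio rises from
  # lagging-reference to leading-reference fork bins
  expect_lt(lo, 1)
  expect_gt(hi, 1)
})
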