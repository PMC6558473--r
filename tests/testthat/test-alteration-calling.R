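make_muts <- function(classes, scores = rep(NA_real_, length(classes))) {
  n <- length(classes)
  data.frame(sample_id = rep("S1", n), gene = sprintf("G%d", seq_len(n)),
             chrom = rep("chr1", n), pos = seq_len(n), ref = rep("G", n),
             alt = rep("A", n), variant_class = classes, score = scores,
             stringsAsFactors = FALSE)
}

make_seg <- function(sample_id, chrom, start, end, log2) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             log2_ratio = log2, n_probes = NA_integer_, stringsAsFactors = FALSE)
}

toy_genes <- data.frame(gene = c("CCND1", "CDKN2A"),
                        chrom = c("chr11", "chr9"),
                        start = c(1000L, 5000L), end = c(2000L, 6000L),
                        stringsAsFactors = FALSE)

test_that("nonsilent filter retains exactly the protein-altering classes", {
  expect_equal(nrow(filter_nonsilent(make_muts("silent"))), 0)
  m <- make_muts(c("nonsynonymous_SNV", "splicing", "silent", "stopgain"))
  expect_equal(nrow(filter_nonsilent(m)), 3)
  # brute-force per-class tally on a 20-row mixed list
  set.seed(7)
  classes <- sample(c("nonsynonymous_SNV", "frameshift_indel", "inframe_indel",
                      "stopgain", "stoploss", "splicing", "silent", "other"),
                    20, replace = TRUE)
  m <- make_muts(classes)
  expect_equal(nrow(filter_nonsilent(m)),
               sum(!classes %in% c("silent", "other")))
})

test_that("pathogenic filter is inclusive at the threshold and drops unscored", {
  m <- make_muts(rep("nonsynonymous_SNV", 3), scores = c(0.07, 0.069, NA))
  kept <- filter_pathogenic(m, 0.07)
  expect_equal(kept$score, 0.07)
  # linear-scan oracle on a mixed list
  set.seed(11)
  scores <- c(runif(15), rep(NA, 5))[sample(20)]
  classes <- rep(c("nonsynonymous_SNV", "silent"), 10)
  m <- make_muts(classes, scores)
  kept <- filter_pathogenic(m, 0.3)
  oracle <- which(classes != "silent" & !is.na(scores) & scores >= 0.3)
  expect_equal(as.integer(rownames(kept)), oracle)
  # boundary behaviors of the threshold argument
  all_scored <- filter_pathogenic(m, 0)
  expect_equal(nrow(all_scored), sum(classes != "silent" & !is.na(scores)))
  expect_error(filter_pathogenic(m, 1.5), "threshold")
})

test_that("TMB is count of nonsilent mutations per Mb and is linear", {
  expect_equal(compute_tmb(make_muts(character(0)), 38), 0)
  m81 <- make_muts(rep("nonsynonymous_SNV", 81))
  expect_equal(compute_tmb(m81, 50), 1.62)
  m <- make_muts(c(rep("nonsynonymous_SNV", 4), rep("silent", 3), "other"))
  expect_equal(compute_tmb(m, 38), 4 / 38)
  # linearity over disjoint lists
  a <- make_muts(rep("stopgain", 5)); b <- make_muts(rep("splicing", 7))
  expect_equal(compute_tmb(rbind(a, b), 38),
               compute_tmb(a, 38) + compute_tmb(b, 38))
  expect_error(compute_tmb(m, 0), "exome_size_mb")
})

test_that("gene CNV calls use strict thresholds and max-|log2| segments", {
  cfg <- calling_config()
  one <- function(log2) {
    seg <- make_seg("S1", "chr11", 900L, 2100L, log2)
    call_gene_cnv(seg, toy_genes, cfg)
    }
  get_state <- function(log2, gene = "CCND1") {
    calls <- one(log2)
    calls$state[calls$gene == gene]
  }
  expect_equal(get_state(0.81), "amplified")
  expect_equal(get_state(0.8), "neutral")     # > 0.8 is strict
  expect_equal(get_state(-0.8), "neutral")    # < -0.8 is strict
  expect_equal(get_state(-0.81), "deleted")
  # threshold strictness down to representable precision
  eps <- .Machine$double.eps * 2
  expect_equal(get_state(0.8 + 1e-12), "amplified")
  expect_equal(get_state(0.8 * (1 + eps)), "amplified")
  # max-|log2| wins regardless of input order
  segs <- rbind(make_seg("S1", "chr11", 900L, 2100L, 0.5),
                make_seg("S1", "chr11", 950L, 2050L, -1.0))
  c1 <- call_gene_cnv(segs, toy_genes, cfg)
  c2 <- call_gene_cnv(segs[2:1, ], toy_genes, cfg)
  expect_equal(c1$state[c1$gene == "CCND1"], "deleted")
  expect_equal(c1, c2)
  # genes without overlap are neutral with supporting 0
  calls <- one(1.0)
  expect_equal(calls$state[calls$gene == "CDKN2A"], "neutral")
  expect_equal(calls$supporting_log2[calls$gene == "CDKN2A"], 0)
  # 1 bp overlap suffices; abutting half-open intervals do not overlap
  seg_abut <- make_seg("S1", "chr11", 2000L, 3000L, 1.0)
  calls <- call_gene_cnv(seg_abut, toy_genes, cfg)
  expect_equal(calls$state[calls$gene == "CCND1"], "neutral")
  seg_1bp <- make_seg("S1", "chr11", 1999L, 3000L, 1.0)
  calls <- call_gene_cnv(seg_1bp, toy_genes, cfg)
  expect_equal(calls$state[calls$gene == "CCND1"], "amplified")
  expect_error(call_gene_cnv(seg_1bp, toy_genes[0, ], cfg), "empty gene model")
})

test_that("arm summaries match a per-base coverage oracle on a 1 kb toy arm", {
  arm <- data.frame(chrom = "chrT", start = 0L, end = 1000L, arm = "Tp",
                    stringsAsFactors = FALSE)
  cfg <- calling_config()
  cases <- list(
    list(s = 0L, e = 1000L, l = -1.0),                    # full-arm loss
    list(s = 0L, e = 400L, l = 1.0),                      # 40% gain -> neutral
    list(s = c(0L, 300L, 700L), e = c(350L, 600L, 1000L), # mosaic
         l = c(0.9, -1.2, 0.6)),
    list(s = c(0L, 100L, 500L), e = c(600L, 700L, 1000L), # overlapping gains
         l = c(0.5, 0.8, -0.4))
  )
  for (cs in cases) {
    seg <- make_seg("S1", "chrT", cs$s, cs$e, cs$l)
    got <- summarize_arms(seg, arm, cfg)
    exp <- arm_call_oracle(cs$s, cs$e, cs$l, 0, 1000)
    expect_equal(got$call, exp$call)
    expect_equal(got$gain_fraction, exp$gain_frac)
    expect_equal(got$loss_fraction, exp$loss_frac)
  }
  expect_error(summarize_arms(make_seg("S1", "chrZ", 0L, 10L, 1), arm, cfg),
               "chrZ")
})

test_that("profiles merge evidence per sample with empty sides allowed", {
  mut <- data.frame(sample_id = c("A", "A", "B"), gene = c("PIK3CA", "TTN", "TP53"),
                    chrom = "chr1", pos = 1:3, ref = "G", alt = "A",
                    variant_class = c("nonsynonymous_SNV", "silent",
                                      "nonsynonymous_SNV"),
                    score = c(0.5, NA, NA), stringsAsFactors = FALSE)
  cnv <- data.frame(sample_id = c("C", "C"), gene = c("CDKN2A", "CCND1"),
                    state = c("deleted", "neutral"),
                    supporting_log2 = c(-1, 0.2), stringsAsFactors = FALSE)
  prof <- build_profiles(mut, cnv)
  expect_equal(names(prof), c("A", "B", "C"))
  expect_equal(length(prof$A$cnv), 0)
  expect_equal(nrow(prof$A$mutations), 1)   # silent row dropped
  expect_equal(prof$A$tmb, 1 / 38)
  expect_equal(nrow(prof$C$mutations), 0)
  expect_equal(unname(prof$C$cnv["CDKN2A"]), "deleted")
  expect_equal(prof$C$tmb, 0)
  # hand-assembled 3-sample expectation
  expect_equal(prof$B$mutations$gene, "TP53")
  # pathogenic-only mode drops unscored qualifying mutations
  prof2 <- build_profiles(mut, cnv, pathogenic_only = TRUE)
  expect_equal(nrow(prof2$B$mutations), 0)
  expect_equal(nrow(prof2$A$mutations), 1)
})
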