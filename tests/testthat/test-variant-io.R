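maf_header <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
                "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                "Variant_Classification", "ParsSNP_Score")

test_that("mutation reader maps MAF vocabulary and handles empty/odd files", {
  # header only -> empty table
  p <- write_raw_maf(setNames(data.frame(matrix(ncol = 8, nrow = 0)), maf_header))
  expect_equal(nrow(read_mutations(p)), 0)

  # single-row direct field mapping
  p <- write_raw_maf(data.frame(
    Tumor_Sample_Barcode = "S1", Hugo_Symbol = "PIK3CA", Chromosome = "chr3",
    Start_Position = 178936091, Reference_Allele = "G", Tumor_Seq_Allele2 = "A",
    Variant_Classification = "Missense_Mutation", ParsSNP_Score = 0.59))
  m <- read_mutations(p)
  expect_equal(nrow(m), 1)
  expect_equal(m$variant_class, "nonsynonymous_SNV")
  expect_equal(m$score, 0.59)
  expect_equal(m$pos, 178936091L)

  # 5-row toy with one Silent row; class counts match an independent scan
  labels <- c("Missense_Mutation", "Silent", "Frame_Shift_Del",
              "Nonsense_Mutation", "Splice_Site")
  p <- write_raw_maf(data.frame(
    Tumor_Sample_Barcode = paste0("S", 1:5), Hugo_Symbol = "TP53",
    Chromosome = "chr17", Start_Position = 1:5, Reference_Allele = "G",
    Tumor_Seq_Allele2 = "A", Variant_Classification = labels,
    ParsSNP_Score = ""))
  m <- read_mutations(p)
  expect_equal(nrow(m), 5)
  expect_equal(sum(m$variant_class == "silent"),
               sum(grepl("\tSilent\t", readLines(p)[-1])))
  expect_equal(m$variant_class,
               c("nonsynonymous_SNV", "silent", "frameshift_indel",
                 "stopgain", "splicing"))
  expect_true(all(is.na(m$score)))
})

test_that("mutation reader errors name the problem and unknown labels warn", {
  df <- data.frame(Tumor_Sample_Barcode = "S1", Hugo_Symbol = "TP53",
                   Chromosome = "17", Start_Position = 10,
                   Reference_Allele = "G", Tumor_Seq_Allele2 = "A",
                   Variant_Classification = "Missense_Mutation")
  expect_error(read_mutations(write_raw_maf(df[, -4])), "Start_Position")
  bad <- df; bad$Start_Position <- "xyz"
  expect_error(read_mutations(write_raw_maf(bad)), "line")
  same <- df; same$Tumor_Seq_Allele2 <- "G"
  expect_error(read_mutations(write_raw_maf(same)), "allele")
  odd <- df; odd$Variant_Classification <- "Weird_Label"
  expect_warning(m <- read_mutations(write_raw_maf(odd)), "Weird_Label")
  expect_equal(m$variant_class, "other")
  # chromosome style is normalized
  m <- read_mutations(write_raw_maf(df))
  expect_equal(m$chrom, "chr17")
})

test_that("SEG reader converts 1-based inclusive to 0-based half-open and sorts", {
  seg_df <- data.frame(sample = c("S2", "S1", "S1", "S2"),
                       chromosome = c("chr9", "chr9", "chr1", "chr1"),
                       loc.start = c(21967752, 100, 500, 7),
                       loc.end = c(22009313, 200, 900, 50),
                       num.mark = c(10, 5, 8, 2),
                       seg.mean = c(-1.2, 0.3, 0.1, -0.5))
  p <- write_raw_maf(seg_df)
  s <- read_segments(p)
  # the documented coordinate example
  r <- s[s$sample_id == "S2" & s$chrom == "chr9", ]
  expect_equal(r$start, 21967751L)
  expect_equal(r$end, 22009313L)
  expect_equal(r$log2_ratio, -1.2)
  # manual ordering oracle: sorted by (sample, chrom, start)
  key <- paste(s$sample_id, s$chrom, sprintf("%012d", s$start))
  expect_equal(key, sort(key))
  expect_equal(nrow(s), 4)
  # empty file after header
  p0 <- write_raw_maf(seg_df[0, ])
  expect_equal(nrow(read_segments(p0)), 0)
  # degenerate interval errors with a line number
  bad <- seg_df; bad$loc.end[1] <- bad$loc.start[1] - 1
  expect_error(read_segments(write_raw_maf(bad)), "line")
})

test_that("coordinate conversion is involutive and IO round-trips exactly", {
  fx <- npc_fixture()
  d <- withr::local_tempdir()
  mp <- file.path(d, "m.tsv"); sp <- file.path(d, "s.seg")
  cp <- file.path(d, "c.tsv")
  write_mutations(fx$mutations, mp)
  write_segments(fx$segments, sp)
  write_clinical(fx$clinical, cp)
  expect_equal(read_mutations(mp), fx$mutations)
  expect_equal(read_segments(sp), fx$segments)
  expect_equal(read_clinical(cp), fx$clinical)
  # SEG -> internal -> SEG is the identity on the file level
  sp2 <- file.path(d, "s2.seg")
  write_segments(read_segments(sp), sp2)
  expect_identical(readLines(sp), readLines(sp2))
  # reader output is deterministic for a fixed file
  expect_identical(read_segments(sp), read_segments(sp))
})

test_that("gene model reader assigns arms by midpoint and rejects duplicates", {
  d <- withr::local_tempdir()
  bed <- file.path(d, "g.bed"); armp <- file.path(d, "a.tsv")
  genes <- data.frame(gene = c("CCND1", "HRAS", "EDGE"),
                      chrom = c("chr11", "chr11", "chr11"),
                      start = c(69455855L, 50000L, 53690000L),
                      end = c(69469242L, 60000L, 53710001L))
  arms <- data.frame(chrom = "chr11", start = c(0L, 53700000L),
                     end = c(53700000L, 135086622L), arm = c("11p", "11q"))
  write_gene_model(genes, arms, bed, armp)
  gm <- read_gene_model(bed, armp)
  expect_equal(gm$arm[gm$gene == "CCND1"], "11q")
  expect_equal(gm$arm[gm$gene == "HRAS"], "11p")
  # EDGE midpoint = 53700000 (floor of 53700000.5): first base of 11q under
  # the half-open rule
  expect_equal(gm$arm[gm$gene == "EDGE"], "11q")
  # hand lookup for the packaged model
  pk <- npc_gene_model()
  expect_equal(pk$genes$arm[pk$genes$gene == "CDKN2A"], "9p")
  expect_equal(pk$genes$arm[pk$genes$gene == "CCND1"], "11q")
  expect_equal(pk$genes$arm[pk$genes$gene == "KRAS"], "12p")
  # duplicate symbols rejected, listing the duplicate
  dup <- rbind(genes, genes[1, ])
  write_gene_model(dup, arms, bed, armp)
  expect_error(read_gene_model(bed, armp), "CCND1")
})

test_that("clinical reader collapses stage, enforces time/event pairing", {
  d <- withr::local_tempdir()
  p <- file.path(d, "clin.tsv")
  df <- data.frame(sample_id = paste0("S", 1:6),
                   age_years = c(47, 60, "", 33, 52, 41),
                   sex = c("male", "F", "", "male", "female", "M"),
                   stage = c("III", "I", "", "IV", "II", "advanced"),
                   who_class = c("NKUC", "", "KSCC", "NKUC", "NKDC", "NKUC"),
                   os_months = c(48, "", 20, 60, 10, 33),
                   os_event = c(1, "", 0, 1, 1, 0),
                   pfs_months = c(31, 5, 12, 45, 8, 22),
                   pfs_event = c(1, 1, 0, 0, 1, 1))
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- read_clinical(p)
  expect_equal(cl$stage, c("advanced", "early", NA, "advanced", "early", "advanced"))
  expect_equal(cl$pfs_months[1], 31)
  expect_equal(cl$pfs_event[1], 1L)
  expect_true(is.na(cl$os_months[2]) && is.na(cl$os_event[2]))
  expect_equal(cl$sex, c("male", "female", NA, "male", "female", "male"))
  # manual median oracle on the toy PFS column
  expect_equal(median(cl$pfs_months), median(c(31, 5, 12, 45, 8, 22)))
  # violations are row-level errors
  bad <- df; bad$os_event[3] <- ""
  utils::write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clinical(p), "together")
  bad <- df; bad$pfs_months[2] <- -1
  utils::write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clinical(p), "negative")
  bad <- df; bad$pfs_event[2] <- 2
  utils::write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clinical(p), "0/1")
})
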