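toy_quant_data <- function() {
  tx <- c("ENST00000000001.1", "ENST00000000002.3", "ENST00000000003.2")
  tpm <- matrix(c(7.5e5, 2.0e5, 0.5e5,
                  6.0e5, 3.0e5, 1.0e5), 3,
                dimnames = list(tx, c("sA", "sB")))
  eff <- matrix(c(100, 300, 500, 120, 280, 520), 3,
                dimnames = list(tx, c("sA", "sB")))
  reads <- matrix(c(600, 300, 100, 450, 400, 150), 3,
                  dimnames = list(tx, c("sA", "sB")))
  list(tx = tx, tpm = tpm, eff = eff, reads = reads,
       len = c(150, 350, 550))
}

test_that("salmon quant files are parsed and realigned by transcript name", {
  d <- toy_quant_data()
  dir <- withr::local_tempdir()
  paths <- write_toy_quants(dir, d$tpm, d$eff, d$reads, d$len)
  q <- read_salmon_quant(paths)
  expect_s3_class(q, "TranscriptQuantSet")
  expect_identical(q$transcript_ids, d$tx)
  expect_equal(q$tpm, d$tpm)
  expect_equal(q$est_reads, d$reads)
  expect_equal(unname(q$length), d$len)

  # second file written in reversed order: rows must realign by Name, so
  # every cell matches a per-cell lookup into the original tables
  paths2 <- write_toy_quants(file.path(dir, "re"), d$tpm, d$eff, d$reads,
                             d$len, reorder_sample = 2)
  q2 <- read_salmon_quant(paths2)
  for (t in d$tx) for (s in c("sA", "sB")) {
    expect_identical(q2$tpm[t, s], d$tpm[t, s])
    expect_identical(q2$est_reads[t, s], d$reads[t, s])
  }
})

test_that("malformed quantification inputs are rejected with clear errors", {
  d <- toy_quant_data()
  dir <- withr::local_tempdir()
  paths <- write_toy_quants(dir, d$tpm, d$eff, d$reads, d$len)
  # drop the TPM column from one file
  tab <- read.delim(paths[1])
  write.table(tab[, setdiff(colnames(tab), "TPM")], paths[1], sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_salmon_quant(paths), "TPM")

  # transcript sets differing across samples
  paths <- write_toy_quants(dir, d$tpm, d$eff, d$reads, d$len)
  tab <- read.delim(paths[2])
  tab$Name[1] <- "ENST9999.1"
  write.table(tab, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_salmon_quant(paths), "differ")

  # non-positive effective length
  paths <- write_toy_quants(dir, d$tpm, d$eff, d$reads, d$len)
  tab <- read.delim(paths[2])
  tab$EffectiveLength[2] <- 0
  write.table(tab, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_salmon_quant(paths), "EffectiveLength")
})

write_toy_gtf <- function(path, rows) {
  writeLines(rows, path)
  path
}

gtf_row <- function(gene, tx, type = "transcript", start = 1, end = 1000) {
  sprintf(
    "chr1\ttest\t%s\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    type, start, end, gene, tx)
}

test_that("tx2gene tables come out of GTF annotations with ntx filled", {
  gtf <- file.path(withr::local_tempdir(), "toy.gtf")
  write_toy_gtf(gtf, c(gtf_row("G1", "T1"), gtf_row("G1", "T2"),
                       gtf_row("G2", "T3")))
  t2g <- build_tx2gene(gtf)
  expect_equal(nrow(t2g), 3)
  expect_equal(t2g$ntx[match(c("T1", "T2", "T3"), t2g$transcript_id)],
               c(2L, 2L, 1L))

  # versioned GENCODE-style identifiers are retained verbatim
  gtf2 <- file.path(withr::local_tempdir(), "v.gtf")
  write_toy_gtf(gtf2, c(gtf_row("ENSG00000000003.14", "ENST00000612152.4")))
  t2g2 <- build_tx2gene(gtf2)
  expect_identical(t2g2$transcript_id, "ENST00000612152.4")
  expect_identical(t2g2$gene_id, "ENSG00000000003.14")

  # one transcript under two genes is inconsistent
  gtf3 <- file.path(withr::local_tempdir(), "dup.gtf")
  write_toy_gtf(gtf3, c(gtf_row("G1", "T1"), gtf_row("G2", "T1")))
  expect_error(build_tx2gene(gtf3), "more than one gene")
})

test_that("counts-from-abundance follows the per-sample rescaling rules", {
  d <- toy_quant_data()
  dir <- withr::local_tempdir()
  q <- read_salmon_quant(write_toy_quants(dir, d$tpm, d$eff, d$reads, d$len))

  # proportional scaling: TPM 750000/250000 with 1000 mapped reads
  tx2 <- c("TA.1", "TB.1")
  tpm2 <- matrix(c(7.5e5, 2.5e5), 2, 1, dimnames = list(tx2, "s1"))
  q2 <- list(transcript_ids = tx2, sample_ids = "s1", tpm = tpm2,
             eff_length = matrix(c(200, 200), 2, 1,
                                 dimnames = list(tx2, "s1")),
             est_reads = matrix(c(800, 200), 2, 1,
                                dimnames = list(tx2, "s1")),
             length = c(250, 250))
  class(q2) <- "TranscriptQuantSet"
  cm2 <- counts_from_abundance(q2, "scaledTPM")
  expect_equal(unname(cm2$counts[, 1]), c(750, 250))

  # spreadsheet-style oracle applying the two formulas cell by cell
  mapped <- colSums(d$reads)
  for (mode in c("scaledTPM", "lengthScaledTPM")) {
    cm <- counts_from_abundance(q, mode)
    ab <- d$tpm
    if (mode == "lengthScaledTPM") ab <- ab * rowMeans(d$eff)
    for (s in 1:2) for (t in 1:3) {
      expect_equal(unname(cm$counts[d$tx[t], s]),
                   unname(ab[t, s] / sum(ab[, s]) * mapped[s]),
                   tolerance = 1e-12)
    }
    # each column sums to the mapped-read total
    expect_equal(unname(colSums(cm$counts)), unname(mapped),
                 tolerance = 1e-9)
  }

  # equal mean effective length for all transcripts: the two modes agree
  qe <- q
  qe$eff_length[] <- 250
  expect_equal(counts_from_abundance(qe, "lengthScaledTPM")$counts,
               counts_from_abundance(qe, "scaledTPM")$counts,
               tolerance = 1e-12)

  # raw mode is the identity on rows that are not all zero
  cr <- counts_from_abundance(q, "raw")
  expect_equal(cr$counts, d$reads[rowSums(d$reads) > 0, ])

  # zero total TPM makes the rescaling undefined
  qz <- q
  qz$tpm[, 1] <- 0
  expect_error(counts_from_abundance(qz, "scaledTPM"), "zero total TPM")
})

test_that("gene summarization sums counts and weights effective lengths", {
  tx <- c("T1.1", "T2.1", "T3.1")
  tpm <- matrix(c(4e5, 4e5, 2e5, 3e5, 3e5, 4e5), 3,
                dimnames = list(tx, c("s1", "s2")))
  eff <- matrix(c(100, 300, 200, 100, 300, 200), 3,
                dimnames = list(tx, c("s1", "s2")))
  reads <- matrix(c(40, 120, 40, 30, 90, 80), 3,
                  dimnames = list(tx, c("s1", "s2")))
  q <- list(transcript_ids = tx, sample_ids = c("s1", "s2"), tpm = tpm,
            eff_length = eff, est_reads = reads, length = c(150, 350, 250))
  class(q) <- "TranscriptQuantSet"
  map <- data.frame(transcript_id = tx, gene_id = c("G1", "G1", "G2"))
  g <- summarize_to_gene(q, map, "raw")
  # gene counts are sums of member transcripts
  expect_equal(unname(g$counts["G1", ]), unname(colSums(reads[1:2, ])))
  expect_equal(unname(g$counts["G2", ]), unname(reads[3, ]))
  # mass conservation
  expect_equal(colSums(g$counts), colSums(reads))
  # equal TPM, lengths 100/300: offset is the plain mean 200
  expect_equal(unname(g$offsets["G1", "s1"]), 200)
  # weighted-mean oracle on the mixed-weight sample
  w <- tpm[1:2, "s2"] / sum(tpm[1:2, "s2"])
  expect_equal(unname(g$offsets["G1", "s2"]),
               sum(w * eff[1:2, "s2"]))
  # single-transcript gene: offset equals its effective length
  expect_equal(unname(g$offsets["G2", ]), unname(eff[3, ]))
  # zero-TPM gene in a sample falls back to the unweighted mean
  q0 <- q
  q0$tpm[1:2, "s1"] <- 0
  g0 <- summarize_to_gene(q0, map, "raw")
  expect_equal(unname(g0$offsets["G1", "s1"]), mean(eff[1:2, "s1"]))
  # unmapped transcript errors
  expect_error(summarize_to_gene(q, map[-1, ], "raw"), "absent")
})

test_that("quant files round-trip bit-for-bit through write and read", {
  params <- sim_params(n_genes = 30, seed = 5)
  sim <- simulate_counts(simulate_truth(params))
  dir <- withr::local_tempdir()
  paths <- write_quant_files(sim$quants, dir)
  expect_identical(strsplit(readLines(paths[1], n = 1), "\t")[[1]],
                   c("Name", "Length", "EffectiveLength", "TPM", "NumReads"))
  q <- read_salmon_quant(paths)
  expect_equal(q$tpm, sim$quants$tpm)
  expect_equal(q$est_reads, sim$quants$est_reads)
})
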