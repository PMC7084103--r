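#!/usr/bin/env Rscript
# Step 6 (optional, requires downloaded data): the same pipeline applied to
# a real proteome. Nothing here runs unless the user has placed the inputs
# below under data-raw/ — none are bundled and none are downloaded by this
# script:
#   data-raw/cds.fasta      coding sequences (e.g. ENA records, one per gene)
#   data-raw/aaindex1.txt   AAindex1 flat file of property scales
#   data-raw/categories.tsv two columns (accession, category), optional
#   data-raw/orthologs.tsv  two id columns pairing a second proteome, optional

suppressMessages(library(frameshiftr))

needed <- c("data-raw/cds.fasta", "data-raw/aaindex1.txt")
if (!all(file.exists(needed))) {
  cat("real-data inputs not found (see header); skipping.\n")
  quit(status = 0)
}

dir.create("results/real", recursive = TRUE, showWarnings = FALSE)
cds <- read_cds_fasta("data-raw/cds.fasta")
categories <- NULL
if (file.exists("data-raw/categories.tsv")) {
  ct <- read.table("data-raw/categories.tsv", sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  categories <- setNames(ct[[2]], ct[[1]])
}
lib <- read_aaindex("data-raw/aaindex1.txt", categories = categories)
cat(sprintf("inputs: %d CDS, %d scales\n", length(cds), length(lib)))

pairs <- enumerate_frameshift_pairs(standard_code(), "+1")
null <- sample_null(pairs, n_samples = 1e6, seed = 1)
ugc <- scan_scale_library(lib, pairs, null)
write.table(ugc, "results/real/ugc_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

res <- proteome_scale_pvalues(cds, lib, "+1", n_null = 1e5, seed = 2)
write.table(res, "results/real/proteome_scan_p1.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
enr <- category_enrichment(res, p_cutoff = 0.05)
write.table(enr, "results/real/enrichment_p1.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/real/\n")
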