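#!/usr/bin/env Rscript
# Step 5: properties beyond hydrophobicity-like scales.
# (a) mRNA purine-density vs protein affinity-profile matching across
#     frames (the mRNA side is frame-invariant);
# (b) net-charge relation between wild-type and +1-frameshifted proteins
#     (frameshifting inverts charge patterns);
# (c) frameshift stability of externally supplied disorder profiles.

suppressMessages(library(frameshiftr))

dir.create("results", showWarnings = FALSE)
cds <- read_cds_fasta("results/synthetic/cds.fasta")
lib <- read_scales_tsv("results/synthetic/scales.tsv")

# (a) use the strongest planted scale as the affinity probe
scan <- read.table("results/proteome_scan_p1.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
probe <- lib[[scan$name[which.max(scan$median_R)]]]
match_tab <- data.frame(id = names(cds), stringsAsFactors = FALSE)
for (frame in c("wt", "+1", "-1")) {
  r <- mrna_protein_matching(cds, probe, frame)
  match_tab[[paste0("R_", sub("^\\+", "p", sub("^-", "m", frame)))]] <-
    unname(r[match_tab$id])
  cat(sprintf("PUR-density vs %s protein profile: median R = %.3f (n = %d)\n",
              frame, median(r), length(r)))
}
write.table(match_tab, "results/mrna_matching.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# (b) net charge of wild type vs +1 variant
wt_charge <- vapply(cds, function(x) net_charge(wildtype_translate(x)),
                    numeric(1))
p1_charge <- vapply(cds, function(x)
  net_charge(frameshift_translate(x, "+1")), numeric(1))
cat(sprintf("net charge wt vs +1: R = %.3f\n", cor(wt_charge, p1_charge)))
write.table(data.frame(id = names(cds), wt = wt_charge, p1 = p1_charge),
            "results/net_charge.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# (c) disorder stand-ins: per-protein profile correlation and
#     structured/unstructured agreement at the 0.5 cutoff
dis_wt <- read_disorder_tsv("results/synthetic/disorder_wt.tsv")
dis_p1 <- read_disorder_tsv("results/synthetic/disorder_p1.tsv")
ids <- intersect(names(dis_wt), names(dis_p1))
dis <- t(vapply(ids, function(id) {
  res <- disorder_stability(dis_wt[[id]], dis_p1[[id]])
  c(R = res$R, mean_wt = res$mean_wt, mean_p1 = res$mean_shifted,
    agreement = res$agreement)
}, numeric(4)))
write.table(data.frame(id = ids, dis), "results/disorder_stability.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("disorder: median profile R = %.3f, median agreement = %.3f (n = %d)\n",
            median(dis[, "R"], na.rm = TRUE), median(dis[, "agreement"]),
            length(ids)))
cat("(independent synthetic disorder draws: R near 0 is the expected outcome;\n")
cat(" real predictor profiles depend on the sequence and correlate.)\n")
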