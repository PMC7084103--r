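#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs — a 500-gene proteome with a
# proteome-like length distribution, a 100-scale property library with one
# planted frameshift-stable category, and stand-in per-residue disorder
# profiles. All downstream steps read these files from results/synthetic/.

suppressMessages(library(frameshiftr))

out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

code <- standard_code()
pairs <- enumerate_frameshift_pairs(code, "+1")

proteome <- generate_proteome(proteome_spec(n_genes = 500, seed = 2001))
write_fasta(proteome$cds, file.path(out_dir, "cds.fasta"))
write_fasta(proteome$protein, file.path(out_dir, "protein_wt.fasta"))
cat(sprintf("proteome: %d genes, mean protein length %.0f residues, GC %.3f\n",
            length(proteome$cds), mean(nchar(proteome$protein)),
            mean(strsplit(paste(proteome$cds, collapse = ""), "")[[1]] %in%
                   c("G", "C"))))

lib <- generate_scale_library(
  scale_library_spec(n_categories = 5, scales_per_category = 20,
                     rho = 0.5, seed = 2002),
  pairs)
write_scales_tsv(lib, file.path(out_dir, "scales.tsv"))
cat(sprintf("scale library: %d scales in %d categories (planted: stable)\n",
            length(lib), length(unique(sapply(lib, scale_category)))))

disorder <- generate_disorder_profiles(proteome$protein, smoothness = 11,
                                       seed = 2003)
write_disorder_tsv(disorder, file.path(out_dir, "disorder_wt.tsv"))
shifted <- vapply(proteome$cds, frameshift_translate, character(1),
                  frame = "+1")
write_fasta(shifted, file.path(out_dir, "protein_p1.fasta"))
write_disorder_tsv(generate_disorder_profiles(shifted, smoothness = 11,
                                              seed = 2004),
                   file.path(out_dir, "disorder_p1.tsv"))
cat("wrote synthetic inputs under", out_dir, "\n")
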