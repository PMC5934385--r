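#!/usr/bin/env Rscript
# Stage 2: sample-level QC (plate call rates, inbreeding/IBS kinship, MDS
# outliers) followed by marker-level QC (exact HWE, missingness, MAF) on the
# simulated inputs. Writes the removal ledgers and the retained genotype set.

suppressMessages(library(adpgx))

samples <- read_samples("results/data/samples.tsv")
geno <- read_genotypes("results/data/genotypes.vcf")

sq <- sample_qc(geno, samples)
mq <- marker_qc(sq$genotypes)

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
write.table(sq$removed, "results/qc/samples_removed.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mq$removed, "results/qc/markers_removed.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mq$stats, "results/qc/marker_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(plate = names(sq$report$plate_rates),
                       pass_rate = sq$report$plate_rates),
            "results/qc/plate_rates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_genotypes_tsv(mq$genotypes, "results/qc/retained_genotypes.tsv")
write_samples(samples[samples$sample_id %in% rownames(mq$genotypes$dosage), ],
              "results/qc/retained_samples.tsv")

cat(sprintf("samples: %d in, %d removed (%s)\n", nrow(samples),
            nrow(sq$removed),
            if (nrow(sq$removed)) paste(unique(sq$removed$reason),
                                        collapse = ",") else "none"))
cat(sprintf("markers: %d in, %d removed, %d retained\n",
            ncol(geno$dosage), nrow(mq$removed), ncol(mq$genotypes$dosage)))
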