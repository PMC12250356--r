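#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with a known ground truth.
#
# Two read libraries (male and female of one karyomorph, 150 bp
# single-end) carrying two satDNA families: "autoSat", neutral, and
# "ySat", accumulated 3x in males with five male-exclusive monomer
# haplotypes (the signature of a repeat expanding in the non-recombining
# region of a Y chromosome). Alongside, a DArT-style SNP genotype matrix
# for 5 males and 5 females with four perfectly male-linked (XY) loci
# planted among 1000 null loci.

suppressPackageStartupMessages(library(sexsatkit))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

families <- list(
  sat_family_spec("autoSat", rul = 32, n_variants = 3,
                  mutation_rate = 0.05, array_copies_per_genome = 120,
                  sex_bias = c(karF_male = 1, karF_female = 1)),
  sat_family_spec("ySat", rul = 28, n_variants = 3,
                  mutation_rate = 0.05, array_copies_per_genome = 120,
                  sex_bias = c(karF_male = 3, karF_female = 1),
                  exclusive_haplotypes = c(karF_male = 5)))

sim <- simulate_sat_reads(families, read_length = 150,
                          n_reads_per_library = 1200, seed = seed,
                          background_bp = 20000)
for (lib in names(sim$reads))
  write_fastq(sim$reads[[lib]], file.path(out, paste0(lib, ".fastq")))
write_fasta(Biostrings::DNAStringSet(unlist(sim$truth$families)),
            file.path(out, "catalog.fasta"))
write_tsv(sim$truth$haplotypes, file.path(out, "truth_haplotypes.tsv"))
write_tsv(data.frame(haplotype_id = rownames(sim$truth$copy_counts),
                     sim$truth$copy_counts, check.names = FALSE),
          file.path(out, "truth_copy_counts.tsv"))

gt <- simulate_genotypes(genotype_sim_spec(1000, 5, 5, het_prob = 0.35,
                                           n_planted_xy = 4, seed = seed + 1))
write_genotype_csv(gt$matrix, file.path(out, "genotypes.csv"))
write_sexmap_csv(gt$sexmap, file.path(out, "sexmap.csv"))
writeLines(gt$truth$xy_loci, file.path(out, "truth_xy_loci.txt"))

cat("Simulated", length(sim$reads), "libraries of",
    length(sim$reads[[1]]), "reads;",
    nrow(sim$truth$haplotypes), "planted haplotypes",
    sprintf("(%d male-exclusive);",
            sum(!is.na(sim$truth$haplotypes$exclusive_to))),
    "genotype matrix", nrow(gt$matrix), "x", ncol(gt$matrix),
    "with", length(gt$truth$xy_loci), "planted XY loci.\n")
cat("Outputs in", out, "\n")
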