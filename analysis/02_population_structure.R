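#!/usr/bin/env Rscript
# Stage 2: quality control, LD pruning and population structure.
#
# Applies the SNP filters (depth >= 3, missingness < 10%, MAF > 5%), prunes
# linked markers (25-SNP windows, step 5, r^2 > 0.05), then summarizes
# structure with PCA on standardized genotypes and a neighbor-joining tree
# of 1 - IBS allele-sharing distances. Run 01_simulate.R first.

suppressMessages(library(woolscan))

fix <- "results/fixture"
out <- "results/structure"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tab <- read_vcf(file.path(fix, "sample.vcf"))
popmap <- read_popmap(file.path(fix, "popmap.tsv"))
cat("Loaded", n_sites(tab), "SNPs,", length(tab$samples), "samples\n")

qc <- apply_qc_filters(tab)
cnt <- attr(qc, "qc_counts")
cat(sprintf("QC: %d genotypes masked, %d sites dropped (missingness), %d (MAF); %d retained\n",
            cnt$masked_genotypes, cnt$dropped_missing, cnt$dropped_maf,
            n_sites(qc)))

kept <- ld_prune(qc)
pruned <- subset_sites(qc, kept)
cat("LD pruning kept", length(kept), "of", n_sites(qc), "SNPs\n")

pca <- pca_genotypes(pruned)
coords <- data.frame(sample = rownames(pca$coords),
                     population = popmap$population[
                       match(rownames(pca$coords), popmap$sample)],
                     group = popmap$group[
                       match(rownames(pca$coords), popmap$sample)],
                     pca$coords[, 1:4])
write.table(coords, file.path(out, "pca_coords.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(component = seq_along(pca$varfrac),
                       variance_fraction = pca$varfrac),
            file.path(out, "pca_varfrac.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCA: PC1 explains %.2f%%, PC2 %.2f%% of the variance\n",
            100 * pca$varfrac[1], 100 * pca$varfrac[2]))

dm <- allele_sharing_distance(pruned)
tree <- neighbor_joining(dm)
write_newick(tree, file.path(out, "nj_tree.nwk"))
grp <- popmap$group[match(tree$tip.label, popmap$sample)]
cat("N-J tree written; tips per group:",
    paste(names(table(grp)), table(grp), collapse = ", "), "\n")

# the two wool groups should separate on PC1 with this much drift
sep <- tapply(coords$PC1, coords$group, mean)
cat(sprintf("Mean PC1 by group: F = %.3f, C = %.3f\n", sep["F"], sep["C"]))
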