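#!/usr/bin/env Rscript
# Stage 3: co-expression modules on the cohort.
#
# Restricts the cohort to genes also retained by the DE stage (the common
# gene universe), builds the unsigned soft-threshold network (power 6, the
# convention for cohorts with > 40 samples), computes the topological
# overlap matrix, cuts the average-linkage tree at 0.9, and summarizes each
# module by its eigengene, correlated against the clinical traits.

library(netprior)

expr <- read_matrix_tsv("results/sim/cohort_expr.tsv")
traits <- read_tsv("results/sim/traits.tsv")
de <- read_tsv("results/de_genes.tsv")

universe <- intersect_gene_universe(de$gene_id, rownames(expr))
expr_u <- expr[universe, ]
message("gene universe: ", length(universe), " genes in both data sets")

tom <- topological_overlap(adjacency_matrix(expr_u, power = 6))
partition <- cluster_modules(1 - tom, min_module_size = 20, cut_height = 0.9)
eig <- module_eigengenes(expr_u, partition)
mt <- module_trait_cor(eig$me, traits)

write_tsv(data.frame(gene_id = names(partition),
                     module = as.integer(partition)), "results/modules.tsv")
write_matrix_tsv(eig$me, "results/eigengenes.tsv", id_col = "module")
write_tsv(mt, "results/module_trait.tsv")

message(attr(partition, "n_modules"), " modules detected (",
        sum(partition == 0), " genes unassigned, ME0)")
sig <- mt[mt$significant & mt$module != "ME0", ]
for (i in seq_len(nrow(sig)))
  message(sprintf("  %s ~ %s: r = %+.2f (p = %.2g)", sig$module[i],
                  sig$trait[i], sig$r[i], sig$p[i]))
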