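#!/usr/bin/env Rscript
# Stage 4: binomial enrichment scoring and candidate prioritization.
#
# If resistance had nothing to do with the cohort's co-expression structure,
# the top-10% DE genes would spread uniformly over modules. Each module is
# scored by the upper-tail binomial probability of its observed top-gene
# count at background rate q = 0.1; the score is -ln(p). Top genes inside
# enriched modules become the candidate ranking, ordered by module score
# then |log2FC|.

library(netprior)

part_tab <- read_tsv("results/modules.tsv")
partition <- setNames(as.integer(part_tab$module), part_tab$gene_id)
de <- read_tsv("results/de_genes.tsv")
top <- de$gene_id[de$top_flag]
mt <- read_tsv("results/module_trait.tsv")

enr <- score_modules(partition, top, mt, q = 0.1, alpha = 0.05)
ranking <- prioritize_genes(enr, partition, de, top)
write_tsv(enr, "results/enrichment.tsv")
write_tsv(ranking, "results/ranking.tsv")

for (i in which(enr$enriched))
  message(sprintf("ME%d enriched: %d/%d top genes (-ln p = %.1f, tumor r = %+.2f)",
                  enr$module[i], enr$k[i], enr$n[i], enr$score[i],
                  enr$tumor_r[i]))
message(nrow(ranking), " candidate genes; top 3: ",
        paste(head(ranking$gene_id, 3), collapse = ", "))
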