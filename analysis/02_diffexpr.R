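#!/usr/bin/env Rscript
# Stage 2: gene-level differential expression.
#
# Selects one representative transcript per protein-coding gene (the most
# expressed isoform), computes log2 fold-changes (resistant / parental,
# pseudocount 1 FPKM), filters low-expression and extreme-signal outliers,
# and flags the top 10% of genes by |log2FC| -- the gene set the enrichment
# stage tests against the co-expression modules.

library(netprior)

tx <- read_tsv("results/sim/transcripts.tsv")
de <- filter_outliers(gene_de_table(tx, pseudocount = 1))
top <- top_fraction(de, q = 0.1)
de$top_flag <- de$gene_id %in% top
write_tsv(de, "results/de_genes.tsv")

message(nrow(tx), " transcripts -> ", nrow(de),
        " protein-coding genes after filtering")
message(length(top), " top-10% genes by |log2FC|; |log2FC| range ",
        sprintf("%.2f..%.2f", min(abs(de$log2fc[de$top_flag])),
                max(abs(de$log2fc[de$top_flag]))))
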