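#!/usr/bin/env Rscript
# Structure the signature into modules of correlated profiles: k-means
# under correlation distance, with the cluster count taken from the size of
# the minimal-mu list (stage 02).

source("analysis/00_config.R")

data <- read_expression(file.path(data_dir, "matrix.tsv"),
                        file.path(data_dir, "labels.tsv"),
                        positive_class = "case",
                        negative_class = "control")
sig <- read_signature(file.path(results_dir, "signature.tsv"))
mu_tab <- read.delim(file.path(results_dir, "mu_path.tsv"))
k <- min(mu_tab$signature_size[1], nrow(sig))

profiles <- t(sparsesig:::dataset_raw(data)[, sig$variable_id,
                                            drop = FALSE])
cl <- kmeans_correlation(profiles, k = k, seed = master_seed)
print(cl)

truth <- read.delim(file.path(data_dir, "truth.tsv"))
assign_tab <- data.frame(variable_id = names(cl$cluster),
                         cluster = unname(cl$cluster),
                         block = truth$block[match(names(cl$cluster),
                                                   truth$variable_id)])
write.table(assign_tab, file.path(results_dir, "clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("clustered %d signature profiles into %d modules (mean within-cluster correlation distance %.3f)",
                nrow(profiles), k, cl$within_mean_distance))
message("block vs cluster cross-table (planted blocks should align with modules):")
print(table(block = assign_tab$block, cluster = assign_tab$cluster))
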