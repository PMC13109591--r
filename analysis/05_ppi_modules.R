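#!/usr/bin/env Rscript
# Stage 5 — DEG-seeded protein-interaction network and Markov clustering.
#
# Simulates a STRING-style interactome with planted communities over the
# gene universe (differentially expressed genes mapped onto nodes first),
# builds the DEG-seeded induced network at combined score >= 400, expands
# it by first- and second-order interactors, partitions it with MCL, and
# validates the modules as gene sets by pre-ranked GSEA per contrast.

library(dantx)

de_dir <- "results/de"
if (!file.exists(file.path(de_dir, "de_PDvsH.tsv")))
  stop("run analysis/03_differential_expression.R first")
out <- "results/ppi"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 505

tables <- lapply(c(PDvsH = "PDvsH", LvsH = "LvsH", PvsH = "PvsH",
                   LvsP = "LvsP"),
                 function(nm) read.delim(file.path(de_dir,
                                                   paste0("de_", nm, ".tsv"))))
deg_union <- unique(unlist(lapply(tables, function(t)
  unlist(threshold_degs(t)))))
universe <- tables$PDvsH$gene
message("DEG union: ", length(deg_union), " genes")

pp <- simulate_ppi(n_nodes = min(120, 3 * length(deg_union)),
                   n_communities = 3, p_within = 0.4, p_between = 0.02,
                   seed = seed)
pool <- c(deg_union, setdiff(universe, deg_union))
nodes <- sort(unique(c(pp$edges$node1, pp$edges$node2)))
map <- setNames(pool[seq_along(nodes)], nodes)
edges <- data.frame(node1 = map[pp$edges$node1], node2 = map[pp$edges$node2],
                    combined_score = pp$edges$combined_score)
write_edges(edges, file.path(out, "ppi_edges.tsv"))

seeds_present <- intersect(deg_union, c(edges$node1, edges$node2))
net <- build_seeded_network(edges, seeds_present, threshold = 400)
net <- expand_network(net, edges, order = 2, max_added = 50, threshold = 400)
message("network after expansion: ", length(net$nodes), " nodes, ",
        nrow(net$edges), " edges")

part <- mcl(net, inflation = 2)
write.table(data.frame(node = names(part$membership),
                       module = part$membership),
            file.path(out, "ppi_modules.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("MCL modules: ", length(part$modules), " (sizes ",
        paste(lengths(part$modules), collapse = ", "), ")")

ranked <- lapply(tables, make_ranked_list)
gsea <- tryCatch(
  suppressWarnings(validate_modules_gsea(part, ranked, min_size = 5,
                                         n_perm = 1000, seed = seed + 1)),
  error = function(e) NULL)
if (!is.null(gsea)) {
  write.table(gsea, file.path(out, "ppi_module_gsea.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message("module x contrast tests: ", nrow(gsea), "; FDR < 0.05: ",
          sum(gsea$padj < 0.05))
}
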