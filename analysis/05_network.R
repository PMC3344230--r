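#!/usr/bin/env Rscript
# Stage 5 — reticulate origin network for the P. cadieri complex.
#
# Runs the diploids-first reconstruction on the transcribed 11-taxon
# observation table: infer the allele -> haplotype maternal map (morphs 5
# and 6 exempt), hypothesize homozygous diploid progenitors, derive
# candidate sexual tetraploids, and search for the cross assignment
# minimising the number of presumed taxa.

suppressPackageStartupMessages(library(reticulator))
dir.create("results", showWarnings = FALSE)

fx <- cadieri_observations()
s <- observation_summary(fx$observations)
cat(sprintf("observed complex: %d taxa, %d alleles (%s), %d haplotype groups\n",
            s$n_taxa, s$n_alleles, paste(s$alleles, collapse = ", "),
            s$n_haplotype_groups))

map <- infer_allele_haplotype_map(fx$observations, fx$exempt)
cat("maternal map (allele -> haplotype):\n")
print(map$map)
write.table(data.frame(allele = names(map$map), haplotype = unname(map$map)),
            "results/maternal_map.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

net <- infer_network(fx$observations, map)
cat(sprintf("network: %d crosses, %d presumed taxa, %d co-optimal assignments\n",
            nrow(net$crosses), net$cost, length(net$co_optimal)))
cat(sprintf("presumed nodes: %s\n", paste(net$presumed_nodes, collapse = ", ")))
if (length(net$unexplained))
  cat(sprintf("unexplained taxa: %s\n", paste(net$unexplained, collapse = ", ")))

edges <- net$crosses[, c("offspring", "mother", "mother_gamete",
                         "father", "father_gamete",
                         "mother_status", "father_status")]
write.table(edges, "results/network_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(edges, row.names = FALSE)

# ambiguity report: taxa whose maternal parent differs across co-optima
amb <- vapply(unique(net$crosses$offspring), function(id) {
  mothers <- unique(vapply(net$co_optimal, function(tab)
    tab$mother[tab$offspring == id], ""))
  length(mothers) > 1
}, TRUE)
if (any(amb))
  cat(sprintf("maternal lineage ambiguous across co-optima: %s\n",
              paste(names(amb)[amb], collapse = ", ")))

# co-optimal networks, one edge table each
dir.create("results/co_optimal", showWarnings = FALSE)
for (i in seq_along(net$co_optimal)) {
  write.table(net$co_optimal[[i]][, names(edges)],
              sprintf("results/co_optimal/network_%02d.tsv", i),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat(sprintf("co-optimal edge tables -> results/co_optimal/ (%d files)\n",
            length(net$co_optimal)))

# human-readable scenario report
rep_lines <- c(
  sprintf("Reticulate origin scenario for the %d-taxon complex", s$n_taxa),
  sprintf("Presumed taxa (%d): %s", net$cost,
          paste(net$presumed_nodes, collapse = ", ")),
  "",
  vapply(seq_len(nrow(edges)), function(i) {
    e <- edges[i, ]
    sprintf("%s  <-  %s (gamete %s)  x  %s (gamete %s)", e$offspring,
            e$mother, e$mother_gamete, e$father, e$father_gamete)
  }, ""),
  "",
  if (any(amb)) sprintf("Maternal lineage ambiguous across co-optima: %s",
                        paste(names(amb)[amb], collapse = ", ")) else
    "Maternal lineages unambiguous across co-optima.")
writeLines(rep_lines, "results/scenario_report.txt")
cat("scenario report -> results/scenario_report.txt\n")

rp <- regional_partition(net, fx$observations)
write.table(rp$alleles, "results/regional_alleles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
priv <- rp$alleles[rp$alleles$private, ]
cat(sprintf("region-private alleles: %s\n",
            paste(sprintf("%s (%s)", priv$item, priv$regions), collapse = ", ")))
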