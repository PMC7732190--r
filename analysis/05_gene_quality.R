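#!/usr/bin/env Rscript
# Gene-quality ranking by monophyly score, and its effect on topology
# recovery. A 20-gene set with a built-in quality gradient (best genes:
# short terminals, long internals) is simulated; each gene's tree is
# inferred (parsimony random-addition start + NNI under LG+F+G) and
# scored by how many reference clades it recovers as monophyletic. The
# inferred ranking is compared to the true gradient, and recovery is
# re-run with the generating branch lengths scaled to the best-end and
# worst-end regimes.

suppressMessages(library(lbazone))
dir.create("results", showWarnings = FALSE)

bb <- make_backbone()            # felsenstein arrangement
pair <- make_backbone_pair()
mixture <- make_profile_set(20, 0.2, seed = 7)
gen <- synth_model(mixture)
hom <- site_model("LG", "empirical", discrete_gamma(0.8, 4))

cfg <- gene_set_config(n_genes = 20, sites_per_gene = 500)
genes <- make_gene_set(bb, cfg, gen, seed = 41)
mr <- monophyly_rank(genes, backbone_reference_clades(bb), hom,
                     seed = 42, tol = 0.5)

true_rank <- vapply(genes, `[[`, numeric(1), "true_rank")
rho <- cor(mr$scores$rank, true_rank, method = "spearman")
cat("Spearman correlation, inferred monophyly rank vs true quality rank:",
    round(rho, 3), "\n")
write.table(cbind(mr$scores, true_rank = true_rank),
            "results/gene_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# Recovery under best-end vs worst-end generating regimes (Felsenstein
# arrangement, homogeneous inference): better genes resist the artifact
scale_pair <- function(ts, is) {
  lapply(pair, lbazone:::scale_tree_edges, terminal_scale = ts,
         internal_scale = is)
}
rows <- list()
for (pool in c("best", "worst")) {
  sc <- if (pool == "best") c(0.5, 1.5) else c(2.0, 0.5)
  cands <- candidate_set(scale_pair(sc[1], sc[2]))
  rec <- recovery_experiment(cands, "felsenstein", gen,
                             list(homogeneous = hom),
                             n_replicates = 15, n_sites = 2000,
                             seed = 43, tol = 0.05, stratum = pool)
  cat(sprintf("%-5s-gene regime: %3.0f%% correct under the homogeneous model\n",
              pool, 100 * recovery_rate(rec, "homogeneous")))
  rows[[pool]] <- rec
}
write.table(do.call(rbind, rows), "results/gene_pool_recovery.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote results/gene_scores.tsv, results/gene_pool_recovery.tsv\n")
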