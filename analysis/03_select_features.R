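#!/usr/bin/env Rscript
# Step 3 — two-step feature selection for the tremor target.
#
# Step one removes redundancy: any feature pair with |Pearson r| > 0.97
# keeps only the earlier column. Step two ranks the survivors by
# random-forest impurity importance, keeps the top 60%, then adds features
# greedily in ranking order, retaining one only if the 5-fold
# cross-validated R2 strictly improves.
#
# Writes: results/selection.json

library(pdsense)

ft_csv <- read.csv("results/features.csv", check.names = FALSE)
x <- as.matrix(ft_csv[, -1])
info <- jsonlite::read_json("results/features.info.json",
                            simplifyVector = TRUE)
y <- info$labels$tremor

pr <- prune_correlated(x)
cat("correlation pruning: ", ncol(x), " -> ", length(pr$retained),
    " features\n", sep = "")

ranked <- rank_and_cut(x[, pr$retained], y, seed = 1)
cat("importance ranking kept top 60%:", length(ranked), "features\n")

sel <- greedy_forward_select(x, y, ranked, model_spec = model_spec("rf"),
                             seed = 1, max_features = 40)
cat("greedy forward retention:", length(sel$retained), "features;",
    "final CV R2:", round(max(sel$cv_trace$score[sel$cv_trace$retained]), 3),
    "\n")
cat("top retained:", head(sel$retained, 5), sep = "\n  ")

jsonlite::write_json(
  list(n_input = ncol(x), n_pruned = length(pr$retained),
       n_ranked = length(ranked), retained = sel$retained,
       cv_trace = sel$cv_trace),
  "results/selection.json", dataframe = "rows", digits = NA, auto_unbox = TRUE)
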