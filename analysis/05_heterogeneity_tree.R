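#!/usr/bin/env Rscript

# Stage 5 — characterize who benefits from which pattern.
#
# Grows a conditional inference tree with the predicted optimal pattern as
# the outcome and all covariates as predictors, showing the covariate
# profile behind each recommendation (in the default truth: stroke first,
# then age / sex / BP-class structure).

library(paoptim)

cohort <- read_participants_csv("results/cohort.csv")
profiles <- read.csv("results/counterfactual_profiles.csv")

d <- cohort
d$optimal <- factor(profiles$optimal, levels = pa_patterns())
tree <- grow_cit(d, outcome = "optimal",
                 predictors = names(default_covariates()),
                 alpha = 0.05, min_node = 200, max_depth = 3)
print(tree)

pred <- cit_predict(tree, d)
acc <- mean(pred$majority == d$optimal)
cat(sprintf("\nLeaf-majority accuracy on the training cohort: %.1f%%\n",
            100 * acc))

# flat serialization of the tree for downstream rendering
flatten <- function(node, path = "root") {
  base <- data.frame(
    id = node$id, path = path, n = node$n,
    split_var = if (is.null(node$split)) NA else node$split$var,
    split_p_adj = if (is.null(node$split)) NA else node$split$p_adj,
    t(as.numeric(node$dist))
  )
  names(base)[6:9] <- paste0("share_", names(node$dist))
  if (is.null(node$split)) return(base)
  rbind(base,
        flatten(node$children[[1]], paste0(path, "/yes")),
        flatten(node$children[[2]], paste0(path, "/no")))
}
write.csv(flatten(tree$root), "results/heterogeneity_tree.csv",
          row.names = FALSE)
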